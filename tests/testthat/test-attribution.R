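test_that("attention maps have the input shape and are non-negative", {
  b <- tinyBundle()
  g <- tinyPanel()
  a <- AIOpred:::.encodeAll(g, 16)[[1]]
  for (m in c("gradient", "gradcam")) {
    am <- attentionMap(b, a, method = m)
    expect_identical(dim(am@intensities), c(16L, 16L))
    expect_true(all(am@intensities >= 0))
  }
})

test_that("a head with zero weights yields an all-zero attention map", {
  b <- tinyBundle()
  b@weights$Wd2[] <- 0
  g <- tinyPanel()
  a <- AIOpred:::.encodeAll(g, 16)[[1]]
  am <- attentionMap(b, a, method = "gradient")
  expect_true(all(am@intensities == 0))
})

test_that("gradient maps equal the channel-max absolute input derivative", {
  # the backpropagated input derivative itself is validated against finite
  # differences on smooth inputs in the network tests; here the map must be
  # its per-pixel channel-max absolute value by definition
  b <- tinyBundle()
  g <- tinyPanel()
  a <- AIOpred:::.encodeAll(g, 16)[[1]]
  bs <- b@dictionary@blockSide
  f <- computeFeatures(sparseCode(extractBlocks(a, bs), b@dictionary))
  am <- attentionMap(b, a, features = f, method = "gradient")
  sal <- AIOpred:::.cnn_saliency(aioPixels(a), as.numeric(f), b@weights)
  ref <- pmax(abs(sal$dx[, , 1]), abs(sal$dx[, , 2]), abs(sal$dx[, , 3]))
  expect_equal(am@intensities, ref)
  expect_gt(max(am@intensities), 0)
})

test_that("per-SNP aggregation matches a brute-force pixel average", {
  set.seed(13)
  m <- matrix(rexp(20), 4, 5)
  am <- new("AttentionMap", intensities = m, accession = "a",
            method = "gradient")
  sc <- aggregateToSnps(list(am), nSnps = 10)
  idx <- snpPixelIndex(5, 4, 10)
  brute <- vapply(1:10, function(k) mean(m[idx == k]), numeric(1))
  expect_equal(unname(sc[, 1]), brute)

  cst <- new("AttentionMap", intensities = matrix(2.5, 4, 5),
             accession = "a", method = "gradient")
  expect_equal(unname(aggregateToSnps(list(cst), 10)[, 1]), rep(2.5, 10))

  ind <- matrix(0, 4, 5); ind[idx == 3] <- 1
  im <- new("AttentionMap", intensities = ind, accession = "a",
            method = "gradient")
  expect_equal(unname(aggregateToSnps(list(im), 10)[, 1]),
               as.numeric(1:10 == 3))
})

test_that("Dunnett selection recovers planted high-importance SNPs exactly", {
  set.seed(1)
  imp <- rbind(matrix(rnorm(5 * 50, 10, 0.5), 5),
               matrix(rnorm(95 * 50, 1, 0.5), 95))
  rownames(imp) <- sprintf("s%03d", 1:100)
  sel <- dunnettSelect(imp, alpha = 0.05)
  expect_identical(which(sel@table$selected), 1:5)
  expect_true(all(sel@table$p_adj[1:5] < 1e-3))
})

test_that("Dunnett statistics and p-values match the multcomp oracle", {
  skip_if_not_installed("multcomp")
  set.seed(7)
  n <- 12; m <- 4
  groups <- sapply(1:m, function(k) rnorm(n, mean = c(0, 0.3, 0.8, 0)[k]))
  control <- rnorm(n * 3)
  mine <- AIOpred:::.dunnettCore(groups, control, side = "greater", seed = 3)
  df <- data.frame(y = c(control, as.vector(groups)),
                   g = factor(rep(c("ctl", paste0("t", 1:m)),
                                  c(length(control), rep(n, m))),
                              levels = c("ctl", paste0("t", 1:m))))
  or <- summary(multcomp::glht(stats::aov(y ~ g, df),
                               linfct = multcomp::mcp(g = "Dunnett"),
                               alternative = "greater"))
  expect_equal(unname(mine$statistic), unname(as.numeric(or$test$tstat)),
               tolerance = 1e-8)
  expect_equal(unname(mine$p_adj), unname(as.numeric(or$test$pvalues)),
               tolerance = 5e-3)
})

test_that("identical scores produce an empty selection with a warning", {
  imp <- matrix(1, 10, 6)
  expect_warning(sel <- dunnettSelect(imp), "identical")
  expect_false(any(sel@table$selected))
})

test_that("the top-k cap limits a large selection", {
  set.seed(2)
  imp <- rbind(matrix(rnorm(8 * 40, 10, 0.3), 8),
               matrix(rnorm(42 * 40, 1, 0.3), 42))
  sel <- dunnettSelect(imp, alpha = 0.05, topK = 3)
  expect_identical(sum(sel@table$selected), 3L)
})

test_that("genotype-class t-tests behave at both extremes", {
  set.seed(17)
  codes <- cbind(rep(c(0L, 2L), each = 30),             # strong separation
                 rep(0L, 60),                           # monomorphic
                 sample(0:2, 60, replace = TRUE))       # null
  colnames(codes) <- c("strong", "mono", "null")
  rownames(codes) <- sprintf("a%02d", 1:60)
  g <- GenotypeSet(codes)
  y <- rnorm(60)
  y[codes[, 1] == 2] <- y[codes[, 1] == 2] + 5          # N(0,1) vs N(5,1)
  traitValues(g, "trait") <- stats::setNames(y, rownames(codes))
  tt <- genotypeClassTTest(g)
  expect_lt(tt$min_p[1], 1e-10)
  expect_false(tt$testable[2])
  expect_true(is.na(tt$min_p[2]))
  expect_gt(tt$min_p[3], 1e-4)
})

test_that("selections export to TSV and 0-based half-open BED", {
  set.seed(3)
  imp <- rbind(matrix(rnorm(2 * 30, 8, 0.3), 2),
               matrix(rnorm(18 * 30, 1, 0.3), 18))
  rownames(imp) <- sprintf("s%02d", 1:20)
  map <- data.frame(chrom = "Ca1", pos = seq(1000, by = 50, length.out = 20),
                    snp_id = rownames(imp))
  sel <- dunnettSelect(imp, snpMap = map)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  exportSelection(sel, tsv = tsv, bed = bed)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), 20L)
  b <- read.delim(bed, header = FALSE)
  expect_identical(nrow(b), 2L)
  expect_identical(b$V3 - b$V2, c(1L, 1L))
  expect_identical(b$V2, c(999L, 1049L))
})
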