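test_that("allele frequencies track the MAF setting without structure", {
  g <- simulateGenotypes(500, 80, mafRange = c(0.5, 0.5), seed = 19)
  codes <- genoCodes(g)
  freq <- colMeans(codes) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 500))
  expect_true(all(abs(freq - 0.5) < 3.5 * se))
  expect_false(anyNA(codes))
})

test_that("missingness and seeding behave as configured", {
  g1 <- simulateGenotypes(40, 60, missingRate = 0.1, seed = 23)
  expect_equal(mean(is.na(genoCodes(g1))), 0.1, tolerance = 0.01)
  g2 <- simulateGenotypes(40, 60, missingRate = 0.1, seed = 23)
  expect_identical(genoCodes(g1), genoCodes(g2))
  g3 <- simulateGenotypes(40, 60, missingRate = 0.1, seed = 24)
  expect_false(identical(genoCodes(g1), genoCodes(g3)))
})

test_that("h2 = 1 gives an exactly linear trait; h2 targets are realised", {
  g <- simulateGenotypes(60, 50, seed = 29)
  gp <- simulatePhenotype(g, nCausal = 5, h2 = 1, seed = 30)
  gt <- groundTruth(gp)
  X <- genoCodes(gp)[, gt$causalIndex]
  expect_equal(unname(traitValues(gp)),
               unname(gt$offset + gt$scale * as.numeric(X %*% gt$beta)))
  expect_equal(gt$h2Realised, 1)

  big <- simulateGenotypes(2000, 50, seed = 31)
  bp <- simulatePhenotype(big, nCausal = 10, h2 = 0.5, seed = 32)
  expect_lt(abs(groundTruth(bp)$h2Realised - 0.5), 0.03)
})

test_that("trait ranges and count traits are emulated", {
  g <- simulateGenotypes(120, 80, seed = 33)
  gp <- simulatePhenotype(g, nCausal = 10, h2 = 0.8,
                          traitRange = c(110, 440), seed = 34)
  y <- traitValues(gp)
  expect_equal(unname(range(y)), c(110, 440))

  gc <- simulatePhenotype(g, nCausal = 10, h2 = 0.8, traitRange = c(0, 88),
                          integerTrait = TRUE, traitName = "snpp", seed = 35)
  yc <- traitValues(gc, "snpp")
  expect_true(all(yc == round(yc) & yc >= 0 & yc <= 88))
})

test_that("population structure separates accessions in PC space", {
  g <- simulateGenotypes(90, 400, nSubpops = 3, fst = 0.3, seed = 37)
  codes <- genoCodes(g)
  pc <- stats::prcomp(codes, rank. = 2)$x
  lab <- SummarizedExperiment::colData(g)$subpop
  # mean silhouette over the first two principal components
  D <- as.matrix(stats::dist(pc))
  sil <- vapply(seq_len(nrow(pc)), function(i) {
    a <- sum(D[i, lab == lab[i]]) / (sum(lab == lab[i]) - 1)
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(D[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("impossible phenotype configurations are rejected", {
  g <- simulateGenotypes(10, 20, seed = 41)
  codes <- genoCodes(g)
  codes[] <- 0L
  mono <- GenotypeSet(codes, snpMap = snpMap(g))
  expect_error(simulatePhenotype(mono, nCausal = 2, h2 = 1, seed = 1),
               "non-zero genetic variance")
})
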