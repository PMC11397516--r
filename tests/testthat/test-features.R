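# build a SparseCodes object directly from a coefficient matrix
codesFromMatrix <- function(C, accession = "a1") {
  new("SparseCodes", coef = as(Matrix::Matrix(C, sparse = TRUE), "CsparseMatrix"),
      accession = factor(rep(accession, nrow(C))),
      blockIndex = seq_len(nrow(C)), relres = numeric(nrow(C)))
}

test_that("log-normal micro features are recovered within sampling error", {
  set.seed(11)
  draws <- stats::rlnorm(500, meanlog = 0.5, sdlog = 0.2)
  C <- cbind(draws, 0)
  fv <- computeFeatures(codesFromMatrix(C))
  expect_length(fv, 6L)
  expect_lt(abs(fv[["mu_1"]] - 0.5), 3 * 0.2 / sqrt(500))
  expect_lt(abs(fv[["sigma_1"]] - 0.2), 3 * 0.2 / sqrt(500))
})

test_that("a single atom used everywhere gives mu = log c, sigma = 0", {
  C <- cbind(rep(2.5, 10), 0, 0)
  fv <- computeFeatures(codesFromMatrix(C))
  expect_equal(fv[["mu_1"]], log(2.5))
  expect_equal(fv[["sigma_1"]], 0)
  expect_equal(unname(fv[c("freq_1", "freq_2", "freq_3")]), c(1, 0, 0))
})

test_that("unused atoms get the (0, 0) sentinel and frequency 0", {
  C <- cbind(c(1, 2, 0), c(0, 0, 3), 0)
  fv <- computeFeatures(codesFromMatrix(C))
  expect_equal(unname(fv[c("mu_3", "sigma_3", "freq_3")]), c(0, 0, 0))
  expect_equal(sum(fv[c("freq_1", "freq_2", "freq_3")]), 1)
  expect_equal(fv[["freq_1"]], 2 / 3)
})

test_that("negative coefficients enter the fit by magnitude", {
  C <- cbind(c(-2, -2, -2), 0)
  fv <- computeFeatures(codesFromMatrix(C))
  expect_equal(fv[["mu_1"]], log(2))
})

test_that("feature vectors are total and sized 3 * nAtoms", {
  cv <- tinyCV()
  b <- cv@bundles[[1]]
  g <- tinyPanel()
  aios <- AIOpred:::.encodeAll(g, 16)
  fm <- featureMatrix(sparseCode(extractBlocks(aios, 4), b@dictionary))
  expect_identical(dim(fm), c(30L, 3L * nrow(dictAtoms(b@dictionary))))
  expect_true(all(is.finite(fm)))
  freqs <- fm[, grep("^freq_", colnames(fm))]
  expect_equal(unname(rowSums(freqs)), rep(1, 30))
})

test_that("an accession with no non-zero coefficients is degenerate", {
  C <- matrix(0, 4, 2)
  expect_error(computeFeatures(codesFromMatrix(C)), "degenerate")
})
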