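test_that("accuracy is the range-normalised MAE complement", {
  expect_equal(predictionAccuracy(c(0, 10), c(0, 10)), 100)
  expect_equal(predictionAccuracy(c(0, 10), c(1, 9)), 90)
  expect_equal(predictionAccuracy(c(0, 10), c(5, 5)), 50)
  expect_error(predictionAccuracy(c(3, 3), c(1, 2)), "zero range")
})

test_that("fold partition sizes match the 407-accession arithmetic", {
  f <- AIOpred:::.cvFolds(407, 10, seed = 1)
  sizes <- tabulate(f, 10)
  expect_true(all(sizes %in% c(40L, 41L)))
  expect_identical(sum(sizes), 407L)
})

test_that("cross-validation produces a complete report and predictions", {
  cv <- tinyCV()
  rep <- cvReport(cv)
  expect_identical(nrow(rep), 2L)
  expect_true(all(is.finite(rep$control_accuracy)))
  expect_true(all(rep$best_epoch >= 1 & rep$best_epoch <= 3))
  expect_identical(nrow(cv@predictions), 30L)
  expect_setequal(cv@predictions$accession, accessionIds(tinyPanel()))
})

test_that("bundles beat the constant predictor on their own training fold", {
  cv <- tinyCV()
  g <- tinyPanel()
  b <- cv@bundles[[1]]
  tr <- b@trainAccessions
  p <- predictTraits(b, g[, tr])
  y <- traitValues(g)[tr]
  expect_true(all(is.finite(p)))
  expect_lte(mean(abs(y - p)), mean(abs(y - mean(y))))
})

test_that("prediction is deterministic and shape-safe", {
  cv <- tinyCV()
  g <- tinyPanel()
  b <- cv@bundles[[1]]
  p1 <- predictTraits(b, g)
  p2 <- predictTraits(b, g)
  expect_identical(p1, p2)
  one <- predictTraits(b, g[, 1])
  expect_length(one, 1L)
  expect_identical(unname(one), unname(p1[1]))
  wrong <- simulateGenotypes(5, 20, seed = 1)
  expect_error(predictTraits(b, wrong), "SNP map mismatch")
})

test_that("degenerate traits are refused", {
  g <- simulateGenotypes(24, 30, seed = 2)
  traitValues(g, "trait") <- stats::setNames(rep(5, 24), accessionIds(g))
  expect_error(trainGenomicModel(g, folds = 2), "variance is zero")
})

test_that("training histories show long-run loss decrease on strong signal", {
  cv <- tinyCV()
  h <- cv@bundles[[1]]@history
  expect_identical(nrow(h), 3L)
  expect_true(all(is.finite(h$loss)))
  # the auxiliary head trains on standardised targets: losses are O(1)
  expect_lt(min(h$loss), 1.2)
})
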