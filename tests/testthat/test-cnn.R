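test_that("activation shapes match the design at full size", {
  sh <- AIOpred:::.cnnObservedShapes(cnnConfig(side = 128), nFeatures = 48L)
  expect_identical(sh$encoder, c(32L, 32L, 128L))
  expect_identical(sh$decoder, c(128L, 128L, 32L))
  expect_identical(sh$gap_len, 32L)
  expect_identical(sh$combined_len, 80L)      # 32 + 3 * 16 atoms
  an <- cnnShapes(cnnConfig(side = 128))
  expect_identical(an$encoder, c(32L, 32L, 128L))
  expect_identical(an$decoder, c(128L, 128L, 32L))
})

test_that("configuration constraints are enforced", {
  expect_error(cnnConfig(side = 30), "divisible by 4")
  expect_error(cnnConfig(valSplit = 1.2), "valSplit")
  expect_error(cnnConfig(channels = c(8, 16)), "three positive")
})

test_that("weight initialisation is seed-reproducible", {
  w1 <- buildCNN(cnnConfig(side = 16, seed = 5), nFeatures = 6L)
  w2 <- buildCNN(cnnConfig(side = 16, seed = 5), nFeatures = 6L)
  expect_identical(w1, w2)
  expect_gt(cnnParameterCount(w1), 1000L)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- cnnConfig(side = 8, channels = c(4, 5, 6), decoderChannels = 3,
                   hidden = 5, seed = 2)
  w <- buildCNN(cfg, nFeatures = 4L)
  set.seed(9)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  f <- rnorm(4)
  tgt <- 0.7
  gb <- AIOpred:::.cnn_grad_batch(list(img), matrix(f, 1), w, tgt)
  lossAt <- function(ww)
    AIOpred:::.cnn_grad_batch(list(img), matrix(f, 1), ww, tgt)$loss
  eps <- 1e-6
  for (nm in c("W1", "W3", "T1", "W5", "Wd1", "Wd2")) {
    for (i in sample(length(w[[nm]]), 3)) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
      expect_equal(gb$grads[[nm]][i], fd, tolerance = 1e-4)
    }
  }
  # gradient wrt the input image (the saliency path)
  sal <- AIOpred:::.cnn_saliency(img, f, w)
  yAt <- function(im) AIOpred:::.cnn_shapes_observed(im, f, w)$y
  for (i in sample(length(img), 5)) {
    ip <- img; ip[i] <- ip[i] + eps
    im <- img; im[i] <- im[i] - eps
    expect_equal(sal$dx[i], (yAt(ip) - yAt(im)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("forward pass is deterministic", {
  cfg <- cnnConfig(side = 16, seed = 3)
  w <- buildCNN(cfg, nFeatures = 6L)
  set.seed(4)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  f <- matrix(rnorm(6), 1)
  y1 <- AIOpred:::.cnn_predict_batch(list(img), f, w)
  y2 <- AIOpred:::.cnn_predict_batch(list(img), f, w)
  expect_identical(y1$y, y2$y)
  expect_identical(y1$gap, y2$gap)
})
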