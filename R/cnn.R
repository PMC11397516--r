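#' Configuration of the encoder-decoder convolutional network
#'
#' The network takes two inputs: the artificial image (side x side x 3) and
#' the numeric dictionary feature vector (length `3 * nAtoms`).  The encoder
#' applies three 3x3 convolutions (channel plan `channels`, ReLU, 'same'
#' padding) with 2x2 max-pooling after the first two, so its output is
#' `channels[3]` feature maps of side/4.  The decoder mirrors it with two
#' 2x2-stride-2 transpose convolutions, each followed by concatenation with
#' the matching encoder map (skip connection) and a 3x3 convolution; its
#' output is `decoderChannels` maps at the original side.  Global average
#' pooling reduces these to one value per channel; the pooled vector is
#' concatenated with the dictionary features and a small dense head produces
#' the auxiliary scalar output used for differentiable training and for
#' saliency.  With the defaults (side 128, plan 32-64-128) the encoder
#' output is 128 channels of 32x32 maps and the decoder output is 32
#' channels of 128x128 maps.
#'
#' @param side input image side in pixels; must be divisible by 4.
#' @param channels encoder channel plan, length 3 (default `c(32, 64, 128)`).
#' @param decoderChannels decoder output channels = GAP length (default 32).
#' @param hidden width of the dense head's hidden layer.
#' @param epochs training epochs (default 150).
#' @param valSplit fraction of the training accessions held out for epoch
#'   selection (default 0.2).
#' @param refitInterval epochs between refits of the boosted regressor on
#'   the frozen features (default 5).
#' @param batchSize minibatch size for Adam (default 8).
#' @param learningRate Adam step size (default 1e-3).
#' @param xgbParams list of xgboost parameters for the boosted regressor;
#'   the MAE objective (`reg:absoluteerror`) is always enforced.
#' @param xgbRounds boosting rounds (default 200).
#' @param seed integer seed controlling weight initialisation, batching and
#'   the regressor.
#' @return a validated list of class `cnnConfig`.
#' @export
cnnConfig <- function(side = 128L, channels = c(32L, 64L, 128L),
                      decoderChannels = 32L, hidden = 64L, epochs = 150L,
                      valSplit = 0.2, refitInterval = 5L, batchSize = 8L,
                      learningRate = 1e-3,
                      xgbParams = list(max_depth = 3, eta = 0.1,
                                       subsample = 0.8, min_child_weight = 3),
                      xgbRounds = 200L, seed = 1L) {
  if (side %% 4 != 0) stop("configuration error: side must be divisible by 4")
  if (length(channels) != 3L || any(channels < 1))
    stop("configuration error: 'channels' must be three positive integers")
  if (valSplit <= 0 || valSplit >= 1)
    stop("configuration error: valSplit must be in (0, 1)")
  structure(list(side = as.integer(side), channels = as.integer(channels),
                 decoderChannels = as.integer(decoderChannels),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 valSplit = valSplit, refitInterval = as.integer(refitInterval),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, xgbParams = xgbParams,
                 xgbRounds = as.integer(xgbRounds), seed = as.integer(seed)),
            class = "cnnConfig")
}

#' Expected activation shapes of the network
#'
#' @param config a [cnnConfig()].
#' @return list with `encoder` (h, w, channels), `decoder` and `gap_len`.
#' @export
cnnShapes <- function(config) {
  s <- config$side
  list(encoder = c(s %/% 4L, s %/% 4L, config$channels[3]),
       decoder = c(s, s, config$decoderChannels),
       gap_len = config$decoderChannels)
}

#' Initialise untrained network weights
#'
#' He-scaled Gaussian initialisation, driven by the R RNG so runs are
#' reproducible under `set.seed`/the config seed.
#'
#' @param config a [cnnConfig()].
#' @param nFeatures length of the numeric dictionary feature vector.
#' @return named list of weight arrays (the layout consumed by the C++
#'   forward/backward pass).
#' @export
buildCNN <- function(config, nFeatures) {
  c1 <- config$channels[1]; c2 <- config$channels[2]; c3 <- config$channels[3]
  dch <- config$decoderChannels; hid <- config$hidden
  set.seed(config$seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0,
                                                sqrt(2 / nin)), nin, nout)
  list(W1 = he(9 * 3, c1),        b1 = numeric(c1),
       W2 = he(9 * c1, c2),       b2 = numeric(c2),
       W3 = he(9 * c2, c3),       b3 = numeric(c3),
       T1 = he(c3, 4 * c2),       bt1 = numeric(c2),
       W4 = he(9 * 2 * c2, c2),   b4 = numeric(c2),
       T2 = he(c2, 4 * c1),       bt2 = numeric(c1),
       W5 = he(9 * 2 * c1, dch),  b5 = numeric(dch),
       Wd1 = he(dch + nFeatures, hid), bd1 = numeric(hid),
       Wd2 = he(hid, 1),          bd2 = 0)
}

#' Number of trainable parameters of a weight list
#' @param weights list from [buildCNN()].
#' @return integer count.
#' @export
cnnParameterCount <- function(weights)
  sum(vapply(weights, length, integer(1)))

## internal: forward pass over a list of AIOs
.cnnForward <- function(aios, feats, weights) {
  imgs <- lapply(aios, function(a) a@pixels)
  .cnn_predict_batch(imgs, feats, weights)
}

## internal: observed activation shapes on a real forward pass
.cnnObservedShapes <- function(config, nFeatures = 3L) {
  w <- buildCNN(config, nFeatures)
  img <- array(0, c(config$side, config$side, 3))
  .cnn_shapes_observed(img, numeric(nFeatures), w)
}

## internal: one Adam training run; returns final weights plus snapshots
.adamInit <- function(weights)
  list(m = lapply(weights, function(w) numeric(length(w))),
       v = lapply(weights, function(w) numeric(length(w))),
       t = 0L)

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    g <- as.vector(grads[[nm]])               # same column-major layout
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(weights = weights, state = state)
}
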