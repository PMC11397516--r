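#' Dictionary learning configuration
#'
#' @param nAtoms dictionary size (default 16, the setting selected for the
#'   chickpea panel).
#' @param blockSide block side in pixels (default 16); must divide the
#'   image side.
#' @param targetError relative reconstruction error target (default 0.01).
#' @param maxSparsity maximum atoms per block (default 10).
#' @param maxIter learning iteration cap.
#' @param seed integer seed.
#' @return a validated list of class `dictConfig`.
#' @export
dictConfig <- function(nAtoms = 16L, blockSide = 16L, targetError = 0.01,
                       maxSparsity = 10L, maxIter = 30L, seed = 1L) {
  stopifnot(nAtoms >= 1, blockSide >= 1, targetError > 0, maxSparsity >= 1)
  structure(list(nAtoms = as.integer(nAtoms),
                 blockSide = as.integer(blockSide),
                 targetError = targetError,
                 maxSparsity = as.integer(maxSparsity),
                 maxIter = as.integer(maxIter), seed = as.integer(seed)),
            class = "dictConfig")
}

#' Prediction accuracy as the range-normalised MAE complement
#'
#' `a = 100 * (1 - MAE(observed, predicted) / range(observed))`, in percent.
#' A perfect predictor scores 100; a predictor whose MAE equals the observed
#' range scores 0.
#'
#' @param observed,predicted equal-length finite numeric vectors.
#' @return accuracy in percent.
#' @examples
#' predictionAccuracy(c(0, 10), c(1, 9))  # 90
#' @export
predictionAccuracy <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted),
            all(is.finite(observed)), all(is.finite(predicted)))
  rg <- diff(range(observed))
  if (rg == 0) stop("observed values have zero range")
  100 * (1 - mean(abs(observed - predicted)) / rg)
}

## internal: deterministic fold assignment (control fold per accession)
.cvFolds <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

## internal: fit one bundle on the given training accessions
.fitBundle <- function(aios, featsAll, traits, trainIds, dcfg, ccfg, dict,
                       fold = 0L) {
  y <- traits[trainIds]
  if (stats::sd(y) == 0) stop("trait variance is zero on the training set")
  set.seed(ccfg$seed + 1000L * fold)
  nVal <- max(1L, round(ccfg$valSplit * length(trainIds)))
  valIds <- sample(trainIds, nVal)
  fitIds <- setdiff(trainIds, valIds)
  fitImgs <- lapply(aios[fitIds], function(a) a@pixels)
  valImgs <- lapply(aios[valIds], function(a) a@pixels)
  fitF <- featsAll[fitIds, , drop = FALSE]
  valF <- featsAll[valIds, , drop = FALSE]
  cfgSeeded <- ccfg
  cfgSeeded$seed <- ccfg$seed + 1000L * fold + 1L
  ## the auxiliary head is trained on standardised targets so the MAE
  ## gradient scale is independent of the trait's units
  yc <- mean(y[fitIds])
  ys <- stats::sd(y[fitIds])
  yStd <- (y - yc) / ys
  weights <- buildCNN(cfgSeeded, ncol(featsAll))
  opt <- .adamInit(weights)
  best <- list(acc = -Inf, epoch = 0L, weights = weights, booster = NULL)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_accuracy = numeric())
  nFit <- length(fitIds)
  for (ep in seq_len(ccfg$epochs)) {
    ord <- sample(nFit)
    epLoss <- 0
    nb <- 0L
    for (start in seq(1L, nFit, by = ccfg$batchSize)) {
      sel <- ord[start:min(start + ccfg$batchSize - 1L, nFit)]
      gb <- .cnn_grad_batch(fitImgs[sel], fitF[sel, , drop = FALSE],
                            weights, yStd[fitIds][sel])
      if (!is.finite(gb$loss))
        stop("non-finite training loss at epoch ", ep,
             "; inspect the trait scale and learning rate")
      st <- .adamStep(weights, gb$grads, opt, ccfg$learningRate)
      weights <- st$weights
      opt <- st$state
      epLoss <- epLoss + gb$loss * length(sel)
      nb <- nb + length(sel)
    }
    valAcc <- NA_real_
    if (ep %% ccfg$refitInterval == 0L || ep == ccfg$epochs) {
      gapFit <- .cnn_predict_batch(fitImgs, fitF, weights)$gap
      gapVal <- .cnn_predict_batch(valImgs, valF, weights)$gap
      booster <- .fitBooster(cbind(gapFit, fitF), y[fitIds], ccfg)
      pv <- stats::predict(booster, cbind(gapVal, valF))
      valAcc <- if (diff(range(y[valIds])) > 0)
        predictionAccuracy(y[valIds], pv)
      else
        -mean(abs(y[valIds] - pv))           # degenerate tiny-val fallback
      if (valAcc >= best$acc)
        best <- list(acc = valAcc, epoch = ep, weights = weights,
                     booster = booster)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = epLoss / nb,
                                   val_accuracy = valAcc))
  }
  new("ModelBundle", weights = best$weights,
      boosterRaw = xgboost::xgb.save.raw(best$booster),
      dictionary = dict, cnnConfig = unclass(cfgSeeded),
      snpIds = character(0), trainAccessions = trainIds,
      history = hist, bestEpoch = best$epoch, fold = as.integer(fold))
}

.fitBooster <- function(X, y, ccfg) {
  params <- ccfg$xgbParams
  params$objective <- "reg:absoluteerror"
  params$nthread <- 1
  params$seed <- ccfg$seed
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
                     nrounds = ccfg$xgbRounds)
}

#' Train the image + dictionary-feature model with cross-validation
#'
#' For each fold, the held-out accessions act as the control set and the
#' rest as training set.  Per fold: a block dictionary is learned on the
#' training accessions only; all accessions are sparse-coded against it to
#' obtain micro/macro features; the convolutional network is trained for
#' `epochs` epochs under mean absolute error via an auxiliary dense head,
#' with an internal validation split (`valSplit`) of the training
#' accessions; every `refitInterval` epochs the gradient-boosting regressor
#' is refit on the concatenated (GAP, dictionary) features of the fit
#' portion and scored on the validation portion, and the epoch with maximal
#' validation accuracy defines the stored bundle.  The control accessions
#' are finally predicted with the stored bundle.
#'
#' Simultaneous training of the network and the boosted regressor is
#' realised by this alternation: true joint backpropagation through decision
#' trees has no gradient, so the trees are refreshed on the evolving network
#' features instead.
#'
#' @param gset a [GenotypeSet-class] with a trait column in `colData`.
#' @param trait trait column name (default `"trait"`).
#' @param dcfg a [dictConfig()].
#' @param ccfg a [cnnConfig()].
#' @param folds number of cross-validation folds (default 10).
#' @param fixedControl optional character vector of accession ids used as a
#'   single fixed control set instead of rotating folds.
#' @return a [TraitCV-class].
#' @export
trainGenomicModel <- function(gset, trait = "trait", dcfg = dictConfig(),
                              ccfg = cnnConfig(), folds = 10L,
                              fixedControl = NULL) {
  traits <- traitValues(gset, trait)
  if (any(!is.finite(traits))) stop("non-finite trait values")
  if (stats::sd(traits) == 0) stop("trait variance is zero")
  ids <- accessionIds(gset)
  if (is.null(fixedControl) && length(ids) < 2L * folds)
    stop("need at least ", 2L * folds, " accessions for ", folds, " folds")
  aios <- .encodeAll(gset, ccfg$side)
  names(aios) <- ids
  if (is.null(fixedControl)) {
    fa <- .cvFolds(length(ids), folds, ccfg$seed)
    foldSets <- split(ids, fa)
  } else {
    stopifnot(all(fixedControl %in% ids))
    fa <- ifelse(ids %in% fixedControl, 1L, NA_integer_)
    foldSets <- list(`1` = fixedControl)
  }
  bundles <- list()
  rows <- list()
  preds <- list()
  for (f in seq_along(foldSets)) {
    controlIds <- foldSets[[f]]
    trainIds <- setdiff(ids, controlIds)
    dSeeded <- dcfg
    dSeeded$seed <- dcfg$seed + f
    dict <- learnDictionary(extractBlocks(aios[trainIds], dcfg$blockSide),
                            nAtoms = dcfg$nAtoms,
                            targetError = dcfg$targetError,
                            maxSparsity = dcfg$maxSparsity,
                            maxIter = dcfg$maxIter, seed = dSeeded$seed)
    featsAll <- featureMatrix(
      sparseCode(extractBlocks(aios[ids], dcfg$blockSide), dict))
    bundle <- .fitBundle(aios, featsAll, traits, trainIds, dcfg, ccfg,
                         dict, fold = f)
    bundle@snpIds <- snpMap(gset)$snp_id
    pc <- .predictWithBundle(bundle, aios[controlIds],
                             featsAll[controlIds, , drop = FALSE])
    acc <- predictionAccuracy(traits[controlIds], pc)
    bundles[[f]] <- bundle
    rows[[f]] <- data.frame(fold = f, n_control = length(controlIds),
                            control_accuracy = acc,
                            best_epoch = bundle@bestEpoch,
                            dict_error = dict@trainError)
    preds[[f]] <- data.frame(accession = controlIds, fold = f,
                             observed = unname(traits[controlIds]),
                             predicted = unname(pc))
  }
  new("TraitCV", bundles = bundles, report = do.call(rbind, rows),
      foldAssignment = if (is.null(fixedControl)) fa else
        ifelse(is.na(fa), 0L, fa),
      predictions = do.call(rbind, preds))
}

#' Train a single model on all accessions (no control fold)
#'
#' Same procedure as one fold of [trainGenomicModel()] but with every
#' accession in the training set; intended for downstream attribution.
#'
#' @inheritParams trainGenomicModel
#' @return a [ModelBundle-class].
#' @export
trainFullModel <- function(gset, trait = "trait", dcfg = dictConfig(),
                           ccfg = cnnConfig()) {
  traits <- traitValues(gset, trait)
  if (stats::sd(traits) == 0) stop("trait variance is zero")
  ids <- accessionIds(gset)
  aios <- .encodeAll(gset, ccfg$side)
  names(aios) <- ids
  dict <- learnDictionary(extractBlocks(aios, dcfg$blockSide),
                          nAtoms = dcfg$nAtoms,
                          targetError = dcfg$targetError,
                          maxSparsity = dcfg$maxSparsity,
                          maxIter = dcfg$maxIter, seed = dcfg$seed)
  featsAll <- featureMatrix(
    sparseCode(extractBlocks(aios, dcfg$blockSide), dict))
  bundle <- .fitBundle(aios, featsAll, traits, ids, dcfg, ccfg, dict,
                       fold = 0L)
  bundle@snpIds <- snpMap(gset)$snp_id
  bundle
}

## internal prediction path shared by CV and predictTraits
.predictWithBundle <- function(bundle, aios, feats) {
  fw <- .cnnForward(aios, feats, bundle@weights)
  booster <- xgboost::xgb.load.raw(bundle@boosterRaw)
  p <- stats::predict(booster, cbind(fw$gap, feats))
  stats::setNames(p, names(aios))
}

#' Predict traits for new accessions with a trained bundle
#'
#' The SNP panel must be identical (same ids, same order) to the one the
#' bundle was trained on.  Accessions are encoded, sparse-coded against the
#' bundle's frozen dictionary, pushed through the network, and scored by
#' the boosted regressor on the concatenated (GAP, dictionary) features.
#' The output is fully determined by the bundle.
#'
#' @param object a [ModelBundle-class].
#' @param genotypes a [GenotypeSet-class].
#' @param ... unused.
#' @return named numeric vector of trait predictions.
#' @export
setMethod("predictTraits", "ModelBundle", function(object, genotypes, ...) {
  if (!identical(snpMap(genotypes)$snp_id, object@snpIds))
    stop("SNP map mismatch: the bundle was trained on a different panel")
  aios <- .encodeAll(genotypes, object@cnnConfig$side)
  names(aios) <- accessionIds(genotypes)
  bs <- object@dictionary@blockSide
  feats <- featureMatrix(sparseCode(extractBlocks(aios, bs),
                                    object@dictionary))
  .predictWithBundle(object, aios, feats[names(aios), , drop = FALSE])
})

#' @rdname trainGenomicModel
#' @param object a [TraitCV-class].
#' @export
setMethod("cvReport", "TraitCV", function(object) object@report)

setMethod("show", "TraitCV", function(object) {
  cat("TraitCV:", nrow(object@report), "folds, mean control accuracy",
      sprintf("%.1f%%\n", mean(object@report$control_accuracy)))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf(paste0("ModelBundle (fold %d): %d SNPs, side %d, best epoch ",
                     "%d, %d CNN parameters\n"),
              object@fold, length(object@snpIds), object@cnnConfig$side,
              object@bestEpoch, cnnParameterCount(object@weights)))
})
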