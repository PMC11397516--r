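#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' GenotypeSet: SNP genotypes with a marker map and trait annotations
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one integer assay `"codes"` with SNPs as rows and accessions as columns.
#' Codes follow the standard dosage convention: 0 = reference homozygote,
#' 1 = heterozygote, 2 = alternative homozygote, `NA` = missing call.
#' The marker map (chromosome, 1-based position, SNP id) lives in `rowData`;
#' per-accession traits (and any simulation labels) live in `colData`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment].
#' @seealso [GenotypeSet()], [genoCodes()], [snpMap()], [traitValues()]
#' @export
setClass("GenotypeSet", contains = "SummarizedExperiment")

setValidity("GenotypeSet", function(object) {
  msg <- NULL
  if (!"codes" %in% assayNames(object))
    msg <- c(msg, "assay 'codes' is required")
  else {
    a <- assay(object, "codes")
    bad <- !is.na(a) & !(a %in% c(0L, 1L, 2L))
    if (any(bad))
      msg <- c(msg, "all non-missing genotype codes must be 0, 1 or 2")
  }
  rd <- rowData(object)
  if (!all(c("chrom", "pos", "snp_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom', 'pos' and 'snp_id'")
  else {
    if (anyDuplicated(rd$snp_id))
      msg <- c(msg, "SNP ids must be unique")
    if (any(!is.na(rd$pos) & rd$pos < 1))
      msg <- c(msg, "positions must be >= 1 (1-based)")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "accession ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' AIO: an artificial image object for one accession
#'
#' A height x width x 3 array of pseudo-colour pixels.  Each pixel encodes
#' one genotype code as a one-hot triple over the channels (R, G, B):
#' code 0 -> (1,0,0), 1 -> (0,1,0), 2 -> (0,0,1); missing calls are the
#' all-zero pixel.  SNPs fill the image left-to-right, top-to-bottom, and
#' the SNP list is reused cyclically from the start until the image is full.
#'
#' @slot pixels numeric array `c(height, width, 3)`.
#' @slot nSnps integer, number of distinct SNPs laid out.
#' @slot accession character, id of the encoded accession (may be `NA`).
#' @seealso [encodeAIO()], [decodeAIO()], [snpPixelIndex()]
#' @export
setClass("AIO", representation(pixels = "array", nSnps = "integer",
                               accession = "character"))

setValidity("AIO", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (object@nSnps < 1L) return("nSnps must be >= 1")
  if (object@nSnps > d[1] * d[2])
    return("image too small: every SNP must appear at least once")
  s <- object@pixels[, , 1] + object@pixels[, , 2] + object@pixels[, , 3]
  if (!all(s %in% c(0, 1)))
    return("each pixel must be one-hot (sum 1) or all-zero (missing)")
  TRUE
})

#' SnpDictionary: learned block dictionary
#'
#' Unit-norm template blocks (atoms) learned from the square blocks of a set
#' of AIOs.  Blocks are `blockSide` x `blockSide` x 3 patches flattened to
#' vectors of length `3 * blockSide^2`; atoms are rows of `atoms`.
#'
#' @slot atoms numeric matrix, `nAtoms x blockDim`, unit-norm rows.
#' @slot blockSide integer block side in pixels.
#' @slot targetError numeric, relative reconstruction error targeted during
#'   learning (and used as the OMP stopping tolerance).
#' @slot maxSparsity integer, maximum atoms per block.
#' @slot trainError numeric, mean relative reconstruction error achieved on
#'   the training blocks.
#' @slot iterations integer, learning iterations performed.
#' @slot converged logical, whether `trainError <= targetError`.
#' @slot seed integer seed used for initialisation.
#' @export
setClass("SnpDictionary", representation(
  atoms = "matrix", blockSide = "integer", targetError = "numeric",
  maxSparsity = "integer", trainError = "numeric", iterations = "integer",
  converged = "logical", seed = "integer"))

setValidity("SnpDictionary", function(object) {
  if (nrow(object@atoms) < 1L) return("at least one atom required")
  if (ncol(object@atoms) != 3L * object@blockSide^2)
    return("atom length must equal 3 * blockSide^2")
  nrm <- sqrt(rowSums(object@atoms^2))
  if (any(abs(nrm - 1) > 1e-6)) return("atoms must have unit Euclidean norm")
  TRUE
})

#' SparseCodes: per-block OMP coefficients for a set of accessions
#'
#' Sparse coefficients of every image block against a frozen
#' [SnpDictionary-class]. Rows are blocks (grouped by accession, in block order),
#' columns are atoms.
#'
#' @slot coef a `Matrix::dgCMatrix`, blocks x atoms.
#' @slot accession factor of length `nrow(coef)`, block provenance.
#' @slot blockIndex integer block position within its image (1-based).
#' @slot relres numeric relative residual norm per block.
#' @export
setClass("SparseCodes", representation(
  coef = "Matrix", accession = "factor", blockIndex = "integer",
  relres = "numeric"))

setValidity("SparseCodes", function(object) {
  n <- nrow(object@coef)
  if (length(object@accession) != n || length(object@blockIndex) != n ||
      length(object@relres) != n)
    return("block annotations must match nrow(coef)")
  TRUE
})

#' ModelBundle: a trained predictor for one cross-validation fold
#'
#' Everything needed to predict traits for new accessions sharing the
#' training SNP panel: the convolutional network weights, the serialized
#' gradient-boosting regressor, the frozen dictionary, and the layout /
#' configuration used at training time.  Prediction is fully determined by
#' the bundle.
#'
#' @slot weights list of network weight arrays.
#' @slot boosterRaw raw bytes of the serialized xgboost model.
#' @slot dictionary the frozen [SnpDictionary-class].
#' @slot cnnConfig list, see [cnnConfig()].
#' @slot snpIds character, the training SNP panel (order matters).
#' @slot history data.frame with per-epoch training loss and validation
#'   accuracy of the boosted regressor.
#' @slot trainAccessions character ids used for fitting.
#' @slot bestEpoch integer epoch whose weights/regressor are stored.
#' @slot fold integer fold label (0 for a model trained on all data).
#' @export
setClass("ModelBundle", representation(
  weights = "list", boosterRaw = "raw", dictionary = "SnpDictionary",
  cnnConfig = "list", snpIds = "character", trainAccessions = "character",
  history = "data.frame", bestEpoch = "integer", fold = "integer"))

#' TraitCV: cross-validation result for one trait
#'
#' @slot bundles list of per-fold [ModelBundle-class] objects.
#' @slot report data.frame with one row per fold: control accuracy (percent),
#'   best epoch, dictionary reconstruction error.
#' @slot foldAssignment integer vector naming each accession's control fold.
#' @slot predictions data.frame of out-of-fold (control) predictions.
#' @export
setClass("TraitCV", representation(
  bundles = "list", report = "data.frame", foldAssignment = "integer",
  predictions = "data.frame"))

#' AttentionMap: per-pixel saliency for one accession
#'
#' Non-negative pixel intensities of the same height x width as the input
#' AIO; larger values mark pixels (hence SNPs) with more influence on the
#' regression output.
#'
#' @slot intensities numeric matrix height x width, values >= 0.
#' @slot accession character id.
#' @slot method character, `"gradient"` or `"gradcam"`.
#' @export
setClass("AttentionMap", representation(
  intensities = "matrix", accession = "character", method = "character"))

setValidity("AttentionMap", function(object) {
  if (any(object@intensities < 0)) return("intensities must be >= 0")
  TRUE
})

#' SnpSelection: result of Dunnett screening of SNP importances
#'
#' @slot table data.frame with columns `snp_id`, `chrom`, `pos`, `mean_score`,
#'   `statistic`, `p_adj`, `selected`.
#' @slot alpha numeric family-wise error level.
#' @slot side character, `"greater"` or `"two.sided"`.
#' @slot controlMean numeric, mean of the pooled control scores.
#' @export
setClass("SnpSelection", representation(
  table = "data.frame", alpha = "numeric", side = "character",
  controlMean = "numeric"))
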