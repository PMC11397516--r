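#' Micro/macro feature vector for one accession's sparse codes
#'
#' For each atom, the magnitudes of the accession's non-zero coefficients
#' are treated as draws from a log-normal law and fitted by maximum
#' likelihood on the log scale: `mu = mean(log |c|)`,
#' `sigma = sqrt(mean((log |c| - mu)^2))`.  These 2 x nAtoms values are the
#' micro features.  The macro features are the atom usage frequencies: the
#' fraction of the accession's non-zero coefficient slots assigned to each
#' atom (non-negative, summing to 1).  Atoms never used by the accession get
#' the imputation sentinel `(0, 0)` for micro and 0 for macro, so the vector
#' always has length `3 * nAtoms`.
#'
#' @param codes a [SparseCodes-class] (may span several accessions).
#' @param accession accession id to extract; defaults to the only level.
#' @return named numeric vector `c(mu_1..mu_K, sigma_1..sigma_K,
#'   freq_1..freq_K)` of length `3 * nAtoms`.
#' @export
computeFeatures <- function(codes, accession = NULL) {
  lev <- levels(codes@accession)
  if (is.null(accession)) {
    if (length(lev) != 1L)
      stop("codes span several accessions; name one")
    accession <- lev
  }
  rows <- which(codes@accession == accession)
  if (!length(rows)) stop("no blocks for accession '", accession, "'")
  C <- codes@coef[rows, , drop = FALSE]
  K <- ncol(C)
  Ct <- as(C, "TsparseMatrix")
  keep <- Ct@x != 0
  atom <- Ct@j[keep] + 1L
  val <- abs(Ct@x[keep])
  if (!length(val))
    stop("degenerate input: accession '", accession,
         "' has no non-zero coefficients")
  mu <- sig <- freq <- numeric(K)
  cnt <- tabulate(atom, nbins = K)
  for (k in which(cnt > 0L)) {
    lg <- log(val[atom == k])
    mu[k] <- mean(lg)
    sig[k] <- sqrt(mean((lg - mu[k])^2))      # MLE; 0 when a single draw
  }
  freq <- cnt / sum(cnt)
  stats::setNames(c(mu, sig, freq),
                  c(paste0("mu_", seq_len(K)), paste0("sigma_", seq_len(K)),
                    paste0("freq_", seq_len(K))))
}

#' Feature matrix for all accessions in a SparseCodes object
#'
#' @param codes a [SparseCodes-class].
#' @return numeric matrix accessions x `3 * nAtoms` with accession row names.
#' @seealso [computeFeatures()]
#' @export
featureMatrix <- function(codes) {
  lev <- levels(codes@accession)
  t(vapply(lev, function(a) computeFeatures(codes, a),
           numeric(3L * ncol(codes@coef))))
}

#' Export a feature matrix as TSV
#'
#' @param feats matrix from [featureMatrix()].
#' @param path output path.
#' @export
writeFeatures <- function(feats, path) {
  df <- data.frame(accession = rownames(feats), feats, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
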