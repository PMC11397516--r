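#' Dense regression attention map for one accession
#'
#' The default `"gradient"` method backpropagates the auxiliary regression
#' output to the input image and takes, per pixel, the maximum over the
#' three pseudo-colour channels of the absolute gradient.  The
#' `"gradcam"` variant instead weights the decoder's output feature maps by
#' their (spatially averaged) gradients and rectifies the weighted sum,
#' giving a coarser, layer-level map.  Both are non-negative and of the
#' same height x width as the input.
#'
#' @param bundle a trained [ModelBundle-class].
#' @param aio the accession's [AIO-class].
#' @param features the accession's numeric feature vector (length
#'   `3 * nAtoms`); if `NULL` it is recomputed from the bundle's dictionary.
#' @param method `"gradient"` (input saliency) or `"gradcam"`.
#' @return an [AttentionMap-class].
#' @export
attentionMap <- function(bundle, aio, features = NULL,
                         method = c("gradient", "gradcam")) {
  method <- match.arg(method)
  if (length(bundle@boosterRaw) == 0) stop("bundle is not trained")
  if (is.null(features)) {
    bs <- bundle@dictionary@blockSide
    features <- computeFeatures(
      sparseCode(extractBlocks(aio, bs), bundle@dictionary),
      accession = NULL)
  }
  sal <- .cnn_saliency(aio@pixels, as.numeric(features), bundle@weights)
  if (method == "gradient") {
    m <- pmax(abs(sal$dx[, , 1]), abs(sal$dx[, , 2]), abs(sal$dx[, , 3]))
  } else {
    w <- apply(sal$ddec, 3, mean)
    m <- matrix(0, dim(sal$dec)[1], dim(sal$dec)[2])
    for (k in seq_along(w)) m <- m + w[k] * sal$dec[, , k]
    m <- pmax(m, 0)
  }
  new("AttentionMap", intensities = m, accession = aio@accession,
      method = method)
}

setMethod("show", "AttentionMap", function(object) {
  cat(sprintf("AttentionMap (%s) %dx%d for accession %s, max %.3g\n",
              object@method, ncol(object@intensities),
              nrow(object@intensities), object@accession,
              max(object@intensities)))
})

#' Aggregate attention maps to per-SNP importance scores
#'
#' The importance of SNP k for an accession is the mean intensity over all
#' pixel positions that display SNP k under the cyclic row-major layout
#' (cyclic repetitions are averaged).
#'
#' @param maps list of [AttentionMap-class] objects sharing one layout.
#' @param nSnps number of SNPs in the layout.
#' @param snpIds optional SNP ids used as row names.
#' @return numeric matrix `nSnps x nAccessions` of scores (>= 0).
#' @export
aggregateToSnps <- function(maps, nSnps, snpIds = NULL) {
  if (is(maps, "AttentionMap")) maps <- list(maps)
  d <- dim(maps[[1]]@intensities)
  idx <- as.vector(snpPixelIndex(d[2], d[1], nSnps))
  out <- vapply(maps, function(m) {
    if (!identical(dim(m@intensities), d))
      stop("layout mismatch between attention maps")
    as.numeric(rowsum(as.vector(m@intensities), idx) /
                 tabulate(idx, nbins = nSnps))
  }, numeric(nSnps))
  rownames(out) <- snpIds %||% sprintf("snp%05d", seq_len(nSnps))
  colnames(out) <- vapply(maps, function(m) m@accession, character(1))
  out
}

## internal: many-to-one Dunnett comparison of group means against a control
## sample.  Returns one-sided or two-sided statistics and adjusted p-values
## under the classical equicorrelated multivariate-t model.
.dunnettCore <- function(groups, control, side = "greater", mcSamples = 2e4,
                         seed = 1L) {
  m <- ncol(groups)
  n <- nrow(groups)
  n0 <- length(control)
  gm <- colMeans(groups)
  cm <- mean(control)
  ss <- sum((control - cm)^2) + sum(sweep(groups, 2, gm)^2)
  df <- n0 - 1L + m * (n - 1L)
  s2 <- ss / df
  if (s2 == 0) {
    return(list(statistic = rep(NA_real_, m), p_adj = rep(NA_real_, m),
                df = df, zeroVariance = TRUE))
  }
  tstat <- (gm - cm) / sqrt(s2 * (1 / n + 1 / n0))
  lambda <- sqrt(n / (n + n0))
  rho <- lambda^2
  padj <- if (m <= 30) {
    S <- matrix(rho, m, m); diag(S) <- 1
    vapply(tstat, function(t0) {
      if (!is.finite(t0)) return(NA_real_)
      lw <- if (side == "greater") rep(-Inf, m) else rep(-abs(t0), m)
      up <- if (side == "greater") rep(t0, m) else rep(abs(t0), m)
      set.seed(seed)
      1 - as.numeric(mvtnorm::pmvt(lower = lw, upper = up, df = df,
                                   corr = S))
    }, numeric(1))
  } else {
    ## Monte-Carlo reference distribution of max T under the one-factor
    ## representation T_k = (sqrt(1-rho) Z_k - lambda Z0) / (S/sigma)
    set.seed(seed)
    Z0 <- stats::rnorm(mcSamples)
    Ssc <- sqrt(stats::rchisq(mcSamples, df) / df)
    mx <- rep(-Inf, mcSamples)
    for (k in seq_len(m)) {
      tk <- (sqrt(1 - rho) * stats::rnorm(mcSamples) - lambda * Z0) / Ssc
      mx <- pmax(mx, if (side == "greater") tk else abs(tk))
    }
    stat <- if (side == "greater") tstat else abs(tstat)
    vapply(stat, function(t0) mean(mx >= t0), numeric(1))
  }
  list(statistic = tstat, p_adj = pmin(padj, 1), df = df,
       zeroVariance = FALSE)
}

#' Select influential SNPs with Dunnett's many-to-one criterion
#'
#' Each SNP's per-accession importance scores form one treatment sample;
#' the pooled scores of all SNPs form the control sample.  Dunnett's
#' many-to-one comparison tests every treatment mean against the control
#' mean at family-wise level `alpha` under the classical equicorrelated
#' multivariate-t model (a seeded Monte-Carlo approximation of the max-T
#' reference distribution is used when the panel is too large for
#' numerical multivariate-t integration).  By default the comparison is
#' one-sided: only SNPs whose mean importance is significantly *greater*
#' than the pooled mean are of interest.
#'
#' @param importance matrix from [aggregateToSnps()] (SNPs x accessions).
#' @param alpha family-wise error level (default 0.05).
#' @param side `"greater"` (default) or `"two.sided"`.
#' @param topK optional cap: keep at most the `topK` smallest adjusted
#'   p-values among the significant SNPs (the chickpea study reports a
#'   fixed 99 per trait).
#' @param snpMap optional data.frame with `snp_id`, `chrom`, `pos` used to
#'   annotate the result.
#' @param seed seed for the (deterministic, quasi-)randomised p-value
#'   integration.
#' @return a [SnpSelection-class].
#' @export
dunnettSelect <- function(importance, alpha = 0.05,
                          side = c("greater", "two.sided"), topK = NULL,
                          snpMap = NULL, seed = 1L) {
  side <- match.arg(side)
  if (ncol(importance) < 2L) stop("need at least 2 accessions")
  if (nrow(importance) < 2L) stop("need at least 2 SNPs")
  groups <- t(importance)                     # accessions x SNPs
  control <- as.numeric(importance)
  res <- .dunnettCore(groups, control, side = side, seed = seed)
  if (res$zeroVariance) {
    warning("all importance scores identical: no SNP can be selected")
    sel <- rep(FALSE, nrow(importance))
  } else {
    sel <- !is.na(res$p_adj) & res$p_adj < alpha
    if (!is.null(topK) && sum(sel) > topK) {
      keep <- order(res$p_adj, -res$statistic)[seq_len(topK)]
      sel <- seq_len(nrow(importance)) %in% keep
    }
  }
  ids <- rownames(importance) %||% sprintf("snp%05d", seq_len(nrow(importance)))
  tab <- data.frame(snp_id = ids, chrom = NA_character_, pos = NA_integer_,
                    mean_score = rowMeans(importance),
                    statistic = res$statistic, p_adj = res$p_adj,
                    selected = sel, row.names = NULL)
  if (!is.null(snpMap)) {
    mi <- match(tab$snp_id, snpMap$snp_id)
    tab$chrom <- snpMap$chrom[mi]
    tab$pos <- snpMap$pos[mi]
  }
  new("SnpSelection", table = tab, alpha = alpha, side = side,
      controlMean = mean(control))
}

setMethod("show", "SnpSelection", function(object) {
  cat(sprintf("SnpSelection: %d of %d SNPs selected (alpha %.3g, %s)\n",
              sum(object@table$selected), nrow(object@table),
              object@alpha, object@side))
})

#' Genotype-class t-tests of trait differences for chosen SNPs
#'
#' For each SNP, accessions are split into the reference-homozygous,
#' heterozygous and alternative-homozygous classes and two-sample two-sided
#' Student's t-tests are run for every pair of classes with at least two
#' members; the per-SNP minimum p-value is reported.  SNPs with fewer than
#' two usable classes are flagged untestable.  P-values are unadjusted
#' (screened at plain p < 0.05 in the chickpea study).
#'
#' @param gset a [GenotypeSet-class] with the trait in `colData`.
#' @param snpIds SNP ids to test (default: all).
#' @param trait trait column name.
#' @return data.frame with `snp_id`, `n0`, `n1`, `n2`, `min_p`, `testable`,
#'   `skipped_pairs`.
#' @export
genotypeClassTTest <- function(gset, snpIds = NULL, trait = "trait") {
  traits <- traitValues(gset, trait)
  codes <- genoCodes(gset)
  map <- snpMap(gset)
  if (is.null(snpIds)) snpIds <- map$snp_id
  idx <- match(snpIds, map$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(utils::head(snpIds[is.na(idx)], 5),
                             collapse = ", "))
  rows <- lapply(seq_along(idx), function(r) {
    g <- codes[, idx[r]]
    cls <- split(traits[!is.na(g)], g[!is.na(g)])
    sizes <- vapply(c("0", "1", "2"), function(k)
      length(cls[[k]]) %||% 0L, numeric(1))
    usable <- names(cls)[vapply(cls, length, integer(1)) >= 2L]
    pairs <- if (length(usable) >= 2L) utils::combn(usable, 2,
                                                    simplify = FALSE) else
      list()
    ps <- vapply(pairs, function(pr) {
      a <- cls[[pr[1]]]; b <- cls[[pr[2]]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b)$p.value
    }, numeric(1))
    data.frame(snp_id = snpIds[r], n0 = sizes[1], n1 = sizes[2],
               n2 = sizes[3],
               min_p = if (length(ps)) min(ps) else NA_real_,
               testable = length(ps) > 0,
               skipped_pairs = sum(vapply(cls, length, integer(1)) == 1L))
  })
  do.call(rbind, rows)
}

#' Export a SNP selection as TSV and/or BED intervals
#'
#' The BED export is 0-based half-open (`pos - 1`, `pos`) for selected SNPs
#' only, suitable for genome-browser overlay.
#'
#' @param selection a [SnpSelection-class].
#' @param tsv,bed output paths (either may be `NULL`).
#' @export
exportSelection <- function(selection, tsv = NULL, bed = NULL) {
  tab <- selection@table
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed)) {
    sel <- tab[tab$selected & !is.na(tab$pos), ]
    utils::write.table(
      data.frame(sel$chrom, sel$pos - 1L, sel$pos, sel$snp_id),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(selection)
}
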