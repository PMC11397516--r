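#' Simulate a biallelic genotype panel with optional population structure
#'
#' Ancestral minor-allele frequencies are drawn uniformly on `mafRange`.
#' With `nSubpops > 1` and divergence `fst > 0`, per-subpopulation allele
#' frequencies follow the Balding-Nichols model
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`; genotypes are then
#' `Binomial(2, p)` draws.  Missing calls (if any) are placed uniformly at
#' random.  The subpopulation label of every accession is stored in
#' `colData(x)$subpop`.
#'
#' The defaults mirror the shape of the chickpea panel the method was
#' developed on (hundreds of accessions, thousands of SNPs) scaled to
#' desk-size problems; all parameters are explicit.
#'
#' @param nAccessions,nSnps panel dimensions.
#' @param mafRange ancestral frequency range, a sub-interval of (0, 0.5].
#' @param nSubpops number of subpopulations (>= 1).
#' @param fst Balding-Nichols divergence F in `[0, 1)`; ignored when
#'   `nSubpops == 1`.
#' @param missingRate fraction of calls set to `NA`.
#' @param nChrom number of chromosome labels over which SNPs are spread.
#' @param seed integer seed.
#' @return a [GenotypeSet-class].
#' @export
simulateGenotypes <- function(nAccessions = 120L, nSnps = 300L,
                              mafRange = c(0.05, 0.5), nSubpops = 1L,
                              fst = 0, missingRate = 0, nChrom = 8L,
                              seed = 1L) {
  stopifnot(nAccessions >= 1, nSnps >= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5, mafRange[1] <= mafRange[2],
            nSubpops >= 1, fst >= 0, fst < 1,
            missingRate >= 0, missingRate < 1)
  set.seed(seed)
  p0 <- stats::runif(nSnps, mafRange[1], mafRange[2])
  subpop <- sort(rep_len(seq_len(nSubpops), nAccessions))
  if (nSubpops > 1L && fst > 0) {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    P <- vapply(seq_len(nSubpops), function(s)
      stats::rbeta(nSnps, a, b), numeric(nSnps))   # nSnps x nSubpops
  } else {
    P <- matrix(p0, nSnps, nSubpops)
  }
  codes <- matrix(0L, nAccessions, nSnps)
  for (i in seq_len(nAccessions))
    codes[i, ] <- stats::rbinom(nSnps, 2L, P[, subpop[i]])
  if (missingRate > 0) {
    nm <- round(missingRate * length(codes))
    codes[sample(length(codes), nm)] <- NA_integer_
  }
  rownames(codes) <- sprintf("ACC%04d", seq_len(nAccessions))
  chrom <- sort(rep_len(seq_len(nChrom), nSnps))
  pos <- unlist(lapply(split(seq_len(nSnps), chrom), function(ix)
    sort(sample.int(1e7, length(ix)))), use.names = FALSE)
  map <- data.frame(chrom = paste0("Ca", chrom), pos = pos,
                    snp_id = sprintf("snp%05d", seq_len(nSnps)))
  colnames(codes) <- map$snp_id
  g <- GenotypeSet(codes, snpMap = map)
  colData(g)$subpop <- subpop
  metadata(g)$sim <- list(mafRange = mafRange, nSubpops = nSubpops,
                          fst = fst, missingRate = missingRate, seed = seed,
                          ancestralFreq = p0)
  g
}

#' Simulate an additive quantitative trait on a genotype panel
#'
#' `nCausal` SNPs are drawn at random, given Gaussian effect sizes
#' `beta ~ N(0, effectSd^2)`, and the genetic value of each accession is the
#' dosage-weighted sum (missing calls count as dosage 0).  Gaussian noise is
#' added with variance `var(g) (1 - h2) / h2` so the realised heritability
#' targets `h2`; with `h2 = 1` the trait is exactly linear in the genotypes,
#' and with `h2 = 0` the genetic term is dropped and the noise variance set
#' to `var(g)`.  The result is mapped linearly onto `traitRange` when given
#' (emulating, e.g., a thousand-seed-weight-like 110-440 g spread),
#' otherwise scaled by `scale` and shifted by `offset`.  For count-like
#' traits (`integerTrait = TRUE`) values are rounded and truncated at 0.
#'
#' @param gset a [GenotypeSet-class].
#' @param nCausal number of causal SNPs.
#' @param effectSd standard deviation of the effect sizes.
#' @param h2 narrow-sense heritability target in `[0, 1]`.
#' @param offset,scale affine mapping of the raw trait.
#' @param traitRange optional length-2 target range; overrides
#'   `offset`/`scale`.
#' @param integerTrait round and truncate at 0 (seeds-per-plant style).
#' @param traitName trait column name written to `colData`.
#' @param seed integer seed.
#' @return the [GenotypeSet-class] with the trait added to `colData` and a
#'   `groundTruth` record (causal ids, effects, realised h2, noise sd) in
#'   `metadata`.
#' @export
simulatePhenotype <- function(gset, nCausal = 10L, effectSd = 1, h2 = 0.8,
                              offset = 0, scale = 1, traitRange = NULL,
                              integerTrait = FALSE, traitName = "trait",
                              seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1, nCausal >= 1, nCausal <= ncol(genoCodes(gset)))
  set.seed(seed)
  codes <- genoCodes(gset)
  codes[is.na(codes)] <- 0L
  causal <- sort(sample(ncol(codes), nCausal))
  beta <- stats::rnorm(nCausal, 0, effectSd)
  g <- as.numeric(codes[, causal, drop = FALSE] %*% beta)
  vg <- stats::var(g)
  if (h2 == 1 && vg == 0)
    stop("h2 = 1 requires non-zero genetic variance ",
         "(causal SNPs are monomorphic)")
  eps <- if (h2 == 1) {
    numeric(length(g))
  } else if (h2 == 0) {
    g <- numeric(length(g))                   # pure-noise trait
    stats::rnorm(length(g), 0, sqrt(max(vg, 1)))
  } else {
    stats::rnorm(length(g), 0, sqrt(vg * (1 - h2) / h2))
  }
  raw <- g + eps
  if (!is.null(traitRange)) {
    stopifnot(length(traitRange) == 2L, diff(traitRange) > 0)
    rr <- range(raw)
    scale <- diff(traitRange) / diff(rr)
    offset <- traitRange[1] - scale * rr[1]
  }
  y <- offset + scale * raw
  if (integerTrait) y <- pmax(0, round(y))
  realised <- if (stats::var(y) > 0)
    stats::var(scale * g) / stats::var(y) else NA_real_
  traitValues(gset, traitName) <- stats::setNames(y, rownames(codes))
  metadata(gset)$groundTruth <- list(
    trait = traitName, causal = snpMap(gset)$snp_id[causal],
    causalIndex = causal, beta = beta, h2Target = h2,
    h2Realised = realised, offset = offset, scale = scale, seed = seed)
  gset
}

#' Ground-truth record of a simulated trait
#' @param gset a [GenotypeSet-class] produced by [simulatePhenotype()].
#' @return list with causal SNP ids, effect sizes and realised heritability.
#' @export
groundTruth <- function(gset) metadata(gset)$groundTruth
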