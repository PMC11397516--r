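#' Split AIOs into square blocks for dictionary learning
#'
#' Each image is cut into non-overlapping `blockSide x blockSide` patches
#' (all three channels), flattened to rows of a block matrix.  Block
#' provenance (accession, block position within its image) is retained so
#' that per-accession features can be computed later.  Blocks are ordered
#' image by image; this realizes the "mosaic of all images" idea in an
#' arrangement-independent way.
#'
#' @param aios list of [AIO-class] objects (or a single one).
#' @param blockSide block side in pixels; must divide the image side.
#' @return list with `blocks` (matrix, nBlocks x `3 * blockSide^2`),
#'   `accession` (factor) and `blockIndex` (integer within-image position).
#' @examples
#' a <- encodeAIO(rep(0:2, length.out = 50), width = 32, height = 32)
#' b <- extractBlocks(list(a), blockSide = 16)
#' nrow(b$blocks)  # (32/16)^2 = 4
#' @export
extractBlocks <- function(aios, blockSide = 16L) {
  if (is(aios, "AIO")) aios <- list(aios)
  d <- dim(aios[[1]]@pixels)
  if (d[1] %% blockSide != 0 || d[2] %% blockSide != 0)
    stop("configuration error: block side ", blockSide,
         " does not divide the image side ", d[1], "x", d[2])
  nbh <- d[1] %/% blockSide
  nbw <- d[2] %/% blockSide
  per <- nbh * nbw
  blocks <- matrix(0, length(aios) * per, 3L * blockSide^2)
  acc <- character(length(aios) * per)
  r <- 0L
  for (a in aios) {
    stopifnot(identical(dim(a@pixels), d))
    for (bj in seq_len(nbw)) {
      for (bi in seq_len(nbh)) {
        r <- r + 1L
        rows <- ((bi - 1L) * blockSide + 1L):(bi * blockSide)
        cols <- ((bj - 1L) * blockSide + 1L):(bj * blockSide)
        blocks[r, ] <- as.vector(a@pixels[rows, cols, ])
        acc[r] <- a@accession
      }
    }
  }
  list(blocks = blocks, accession = factor(acc, levels = unique(acc)),
       blockIndex = rep(seq_len(per), times = length(aios)))
}

#' Learn a block dictionary by alternating sparse coding and SVD atom updates
#'
#' Iterates two steps until the mean relative reconstruction error of the
#' training blocks reaches `targetError` or `maxIter` passes are done:
#' (1) code every block against the current atoms with orthogonal matching
#' pursuit (at most `maxSparsity` atoms per block); (2) update each atom as
#' the leading singular vector of the residual restricted to the blocks that
#' use it, which simultaneously refreshes those blocks' coefficients.
#' Atoms that fall out of use are re-seeded with the currently
#' worst-reconstructed block.  Atoms are kept at unit Euclidean norm.
#'
#' @param blocks block matrix from [extractBlocks()] (or its `$blocks`).
#' @param nAtoms dictionary size (default 16).
#' @param targetError relative reconstruction error target (default 0.01).
#' @param maxSparsity maximum atoms per block during learning and coding
#'   (default 10).
#' @param maxIter iteration cap; reaching it without convergence is reported
#'   via a warning and the `converged` slot.
#' @param seed integer seed for the initial atom draw.
#' @return a [SnpDictionary-class].
#' @export
learnDictionary <- function(blocks, nAtoms = 16L, targetError = 0.01,
                            maxSparsity = 10L, maxIter = 30L, seed = 1L) {
  if (is.list(blocks)) blocks <- blocks$blocks
  n <- nrow(blocks)
  if (n < nAtoms)
    stop("need at least as many blocks (", n, ") as atoms (", nAtoms, ")")
  norms <- sqrt(rowSums(blocks^2))
  if (all(norms == 0)) stop("all blocks are zero; nothing to learn")
  set.seed(seed)
  cand <- which(norms > 0)
  init <- sample(cand, min(nAtoms, length(cand)))
  D <- blocks[init, , drop = FALSE]
  if (nrow(D) < nAtoms)                       # duplicate-pad degenerate case
    D <- D[rep(seq_len(nrow(D)), length.out = nAtoms), , drop = FALSE]
  D <- D / sqrt(rowSums(D^2))
  err <- Inf
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    cd <- .omp_encode_batch(blocks, D, as.integer(maxSparsity), targetError)
    err <- mean(cd$relres[norms > 0])
    if (err <= targetError) break
    C <- Matrix::sparseMatrix(i = cd$i, j = cd$j, x = cd$x,
                              dims = c(n, nAtoms))
    R <- blocks - as.matrix(C %*% D)          # global residual
    for (k in seq_len(nAtoms)) {
      use <- which(C[, k] != 0)
      if (!length(use)) {                     # dead atom: re-seed
        rr <- sqrt(rowSums(R^2)) / pmax(norms, 1e-12)
        worst <- which.max(rr * (norms > 0))
        if (norms[worst] > 0) {
          D[k, ] <- blocks[worst, ] / norms[worst]
        }
        next
      }
      Ek <- R[use, , drop = FALSE] +
        as.matrix(C[use, k, drop = FALSE]) %*% D[k, , drop = FALSE]
      if (length(use) == 1L) {
        v <- as.numeric(Ek)
        nv <- sqrt(sum(v^2))
        if (nv > 0) {
          D[k, ] <- v / nv
          C[use, k] <- nv
        }
      } else {
        sv <- svd(Ek, nu = 1, nv = 1)
        D[k, ] <- as.numeric(sv$v)
        C[use, k] <- sv$u[, 1] * sv$d[1]
      }
      R[use, ] <- Ek - as.matrix(C[use, k, drop = FALSE]) %*%
        D[k, , drop = FALSE]
    }
  }
  converged <- err <= targetError
  if (!converged)
    warning(sprintf(paste0("dictionary learning stopped at the iteration ",
                           "cap (%d) with mean relative error %.4g > %.4g"),
                    maxIter, err, targetError))
  new("SnpDictionary", atoms = D, blockSide = as.integer(
        round(sqrt(ncol(blocks) / 3))),
      targetError = targetError, maxSparsity = as.integer(maxSparsity),
      trainError = err, iterations = it, converged = converged,
      seed = as.integer(seed))
}

#' @rdname SnpDictionary-accessors
#' @export
setMethod("dictAtoms", "SnpDictionary", function(x) x@atoms)

setMethod("show", "SnpDictionary", function(object) {
  cat(sprintf(paste0("SnpDictionary: %d atoms, block %dx%d, target error ",
                     "%.3g, achieved %.3g (%s after %d iterations)\n"),
              nrow(object@atoms), object@blockSide, object@blockSide,
              object@targetError, object@trainError,
              if (object@converged) "converged" else "cap reached",
              object@iterations))
})

#' Sparse-code blocks against a frozen dictionary
#'
#' Greedy orthogonal matching pursuit: per block, atoms are added one at a
#' time (never repeating), the coefficients of the selected set are re-solved
#' by least squares at each step, and coding stops when the relative residual
#' drops below the dictionary's `targetError` or `maxSparsity` atoms are in
#' use.
#'
#' @param blocks output of [extractBlocks()] (the list, to keep provenance)
#'   or a bare block matrix.
#' @param dictionary a [SnpDictionary-class].
#' @return a [SparseCodes-class].
#' @export
sparseCode <- function(blocks, dictionary) {
  prov <- NULL
  if (is.list(blocks)) {
    prov <- blocks
    blocks <- blocks$blocks
  }
  if (ncol(blocks) != ncol(dictionary@atoms))
    stop("block dimension ", ncol(blocks), " does not match the dictionary (",
         ncol(dictionary@atoms), ")")
  cd <- .omp_encode_batch(blocks, dictionary@atoms,
                          dictionary@maxSparsity, dictionary@targetError)
  C <- Matrix::sparseMatrix(i = cd$i, j = cd$j, x = cd$x,
                            dims = c(nrow(blocks), nrow(dictionary@atoms)))
  if (is.null(prov)) {
    acc <- factor(rep("block-set", nrow(blocks)))
    bidx <- seq_len(nrow(blocks))
  } else {
    acc <- prov$accession
    bidx <- prov$blockIndex
  }
  new("SparseCodes", coef = C, accession = acc,
      blockIndex = as.integer(bidx), relres = as.numeric(cd$relres))
}

setMethod("show", "SparseCodes", function(object) {
  cat(sprintf(paste0("SparseCodes: %d blocks x %d atoms, %d accessions, ",
                     "%.1f nonzeros/block, mean rel. residual %.3g\n"),
              nrow(object@coef), ncol(object@coef),
              nlevels(object@accession),
              length(object@coef@x) / nrow(object@coef),
              mean(object@relres)))
})
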