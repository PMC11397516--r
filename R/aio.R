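#' One-hot pseudo-colour encoding of a single genotype code
#'
#' Maps a dosage code to an (R, G, B) pixel: the R channel indicates the
#' reference homozygote (code 0), G the heterozygote (code 1) and B the
#' alternative homozygote (code 2).  A missing call maps to the all-zero
#' pixel, so no indicator fires.
#'
#' @param code integer genotype code in `{0, 1, 2}` or `NA`.
#' @return named numeric vector `c(R = , G = , B = )`.
#' @examples
#' encodePixel(0L)  # c(R = 1, G = 0, B = 0)
#' @export
encodePixel <- function(code) {
  if (length(code) != 1L)
    stop("encodePixel() takes a single code; use encodeAIO() for vectors")
  if (!is.na(code) && !code %in% c(0, 1, 2))
    stop("genotype code must be 0, 1, 2 or NA; got ", code)
  c(R = as.numeric(!is.na(code) && code == 0),
    G = as.numeric(!is.na(code) && code == 1),
    B = as.numeric(!is.na(code) && code == 2))
}

#' Pixel-to-SNP index of the cyclic row-major layout
#'
#' Pixel `(x, y)` (0-based column x, row y) carries SNP
#' `(y * width + x) mod nSnps`: the SNP list fills the image left to right,
#' row by row, and is reused from the start until all pixels are filled.
#'
#' @param width,height image dimensions in pixels.
#' @param nSnps number of SNPs laid out; must not exceed `width * height`.
#' @return integer matrix `height x width` of 1-based SNP indices, so that
#'   entry `[y + 1, x + 1]` is the SNP shown at pixel `(x, y)`.
#' @export
snpPixelIndex <- function(width, height, nSnps) {
  if (nSnps > width * height)
    stop("image too small: ", nSnps, " SNPs cannot fit into ",
         width, "x", height, " pixels")
  p <- outer(seq_len(height) - 1L, seq_len(width) - 1L,
             function(y, x) y * width + x)
  (p %% nSnps) + 1L
}

#' Encode a genotype vector as an artificial image object
#'
#' @param genotypes integer vector of codes in `{0, 1, 2, NA}`.
#' @param width,height image dimensions (default 128 x 128).
#' @param accession optional accession id stored with the image.
#' @return an [AIO-class].
#' @examples
#' a <- encodeAIO(c(0L, 1L, 2L), width = 3, height = 2)
#' aioPixels(a)[1, 1, ]  # red pixel for code 0
#' @export
encodeAIO <- function(genotypes, width = 128L, height = 128L,
                      accession = NA_character_) {
  n <- length(genotypes)
  if (n < 1L) stop("empty genotype vector")
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; first offender at position ",
         which(bad)[1])
  idx <- snpPixelIndex(width, height, n)
  g <- genotypes[idx]                        # height x width recycled codes
  px <- array(0, dim = c(height, width, 3))
  px[, , 1][!is.na(g) & g == 0] <- 1
  px[, , 2][!is.na(g) & g == 1] <- 1
  px[, , 3][!is.na(g) & g == 2] <- 1
  new("AIO", pixels = px, nSnps = as.integer(n),
      accession = as.character(accession))
}

#' Decode an AIO back to its genotype vector
#'
#' Inverts [encodeAIO()]: reads the one-hot pixel at every placement of each
#' SNP and demands that all cyclic repetitions agree.  Non-one-hot pixels or
#' conflicting placements raise an integrity error.
#'
#' @param aio an [AIO-class].
#' @param nSnps number of SNPs to decode (defaults to the value stored in
#'   the object).
#' @return integer vector of codes with `NA` for missing.
#' @export
decodeAIO <- function(aio, nSnps = aio@nSnps) {
  px <- aio@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  s <- px[, , 1] + px[, , 2] + px[, , 3]
  if (!all(s %in% c(0, 1))) stop("integrity error: non-one-hot pixel found")
  code <- matrix(NA_integer_, h, w)
  code[px[, , 1] == 1] <- 0L
  code[px[, , 2] == 1] <- 1L
  code[px[, , 3] == 1] <- 2L
  idx <- snpPixelIndex(w, h, nSnps)
  out <- integer(nSnps)
  for (k in seq_len(nSnps)) {
    v <- unique(code[idx == k])
    if (length(v) > 1L)
      stop("integrity error: conflicting placements for SNP index ", k)
    out[k] <- v
  }
  out
}

#' @rdname AIO-accessors
#' @export
setMethod("aioPixels", "AIO", function(x) x@pixels)

setMethod("show", "AIO", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("AIO %dx%d px, %d SNPs (accession %s)\n", d[2], d[1],
              object@nSnps, object@accession))
})

#' Export an AIO as a lossless PNG image for visual inspection
#'
#' @param aio an [AIO-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeAIOPng <- function(aio, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  png::writePNG(aio@pixels, target = path)
  invisible(path)
}

## internal: encode all accessions of a GenotypeSet
.encodeAll <- function(gset, side) {
  codes <- genoCodes(gset)
  lapply(seq_len(nrow(codes)), function(i)
    encodeAIO(codes[i, ], width = side, height = side,
              accession = rownames(codes)[i]))
}
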