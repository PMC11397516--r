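#' Construct a GenotypeSet
#'
#' @param codes integer matrix of genotype dosages, accessions x SNPs,
#'   values in `{0, 1, 2, NA}`.  Row names (if present) are used as
#'   accession ids unless `accessionIds` is given.
#' @param snpMap data.frame with columns `chrom`, `pos` (1-based) and
#'   `snp_id`, one row per SNP.  If `NULL`, a placeholder map (`chrom "un"`,
#'   positions `1..m`) is created from the column names of `codes`.
#' @param accessionIds character vector of unique accession ids.
#' @param traits optional data.frame (or named numeric vector, stored as
#'   trait `"trait"`) of per-accession trait values.
#'
#' @return a [GenotypeSet-class] object.
#' @examples
#' g <- GenotypeSet(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'                         dimnames = list(c("a1", "a2"), c("s1", "s2"))))
#' genoCodes(g)
#' @export
GenotypeSet <- function(codes, snpMap = NULL, accessionIds = NULL,
                        traits = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(accessionIds)) accessionIds <- rownames(codes)
  if (is.null(accessionIds))
    accessionIds <- sprintf("ACC%04d", seq_len(nrow(codes)))
  if (is.null(snpMap)) {
    ids <- colnames(codes)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(ncol(codes)))
    snpMap <- data.frame(chrom = "un", pos = seq_len(ncol(codes)),
                         snp_id = ids)
  }
  stopifnot(nrow(snpMap) == ncol(codes), length(accessionIds) == nrow(codes))
  cd <- DataFrame(row.names = accessionIds)
  if (!is.null(traits)) {
    if (is.numeric(traits) && !is.null(names(traits)))
      traits <- data.frame(trait = traits[accessionIds])
    stopifnot(nrow(traits) == length(accessionIds))
    cd <- DataFrame(traits, row.names = accessionIds)
  }
  se <- SummarizedExperiment(
    assays = list(codes = t(codes)),
    rowData = DataFrame(snpMap[, c("chrom", "pos", "snp_id")],
                        row.names = snpMap$snp_id),
    colData = cd)
  new("GenotypeSet", se)
}

#' Accessors for GenotypeSet
#'
#' `genoCodes` returns the dosage matrix in accession-major orientation
#' (accessions x SNPs); `snpMap` the marker map as a data.frame;
#' `accessionIds` the accession ids; `traitValues` a named numeric vector
#' for one trait column of `colData`.
#'
#' @param x a [GenotypeSet-class].
#' @param trait trait column name in `colData(x)`.
#' @param value named numeric vector of trait values (names matched against
#'   accession ids; unmatched ids raise an error).
#' @param ... unused.
#' @name GenotypeSet-accessors
#' @aliases genoCodes snpMap accessionIds traitValues traitValues<-
NULL

#' @rdname GenotypeSet-accessors
#' @export
setMethod("genoCodes", "GenotypeSet", function(x, ...) t(assay(x, "codes")))

#' @rdname GenotypeSet-accessors
#' @export
setMethod("snpMap", "GenotypeSet", function(x, ...)
  as.data.frame(rowData(x), row.names = NULL))

#' @rdname GenotypeSet-accessors
#' @export
setMethod("accessionIds", "GenotypeSet", function(x) colnames(x))

#' @rdname GenotypeSet-accessors
#' @export
setMethod("traitValues", "GenotypeSet", function(x, trait = "trait", ...) {
  if (!trait %in% colnames(colData(x)))
    stop("no trait column '", trait, "' in colData")
  stats::setNames(as.numeric(colData(x)[[trait]]), colnames(x))
})

#' @rdname GenotypeSet-accessors
#' @export
setReplaceMethod("traitValues", "GenotypeSet", function(x, trait = "trait",
                                                        value) {
  miss <- setdiff(colnames(x), names(value))
  if (length(miss))
    stop("trait values missing for accessions: ",
         paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(names(value), colnames(x))
  if (length(extra))
    warning(length(extra), " trait id(s) not present in the genotype set")
  colData(x)[[trait]] <- as.numeric(value[colnames(x)])
  validObject(x)
  x
})

setMethod("show", "GenotypeSet", function(object) {
  cat("GenotypeSet:", ncol(object), "accessions x", nrow(object), "SNPs\n")
  a <- assay(object, "codes")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(a))))
  tr <- setdiff(colnames(colData(object)), "subpop")
  if (length(tr)) cat("  traits:", paste(tr, collapse = ", "), "\n")
})

## ---- reading -------------------------------------------------------------

#' Read genotypes from VCF or a delimited dosage matrix
#'
#' VCF input uses the `GT` field only and requires biallelic sites; sites
#' with more than one ALT allele are rejected.  Matrix input is a delimited
#' text file with a header row of SNP ids, one accession per row, the
#' accession id in the first column, dosage codes 0/1/2 and missing values
#' written as `NA`.  An optional side-car map file supplies chromosome and
#' position per SNP; otherwise a placeholder map is generated.
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"matrix"`.
#' @param mapFile optional TSV with columns `chrom`, `pos`, `snp_id`
#'   (matrix format only).
#' @param sep field separator for matrix format.
#' @return a [GenotypeSet-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("vcf", "matrix"), mapFile = NULL,
                          sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    stop("parse error in '", path, "': file is empty")
  if (format == "vcf") .readVcfGenotypes(path) else
    .readMatrixGenotypes(path, mapFile, sep)
}

.readVcfGenotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("parse error in '", path, "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("non-biallelic site(s) at line(s) with id ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "),
         "; split them upstream (e.g. 'bcftools norm -m-') first")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0)
    stop("parse error in '", path, "': no sample GT fields found")
  code1 <- function(g) {
    g <- sub(":.*", "", g)
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_integer_)
      a <- suppressWarnings(as.integer(a))
      if (any(is.na(a)) || any(!a %in% 0:1)) return(NA_integer_)
      sum(a)
    }, integer(1))
  }
  codes <- apply(gt, 2, code1)               # SNPs x samples
  if (is.null(dim(codes)))
    codes <- matrix(codes, nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  GenotypeSet(t(codes),
              snpMap = data.frame(chrom = fix[, "CHROM"],
                                  pos = as.integer(fix[, "POS"]),
                                  snp_id = ids),
              accessionIds = colnames(gt))
}

.readMatrixGenotypes <- function(path, mapFile, sep) {
  d <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                  check.names = FALSE, row.names = 1,
                                  na.strings = "NA",
                                  colClasses = "character"),
                error = function(e)
                  stop("parse error in '", path, "': ", conditionMessage(e)))
  codes <- as.matrix(d)
  suppressWarnings(storage.mode(codes) <- "integer")
  bad <- which(!is.na(codes) & !(codes %in% 0:2))
  if (any(is.na(codes) & !is.na(as.matrix(d))) || length(bad))
    stop("validation error in '", path,
         "': genotype codes must be 0, 1, 2 or NA")
  map <- NULL
  if (!is.null(mapFile)) {
    map <- utils::read.table(mapFile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "snp_id") %in% colnames(map)))
    if (!identical(as.character(map$snp_id), colnames(codes)))
      stop("map file SNP ids do not match the matrix header")
  }
  GenotypeSet(codes, snpMap = map)
}

#' Write a GenotypeSet as a delimited dosage matrix (plus optional map)
#'
#' @param x a [GenotypeSet-class].
#' @param path output path for the matrix file.
#' @param mapFile optional path for the side-car marker map TSV.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, mapFile = NULL) {
  codes <- genoCodes(x)
  df <- data.frame(accession = rownames(codes), codes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(mapFile))
    utils::write.table(snpMap(x), mapFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read or write a two-column trait table
#'
#' The file has a header and two columns: accession id and a numeric trait
#' value.  Duplicated ids and non-numeric values are errors (with the
#' offending row reported).
#'
#' @param path file path.
#' @return named numeric vector of trait values.
#' @export
readTraits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (ncol(d) < 2) stop("parse error in '", path, "': expected two columns")
  vals <- suppressWarnings(as.numeric(d[[2]]))
  bad <- which(is.na(vals) & !(d[[2]] %in% c("NA", "")))
  if (length(bad))
    stop("validation error in '", path, "': non-numeric trait value at row ",
         bad[1] + 1L)
  if (anyDuplicated(d[[1]]))
    stop("validation error in '", path, "': duplicated accession id '",
         d[[1]][duplicated(d[[1]])][1], "'")
  if (any(!is.finite(vals)))
    stop("validation error in '", path, "': non-finite trait value")
  stats::setNames(vals, d[[1]])
}

#' @rdname readTraits
#' @param traits named numeric vector.
#' @param traitName header name for the value column.
#' @export
writeTraits <- function(traits, path, traitName = "trait") {
  df <- data.frame(accession = names(traits), value = as.numeric(traits))
  names(df)[2] <- traitName
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
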