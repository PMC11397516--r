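#' @rdname GenotypeSet-accessors
#' @export
setGeneric("genoCodes", function(x, ...) standardGeneric("genoCodes"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("snpMap", function(x, ...) standardGeneric("snpMap"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("traitValues", function(x, trait = "trait", ...) standardGeneric("traitValues"))

#' @rdname GenotypeSet-accessors
#' @export
setGeneric("traitValues<-",
           function(x, trait = "trait", value) standardGeneric("traitValues<-"))

#' Accessors for AIO
#'
#' `aioPixels` returns the height x width x 3 pixel array.
#'
#' @param x an [AIO-class].
#' @name AIO-accessors
#' @export
setGeneric("aioPixels", function(x) standardGeneric("aioPixels"))

#' Accessors for SnpDictionary
#'
#' `dictAtoms` returns the atoms matrix (`nAtoms x blockDim`, unit-norm
#' rows).
#'
#' @param x a [SnpDictionary-class].
#' @name SnpDictionary-accessors
#' @export
setGeneric("dictAtoms", function(x) standardGeneric("dictAtoms"))

#' @export
setGeneric("predictTraits", function(object, genotypes, ...)
  standardGeneric("predictTraits"))

#' @rdname trainGenomicModel
#' @export
setGeneric("cvReport", function(object) standardGeneric("cvReport"))
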