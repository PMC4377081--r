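#' @rdname GenotypeMatrix-class
#' @param x,object a `GenotypeMatrix`
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ShrinkageResult-class
#' @param object a `ShrinkageResult` or `RidgeModel`
#' @export
setGeneric("kHat", function(object) standardGeneric("kHat"))

#' @rdname ShrinkageResult-class
#' @export
setGeneric("rHat", function(object) standardGeneric("rHat"))

#' @rdname RidgeModel-class
#' @export
setGeneric("coefOriginal", function(object) standardGeneric("coefOriginal"))

#' @rdname RidgeModel-class
#' @export
setGeneric("interceptOriginal", function(object) standardGeneric("interceptOriginal"))
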