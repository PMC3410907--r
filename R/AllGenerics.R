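#' @rdname HaplotypePanel-class
#' @param x An object.
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname GenotypeMatrix-class
#' @param x An object.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GeneticMap-class
#' @param x An object.
#' @export
setGeneric("mapAnchors", function(x) standardGeneric("mapAnchors"))

#' @rdname SummaryStats-class
#' @param x An object.
#' @export
setGeneric("statRecords", function(x) standardGeneric("statRecords"))

#' @rdname SummaryStats-class
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname ArrayDesign-class
#' @param x An object.
#' @export
setGeneric("designEntries", function(x) standardGeneric("designEntries"))

#' Greedy LD pruning
#'
#' @param x A [HaplotypePanel-class] or [GenotypeMatrix-class].
#' @param ids Candidate variant ids (default: all variants of `x`).
#' @param r2Max Retained pairs must satisfy r-squared <= `r2Max`.
#' @param windowBp Only pairs closer than this are constrained.
#' @param ... Passed to methods.
#' @return Character vector of retained ids, in position order.
#' @export
setGeneric("ldPrune", function(x, ids = variantIds(x), r2Max = 0.3,
                               windowBp = 1e6L, ...) standardGeneric("ldPrune"))
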