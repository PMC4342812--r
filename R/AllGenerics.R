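#' Extract the beta-value matrix
#'
#' @param x A [BetaMatrix-class] object.
#' @return Numeric matrix of methylation fractions (probes x samples).
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Sample-to-condition assignment
#'
#' @param x A [BetaMatrix-class] object.
#' @return Named character vector mapping sample id to condition label.
#' @export
setGeneric("conditionOf", function(x) standardGeneric("conditionOf"))

#' Detection p-value matrix, if present
#'
#' @param x A [BetaMatrix-class] object.
#' @return Numeric matrix of detection p-values, or `NULL` when the assay was
#'   not supplied.
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname betaValues
setMethod("betaValues", "BetaMatrix", function(x) assay(x, "beta"))

#' @rdname conditionOf
setMethod("conditionOf", "BetaMatrix", function(x) {
    stats::setNames(as.character(colData(x)$condition), colnames(x))
})

#' @rdname detectionP
setMethod("detectionP", "BetaMatrix", function(x) {
    if ("detectionP" %in% assayNames(x)) assay(x, "detectionP") else NULL
})
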