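#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
NULL

#' Condition vocabulary for the irradiation / demethylation study design
#'
#' The closed set of treatment-condition labels a [BetaMatrix] may carry:
#' mock (untreated control), aza (5-aza-2'-deoxycytidine, the demethylation
#' positive control), ir2gy and ir5gy (2 Gy and 5 Gy ionizing radiation).
#' Extra labels are rejected at the boundary rather than ignored, so that a
#' mislabelled sample can never silently enter the wrong contrast.
#'
#' @return Character vector of the four condition labels, in canonical order.
#' @export
#' @examples
#' conditionLevels()
conditionLevels <- function() c("mock", "aza", "ir2gy", "ir5gy")

#' Contrast vocabulary
#'
#' Each treated condition is compared against mock; these are the three
#' contrast labels used throughout the screen.
#'
#' @return Character vector of contrast labels.
#' @export
contrastLevels <- function() c("aza-vs-mock", "ir2gy-vs-mock", "ir5gy-vs-mock")

#' BetaMatrix: probe-by-sample methylation fractions
#'
#' An S4 container for Illumina 450K-style methylation data, extending
#' \linkS4class{SummarizedExperiment}. The `"beta"` assay holds methylation
#' fractions in \[0, 1\] (methylated intensity over combined intensity); an
#' optional `"detectionP"` assay holds per-probe, per-sample detection
#' p-values. `colData()$condition` assigns each sample one of the labels in
#' [conditionLevels()].
#'
#' Validity requires: every non-missing beta in \[0, 1\]; unique probe and
#' sample identifiers; condition labels from the closed vocabulary; and at
#' least one mock sample (the screen is meaningless without its control arm).
#'
#' @seealso [readBetaMatrix()], [writeBetaMatrix()], [betaValues()],
#'   [conditionOf()], [detectionP()]
#' @export
setClass("BetaMatrix", contains = "SummarizedExperiment")

.validBetaMatrix <- function(object) {
    msg <- character()
    if (!("beta" %in% assayNames(object)))
        return("assay 'beta' is required")
    b <- assay(object, "beta")
    if (!is.numeric(b))
        msg <- c(msg, "assay 'beta' must be numeric")
    bad <- which(!is.na(b) & (b < 0 | b > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        msg <- c(msg, sprintf(
            "beta value %.4g out of [0,1] at probe '%s', sample '%s'",
            b[i, j], rownames(object)[i], colnames(object)[j]))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!("condition" %in% colnames(colData(object)))) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        cond <- as.character(colData(object)$condition)
        unknown <- setdiff(unique(cond), conditionLevels())
        if (length(unknown) > 0)
            msg <- c(msg, sprintf("unknown condition label(s): %s",
                                  paste(unknown, collapse = ", ")))
        if (!any(cond == "mock"))
            msg <- c(msg, "at least one mock sample is required")
    }
    if ("detectionP" %in% assayNames(object)) {
        p <- assay(object, "detectionP")
        if (any(!is.na(p) & (p < 0 | p > 1)))
            msg <- c(msg, "detection p-values must lie in [0,1]")
    }
    if (length(msg) > 0) msg else TRUE
}

setValidity("BetaMatrix", .validBetaMatrix)

#' Construct a BetaMatrix
#'
#' @param beta Numeric matrix of methylation fractions in \[0, 1\], with probe
#'   ids as rownames and sample ids as colnames.
#' @param condition Character or factor of length `ncol(beta)` with one label
#'   from [conditionLevels()] per sample.
#' @param detectionP Optional numeric matrix of detection p-values, same
#'   dimensions as `beta`.
#' @return A validated [BetaMatrix-class] object.
#' @export
#' @examples
#' b <- matrix(c(0.8, 0.1, 0.4, 0.82, 0.12, 0.39), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaMatrix(b, condition = c("mock", "aza"))
BetaMatrix <- function(beta, condition, detectionP = NULL) {
    beta <- as.matrix(beta)
    assays <- list(beta = beta)
    if (!is.null(detectionP)) {
        detectionP <- as.matrix(detectionP)
        stopifnot(identical(dim(detectionP), dim(beta)))
        dimnames(detectionP) <- dimnames(beta)
        assays$detectionP <- detectionP
    }
    cd <- DataFrame(condition = factor(as.character(condition),
                                       levels = conditionLevels()),
                    row.names = colnames(beta))
    se <- SummarizedExperiment(assays = assays, colData = cd)
    new("BetaMatrix", se)
}

#' ScreenConfig: thresholds for the differential-methylation screen
#'
#' Holds the two calling criteria and the reliability-filter thresholds.
#' `deltaBetaMin` (default 0.2) is the minimum |delta-beta|; the 0.2 cut-off
#' corresponds to the 99% confidence interval of the 450K detection limit.
#' `foldMin` (default 1.5) is the minimum beta fold ratio between condition
#' means. `detectionPMax` (default 0.01) rejects probes whose signal is not
#' distinguishable from background in any sample. `mockReplicateDeltaMax`
#' (default 0.2) rejects probes whose mock replicates disagree by more than a
#' callable effect. `ratioFloor` (default 0.01) floors the ratio denominator
#' so fully demethylated probes keep a finite fold; it sits below array noise.
#'
#' @export
setClass("ScreenConfig", representation(
    deltaBetaMin = "numeric",
    foldMin = "numeric",
    detectionPMax = "numeric",
    mockReplicateDeltaMax = "numeric",
    ratioFloor = "numeric"
))

setValidity("ScreenConfig", function(object) {
    msg <- character()
    v <- c(deltaBetaMin = object@deltaBetaMin, foldMin = object@foldMin,
           detectionPMax = object@detectionPMax,
           mockReplicateDeltaMax = object@mockReplicateDeltaMax,
           ratioFloor = object@ratioFloor)
    if (any(lengths(list(object@deltaBetaMin, object@foldMin,
                         object@detectionPMax, object@mockReplicateDeltaMax,
                         object@ratioFloor)) != 1L))
        msg <- c(msg, "all thresholds must be scalar")
    else {
        if (any(v <= 0)) msg <- c(msg, "all thresholds must be positive")
        if (object@deltaBetaMin >= 1) msg <- c(msg, "deltaBetaMin must be < 1")
    }
    if (length(msg) > 0) msg else TRUE
})

#' @param deltaBetaMin Minimum absolute delta-beta for a call (fraction).
#' @param foldMin Minimum fold ratio between condition-mean betas.
#' @param detectionPMax Maximum tolerated detection p-value.
#' @param mockReplicateDeltaMax Maximum tolerated spread among mock replicates.
#' @param ratioFloor Floor applied to the ratio denominator.
#' @return A `ScreenConfig` object.
#' @rdname ScreenConfig-class
#' @export
#' @examples
#' screenConfig()
#' screenConfig(deltaBetaMin = 0.3)
screenConfig <- function(deltaBetaMin = 0.2, foldMin = 1.5,
                         detectionPMax = 0.01, mockReplicateDeltaMax = 0.2,
                         ratioFloor = 0.01) {
    new("ScreenConfig", deltaBetaMin = deltaBetaMin, foldMin = foldMin,
        detectionPMax = detectionPMax,
        mockReplicateDeltaMax = mockReplicateDeltaMax, ratioFloor = ratioFloor)
}

#' SyntheticTruth: planted structure behind a generated dataset
#'
#' Records everything the synthetic-data generator planted, so recovery can be
#' scored exactly: per-contrast planted probe effects (with a `callable` flag
#' for effects that survive clipping and satisfy both calling criteria by
#' construction), probes planted to fail the reliability filter, gene-level
#' expression / qMSP / occupancy effects, the probe-to-gene map, the noise
#' level, and the master seed.
#'
#' @export
setClass("SyntheticTruth", representation(
    plantedHypo = "data.frame",   # probe_id, contrast, delta_beta, callable
    plantedFailures = "data.frame", # probe_id, reason
    geneEffects = "data.frame",   # gene, condition, expr_fold, qmsp_rel, occ_decrease
    probeGeneMap = "data.frame",  # probe_id, gene
    noiseSd = "numeric",
    seed = "integer"
))

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth (seed ", object@seed, ")\n", sep = "")
    cat("  planted hypo effects: ", nrow(object@plantedHypo),
        " (", sum(object@plantedHypo$callable), " callable)\n", sep = "")
    cat("  planted filter failures: ", nrow(object@plantedFailures), "\n", sep = "")
    cat("  gene-level effects: ", nrow(object@geneEffects), " rows, ",
        length(unique(object@geneEffects$gene)), " genes\n", sep = "")
    cat("  beta noise sd: ", object@noiseSd, "\n", sep = "")
})

setMethod("show", "BetaMatrix", function(object) {
    cat("BetaMatrix: ", nrow(object), " probes x ", ncol(object), " samples\n",
        sep = "")
    tab <- table(factor(colData(object)$condition, levels = conditionLevels()))
    cat("  samples per condition: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
    cat("  assays: ", paste(assayNames(object), collapse = ", "), "\n", sep = "")
})
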