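#' Beta value from methylated / unmethylated intensities
#'
#' beta = M / (M + U + offset): the methylated bead intensity over the
#' combined intensity, so beta = 0 is fully unmethylated and beta = 1 fully
#' methylated. The default offset is 0; an Illumina-style stabilising offset
#' (conventionally 100) can be supplied to damp low-intensity probes.
#'
#' @param methylated Non-negative methylated-channel intensity (vectorised).
#' @param unmethylated Non-negative unmethylated-channel intensity.
#' @param offset Non-negative offset added to the denominator (default 0).
#' @return Beta value(s) in \[0, 1\].
#' @export
#' @examples
#' computeBeta(600, 200)            # 0.75
#' computeBeta(300, 300, offset = 100)  # ~0.4286
computeBeta <- function(methylated, unmethylated, offset = 0) {
    if (any(methylated < 0) || any(unmethylated < 0) || any(offset < 0))
        stop("intensities and offset must be non-negative", call. = FALSE)
    denom <- methylated + unmethylated + offset
    if (any(denom == 0))
        stop("undefined beta: methylated, unmethylated and offset all zero",
             call. = FALSE)
    methylated / denom
}

#' Partition probes into reliable and excluded sets
#'
#' A probe is excluded when (a) any detection p-value exceeds
#' `detectionPMax` — its signal is indistinguishable from background in at
#' least one sample; (b) with two or more mock samples, the maximum pairwise
#' |delta-beta| among mock replicates exceeds `mockReplicateDeltaMax` — the
#' control arm itself fluctuates by a callable effect size; or (c) any beta
#' value is missing. Kept and excluded sets always partition the probe set.
#' Reasons are reported with precedence detection > mock-instability >
#' missing.
#'
#' @param bm A [BetaMatrix-class].
#' @param cfg A [screenConfig()].
#' @return List with `kept` (character vector of probe ids) and `excluded`
#'   (data.frame `probe_id`, `reason`).
#' @export
filterReliableProbes <- function(bm, cfg = screenConfig()) {
    stopifnot(is(bm, "BetaMatrix"), is(cfg, "ScreenConfig"))
    b <- betaValues(bm)
    p <- detectionP(bm)
    mockCols <- which(conditionOf(bm) == "mock")
    detFail <- if (is.null(p)) rep(FALSE, nrow(b)) else
        apply(p, 1L, function(x) any(!is.na(x) & x > cfg@detectionPMax))
    mockFail <- rep(FALSE, nrow(b))
    if (length(mockCols) >= 2L) {
        mockB <- b[, mockCols, drop = FALSE]
        rng <- apply(mockB, 1L, function(x) {
            x <- x[!is.na(x)]
            if (length(x) < 2L) 0 else max(x) - min(x)
        })
        mockFail <- rng > cfg@mockReplicateDeltaMax
    }
    missFail <- apply(b, 1L, anyNA)
    reason <- rep(NA_character_, nrow(b))
    reason[missFail] <- "missing"
    reason[mockFail] <- "mock-instability"
    reason[detFail] <- "detection"
    excluded <- !is.na(reason)
    list(kept = rownames(b)[!excluded],
         excluded = data.frame(probe_id = rownames(b)[excluded],
                               reason = reason[excluded],
                               stringsAsFactors = FALSE))
}

.treatedCondition <- function(contrast) {
    contrast <- match.arg(contrast, contrastLevels())
    sub("-vs-mock$", "", contrast)
}

#' Call differential methylation for one treated-vs-mock contrast
#'
#' Per-condition beta is the mean over that condition's samples. A probe is
#' called hypomethylated when delta-beta = beta_treated - beta_mock is at
#' most -`deltaBetaMin` AND the fold ratio beta_mock / max(beta_treated,
#' ratioFloor) is strictly greater than `foldMin`; hypermethylation is the
#' mirror image (ratio beta_treated / max(beta_mock, ratioFloor)). Both
#' criteria must pass jointly; probes failing either are called `none`. No
#' p-values are computed: the screen is purely threshold-based.
#'
#' @param bm A [BetaMatrix-class].
#' @param contrast One of [contrastLevels()].
#' @param kept Probe ids to call (typically `filterReliableProbes(bm)$kept`);
#'   defaults to all probes.
#' @param cfg A [screenConfig()].
#' @return data.frame with one row per kept probe: `probe_id`, `contrast`,
#'   `beta_mock`, `beta_treated`, `delta_beta`, `fold_ratio`, `direction`
#'   (hypo / hyper / none), `reliable`.
#' @export
#' @examples
#' b <- matrix(c(0.62, 0.35, 0.90, 0.21, 0.20, 0.65), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("m1", "a1")))
#' bm <- BetaMatrix(b, condition = c("mock", "aza"))
#' callContrast(bm, "aza-vs-mock")  # cg1 hypo; cg2, cg3 none
callContrast <- function(bm, contrast, kept = rownames(bm),
                         cfg = screenConfig()) {
    stopifnot(is(bm, "BetaMatrix"), is(cfg, "ScreenConfig"))
    contrast <- match.arg(contrast, contrastLevels())
    treated <- .treatedCondition(contrast)
    cond <- conditionOf(bm)
    if (!any(cond == treated))
        stop("no samples for treated condition '", treated, "'",
             call. = FALSE)
    if (!any(cond == "mock"))
        stop("no mock samples present", call. = FALSE)
    unknown <- setdiff(kept, rownames(bm))
    if (length(unknown) > 0)
        stop("unknown probe id(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    b <- betaValues(bm)[kept, , drop = FALSE]
    bMock <- rowMeans(b[, cond == "mock", drop = FALSE])
    bTrt <- rowMeans(b[, cond == treated, drop = FALSE])
    delta <- bTrt - bMock
    eps <- cfg@ratioFloor
    hypoRatio <- bMock / pmax(bTrt, eps)
    hyperRatio <- bTrt / pmax(bMock, eps)
    isHypo <- !is.na(delta) & delta <= -cfg@deltaBetaMin &
        hypoRatio > cfg@foldMin
    isHyper <- !is.na(delta) & delta >= cfg@deltaBetaMin &
        hyperRatio > cfg@foldMin
    direction <- rep("none", length(delta))
    direction[isHypo] <- "hypo"
    direction[isHyper] <- "hyper"
    # fold reported in the direction of change (loss -> mock/treated)
    foldRatio <- ifelse(!is.na(delta) & delta <= 0, hypoRatio, hyperRatio)
    data.frame(probe_id = kept, contrast = contrast, beta_mock = unname(bMock),
               beta_treated = unname(bTrt), delta_beta = unname(delta),
               fold_ratio = unname(foldRatio), direction = direction,
               reliable = TRUE, stringsAsFactors = FALSE)
}

#' Tally calls by direction for one contrast
#'
#' @param calls Output of [callContrast()] for a single contrast.
#' @return Named integer vector `c(hypo=, hyper=, none=)`; counts sum to
#'   `nrow(calls)`.
#' @export
countByDirection <- function(calls) {
    if (nrow(calls) > 0 && length(unique(calls$contrast)) > 1L)
        stop("calls mix contrasts: ",
             paste(unique(calls$contrast), collapse = ", "), call. = FALSE)
    vapply(c(hypo = "hypo", hyper = "hyper", none = "none"),
           function(d) sum(calls$direction == d), integer(1))
}

#' Probe ids called hypomethylated
#'
#' Convenience accessor used when building the condition-intersection Venn.
#'
#' @param calls Output of [callContrast()].
#' @return Character vector of hypomethylated probe ids.
#' @export
hypoProbes <- function(calls) calls$probe_id[calls$direction == "hypo"]
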