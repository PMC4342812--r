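# Downstream validation models: relative expression by the delta-delta-Ct
# method (GAPDH reference), qMSP relative methylation (Alu reference), and
# DNMT1 promoter occupancy as ChIP-qPCR percent-of-input. Amplification
# efficiency is fixed at 2 (perfect doubling per cycle); replicates are
# aggregated by arithmetic mean of Ct before any delta is taken.

.meanCt <- function(x, what) {
    if (length(x) == 0L)
        stop("empty replicate list for ", what, call. = FALSE)
    if (any(!is.finite(x) | x <= 0))
        stop("Ct values must be positive and finite (", what, ")",
             call. = FALSE)
    mean(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' delta-Ct = mean(target Ct) - mean(reference Ct) within each arm;
#' delta-delta-Ct = delta-Ct(treated) - delta-Ct(control); relative
#' expression fold-change = 2^-ddCt. The reference gene is GAPDH in the
#' expression assay.
#'
#' @param targetTreated,refTreated Replicate Ct vectors for the treated arm.
#' @param targetControl,refControl Replicate Ct vectors for the control arm.
#' @return List with `foldChange` (2^-ddCt, > 0), `ddCt`, and `ctSpread`
#'   (standard deviation of the treated target replicates; 0 for a single
#'   replicate).
#' @export
#' @examples
#' ddctFoldChange(26, 20, 28, 20)$foldChange  # 4
ddctFoldChange <- function(targetTreated, refTreated, targetControl,
                           refControl) {
    dctT <- .meanCt(targetTreated, "treated target") -
        .meanCt(refTreated, "treated reference")
    dctC <- .meanCt(targetControl, "control target") -
        .meanCt(refControl, "control reference")
    ddct <- dctT - dctC
    spread <- if (length(targetTreated) > 1L) stats::sd(targetTreated) else 0
    list(foldChange = 2^(-ddct), ddCt = ddct, ctSpread = spread)
}

#' Relative methylation by quantitative methylation-specific PCR
#'
#' qMSP on bisulfite-converted DNA, normalized to an Alu repeat element:
#' relative methylation = 2^-\[(Ct_gene - Ct_Alu)_treated -
#' (Ct_gene - Ct_Alu)_mock\], so mock = 1 and values below 1 indicate
#' demethylation relative to mock.
#'
#' @param geneTreated,aluTreated Replicate Ct vectors, treated arm.
#' @param geneMock,aluMock Replicate Ct vectors, mock arm.
#' @return Relative methylation (positive; mock-normalized).
#' @export
#' @examples
#' qmspRelativeMethylation(23, 16, 21, 16)  # 0.25
qmspRelativeMethylation <- function(geneTreated, aluTreated, geneMock,
                                    aluMock) {
    dctT <- .meanCt(geneTreated, "treated gene") -
        .meanCt(aluTreated, "treated Alu")
    dctM <- .meanCt(geneMock, "mock gene") - .meanCt(aluMock, "mock Alu")
    2^(-(dctT - dctM))
}

#' ChIP-qPCR signal as percent of input chromatin
#'
#' The input aliquot is only `inputPercent` of the chromatin that went into
#' the IP, so its Ct is first adjusted to a 100% equivalent:
#' adjusted = Ct_input - log2(100 / inputPercent). Occupancy is then
#' 100 x 2^(adjusted - Ct_IP): one IP cycle less than adjusted input means
#' 200%, one more means 50% (doubling per cycle).
#'
#' @param ctIp Mean Ct of the immunoprecipitated material.
#' @param ctInput Mean Ct of the input aliquot.
#' @param inputPercent Percent of chromatin used as input, in (0, 100\].
#' @return Percent of input (>= 0; can exceed 100).
#' @export
#' @examples
#' chipPercentInput(18, 20, 1)    # ~4.0
#' chipPercentInput(20, 20, 100)  # 100
chipPercentInput <- function(ctIp, ctInput, inputPercent) {
    if (length(inputPercent) != 1L || !is.finite(inputPercent) ||
        inputPercent <= 0 || inputPercent > 100)
        stop("inputPercent must lie in (0, 100]", call. = FALSE)
    if (any(!is.finite(c(ctIp, ctInput))))
        stop("Ct values must be finite", call. = FALSE)
    adjusted <- ctInput - log2(100 / inputPercent)
    100 * 2^(adjusted - ctIp)
}

#' Percent decrease in occupancy relative to mock
#'
#' 100 x (1 - treated / mock) on percent-of-input values. Negative results
#' (occupancy increases) are permitted and reported as negative decreases.
#'
#' @param mock Mock percent-of-input (> 0).
#' @param treated Treated percent-of-input.
#' @return Percent decrease.
#' @export
#' @examples
#' occupancyDecrease(1.00, 0.79)  # 21
#' occupancyDecrease(2, 1)       # 50
occupancyDecrease <- function(mock, treated) {
    if (any(mock <= 0))
        stop("undefined decrease: mock percent-of-input must be > 0",
             call. = FALSE)
    100 * (1 - treated / mock)
}

#' Compute expression fold-changes for all genes and treated conditions
#'
#' Runs [ddctFoldChange()] on a long-format expression Ct table (see
#' [readCtTable()]) for every gene and every treated condition present,
#' against the mock arm.
#'
#' @param ctTable Expression Ct table.
#' @return data.frame `gene`, `condition`, `fold_change`, `ddct`,
#'   `ct_spread`.
#' @export
expressionFoldChanges <- function(ctTable) {
    tab <- ctTable[ctTable$assay == "expression", , drop = FALSE]
    out <- list()
    for (g in sort(unique(tab$gene))) {
        sub <- tab[tab$gene == g, , drop = FALSE]
        ctOf <- function(cond, ch) sub$ct[sub$condition == cond &
                                          sub$channel == ch]
        for (cond in intersect(conditionLevels(), unique(sub$condition))) {
            if (cond == "mock") next
            r <- ddctFoldChange(ctOf(cond, "target"), ctOf(cond, "reference"),
                                ctOf("mock", "target"),
                                ctOf("mock", "reference"))
            out[[length(out) + 1L]] <- data.frame(
                gene = g, condition = cond, fold_change = r$foldChange,
                ddct = r$ddCt, ct_spread = r$ctSpread,
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(gene = character(), condition = character(),
                          fold_change = numeric(), ddct = numeric(),
                          ct_spread = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Compute qMSP relative methylation for all genes and treated conditions
#'
#' @param ctTable qMSP Ct table (see [readCtTable()]).
#' @return data.frame `gene`, `condition`, `relative_methylation`
#'   (mock = 1).
#' @export
qmspRelativeLevels <- function(ctTable) {
    tab <- ctTable[ctTable$assay == "qmsp", , drop = FALSE]
    out <- list()
    for (g in sort(unique(tab$gene))) {
        sub <- tab[tab$gene == g, , drop = FALSE]
        ctOf <- function(cond, ch) sub$ct[sub$condition == cond &
                                          sub$channel == ch]
        for (cond in intersect(conditionLevels(), unique(sub$condition))) {
            if (cond == "mock") next
            rel <- qmspRelativeMethylation(ctOf(cond, "target"),
                                           ctOf(cond, "reference"),
                                           ctOf("mock", "target"),
                                           ctOf("mock", "reference"))
            out[[length(out) + 1L]] <- data.frame(
                gene = g, condition = cond, relative_methylation = rel,
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(gene = character(), condition = character(),
                          relative_methylation = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Compute DNMT1 promoter occupancy and its decrease versus mock
#'
#' Percent-of-input is computed per gene, condition and antibody from the
#' ChIP Ct table; the IgG channel is reported alongside DNMT1 but never
#' subtracted. The decrease versus mock is computed for the DNMT1 antibody.
#'
#' @param ctTable ChIP Ct table (see [readCtTable()]).
#' @param inputPercent Percent of chromatin used as input (default 1).
#' @return List with `percentInput` (gene, condition, antibody,
#'   percent_input) and `decrease` (gene, condition, decrease; DNMT1,
#'   treated conditions only).
#' @export
chipOccupancy <- function(ctTable, inputPercent = 1) {
    tab <- ctTable[ctTable$assay == "chip", , drop = FALSE]
    pi <- list(); dec <- list()
    for (g in sort(unique(tab$gene))) {
        sub <- tab[tab$gene == g, , drop = FALSE]
        ctOf <- function(cond, ch) sub$ct[sub$condition == cond &
                                          sub$channel == ch]
        conds <- intersect(conditionLevels(), unique(sub$condition))
        perc <- list()
        for (cond in conds) {
            for (ab in c("dnmt1", "igg")) {
                ip <- ctOf(cond, paste0("ip_", ab))
                if (length(ip) == 0L) next
                p <- chipPercentInput(mean(ip),
                                      .meanCt(ctOf(cond, "input"), "input"),
                                      inputPercent)
                perc[[paste(cond, ab)]] <- p
                pi[[length(pi) + 1L]] <- data.frame(
                    gene = g, condition = cond, antibody = ab,
                    percent_input = p, stringsAsFactors = FALSE)
            }
        }
        for (cond in setdiff(conds, "mock")) {
            pm <- perc[[paste("mock", "dnmt1")]]
            pt <- perc[[paste(cond, "dnmt1")]]
            if (is.null(pm) || is.null(pt)) next
            dec[[length(dec) + 1L]] <- data.frame(
                gene = g, condition = cond,
                decrease = occupancyDecrease(pm, pt), stringsAsFactors = FALSE)
        }
    }
    empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
    list(percentInput = if (length(pi)) do.call(rbind, pi) else
             empty(gene = character(), condition = character(),
                   antibody = character(), percent_input = numeric()),
         decrease = if (length(dec)) do.call(rbind, dec) else
             empty(gene = character(), condition = character(),
                   decrease = numeric()))
}

#' Score gene-level concordance between hypomethylation and validation assays
#'
#' A retained (non-excluded) candidate is `validated` when it is
#' hypomethylated in the aza control and at least one irradiated contrast
#' (true for every candidate by construction) AND its expression fold-change
#' reaches `exprFoldMin` in aza and in every supporting irradiated contrast.
#' DNMT1 occupancy decrease (> 0 in the same contrasts) is recorded as
#' `occupancy_down` but does not gate validation: hypomethylation with
#' increased expression can occur without a detectable DNMT1 occupancy drop.
#' Retained candidates with no expression record are reported with status
#' `unassayed` and are never validated.
#'
#' @param candidates Candidate table from [applyExclusionRules()].
#' @param expr Expression results (`gene`, `condition`, `fold_change`), e.g.
#'   from [expressionFoldChanges()].
#' @param occ Occupancy decreases (`gene`, `condition`, `decrease`), e.g.
#'   `chipOccupancy(...)$decrease`; may be `NULL`.
#' @param exprFoldMin Minimum expression fold-change (> 1; default 1.5,
#'   mirroring the methylation fold criterion).
#' @return data.frame `gene`, `hypomethylated`, `expression_up`,
#'   `occupancy_down`, `validated`, `status` (`validated`, `not_validated`,
#'   `excluded`, `unassayed`).
#' @export
scoreConcordance <- function(candidates, expr, occ = NULL,
                             exprFoldMin = 1.5) {
    stopifnot(exprFoldMin > 1)
    rows <- lapply(seq_len(nrow(candidates)), function(i) {
        g <- candidates$gene[i]
        contrasts <- c("aza", c("ir2gy", "ir5gy")[c(candidates$ir2gy[i],
                                                    candidates$ir5gy[i])])
        hypo <- candidates$ir2gy[i] || candidates$ir5gy[i]
        folds <- if (is.null(expr)) numeric(0) else
            expr$fold_change[expr$gene == g &
                             expr$condition %in% contrasts]
        excluded <- isTRUE(candidates$excluded[i])
        assayed <- length(folds) == length(contrasts)
        # excluded genes cannot be assayed gene-specifically, so they never
        # count as expression-up even if a (non-specific) record exists
        exprUp <- !excluded && assayed && all(folds >= exprFoldMin)
        decs <- if (is.null(occ)) numeric(0) else
            occ$decrease[occ$gene == g & occ$condition %in% contrasts]
        occDown <- length(decs) == length(contrasts) && all(decs > 0)
        validated <- !excluded && hypo && exprUp
        status <- if (excluded) "excluded"
        else if (!assayed) "unassayed"
        else if (validated) "validated"
        else "not_validated"
        data.frame(gene = g, hypomethylated = hypo, expression_up = exprUp,
                   occupancy_down = occDown, validated = validated,
                   status = status, stringsAsFactors = FALSE)
    })
    if (length(rows) == 0L)
        return(data.frame(gene = character(), hypomethylated = logical(),
                          expression_up = logical(),
                          occupancy_down = logical(), validated = logical(),
                          status = character(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}
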