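# End-to-end orchestration: filter -> call (3 contrasts) -> Venn ->
# select -> collapse -> exclude -> cluster -> validate -> report.
# Every run writes its resolved configuration and per-stage counts next to
# the outputs; rejected probes are enumerated, never silently dropped.
# Outputs contain no timestamps, so identical config + seed reproduces
# every file byte-identically.

#' Assemble and validate a pipeline configuration
#'
#' Inputs come either from files (`betaPath` + `annotationPath`, optional Ct
#' tables), from an in-memory synthetic bundle (`bundle`), or from
#' `synthetic = TRUE`, which generates the narrative-shaped bundle from
#' `seed` at run time. Exactly one input source must be provided.
#'
#' @param betaPath,conditionsPath,detectionPPath Beta-matrix input files
#'   (see [readBetaMatrix()]).
#' @param annotationPath Probe annotation file.
#' @param expressionCtPath,qmspCtPath,chipCtPath Optional Ct tables.
#' @param bundle Optional in-memory bundle (as from
#'   [generatePaperShapedFixture()]).
#' @param synthetic Generate the narrative-shaped bundle at run time.
#' @param screen A [screenConfig()].
#' @param similarityThreshold Paralog-similarity exclusion threshold
#'   (percent, default 94).
#' @param exprFoldMin Expression-validation fold threshold (default 1.5).
#' @param chipInputPercent Percent of chromatin used as ChIP input
#'   (default 1).
#' @param outDir Output directory (required by [runPipeline()]).
#' @param seed Integer seed (required when `synthetic = TRUE`).
#' @return A validated config (list, class `radMethylConfig`).
#' @export
pipelineConfig <- function(betaPath = NULL, conditionsPath = NULL,
                           detectionPPath = NULL, annotationPath = NULL,
                           expressionCtPath = NULL, qmspCtPath = NULL,
                           chipCtPath = NULL, bundle = NULL,
                           synthetic = FALSE, screen = screenConfig(),
                           similarityThreshold = 94, exprFoldMin = 1.5,
                           chipInputPercent = 1, outDir = NULL, seed = NULL) {
    sources <- c(files = !is.null(betaPath), bundle = !is.null(bundle),
                 synthetic = isTRUE(synthetic))
    if (sum(sources) != 1L)
        stop("exactly one input source required: beta/annotation paths, ",
             "an in-memory bundle, or synthetic = TRUE", call. = FALSE)
    if (sources["files"] && is.null(annotationPath))
        stop("annotationPath is required with betaPath", call. = FALSE)
    if (sources["synthetic"] && is.null(seed))
        stop("seed is required for a synthetic run", call. = FALSE)
    stopifnot(is(screen, "ScreenConfig"), similarityThreshold > 0,
              similarityThreshold <= 100, exprFoldMin > 1,
              chipInputPercent > 0, chipInputPercent <= 100)
    structure(list(betaPath = betaPath, conditionsPath = conditionsPath,
                   detectionPPath = detectionPPath,
                   annotationPath = annotationPath,
                   expressionCtPath = expressionCtPath,
                   qmspCtPath = qmspCtPath, chipCtPath = chipCtPath,
                   bundle = bundle, synthetic = isTRUE(synthetic),
                   screen = screen,
                   similarityThreshold = similarityThreshold,
                   exprFoldMin = exprFoldMin,
                   chipInputPercent = chipInputPercent, outDir = outDir,
                   seed = seed),
              class = "radMethylConfig")
}

.resolveInputs <- function(cfg) {
    if (cfg$synthetic)
        return(generatePaperShapedFixture(cfg$seed))
    if (!is.null(cfg$bundle)) return(cfg$bundle)
    args <- list(cfg$betaPath)
    if (!is.null(cfg$conditionsPath)) args$conditionsPath <- cfg$conditionsPath
    if (!is.null(cfg$detectionPPath)) args$detectionPPath <- cfg$detectionPPath
    list(bm = do.call(readBetaMatrix, args),
         annotation = readProbeAnnotation(cfg$annotationPath),
         expressionCt = if (!is.null(cfg$expressionCtPath))
             readCtTable(cfg$expressionCtPath),
         qmspCt = if (!is.null(cfg$qmspCtPath)) readCtTable(cfg$qmspCtPath),
         chipCt = if (!is.null(cfg$chipCtPath)) readCtTable(cfg$chipCtPath),
         chipInputPercent = cfg$chipInputPercent)
}

.echoConfig <- function(cfg) {
    s <- cfg$screen
    data.frame(
        key = c("seed", "synthetic", "delta_beta_min", "fold_min",
                "detection_p_max", "mock_replicate_delta_max", "ratio_floor",
                "similarity_threshold", "expr_fold_min",
                "chip_input_percent"),
        value = c(if (is.null(cfg$seed)) "" else as.character(cfg$seed),
                  as.character(cfg$synthetic), .fmtNum(s@deltaBetaMin),
                  .fmtNum(s@foldMin), .fmtNum(s@detectionPMax),
                  .fmtNum(s@mockReplicateDeltaMax), .fmtNum(s@ratioFloor),
                  .fmtNum(cfg$similarityThreshold),
                  .fmtNum(cfg$exprFoldMin), .fmtNum(cfg$chipInputPercent)),
        stringsAsFactors = FALSE)
}

#' Run the discovery-and-validation pipeline end to end
#'
#' Executes reliability filtering, the three treated-vs-mock contrasts, the
#' Venn intersection with the aza control, gene collapse, exclusion rules,
#' heatmap clustering of the candidate probes, the expression / qMSP / ChIP
#' validation models (where Ct tables are available), and concordance
#' scoring; writes all result tables plus a provenance log to
#' `cfg$outDir`.
#'
#' @param cfg A [pipelineConfig()] with `outDir` set.
#' @return Invisibly, the run report: a list with per-stage tables and a
#'   `counts` element (see [summarizeCounts()]).
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "radMethylConfig"))
    if (is.null(cfg$outDir))
        stop("outDir is required", call. = FALSE)
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    inputs <- .resolveInputs(cfg)
    bm <- inputs$bm
    ann <- inputs$annotation

    flt <- filterReliableProbes(bm, cfg$screen)
    calls <- lapply(stats::setNames(nm = contrastLevels()), function(ct)
        callContrast(bm, ct, kept = flt$kept, cfg = cfg$screen))
    vp <- vennPartition(hypoProbes(calls[["aza-vs-mock"]]),
                        hypoProbes(calls[["ir2gy-vs-mock"]]),
                        hypoProbes(calls[["ir5gy-vs-mock"]]))
    selected <- selectIrCandidates(vp)
    candidates <- collapseToGenes(selected, ann)
    candidates <- applyExclusionRules(candidates, ann,
                                      cfg$similarityThreshold)

    ord <- if (nrow(selected) > 0)
        heatmapOrder(bm, selected$probe_id) else NULL

    expr <- if (!is.null(inputs$expressionCt))
        expressionFoldChanges(inputs$expressionCt)
    qmsp <- if (!is.null(inputs$qmspCt)) qmspRelativeLevels(inputs$qmspCt)
    occ <- if (!is.null(inputs$chipCt))
        chipOccupancy(inputs$chipCt,
                      inputPercent = if (is.null(inputs$chipInputPercent))
                          cfg$chipInputPercent else inputs$chipInputPercent)
    verdicts <- scoreConcordance(candidates, expr,
                                 occ = if (!is.null(occ)) occ$decrease,
                                 exprFoldMin = cfg$exprFoldMin)

    out <- function(f) file.path(cfg$outDir, f)
    for (ct in contrastLevels())
        .writeTsv(transform(calls[[ct]],
                            beta_mock = .fmtNum(beta_mock, 10),
                            beta_treated = .fmtNum(beta_treated, 10),
                            delta_beta = .fmtNum(delta_beta, 10),
                            fold_ratio = .fmtNum(fold_ratio, 10)),
                  out(sprintf("calls_%s.tsv", ct)))
    .writeTsv(flt$excluded, out("excluded_probes.tsv"))
    .writeTsv(vennSummary(vp), out("venn_summary.tsv"))
    writeCandidateReport(candidates, do.call(rbind, unname(calls)),
                         validations = list(expression = expr,
                                            occupancy = if (!is.null(occ))
                                                occ$decrease,
                                            verdicts = verdicts),
                         path = out("candidates.tsv"))
    if (!is.null(ord)) {
        .writeTsv(rbind(data.frame(axis = "probe",
                                   rank = seq_along(ord$probes),
                                   id = ord$probes),
                        data.frame(axis = "sample",
                                   rank = seq_along(ord$samples),
                                   id = ord$samples)),
                  out("heatmap_order.tsv"))
        if (!is.null(ord$probeDendrogram) &&
            nrow(ord$probeDendrogram$merge) > 0) {
            m <- ord$probeDendrogram$merge
            .writeTsv(data.frame(step = seq_len(nrow(m)), node_a = m[, 1L],
                                 node_b = m[, 2L],
                                 height = .fmtNum(
                                     ord$probeDendrogram$height, 10)),
                      out("probe_dendrogram_merges.tsv"))
        }
        b <- betaValues(bm)[ord$probes, ord$samples, drop = FALSE]
        .writeTsv(data.frame(probe_id = rownames(b),
                             format(b, digits = 10, trim = TRUE),
                             check.names = FALSE), out("ordered_beta.tsv"))
    }
    if (!is.null(verdicts)) .writeTsv(verdicts, out("verdicts.tsv"))

    report <- list(calls = calls, filtered = flt, venn = vp,
                   selected = selected, candidates = candidates,
                   heatmap = ord, expression = expr, qmsp = qmsp,
                   occupancy = occ, verdicts = verdicts, config = cfg)
    report$counts <- summarizeCounts(report)
    .writeTsv(report$counts, out("stage_counts.tsv"))
    .writeTsv(.echoConfig(cfg), out("run_config.tsv"))
    class(report) <- "radMethylReport"
    invisible(report)
}

#' Per-stage count summary of a pipeline run
#'
#' Tallies probes kept and excluded by the reliability filter, hypo / hyper
#' calls per contrast, the seven Venn pattern sizes, and candidate /
#' excluded / retained / validated gene counts. The counts satisfy
#' validated <= retained <= candidates on every run.
#'
#' @param report A report from [runPipeline()].
#' @return data.frame with `metric` and `value` columns.
#' @export
summarizeCounts <- function(report) {
    rows <- list()
    add <- function(metric, value)
        rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                                 value = as.integer(value),
                                                 stringsAsFactors = FALSE)
    add("probes_kept", length(report$filtered$kept))
    add("probes_excluded", nrow(report$filtered$excluded))
    for (ct in names(report$calls)) {
        n <- countByDirection(report$calls[[ct]])
        add(paste0("hypo_", ct), n[["hypo"]])
        add(paste0("hyper_", ct), n[["hyper"]])
    }
    for (p in names(report$venn)) add(paste0("venn_", p),
                                      length(report$venn[[p]]))
    add("selected_probes", nrow(report$selected))
    nCand <- nrow(report$candidates)
    nExcl <- sum(report$candidates$excluded)
    add("candidate_genes", nCand)
    add("excluded_genes", nExcl)
    add("retained_genes", nCand - nExcl)
    add("validated_genes",
        if (is.null(report$verdicts)) 0L else sum(report$verdicts$validated))
    do.call(rbind, rows)
}

#' @export
print.radMethylReport <- function(x, ...) {
    cat("radMethyl pipeline report\n")
    c <- x$counts
    pick <- function(m) c$value[c$metric == m]
    cat(sprintf("  probes: %d kept, %d excluded by reliability filter\n",
                pick("probes_kept"), pick("probes_excluded")))
    for (ct in contrastLevels())
        cat(sprintf("  %s: %d hypo, %d hyper\n", ct,
                    pick(paste0("hypo_", ct)), pick(paste0("hyper_", ct))))
    cat(sprintf("  candidates: %d (%d excluded, %d retained, %d validated)\n",
                pick("candidate_genes"), pick("excluded_genes"),
                pick("retained_genes"), pick("validated_genes")))
    invisible(x)
}
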