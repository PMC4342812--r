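# Synthetic array-style data with known planted structure. The generator
# emulates the study design: a mock arm, a 5-aza-dC demethylation-control
# arm, and 2 Gy / 5 Gy irradiated arms, with genome-like bimodal baseline
# beta values, planted hypomethylation effects (shared and unique between
# the aza and irradiated conditions), technical noise on the beta scale,
# and downstream Ct tables whose effects are log2-linked to the planted
# gene-level truth. Everything is deterministic under the master seed.

# evaluate expr under a local RNG state; restores the caller's stream
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

# per-table sub-stream seeds derived from the master seed, so regenerating
# one table never perturbs another
.subSeed <- function(seed, table) {
    offset <- c(beta = 11L, expression = 22L, qmsp = 33L, chip = 44L,
                fixture = 55L)[[table]]
    as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Generate a beta matrix with planted hypomethylation effects
#'
#' Baseline per-probe beta is drawn from a bimodal mixture (a low mode near
#' 0.1 and a high mode near 0.8, mimicking genome-wide 450K marginals).
#' Probes planted with a hypomethylation effect start from the high mode so
#' the effect is callable; the effect shifts only the treated condition(s).
#' Per-sample technical noise is additive on the beta scale and results are
#' clipped to \[0, 1\]; effects whose clipped treated mean no longer
#' satisfies both calling criteria are flagged not callable in the truth.
#' Probes can additionally be planted to fail the reliability filter via a
#' detection p-value above threshold or unstable mock replicates.
#'
#' @param nProbes Number of probes.
#' @param design Named integer vector of samples per condition (default two
#'   samples for each of mock / aza / ir2gy / ir5gy).
#' @param planted Optional data.frame `probe_id`, `contrast` (a
#'   [contrastLevels()] label), `delta_beta` (signed effect; negative =
#'   hypomethylation).
#' @param noiseSd Technical noise standard deviation on the beta scale
#'   (default 0.02).
#' @param nDetectionFail Probes planted with a failing detection p-value.
#' @param nMockUnstable Probes planted with divergent mock replicates
#'   (requires >= 2 mock samples).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `bm` (a [BetaMatrix-class]) and `truth`
#'   (a [SyntheticTruth-class]).
#' @export
generateBetaMatrix <- function(nProbes,
                               design = c(mock = 2L, aza = 2L, ir2gy = 2L,
                                          ir5gy = 2L),
                               planted = NULL, noiseSd = 0.02,
                               nDetectionFail = 0L, nMockUnstable = 0L,
                               seed) {
    stopifnot(nProbes >= 1L, !is.null(names(design)),
              all(names(design) %in% conditionLevels()), design["mock"] >= 1L)
    if (is.null(planted))
        planted <- data.frame(probe_id = character(), contrast = character(),
                              delta_beta = numeric(),
                              stringsAsFactors = FALSE)
    probeIds <- unique(c(planted$probe_id,
                         sprintf("cg%08d", seq_len(nProbes))))[seq_len(nProbes)]
    if (length(probeIds) < length(unique(planted$probe_id)))
        stop("nProbes smaller than the planted probe set", call. = FALSE)
    samples <- unlist(lapply(names(design), function(cn)
        sprintf("%s_%d", cn, seq_len(design[[cn]]))), use.names = FALSE)
    condition <- rep(names(design), times = design)
    .withSeed(seed, {
        plantedIds <- unique(planted$probe_id)
        isPlanted <- probeIds %in% plantedIds
        baseline <- numeric(length(probeIds))
        low <- stats::runif(length(probeIds)) < 0.6
        baseline[low] <- stats::rbeta(sum(low), 2, 18)
        baseline[!low] <- stats::rbeta(sum(!low), 16, 4)
        # planted hypo effects need headroom: start from the high mode
        baseline[isPlanted] <- stats::runif(sum(isPlanted), 0.6, 0.9)
        effect <- matrix(0, length(probeIds), length(samples),
                         dimnames = list(probeIds, samples))
        for (k in seq_len(nrow(planted))) {
            trt <- .treatedCondition(planted$contrast[k])
            effect[planted$probe_id[k], condition == trt] <-
                effect[planted$probe_id[k], condition == trt] +
                planted$delta_beta[k]
        }
        beta <- baseline + effect +
            matrix(stats::rnorm(length(probeIds) * length(samples),
                                sd = noiseSd),
                   length(probeIds), length(samples))
        beta <- pmin(pmax(beta, 0), 1)
        dimnames(beta) <- list(probeIds, samples)
        detP <- matrix(stats::runif(length(beta), 0, 0.005), nrow(beta),
                       ncol(beta), dimnames = dimnames(beta))
        failures <- data.frame(probe_id = character(), reason = character(),
                               stringsAsFactors = FALSE)
        free <- setdiff(probeIds, plantedIds)
        if (nDetectionFail > 0L) {
            ids <- free[seq_len(nDetectionFail)]
            free <- setdiff(free, ids)
            detP[ids, sample(ncol(beta), 1L)] <- 0.5
            failures <- rbind(failures,
                              data.frame(probe_id = ids,
                                         reason = "detection",
                                         stringsAsFactors = FALSE))
        }
        if (nMockUnstable > 0L) {
            mockCols <- which(condition == "mock")
            if (length(mockCols) < 2L)
                stop("mock-unstable probes need >= 2 mock samples",
                     call. = FALSE)
            ids <- free[seq_len(nMockUnstable)]
            beta[ids, mockCols[1L]] <- 0.15
            beta[ids, mockCols[2L]] <- 0.85
            failures <- rbind(failures,
                              data.frame(probe_id = ids,
                                         reason = "mock-instability",
                                         stringsAsFactors = FALSE))
        }
        cfg <- screenConfig()
        callable <- vapply(seq_len(nrow(planted)), function(k) {
            b0 <- baseline[match(planted$probe_id[k], probeIds)]
            b1 <- min(max(b0 + planted$delta_beta[k], 0), 1)
            abs(b1 - b0) >= cfg@deltaBetaMin &&
                (if (planted$delta_beta[k] < 0)
                     b0 / max(b1, cfg@ratioFloor) else
                     b1 / max(b0, cfg@ratioFloor)) > cfg@foldMin
        }, logical(1))
        truthPlanted <- cbind(planted, callable = callable)
        bm <- BetaMatrix(beta, condition = condition, detectionP = detP)
        truth <- new("SyntheticTruth", plantedHypo = truthPlanted,
                     plantedFailures = failures,
                     geneEffects = data.frame(gene = character(),
                                              condition = character(),
                                              expr_fold = numeric(),
                                              qmsp_rel = numeric(),
                                              occ_decrease = numeric(),
                                              stringsAsFactors = FALSE),
                     probeGeneMap = data.frame(probe_id = character(),
                                               gene = character(),
                                               stringsAsFactors = FALSE),
                     noiseSd = noiseSd, seed = as.integer(seed))
        list(bm = bm, truth = truth)
    })
}

# Ct-model baselines shared by the generator and documented in the vignette:
# reference channels are held constant per arm; effects enter the target /
# IP channel as -log2(effect) cycles; replicate noise sd is 0.1 cycles.
.ctModel <- list(expression = list(refCt = 20, baselineDct = 6),
                 qmsp = list(refCt = 16, baselineDct = 5),
                 chip = list(inputCt = 20, inputPercent = 1,
                             mockDnmt1Pct = 2, iggPct = 0.1))

#' Generate replicate Ct tables for a planted gene-level truth
#'
#' For `expression` and `qmsp`, the reference channel (GAPDH / Alu) is held
#' constant per arm and the target Ct is reference + baseline delta-Ct -
#' log2(effect) + N(0, 0.1) per replicate, where the effect is the planted
#' expression fold (mock = 1) or relative methylation. For `chip`, the input
#' Ct is constant; DNMT1 IP Ct encodes the planted percent-of-input (mock
#' 2%, treated reduced by the planted decrease) and IgG a constant 0.1%
#' background. Triplicates throughout.
#'
#' @param truth A [SyntheticTruth-class] with gene effects for the assay.
#' @param assay One of `"expression"`, `"qmsp"`, `"chip"`.
#' @param seed Integer seed.
#' @param nReplicates Replicates per channel (default 3).
#' @return A long-format Ct table (see [readCtTable()]).
#' @export
generateCtTables <- function(truth, assay, seed, nReplicates = 3L) {
    assay <- match.arg(assay, c("expression", "qmsp", "chip"))
    ge <- truth@geneEffects
    effCol <- c(expression = "expr_fold", qmsp = "qmsp_rel",
                chip = "occ_decrease")[[assay]]
    ge <- ge[!is.na(ge[[effCol]]), , drop = FALSE]
    if (nrow(ge) == 0L)
        stop("truth has no gene effects for assay '", assay, "'",
             call. = FALSE)
    noise <- function(n) stats::rnorm(n, sd = 0.1)
    rows <- list()
    add <- function(gene, condition, channel, ct) {
        rows[[length(rows) + 1L]] <<- data.frame(
            gene = gene, condition = condition, assay = assay,
            channel = channel, replicate = seq_along(ct), ct = ct,
            stringsAsFactors = FALSE)
    }
    .withSeed(seed, {
        for (g in unique(ge$gene)) {
            sub <- ge[ge$gene == g, , drop = FALSE]
            conds <- c("mock", intersect(conditionLevels(), sub$condition))
            for (cond in conds) {
                eff <- if (cond == "mock") 1 else
                    sub[[effCol]][sub$condition == cond]
                if (assay %in% c("expression", "qmsp")) {
                    p <- .ctModel[[assay]]
                    add(g, cond, "reference", rep(p$refCt, nReplicates))
                    add(g, cond, "target",
                        p$refCt + p$baselineDct - log2(eff) +
                            noise(nReplicates))
                } else {
                    p <- .ctModel$chip
                    pct <- if (cond == "mock") p$mockDnmt1Pct else
                        p$mockDnmt1Pct * (1 - eff / 100)
                    if (pct <= 0)
                        stop("planted occupancy decrease >= 100% for gene '",
                             g, "'", call. = FALSE)
                    adjusted <- p$inputCt - log2(100 / p$inputPercent)
                    add(g, cond, "input", rep(p$inputCt, nReplicates))
                    add(g, cond, "ip_dnmt1",
                        adjusted - log2(pct / 100) + noise(nReplicates))
                    add(g, cond, "ip_igg",
                        adjusted - log2(p$iggPct / 100) + noise(nReplicates))
                }
            }
        }
    })
    tab <- do.call(rbind, rows)
    validateCtTable(tab)
    tab
}

# deterministic assignment of the 29 candidate genes to Venn groups:
# the seven expression-validated genes sit in the shared (aza+2Gy+5Gy)
# group; the remainder fill shared/2Gy-only/5Gy-only alphabetically so that
# aza&2Gy = 25 probes, aza&5Gy = 21 probes, shared = 17.
.paperShapeGroups <- function(genes) {
    validated <- c("ANGPT1", "APBB2", "CHGA", "CTGF", "IFI16", "IGLON5",
                   "SLC43A2")
    stopifnot(all(validated %in% genes))
    rest <- sort(setdiff(genes, validated))
    both <- c(validated, rest[1:10])
    list(both = both,
         ir2gyOnly = rest[11:18],
         ir5gyOnly = rest[19:22],
         validated = validated)
}

#' Generate the full narrative-shaped synthetic input bundle
#'
#' Produces an end-to-end rehearsal dataset whose planted structure mirrors
#' the study narrative at desk scale: 25 probes hypomethylated in both aza
#' and 2 Gy, 21 in both aza and 5 Gy (17 shared), collapsing to the 29
#' packaged candidate genes, of which 3 carry exclusion flags (one
#' pseudogene, two 94%-similar paralogs) and exactly 7 carry expression
#' effects at or above the validation fold threshold in all their supporting
#' contrasts. Background probes include aza-only and irradiation-only
#' hypomethylation plus planted reliability failures. Planted DNMT1
#' occupancy decreases for the validated genes span 21-50% (aza), 50-81%
#' (2 Gy) and 48-81% (5 Gy); one validated gene (IFI16) is planted with an
#' occupancy increase, exercising the rule that occupancy does not gate
#' validation.
#'
#' @param seed Integer master seed.
#' @param nProbes Total probes in the array (default 1500).
#' @return List with `bm`, `truth`, `annotation`, `expressionCt`, `qmspCt`,
#'   `chipCt`, and `chipInputPercent`.
#' @export
generatePaperShapedFixture <- function(seed, nProbes = 1500L) {
    annPath <- system.file("extdata", "candidate_genes.tsv",
                           package = "radMethyl")
    ann <- readProbeAnnotation(annPath)
    genes <- sort(unique(unlist(ann$gene_symbols)))
    grp <- .paperShapeGroups(genes)
    probeOf <- function(g) ann$probe_id[vapply(ann$gene_symbols,
                                               function(s) g %in% s,
                                               logical(1))]
    candProbes <- vapply(genes, probeOf, character(1))
    plantRows <- function(gs, contrasts) {
        do.call(rbind, lapply(contrasts, function(ct)
            data.frame(probe_id = unname(candProbes[gs]), contrast = ct,
                       delta_beta = -0.4, stringsAsFactors = FALSE)))
    }
    planted <- rbind(
        plantRows(grp$both, contrastLevels()),
        plantRows(grp$ir2gyOnly, c("aza-vs-mock", "ir2gy-vs-mock")),
        plantRows(grp$ir5gyOnly, c("aza-vs-mock", "ir5gy-vs-mock")))
    # background structure: a (scaled-down) aza-only block plus small
    # irradiation-only blocks that must not survive candidate selection
    bg <- sprintf("cg%08d", seq_len(nProbes))
    bg <- setdiff(bg, ann$probe_id)
    planted <- rbind(planted,
                     data.frame(probe_id = bg[1:40],
                                contrast = "aza-vs-mock", delta_beta = -0.4,
                                stringsAsFactors = FALSE),
                     data.frame(probe_id = bg[41:45],
                                contrast = "ir2gy-vs-mock",
                                delta_beta = -0.4, stringsAsFactors = FALSE),
                     data.frame(probe_id = bg[46:49],
                                contrast = "ir5gy-vs-mock",
                                delta_beta = -0.4, stringsAsFactors = FALSE))
    gen <- generateBetaMatrix(
        nProbes = nProbes, planted = planted, noiseSd = 0.02,
        nDetectionFail = 10L, nMockUnstable = 10L,
        seed = .subSeed(seed, "beta"))
    truth <- gen$truth
    # gene-level planted effects; excluded genes are left unassayed,
    # mirroring their removal before qRT-PCR
    excluded <- c("CXADRP2", "TSPY1", "TSPY4")
    assayed <- setdiff(genes, excluded)
    vGenes <- grp$validated
    contrastsOf <- function(g) {
        if (g %in% grp$both) c("aza", "ir2gy", "ir5gy")
        else if (g %in% grp$ir2gyOnly) c("aza", "ir2gy")
        else c("aza", "ir5gy")
    }
    occPlan <- data.frame(
        gene = vGenes,
        aza = seq(21, 50, length.out = length(vGenes)),
        ir2gy = seq(50, 81, length.out = length(vGenes)),
        ir5gy = seq(48, 81, length.out = length(vGenes)))
    occPlan[occPlan$gene == "IFI16", c("aza", "ir2gy", "ir5gy")] <- -5
    eff <- list()
    for (g in assayed) {
        for (cond in contrastsOf(g)) {
            isV <- g %in% vGenes
            fold <- if (isV) {
                c(aza = 2.5, ir2gy = 2.0, ir5gy = 1.8)[[cond]]
            } else 1.1
            qm <- if (isV && g %in% c("APBB2", "CHGA", "CTGF")) 0.4 else NA
            occ <- if (isV) occPlan[[cond]][occPlan$gene == g] else NA
            eff[[length(eff) + 1L]] <- data.frame(
                gene = g, condition = cond, expr_fold = fold, qmsp_rel = qm,
                occ_decrease = occ, stringsAsFactors = FALSE)
        }
    }
    truth@geneEffects <- do.call(rbind, eff)
    truth@probeGeneMap <- data.frame(probe_id = unname(candProbes),
                                     gene = genes, stringsAsFactors = FALSE)
    truth@seed <- as.integer(seed)
    list(bm = gen$bm, truth = truth, annotation = ann,
         expressionCt = generateCtTables(truth, "expression",
                                         .subSeed(seed, "expression")),
         qmspCt = generateCtTables(truth, "qmsp", .subSeed(seed, "qmsp")),
         chipCt = generateCtTables(truth, "chip", .subSeed(seed, "chip")),
         chipInputPercent = .ctModel$chip$inputPercent)
}

#' Write a synthetic bundle in the formats the readers consume
#'
#' Writes the beta matrix (with condition sidecar and detection p-values),
#' the annotation, the three Ct tables, and a planted-truth table for test
#' harnesses.
#'
#' @param bundle Output of [generatePaperShapedFixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of written paths.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(beta = file.path(dir, "beta.tsv"),
               conditions = file.path(dir, "beta_conditions.tsv"),
               detectionP = file.path(dir, "beta_detectionP.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               expression = file.path(dir, "expression_ct.tsv"),
               qmsp = file.path(dir, "qmsp_ct.tsv"),
               chip = file.path(dir, "chip_ct.tsv"),
               truth = file.path(dir, "planted_truth.tsv"))
    writeBetaMatrix(bundle$bm, paths["beta"])
    ann <- bundle$annotation
    .writeTsv(data.frame(
        probe_id = ann$probe_id,
        gene_symbols = vapply(ann$gene_symbols, paste, character(1),
                              collapse = ";"),
        chromosome = ann$chromosome, tss = ann$tss, strand = ann$strand,
        island_relation = ann$island_relation, pseudogene = ann$pseudogene,
        paralog_similarity_pct = ann$paralog_similarity_pct,
        stringsAsFactors = FALSE), paths["annotation"])
    writeCtTable(bundle$expressionCt, paths["expression"])
    writeCtTable(bundle$qmspCt, paths["qmsp"])
    writeCtTable(bundle$chipCt, paths["chip"])
    .writeTsv(bundle$truth@plantedHypo, paths["truth"])
    invisible(paths)
}
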