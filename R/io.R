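#' @importFrom utils read.delim write.table
#' @importFrom IRanges CharacterList IRanges
#' @importFrom GenomicRanges GRanges
NULL

# All tabular exchange is tab-delimited UTF-8 with a header row; lines
# starting with "#" are comments. Readers validate at the boundary and name
# the offending cell; they never coerce out-of-range values silently.

.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE, na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8")
}

.requireColumns <- function(df, cols, what) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing) > 0)
        stop(what, ": missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a beta-value matrix with its condition sidecar
#'
#' Reads a tab-delimited probe-by-sample table of methylation fractions. The
#' first column (`probe_id`) holds probe identifiers; the remaining column
#' names are sample identifiers. Condition labels travel in a two-column
#' sidecar table (`sample`, `condition`); by default the sidecar is looked up
#' next to the matrix as `<stem>_conditions.tsv`.
#'
#' @param path Path to the beta table.
#' @param conditionsPath Path to the sample-to-condition sidecar.
#' @param detectionPPath Optional path to a detection p-value table with the
#'   same layout as the beta table.
#' @return A validated [BetaMatrix-class]; probe (row) order is preserved.
#' @export
readBetaMatrix <- function(path,
                           conditionsPath = paste0(
                               tools::file_path_sans_ext(path),
                               "_conditions.tsv"),
                           detectionPPath = NULL) {
    tab <- .readTsv(path)
    .requireColumns(tab, "probe_id", "beta table")
    probes <- as.character(tab$probe_id)
    if (anyDuplicated(probes))
        stop("duplicate probe id(s): ",
             paste(unique(probes[duplicated(probes)]), collapse = ", "),
             call. = FALSE)
    beta <- as.matrix(tab[, setdiff(colnames(tab), "probe_id"), drop = FALSE])
    if (!is.numeric(beta))
        stop("beta table contains non-numeric values", call. = FALSE)
    rownames(beta) <- probes
    bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        stop(sprintf("beta value %.4g out of [0,1] at probe '%s', sample '%s'",
                     beta[i, j], rownames(beta)[i], colnames(beta)[j]),
             call. = FALSE)
    }
    cond <- .readTsv(conditionsPath)
    .requireColumns(cond, c("sample", "condition"), "conditions sidecar")
    unknown <- setdiff(unique(cond$condition), conditionLevels())
    if (length(unknown) > 0)
        stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    missing <- setdiff(colnames(beta), cond$sample)
    if (length(missing) > 0)
        stop("no condition assigned for sample(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    condition <- cond$condition[match(colnames(beta), cond$sample)]
    detP <- NULL
    if (!is.null(detectionPPath)) {
        ptab <- .readTsv(detectionPPath)
        .requireColumns(ptab, "probe_id", "detection p table")
        detP <- as.matrix(ptab[, setdiff(colnames(ptab), "probe_id"),
                               drop = FALSE])
        rownames(detP) <- as.character(ptab$probe_id)
        detP <- detP[probes, colnames(beta), drop = FALSE]
    }
    BetaMatrix(beta, condition = condition, detectionP = detP)
}

#' Write a BetaMatrix (matrix, condition sidecar, optional detection p-values)
#'
#' Inverse of [readBetaMatrix()]; the round trip is value-preserving at full
#' double precision.
#'
#' @param bm A [BetaMatrix-class].
#' @param path Output path for the beta table.
#' @param conditionsPath Output path for the condition sidecar.
#' @param detectionPPath Output path for detection p-values (used only when
#'   the assay is present).
#' @return Invisibly, the beta-table path.
#' @export
writeBetaMatrix <- function(bm, path,
                            conditionsPath = paste0(
                                tools::file_path_sans_ext(path),
                                "_conditions.tsv"),
                            detectionPPath = paste0(
                                tools::file_path_sans_ext(path),
                                "_detectionP.tsv")) {
    b <- betaValues(bm)
    df <- data.frame(probe_id = rownames(b),
                     format(b, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, path)
    .writeTsv(data.frame(sample = colnames(b),
                         condition = unname(conditionOf(bm))),
              conditionsPath)
    p <- detectionP(bm)
    if (!is.null(p)) {
        pdf <- data.frame(probe_id = rownames(b),
                          format(p, digits = 17, trim = TRUE,
                                 scientific = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
        .writeTsv(pdf, detectionPPath)
    }
    invisible(path)
}

#' Read a probe annotation table
#'
#' Required columns: `probe_id`, `gene_symbols`, `chromosome`, `tss`,
#' `strand`, `island_relation`, `pseudogene`, `paralog_similarity_pct`.
#' Semicolon-separated `gene_symbols` cells are split into character vectors
#' (a 450K manifest convention); an empty cell yields a zero-length vector and
#' the row is retained. An empty `paralog_similarity_pct` cell means the
#' similarity was not assessed and is kept as `NA`, never coerced to 0.
#'
#' @param path Path to the annotation table.
#' @return A [S4Vectors::DataFrame] with `gene_symbols` as a
#'   [IRanges::CharacterList] column.
#' @export
#' @examples
#' ann <- readProbeAnnotation(system.file("extdata", "candidate_genes.tsv",
#'                                        package = "radMethyl"))
#' length(unique(unlist(ann$gene_symbols)))  # 29 candidate genes
readProbeAnnotation <- function(path) {
    tab <- .readTsv(path)
    .requireColumns(tab, c("probe_id", "gene_symbols", "chromosome", "tss",
                           "strand", "island_relation", "pseudogene",
                           "paralog_similarity_pct"),
                    "probe annotation")
    if (anyDuplicated(tab$probe_id))
        stop("duplicate probe id(s) in annotation: ",
             paste(unique(tab$probe_id[duplicated(tab$probe_id)]),
                   collapse = ", "), call. = FALSE)
    tss <- suppressWarnings(as.numeric(tab$tss))
    if (any(is.na(tss)))
        stop("non-numeric tss for probe(s): ",
             paste(tab$probe_id[is.na(tss)], collapse = ", "), call. = FALSE)
    if (any(tss < 1))
        stop("tss must be >= 1 (1-based coordinates)", call. = FALSE)
    sim <- suppressWarnings(as.numeric(tab$paralog_similarity_pct))
    if (any(!is.na(sim) & (sim < 0 | sim > 100)))
        stop("paralog_similarity_pct must lie in [0,100]", call. = FALSE)
    genes <- strsplit(ifelse(is.na(tab$gene_symbols), "",
                             as.character(tab$gene_symbols)), ";",
                      fixed = TRUE)
    genes <- lapply(genes, function(g) g[nzchar(g)])
    DataFrame(probe_id = as.character(tab$probe_id),
              gene_symbols = CharacterList(genes),
              chromosome = as.character(tab$chromosome),
              tss = as.integer(tss),
              strand = as.character(tab$strand),
              island_relation = as.character(tab$island_relation),
              pseudogene = as.logical(tab$pseudogene),
              paralog_similarity_pct = sim)
}

# gene -> rows of ann whose gene_symbols contain it
.annRowsForGene <- function(ann, gene) {
    which(vapply(ann$gene_symbols, function(g) gene %in% g, logical(1)))
}

#' Write promoter intervals (TSS +/- flank) as BED6
#'
#' The promoter is defined as the symmetric window of `flank` bp upstream and
#' downstream of the transcription start site. The annotation TSS is 1-based;
#' BED is 0-based half-open, so the written interval is
#' `[tss - 1 - flank, tss - 1 + flank)`, clamped at 0. The flank is symmetric
#' regardless of strand; strand is still written in column 6.
#'
#' @param ann Annotation from [readProbeAnnotation()].
#' @param genes Gene symbols to emit, one BED record each.
#' @param path Output BED path.
#' @param flank Flank size in bp (default 1000, i.e. TSS +/- 1 kb).
#' @return Invisibly, the output path.
#' @export
writePromoterBed <- function(ann, genes, path, flank = 1000) {
    stopifnot(flank > 0)
    missing <- genes[vapply(genes, function(g)
        length(.annRowsForGene(ann, g)) == 0L, logical(1))]
    if (length(missing) > 0)
        stop("gene(s) absent from annotation: ",
             paste(missing, collapse = ", "), call. = FALSE)
    recs <- lapply(genes, function(g) {
        rows <- .annRowsForGene(ann, g)
        tss <- unique(ann$tss[rows])
        chrom <- unique(ann$chromosome[rows])
        strand <- unique(ann$strand[rows])
        if (length(tss) != 1L || length(chrom) != 1L)
            stop("gene '", g, "' does not resolve to a single TSS",
                 call. = FALSE)
        list(chrom = chrom, tss = tss, strand = strand[1L])
    })
    # BED chromStart = tss - 1 - flank (clamped at 0) corresponds to
    # 1-based start tss - flank (clamped at 1); chromEnd = tss - 1 + flank.
    tss <- vapply(recs, `[[`, numeric(1), "tss")
    gr <- GRanges(vapply(recs, `[[`, character(1), "chrom"),
                  IRanges(start = pmax(1, tss - flank),
                          end = tss - 1 + flank),
                  strand = vapply(recs, `[[`, character(1), "strand"),
                  name = genes, score = 0L)
    names(gr) <- genes
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' Columns: `gene`, `condition`, `assay`, `channel`, `replicate`, `ct`.
#' `assay` is one of expression / qmsp / chip; allowed channels are
#' target + reference for expression (reference = GAPDH) and qMSP
#' (reference = Alu), and input + ip_dnmt1 + ip_igg for ChIP. Ct values must
#' be positive and finite.
#'
#' @param path Path to the Ct table.
#' @return A validated data.frame.
#' @export
readCtTable <- function(path) {
    tab <- .readTsv(path)
    .requireColumns(tab, c("gene", "condition", "assay", "channel",
                           "replicate", "ct"), "Ct table")
    validateCtTable(tab)
    tab
}

#' Validate a Ct table already in memory
#'
#' @param tab A data.frame with Ct-table columns (see [readCtTable()]).
#' @return Invisibly `TRUE`; stops with a message naming the offending record
#'   otherwise.
#' @export
validateCtTable <- function(tab) {
    unknownCond <- setdiff(unique(tab$condition), conditionLevels())
    if (length(unknownCond) > 0)
        stop("unknown condition label(s) in Ct table: ",
             paste(unknownCond, collapse = ", "), call. = FALSE)
    badAssay <- setdiff(unique(tab$assay), c("expression", "qmsp", "chip"))
    if (length(badAssay) > 0)
        stop("unknown assay: ", paste(badAssay, collapse = ", "),
             call. = FALSE)
    allowed <- list(expression = c("target", "reference"),
                    qmsp = c("target", "reference"),
                    chip = c("input", "ip_dnmt1", "ip_igg"))
    for (a in unique(tab$assay)) {
        badCh <- setdiff(unique(tab$channel[tab$assay == a]), allowed[[a]])
        if (length(badCh) > 0)
            stop("channel(s) not allowed for assay '", a, "': ",
                 paste(badCh, collapse = ", "), call. = FALSE)
    }
    ct <- suppressWarnings(as.numeric(tab$ct))
    bad <- which(is.na(ct) | !is.finite(ct) | ct <= 0)
    if (length(bad) > 0)
        stop(sprintf(
            "invalid Ct at row %d (gene '%s', condition '%s', channel '%s')",
            bad[1L], tab$gene[bad[1L]], tab$condition[bad[1L]],
            tab$channel[bad[1L]]), call. = FALSE)
    invisible(TRUE)
}

#' Write a Ct table
#'
#' @param tab Ct table (validated before writing).
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
writeCtTable <- function(tab, path) {
    validateCtTable(tab)
    .writeTsv(tab, path)
    invisible(path)
}

.fmtNum <- function(x, digits = 6) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

#' Write the per-gene candidate report
#'
#' One row per candidate gene, ordered lexicographically by symbol:
#' supporting probes and contrasts, gene-level delta-beta and fold ratio per
#' contrast (means over supporting probes), exclusion status, expression
#' fold-changes, DNMT1 occupancy decreases, and the final concordance
#' verdict. Identical inputs produce byte-identical files.
#'
#' @param candidates Candidate table from [applyExclusionRules()] (or
#'   [collapseToGenes()]).
#' @param calls Combined methylation-call table across contrasts (may be
#'   `NULL`).
#' @param validations Optional list with elements `expression` (gene,
#'   condition, fold_change), `occupancy` (gene, condition, decrease) and
#'   `verdicts` (from [scoreConcordance()]); any may be absent.
#' @param path Output path.
#' @return Invisibly, the output path.
#' @export
writeCandidateReport <- function(candidates, calls = NULL,
                                 validations = list(), path) {
    cols <- c("gene", "supporting_probes", "supporting_contrasts", "excluded",
              "exclusion_reason",
              paste0("delta_beta_", c("aza", "ir2gy", "ir5gy")),
              paste0("fold_ratio_", c("aza", "ir2gy", "ir5gy")),
              paste0("expr_fold_", c("aza", "ir2gy", "ir5gy")),
              paste0("dnmt1_decrease_", c("aza", "ir2gy", "ir5gy")),
              "validated")
    if (is.null(candidates) || nrow(candidates) == 0) {
        writeLines(paste(cols, collapse = "\t"), path)
        return(invisible(path))
    }
    ord <- order(candidates$gene, method = "radix")
    cand <- candidates[ord, , drop = FALSE]
    out <- data.frame(gene = cand$gene,
                      supporting_probes = vapply(cand$supporting_probes,
                                                 paste, character(1),
                                                 collapse = ";"),
                      supporting_contrasts = vapply(
                          seq_len(nrow(cand)), function(i) paste(
                              c("ir2gy", "ir5gy")[c(cand$ir2gy[i],
                                                    cand$ir5gy[i])],
                              collapse = ";"), character(1)),
                      excluded = cand$excluded,
                      exclusion_reason = cand$exclusion_reason,
                      stringsAsFactors = FALSE)
    condOf <- c(aza = "aza-vs-mock", ir2gy = "ir2gy-vs-mock",
                ir5gy = "ir5gy-vs-mock")
    for (cn in names(condOf)) {
        db <- fr <- rep(NA_real_, nrow(cand))
        if (!is.null(calls) && nrow(calls) > 0) {
            sub <- calls[calls$contrast == condOf[[cn]], , drop = FALSE]
            for (i in seq_len(nrow(cand))) {
                hit <- sub[sub$probe_id %in% cand$supporting_probes[[i]], ,
                           drop = FALSE]
                if (nrow(hit) > 0) {
                    db[i] <- mean(hit$delta_beta)
                    fr[i] <- mean(hit$fold_ratio)
                }
            }
        }
        out[[paste0("delta_beta_", cn)]] <- .fmtNum(db)
        out[[paste0("fold_ratio_", cn)]] <- .fmtNum(fr)
    }
    expr <- validations$expression
    occ <- validations$occupancy
    for (cn in names(condOf)) {
        ef <- dd <- rep(NA_real_, nrow(cand))
        if (!is.null(expr) && nrow(expr) > 0) {
            sub <- expr[expr$condition == cn, , drop = FALSE]
            ef <- sub$fold_change[match(cand$gene, sub$gene)]
        }
        if (!is.null(occ) && nrow(occ) > 0) {
            sub <- occ[occ$condition == cn, , drop = FALSE]
            dd <- sub$decrease[match(cand$gene, sub$gene)]
        }
        out[[paste0("expr_fold_", cn)]] <- .fmtNum(ef)
        out[[paste0("dnmt1_decrease_", cn)]] <- .fmtNum(dd)
    }
    verdicts <- validations$verdicts
    v <- rep(NA, nrow(cand))
    if (!is.null(verdicts) && nrow(verdicts) > 0)
        v <- verdicts$validated[match(cand$gene, verdicts$gene)]
    out$validated <- v
    out <- out[, cols]
    .writeTsv(out, path)
    invisible(path)
}
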