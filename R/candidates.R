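# Candidate selection: intersect the per-contrast hypomethylated probe sets
# with the 5-aza-dC demethylation control, collapse probes to genes, and
# apply the pseudogene / paralog-similarity exclusion rules.

#' Disjoint Venn partition of three hypomethylated probe sets
#'
#' Partitions the union of the aza, 2 Gy and 5 Gy hypomethylated probe sets
#' into the seven exclusive membership patterns. Patterns are named by the
#' "+"-joined members in canonical order (`aza`, `ir2gy`, `ir5gy`).
#'
#' @param hypoAza,hypoIr2gy,hypoIr5gy Character vectors of probe ids.
#' @return Named list of seven character vectors (disjoint; union equals the
#'   union of the inputs).
#' @export
#' @examples
#' vennPartition(c("p1", "p2", "p3", "p4"), c("p2", "p3", "p5"), character())
vennPartition <- function(hypoAza, hypoIr2gy, hypoIr5gy) {
    sets <- list(aza = unique(as.character(hypoAza)),
                 ir2gy = unique(as.character(hypoIr2gy)),
                 ir5gy = unique(as.character(hypoIr5gy)))
    all <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) all %in% s, logical(length(all)))
    if (length(all) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
    patterns <- c("aza", "ir2gy", "ir5gy", "aza+ir2gy", "aza+ir5gy",
                  "ir2gy+ir5gy", "aza+ir2gy+ir5gy")
    out <- stats::setNames(vector("list", length(patterns)), patterns)
    key <- apply(member, 1L, function(m)
        paste(names(sets)[m], collapse = "+"))
    for (p in patterns) out[[p]] <- all[key == p]
    out
}

#' Select radiation-induced hypomethylation candidates
#'
#' The 5-aza-dC arm is the demethylation positive control: a probe is a
#' candidate only when it is hypomethylated in aza AND in at least one
#' irradiated contrast. Probes hypomethylated only after irradiation (no aza
#' support) or only in aza are reported by the Venn partition but not
#' promoted.
#'
#' @param vp A [vennPartition()] result.
#' @return data.frame with `probe_id` and logical columns `ir2gy`, `ir5gy`
#'   recording which irradiated contrast(s) supported each probe.
#' @export
selectIrCandidates <- function(vp) {
    pick <- function(pattern) vp[[pattern]]
    probes <- c(pick("aza+ir2gy"), pick("aza+ir5gy"), pick("aza+ir2gy+ir5gy"))
    data.frame(probe_id = probes,
               ir2gy = probes %in% c(pick("aza+ir2gy"),
                                     pick("aza+ir2gy+ir5gy")),
               ir5gy = probes %in% c(pick("aza+ir5gy"),
                                     pick("aza+ir2gy+ir5gy")),
               stringsAsFactors = FALSE)
}

#' Collapse candidate probes to genes
#'
#' One candidate record per distinct gene symbol over the supporting probes'
#' annotations. A probe annotated with several symbols supports every listed
#' gene; probes with an empty gene list produce no gene but are tallied in
#' the `n_unannotated` attribute. A gene's supporting contrasts are the union
#' over its supporting probes.
#'
#' @param selected Either the data.frame from [selectIrCandidates()] or a
#'   plain character vector of probe ids (then no contrast support is
#'   recorded).
#' @param ann Annotation from [readProbeAnnotation()].
#' @return data.frame with `gene`, `supporting_probes` (list column),
#'   `n_probes`, `ir2gy`, `ir5gy`, `excluded` (all `FALSE`),
#'   `exclusion_reason` ("none"); attribute `n_unannotated` counts probes
#'   without gene annotation. Genes in symbol order.
#' @export
collapseToGenes <- function(selected, ann) {
    if (is.character(selected))
        selected <- data.frame(probe_id = selected, ir2gy = FALSE,
                               ir5gy = FALSE, stringsAsFactors = FALSE)
    idx <- match(selected$probe_id, ann$probe_id)
    if (anyNA(idx))
        stop("probe id(s) absent from annotation: ",
             paste(selected$probe_id[is.na(idx)], collapse = ", "),
             call. = FALSE)
    symbols <- as.list(ann$gene_symbols[idx])
    nUnannotated <- sum(lengths(symbols) == 0L)
    genes <- sort(unique(unlist(symbols)))
    rows <- lapply(genes, function(g) {
        sup <- which(vapply(symbols, function(s) g %in% s, logical(1)))
        data.frame(gene = g,
                   n_probes = length(sup),
                   ir2gy = any(selected$ir2gy[sup]),
                   ir5gy = any(selected$ir5gy[sup]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(), n_probes = integer(),
                          ir2gy = logical(), ir5gy = logical(),
                          stringsAsFactors = FALSE)
    out$supporting_probes <- lapply(genes, function(g)
        selected$probe_id[vapply(symbols, function(s) g %in% s, logical(1))])
    out$excluded <- rep(FALSE, nrow(out))
    out$exclusion_reason <- rep("none", nrow(out))
    out <- out[, c("gene", "supporting_probes", "n_probes", "ir2gy", "ir5gy",
                   "excluded", "exclusion_reason")]
    attr(out, "n_unannotated") <- nUnannotated
    out
}

#' Flag candidate genes that cannot be assayed gene-specifically
#'
#' Pseudogenes and genes whose paralog sequence similarity reaches the
#' threshold (default 94%) cannot be distinguished by gene-specific qPCR
#' primers, so they are flagged as excluded from downstream validation. They
#' remain in the candidate table with their reason; exclusion gates
#' validation eligibility only, never discovery membership.
#'
#' @param genes Candidate table from [collapseToGenes()].
#' @param ann Annotation from [readProbeAnnotation()].
#' @param similarityThreshold Percent similarity at or above which a gene is
#'   excluded (default 94, in (0, 100\]).
#' @return The candidate table with `excluded` / `exclusion_reason`
#'   (`pseudogene`, `paralog_similarity`, or `none`) set; row order
#'   preserved.
#' @export
applyExclusionRules <- function(genes, ann, similarityThreshold = 94) {
    stopifnot(similarityThreshold > 0, similarityThreshold <= 100)
    for (i in seq_len(nrow(genes))) {
        rows <- .annRowsForGene(ann, genes$gene[i])
        if (length(rows) == 0L) next
        if (any(ann$pseudogene[rows], na.rm = TRUE)) {
            genes$excluded[i] <- TRUE
            genes$exclusion_reason[i] <- "pseudogene"
        } else {
            sim <- ann$paralog_similarity_pct[rows]
            if (any(!is.na(sim) & sim >= similarityThreshold)) {
                genes$excluded[i] <- TRUE
                genes$exclusion_reason[i] <- "paralog_similarity"
            }
        }
    }
    genes
}

#' Venn pattern sizes as a table
#'
#' @param vp A [vennPartition()] result.
#' @return data.frame with `pattern` and `n_probes`.
#' @export
vennSummary <- function(vp) {
    data.frame(pattern = names(vp), n_probes = lengths(vp),
               row.names = NULL, stringsAsFactors = FALSE)
}
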