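test_that("Venn partition computes exclusive membership patterns", {
    vp <- vennPartition(c("p1", "p2", "p3", "p4"), c("p2", "p3", "p5"),
                        character())
    expect_setequal(vp[["aza+ir2gy"]], c("p2", "p3"))
    expect_setequal(vp[["aza"]], c("p1", "p4"))
    expect_setequal(vp[["ir2gy"]], "p5")
    expect_length(vp[["aza+ir2gy+ir5gy"]], 0L)

    disjoint <- vennPartition(c("a1", "a2"), c("b1"), c("c1", "c2"))
    expect_length(unlist(disjoint[grepl("\\+", names(disjoint))]), 0L)
})

test_that("Venn partition matches per-probe enumeration on random sets", {
    set.seed(19)
    for (rep in 1:5) {
        pool <- sprintf("p%03d", 1:200)
        aza <- sample(pool, 80); ir2 <- sample(pool, 60)
        ir5 <- sample(pool, 50)
        vp <- vennPartition(aza, ir2, ir5)
        # disjoint and complete
        expect_equal(sum(lengths(vp)), length(unique(c(aza, ir2, ir5))))
        expect_false(anyDuplicated(unlist(vp)) > 0)
        oracle <- enumerateVenn(aza, ir2, ir5)
        for (pat in names(vp))
            expect_setequal(vp[[pat]], names(oracle)[oracle == pat])
    }
})

test_that("candidates require aza support plus at least one IR dose", {
    vp <- vennPartition(c("a", "b", "c", "d", "z"),
                        c("a", "b", "d", "x"), c("c", "d"))
    sel <- selectIrCandidates(vp)
    expect_setequal(sel$probe_id, c("a", "b", "c", "d"))
    expect_true(all(sel$ir2gy[sel$probe_id %in% c("a", "b", "d")]))
    expect_true(all(sel$ir5gy[sel$probe_id %in% c("c", "d")]))
    # IR-only probes are never promoted
    onlyIr <- selectIrCandidates(vennPartition(character(), "x", "y"))
    expect_equal(nrow(onlyIr), 0L)
})

test_that("candidate selection is monotone in its input sets", {
    set.seed(23)
    pool <- sprintf("p%03d", 1:100)
    aza <- sample(pool, 40); ir2 <- sample(pool, 30); ir5 <- sample(pool, 20)
    base <- selectIrCandidates(vennPartition(aza, ir2, ir5))$probe_id
    extra <- setdiff(pool, aza)[1:5]
    grown <- selectIrCandidates(vennPartition(c(aza, extra), ir2,
                                              ir5))$probe_id
    expect_true(all(base %in% grown))
})

test_that("probe-to-gene collapse unions symbols and tracks contrasts", {
    dir <- withr::local_tempdir()
    writeLines(c(paste("probe_id", "gene_symbols", "chromosome", "tss",
                       "strand", "island_relation", "pseudogene",
                       "paralog_similarity_pct", sep = "\t"),
                 "p1\tGENEA\tchr1\t100\t+\tisland\tFALSE\t",
                 "p2\tGENEA;GENEB\tchr1\t200\t+\tisland\tFALSE\t",
                 "p3\t\tchr1\t300\t+\tisland\tFALSE\t"),
               file.path(dir, "ann.tsv"))
    ann <- readProbeAnnotation(file.path(dir, "ann.tsv"))
    sel <- data.frame(probe_id = c("p1", "p2", "p3"),
                      ir2gy = c(TRUE, FALSE, FALSE),
                      ir5gy = c(FALSE, TRUE, FALSE))
    genes <- collapseToGenes(sel, ann)
    expect_setequal(genes$gene, c("GENEA", "GENEB"))
    expect_equal(genes$n_probes[genes$gene == "GENEA"], 2L)
    expect_true(genes$ir2gy[genes$gene == "GENEA"])  # union over probes
    expect_true(genes$ir5gy[genes$gene == "GENEA"])
    expect_equal(attr(genes, "n_unannotated"), 1L)
    expect_error(collapseToGenes(c("p1", "missing"), ann),
                 "absent from annotation")
})

test_that("gene collapse equals the brute-force symbol union on random input", {
    set.seed(29)
    nGenes <- 40L
    symbols <- sprintf("G%02d", seq_len(nGenes))
    rows <- vapply(1:120, function(i)
        paste(sample(symbols, sample(1:2, 1)), collapse = ";"), character(1))
    dir <- withr::local_tempdir()
    writeLines(c(paste("probe_id", "gene_symbols", "chromosome", "tss",
                       "strand", "island_relation", "pseudogene",
                       "paralog_similarity_pct", sep = "\t"),
                 sprintf("p%03d\t%s\tchr1\t%d\t+\tisland\tFALSE\t",
                         1:120, rows, 1:120)),
               file.path(dir, "ann.tsv"))
    ann <- readProbeAnnotation(file.path(dir, "ann.tsv"))
    probes <- sprintf("p%03d", sample(1:120, 100))
    genes <- collapseToGenes(probes, ann)
    oracle <- sort(unique(unlist(strsplit(
        rows[match(probes, sprintf("p%03d", 1:120))], ";"))))
    expect_identical(genes$gene, oracle)
})

test_that("exclusion rules flag pseudogenes and near-identical paralogs", {
    ann <- readProbeAnnotation(system.file("extdata", "candidate_genes.tsv",
                                           package = "radMethyl"))
    genes <- collapseToGenes(ann$probe_id, ann)
    flagged <- applyExclusionRules(genes, ann, similarityThreshold = 94)
    expect_identical(flagged$exclusion_reason[flagged$gene == "CXADRP2"],
                     "pseudogene")
    expect_identical(flagged$exclusion_reason[flagged$gene == "TSPY1"],
                     "paralog_similarity")
    expect_identical(flagged$exclusion_reason[flagged$gene == "TSPY4"],
                     "paralog_similarity")
    expect_false(flagged$excluded[flagged$gene == "ANGPT1"])
    # retained + excluded partition the candidates; order preserved
    expect_equal(sum(flagged$excluded) + sum(!flagged$excluded),
                 nrow(flagged))
    expect_identical(flagged$gene, genes$gene)
    # a stricter threshold than 94% releases the paralogs
    relaxed <- applyExclusionRules(genes, ann, similarityThreshold = 95)
    expect_false(relaxed$excluded[relaxed$gene == "TSPY1"])
})
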