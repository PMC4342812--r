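annFixture <- function() {
    readProbeAnnotation(system.file("extdata", "candidate_genes.tsv",
                                    package = "radMethyl"))
}

test_that("the packaged candidate annotation holds 29 distinct genes", {
    ann <- annFixture()
    expect_equal(length(unique(unlist(ann$gene_symbols))), 29L)
    expect_true(all(ann$tss >= 1))
    # missing similarity stays NA, never coerced to 0
    expect_true(anyNA(ann$paralog_similarity_pct))
    expect_false(any(ann$paralog_similarity_pct == 0, na.rm = TRUE))
})

test_that("multi-gene cells split on semicolons; empty cells retained", {
    dir <- withr::local_tempdir()
    writeLines(c(paste("probe_id", "gene_symbols", "chromosome", "tss",
                       "strand", "island_relation", "pseudogene",
                       "paralog_similarity_pct", sep = "\t"),
                 "p1\tTSPY1;TSPY4\tchrY\t100\t+\tisland\tFALSE\t94",
                 "p2\t\tchr1\t200\t-\topen_sea\tFALSE\t"),
               file.path(dir, "ann.tsv"))
    ann <- readProbeAnnotation(file.path(dir, "ann.tsv"))
    expect_equal(lengths(ann$gene_symbols), c(2L, 0L))
    expect_identical(as.character(ann$gene_symbols[[1]]),
                     c("TSPY1", "TSPY4"))
    expect_equal(nrow(ann), 2L)
})

test_that("annotation reader rejects malformed tables with named causes", {
    dir <- withr::local_tempdir()
    writeLines(c("probe_id\tgene_symbols", "p1\tA"),
               file.path(dir, "short.tsv"))
    expect_error(readProbeAnnotation(file.path(dir, "short.tsv")),
                 "missing required column")
    writeLines(c(paste("probe_id", "gene_symbols", "chromosome", "tss",
                       "strand", "island_relation", "pseudogene",
                       "paralog_similarity_pct", sep = "\t"),
                 "p1\tA\tchr1\tabc\t+\tisland\tFALSE\t"),
               file.path(dir, "badtss.tsv"))
    expect_error(readProbeAnnotation(file.path(dir, "badtss.tsv")),
                 "non-numeric tss.*p1")
})

test_that("promoter BED uses 0-based half-open TSS +/- flank with clamping", {
    dir <- withr::local_tempdir()
    writeLines(c(paste("probe_id", "gene_symbols", "chromosome", "tss",
                       "strand", "island_relation", "pseudogene",
                       "paralog_similarity_pct", sep = "\t"),
                 "p1\tGENEA\tchr1\t10000\t+\tisland\tFALSE\t",
                 "p2\tGENEB\tchr2\t500\t+\tisland\tFALSE\t",
                 "p3\tGENEC\tchr1\t10000\t-\tisland\tFALSE\t"),
               file.path(dir, "ann.tsv"))
    ann <- readProbeAnnotation(file.path(dir, "ann.tsv"))
    bed <- file.path(dir, "prom.bed")
    writePromoterBed(ann, c("GENEA", "GENEB", "GENEC"), bed, flank = 1000)
    tab <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
    expect_equal(tab$V2[tab$V4 == "GENEA"], 8999)
    expect_equal(tab$V3[tab$V4 == "GENEA"], 10999)
    expect_equal(tab$V2[tab$V4 == "GENEB"], 0)  # clamped
    expect_equal(tab$V3[tab$V4 == "GENEB"], 1499)
    # symmetric flank: minus strand interval identical for the same TSS
    expect_equal(tab$V2[tab$V4 == "GENEC"], tab$V2[tab$V4 == "GENEA"])
    expect_equal(tab$V3[tab$V4 == "GENEC"], tab$V3[tab$V4 == "GENEA"])
    expect_true(all(tab$V2 >= 0 & tab$V2 < tab$V3))
    expect_error(writePromoterBed(ann, c("GENEA", "NOPE"), bed),
                 "absent from annotation.*NOPE")
})

test_that("Ct table reader validates vocabulary and values", {
    dir <- withr::local_tempdir()
    tab <- data.frame(gene = "ANGPT1", condition = "aza",
                      assay = "expression", channel = c("target", "reference"),
                      replicate = 1L, ct = c(24.5, 20.1))
    writeCtTable(tab, file.path(dir, "ct.tsv"))
    back <- readCtTable(file.path(dir, "ct.tsv"))
    expect_equal(back$ct, tab$ct)
    bad <- tab; bad$ct[1] <- -3
    expect_error(validateCtTable(bad), "invalid Ct.*ANGPT1")
    bad2 <- tab; bad2$channel[1] <- "input"
    expect_error(validateCtTable(bad2), "not allowed for assay")
    bad3 <- tab; bad3$condition <- "sham"
    expect_error(validateCtTable(bad3), "unknown condition")
})

test_that("candidate report is deterministic, ordered, and handles empties", {
    ann <- annFixture()
    sel <- data.frame(probe_id = c("cg90000009", "cg90000001"),
                      ir2gy = c(TRUE, TRUE), ir5gy = c(FALSE, TRUE))
    cand <- applyExclusionRules(collapseToGenes(sel, ann), ann)
    dir <- withr::local_tempdir()
    f1 <- file.path(dir, "r1.tsv"); f2 <- file.path(dir, "r2.tsv")
    writeCandidateReport(cand, path = f1)
    writeCandidateReport(cand, path = f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    tab <- read.delim(f1)
    expect_identical(tab$gene, sort(tab$gene))  # lexicographic rows
    expect_equal(sum(tab$excluded), 1L)         # CXADRP2 flagged

    f0 <- file.path(dir, "empty.tsv")
    writeCandidateReport(cand[0, ], path = f0)
    expect_equal(nrow(read.delim(f0)), 0L)      # header-only file
})
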