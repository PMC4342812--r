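test_that("delta-delta-Ct fold change follows its closed form", {
    expect_equal(ddctFoldChange(26, 20, 28, 20)$foldChange, 4)
    expect_equal(ddctFoldChange(26, 20, 28, 20)$ddCt, -2)
    # identity: any arm against itself gives fold 1
    expect_equal(ddctFoldChange(c(24.1, 24.3), c(20, 20.2),
                                c(24.1, 24.3), c(20, 20.2))$foldChange, 1)
    # replicate means against an independent closed-form evaluation
    tt <- c(24.1, 24.3); rt <- c(20.0, 20.2)
    tc <- c(26.7, 26.5); rc <- c(19.9, 20.1)
    expected <- 2^-((mean(tt) - mean(rt)) - (mean(tc) - mean(rc)))
    expect_equal(ddctFoldChange(tt, rt, tc, rc)$foldChange, expected,
                 tolerance = 1e-12)
    expect_equal(ddctFoldChange(tt, rt, tc, rc)$ctSpread, sd(tt))
    expect_error(ddctFoldChange(numeric(), 20, 28, 20), "empty replicate")
})

test_that("qMSP relative methylation is Alu-normalized and mock-anchored", {
    # mock delta-Ct 5, treated delta-Ct 7 -> 2^-2
    expect_equal(qmspRelativeMethylation(23, 16, 21, 16), 0.25)
    expect_equal(qmspRelativeMethylation(c(21, 21), c(16, 16),
                                         c(21, 21), c(16, 16)), 1)
})

test_that("ChIP percent-of-input adjusts for the input fraction and doubles per cycle", {
    expect_equal(chipPercentInput(18, 20, 1), 100 * 2^(20 - log2(100) - 18))
    expect_equal(chipPercentInput(18, 20, 1), 4, tolerance = 1e-10)
    expect_equal(chipPercentInput(20, 20, 100), 100)
    # one extra IP cycle halves the signal; strictly decreasing in ct_ip
    expect_equal(chipPercentInput(19, 20, 1) / chipPercentInput(18, 20, 1),
                 0.5)
    cts <- seq(14, 22, by = 0.5)
    vals <- vapply(cts, chipPercentInput, numeric(1), ctInput = 20,
                   inputPercent = 1)
    expect_true(all(diff(vals) < 0))
    expect_error(chipPercentInput(18, 20, 0), "inputPercent")
})

test_that("occupancy decrease is the percent drop versus mock", {
    expect_equal(occupancyDecrease(1.00, 0.79), 21)
    expect_equal(occupancyDecrease(2, 2), 0)
    expect_equal(occupancyDecrease(2, 1), 50)
    expect_equal(occupancyDecrease(1, 1.2), -20)  # increases reported
    expect_error(occupancyDecrease(0, 1), "mock")
})

test_that("concordance requires expression support in every supporting contrast", {
    cand <- data.frame(
        gene = c("GOOD", "PSEUDO", "WEAK", "QUIET"),
        supporting_probes = I(list("p1", "p2", "p3", "p4")),
        n_probes = 1L,
        ir2gy = c(TRUE, TRUE, TRUE, TRUE),
        ir5gy = c(FALSE, FALSE, FALSE, FALSE),
        excluded = c(FALSE, TRUE, FALSE, FALSE),
        exclusion_reason = c("none", "pseudogene", "none", "none"))
    expr <- data.frame(
        gene = c("GOOD", "GOOD", "PSEUDO", "PSEUDO", "WEAK", "WEAK"),
        condition = rep(c("aza", "ir2gy"), 3),
        fold_change = c(2.0, 1.8, 3.0, 3.0, 1.2, 2.0))
    occ <- data.frame(gene = c("GOOD", "GOOD"),
                      condition = c("aza", "ir2gy"), decrease = c(30, 60))
    v <- scoreConcordance(cand, expr, occ)
    expect_true(v$validated[v$gene == "GOOD"])
    expect_true(v$occupancy_down[v$gene == "GOOD"])
    # exclusion vetoes validation regardless of fold
    expect_false(v$validated[v$gene == "PSEUDO"])
    expect_identical(v$status[v$gene == "PSEUDO"], "excluded")
    # 1.2-fold in aza is below the 1.5 threshold
    expect_false(v$validated[v$gene == "WEAK"])
    # no expression record at all -> unassayed, never validated
    expect_identical(v$status[v$gene == "QUIET"], "unassayed")
    expect_false(v$validated[v$gene == "QUIET"])
    # set inclusions: validated subset of expression_up subset of retained
    expect_true(all(v$gene[v$validated] %in% v$gene[v$expression_up]))
    expect_true(all(v$gene[v$expression_up] %in% v$gene[!cand$excluded]))
})

test_that("table-level helpers recover per-gene, per-condition quantities", {
    ct <- data.frame(gene = "G1",
                     condition = rep(c("mock", "aza"), each = 2),
                     assay = "expression",
                     channel = rep(c("target", "reference"), 2),
                     replicate = 1L,
                     ct = c(26, 20, 24, 20))
    ef <- expressionFoldChanges(ct)
    expect_equal(ef$fold_change[ef$condition == "aza"], 4)

    chip <- data.frame(gene = "G1",
                       condition = rep(c("mock", "aza"), each = 3),
                       assay = "chip",
                       channel = rep(c("input", "ip_dnmt1", "ip_igg"), 2),
                       replicate = 1L,
                       ct = c(20, 20 - log2(100) - log2(0.02), 25,
                              20, 20 - log2(100) - log2(0.01), 25))
    occ <- chipOccupancy(chip, inputPercent = 1)
    expect_equal(occ$percentInput$percent_input[
        occ$percentInput$condition == "mock" &
        occ$percentInput$antibody == "dnmt1"], 2, tolerance = 1e-10)
    expect_equal(occ$decrease$decrease, 50, tolerance = 1e-10)
})
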