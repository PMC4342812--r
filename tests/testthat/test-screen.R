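test_that("reliability filter applies detection, mock-instability and missing rules", {
    b <- matrix(c(0.5, 0.5, 0.5, 0.5,
                  0.5, 0.9, 0.5, 0.5,
                  0.5, 0.5, NA,  0.5,
                  0.3, 0.3, 0.3, 0.3),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("p", 1:4),
                                c("m1", "m2", "a1", "a2")))
    p <- matrix(0.001, 4, 4, dimnames = dimnames(b))
    p["p1", "a1"] <- 0.5
    bm <- BetaMatrix(b, condition = c("mock", "mock", "aza", "aza"),
                     detectionP = p)
    flt <- filterReliableProbes(bm)
    expect_setequal(flt$kept, "p4")
    expect_equal(flt$excluded$reason[flt$excluded$probe_id == "p1"],
                 "detection")
    expect_equal(flt$excluded$reason[flt$excluded$probe_id == "p2"],
                 "mock-instability")
    expect_equal(flt$excluded$reason[flt$excluded$probe_id == "p3"],
                 "missing")
    # kept and excluded always partition the probe set
    expect_setequal(c(flt$kept, flt$excluded$probe_id), rownames(b))
    expect_length(intersect(flt$kept, flt$excluded$probe_id), 0L)
})

test_that("contrast calling applies the joint delta-beta and fold criteria", {
    b <- matrix(c(0.62, 0.21,
                  0.35, 0.20,
                  0.90, 0.65),
                nrow = 3, byrow = TRUE,
                dimnames = list(paste0("cg", 1:3), c("m1", "a1")))
    bm <- BetaMatrix(b, condition = c("mock", "aza"))
    calls <- callContrast(bm, "aza-vs-mock")
    expect_equal(calls$delta_beta, c(-0.41, -0.15, -0.25))
    expect_equal(calls$fold_ratio[1], 0.62 / 0.21, tolerance = 1e-12)
    # cg1 passes both; cg2 fails |delta|; cg3 passes delta but 1.38x fold
    expect_identical(calls$direction, c("hypo", "none", "none"))
    expect_error(callContrast(bm, "ir2gy-vs-mock"), "no samples")
})

test_that("direction is antisymmetric under swapping control and treated", {
    set.seed(7)
    b <- matrix(runif(200), 50, 4,
                dimnames = list(sprintf("p%02d", 1:50),
                                c("m1", "m2", "t1", "t2")))
    fwd <- callContrast(BetaMatrix(b, c("mock", "mock", "aza", "aza")),
                        "aza-vs-mock")
    rev <- callContrast(BetaMatrix(b, c("aza", "aza", "mock", "mock")),
                        "aza-vs-mock")
    expect_setequal(fwd$probe_id[fwd$direction == "hypo"],
                    rev$probe_id[rev$direction == "hyper"])
    expect_setequal(fwd$probe_id[fwd$direction == "hyper"],
                    rev$probe_id[rev$direction == "hypo"])
    expect_equal(fwd$delta_beta, -rev$delta_beta)
})

test_that("no calls arise when treated equals mock", {
    set.seed(11)
    half <- matrix(runif(60), 30, 2)
    b <- cbind(half, half)
    dimnames(b) <- list(sprintf("p%02d", 1:30), c("m1", "m2", "a1", "a2"))
    calls <- callContrast(BetaMatrix(b, c("mock", "mock", "aza", "aza")),
                          "aza-vs-mock")
    expect_identical(unique(calls$direction), "none")
})

test_that("lowering either threshold never shrinks the hypo set", {
    set.seed(13)
    for (rep in 1:5) {
        b <- matrix(runif(120), 30, 4,
                    dimnames = list(sprintf("p%02d", 1:30),
                                    c("m1", "m2", "a1", "a2")))
        bm <- BetaMatrix(b, c("mock", "mock", "aza", "aza"))
        strict <- hypoProbes(callContrast(bm, "aza-vs-mock",
                                          cfg = screenConfig()))
        looseDelta <- hypoProbes(callContrast(
            bm, "aza-vs-mock", cfg = screenConfig(deltaBetaMin = 0.1)))
        looseFold <- hypoProbes(callContrast(
            bm, "aza-vs-mock", cfg = screenConfig(foldMin = 1.2)))
        expect_true(all(strict %in% looseDelta))
        expect_true(all(strict %in% looseFold))
    }
})

test_that("calls match an independent brute-force oracle on small matrices", {
    set.seed(17)
    for (rep in 1:10) {
        n <- sample(5:50, 1)
        cond <- c("mock", "mock", "aza", "ir2gy", "ir2gy")
        b <- matrix(runif(n * 5), n, 5,
                    dimnames = list(sprintf("p%03d", seq_len(n)),
                                    sprintf("s%d", 1:5)))
        bm <- BetaMatrix(b, cond)
        for (ct in c("aza-vs-mock", "ir2gy-vs-mock")) {
            got <- callContrast(bm, ct)
            oracle <- bruteForceCalls(b, cond, sub("-vs-mock", "", ct))
            expect_identical(stats::setNames(got$direction, got$probe_id),
                             oracle)
        }
    }
})

test_that("direction tallies are consistent and refuse mixed contrasts", {
    empty <- callContrast(
        BetaMatrix(matrix(c(0.5, 0.5), 1,
                          dimnames = list("p1", c("s1", "s2"))),
                   c("mock", "aza")), "aza-vs-mock")[0, ]
    expect_equal(unname(countByDirection(empty)), c(0L, 0L, 0L))
    calls <- data.frame(probe_id = sprintf("p%d", 1:5),
                        contrast = "aza-vs-mock",
                        direction = c("hypo", "hypo", "hypo", "none", "none"))
    expect_equal(countByDirection(calls),
                 c(hypo = 3L, hyper = 0L, none = 2L))
    mixed <- calls; mixed$contrast[1] <- "ir2gy-vs-mock"
    expect_error(countByDirection(mixed), "mix")
})
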