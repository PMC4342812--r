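# Shared builders and independent oracles for the test suite.

# tiny BetaMatrix with one sample per condition unless widths are given
makeBeta <- function(beta, condition) {
    BetaMatrix(beta, condition = condition)
}

# Independent brute-force reimplementation of the two-threshold calling
# rule: explicit per-probe loops, no shared code with callContrast().
bruteForceCalls <- function(beta, condition, treated, deltaMin = 0.2,
                            foldMin = 1.5, eps = 0.01) {
    out <- character(nrow(beta))
    for (i in seq_len(nrow(beta))) {
        bm <- 0; nm <- 0; bt <- 0; nt <- 0
        for (j in seq_len(ncol(beta))) {
            if (condition[j] == "mock") { bm <- bm + beta[i, j]; nm <- nm + 1 }
            if (condition[j] == treated) { bt <- bt + beta[i, j]; nt <- nt + 1 }
        }
        bm <- bm / nm; bt <- bt / nt
        d <- bt - bm
        if (d <= -deltaMin && bm / max(bt, eps) > foldMin) out[i] <- "hypo"
        else if (d >= deltaMin && bt / max(bm, eps) > foldMin) out[i] <- "hyper"
        else out[i] <- "none"
    }
    stats::setNames(out, rownames(beta))
}

# Brute-force average-linkage agglomeration: cluster distance recomputed
# each step as the mean over all member pairs of the ORIGINAL distance
# matrix (no Lance-Williams update), ties by smallest (i, j).
bruteForceAverageLinkage <- function(D) {
    n <- nrow(D)
    clusters <- lapply(seq_len(n), identity)   # member leaf sets
    code <- -seq_len(n)
    merges <- matrix(0L, n - 1L, 2L)
    heights <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        k <- length(clusters)
        best <- NULL; bestD <- Inf
        for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
            dd <- mean(D[clusters[[i]], clusters[[j]]])
            if (dd < bestD) { bestD <- dd; best <- c(i, j) }
        }
        i <- best[1L]; j <- best[2L]
        a <- code[i]; b <- code[j]
        merges[step, ] <- if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
            else if (a < 0) c(a, b) else if (b < 0) c(b, a) else sort(c(a, b))
        heights[step] <- bestD
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        code[i] <- step
        clusters[[j]] <- NULL
        code <- code[-j]
    }
    list(merge = merges, height = heights)
}

# exclusive Venn membership by per-probe enumeration (oracle)
enumerateVenn <- function(aza, ir2, ir5) {
    all <- sort(unique(c(aza, ir2, ir5)))
    sapply(all, function(p) paste(c("aza", "ir2gy", "ir5gy")[
        c(p %in% aza, p %in% ir2, p %in% ir5)], collapse = "+"))
}

# cluster memberships at every merge height (set-of-sets, order-free)
cutPartitions <- function(hc) {
    n <- length(hc$labels)
    lapply(seq_len(n - 1L), function(k) {
        grp <- stats::cutree(hc, k = n - k)
        unname(sort(vapply(split(hc$labels, grp), function(g)
            paste(sort(g), collapse = ","), character(1))))
    })
}
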