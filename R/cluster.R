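# Hierarchical clustering for heatmap ordering. Similarity is Pearson
# correlation (centred r, not uncentred cosine); distance is 1 - r, bounded
# in [0, 2]. Agglomeration is average linkage (UPGMA) with a documented
# deterministic tie-break, so identical inputs always give identical merges.

#' Pearson-correlation distance between two vectors
#'
#' Returns 1 - r(x, y), where r is the (centred) Pearson correlation
#' coefficient, giving a dissimilarity in \[0, 2\]: 0 for perfectly
#' correlated profiles, 2 for perfectly anti-correlated ones. Symmetric and
#' invariant to positive affine rescaling of either argument.
#'
#' @param x,y Numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return Distance in \[0, 2\].
#' @export
#' @examples
#' pearsonDistance(1:5, 2 * (1:5) + 3)  # 0
#' pearsonDistance(1:5, -(1:5))         # 2
pearsonDistance <- function(x, y) {
    if (length(x) != length(y) || length(x) < 2L)
        stop("vectors must have equal length >= 2", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero-variance vector", call. = FALSE)
    1 - stats::cor(x, y)
}

# Pairwise 1 - r distance matrix over the rows of m; errors name the
# zero-variance item.
.pearsonDistanceMatrix <- function(m) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
        stop("undefined correlation: zero-variance item(s): ",
             paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    1 - stats::cor(t(m))
}

# hclust merge-row convention: singletons (negative, by leaf number) before
# earlier merges (positive, by step), pairs sorted within each kind
.normalizeMergeRow <- function(a, b) {
    if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
    else if (a < 0) c(a, b)
    else if (b < 0) c(b, a)
    else sort(c(a, b))
}

#' Average-linkage hierarchical clustering with Pearson distance
#'
#' Agglomerates items (rows or columns of `m`) under average linkage
#' (UPGMA): the distance between clusters is the mean of all pairwise
#' 1 - r distances between their members, maintained by the Lance-Williams
#' update. Ties are broken deterministically by merging the candidate pair
#' with the lexicographically smallest pair of cluster indices (leaves in
#' input order, merged clusters in order of creation), so a given input
#' always yields the same merge sequence.
#'
#' @param m Numeric matrix; items on the chosen axis must have >= 2
#'   observations and nonzero variance.
#' @param axis Cluster `"rows"` (default) or `"columns"`.
#' @return An object of class [stats::hclust]: `merge`, `height` (bounded in
#'   \[0, 2\], non-decreasing), `order`, `labels`, `method = "average"`.
#'   For a single item, an hclust-shaped object with an empty merge list.
#' @export
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
#' hc <- hierarchicalCluster(m)
#' hc$merge  # a and b (r = 1) merge first at height 0
hierarchicalCluster <- function(m, axis = c("rows", "columns")) {
    axis <- match.arg(axis)
    if (axis == "columns") m <- t(m)
    m <- as.matrix(m)
    n <- nrow(m)
    if (n < 1L) stop("no items to cluster", call. = FALSE)
    labels <- rownames(m)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    if (n == 1L) {
        return(structure(list(merge = matrix(integer(0), 0L, 2L),
                              height = numeric(0), order = 1L,
                              labels = labels, method = "average",
                              dist.method = "pearson"),
                         class = "hclust"))
    }
    if (ncol(m) < 2L)
        stop("need >= 2 observations per item for correlation", call. = FALSE)
    d <- .pearsonDistanceMatrix(m)
    # active clusters ordered by creation; hclust codes: -leaf / +merge step
    code <- -seq_len(n)
    size <- rep(1L, n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        k <- length(code)
        best <- c(NA_integer_, NA_integer_); bestD <- Inf
        for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
            if (d[i, j] < bestD) { bestD <- d[i, j]; best <- c(i, j) }
        }
        i <- best[1L]; j <- best[2L]
        merge[step, ] <- .normalizeMergeRow(code[i], code[j])
        height[step] <- bestD
        ni <- size[i]; nj <- size[j]
        newRow <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
        keep <- setdiff(seq_len(k), c(i, j))
        d <- rbind(cbind(d[keep, keep, drop = FALSE], newRow[keep]),
                   c(newRow[keep], 0))
        code <- c(code[keep], step)
        size <- c(size[keep], ni + nj)
    }
    getOrder <- function(x) {
        if (x < 0) -x else c(getOrder(merge[x, 1L]), getOrder(merge[x, 2L]))
    }
    structure(list(merge = merge, height = height,
                   order = getOrder(n - 1L), labels = labels,
                   method = "average", dist.method = "pearson"),
              class = "hclust")
}

#' Row and column display order for a candidate-probe heatmap
#'
#' Clusters the selected probes (rows) and all samples (columns) of a beta
#' matrix and returns the dendrogram leaf orders; beta values themselves are
#' untouched. Degenerate axes (a single item, or items too short to
#' correlate) fall back to identity order.
#'
#' @param bm A [BetaMatrix-class].
#' @param probes Probe ids to display (must exist in `bm`).
#' @return List with `probes` and `samples` (ordered id vectors) and the two
#'   dendrograms (`probeDendrogram`, `sampleDendrogram`, `NULL` when
#'   degenerate).
#' @export
heatmapOrder <- function(bm, probes) {
    stopifnot(is(bm, "BetaMatrix"))
    unknown <- setdiff(probes, rownames(bm))
    if (length(unknown) > 0)
        stop("unknown probe id(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    b <- betaValues(bm)[probes, , drop = FALSE]
    clusterAxis <- function(mat) {
        if (nrow(mat) < 2L || ncol(mat) < 2L) return(NULL)
        hierarchicalCluster(mat)
    }
    hr <- clusterAxis(b)
    hcCols <- clusterAxis(t(b))
    list(probes = if (is.null(hr)) probes else probes[hr$order],
         samples = if (is.null(hcCols)) colnames(b) else
             colnames(b)[hcCols$order],
         probeDendrogram = hr, sampleDendrogram = hcCols)
}

#' Render a candidate-probe heatmap (convenience layer)
#'
#' Thin wrapper around \pkg{pheatmap} using [heatmapOrder()] orders and the
#' conventional green-to-red gradient over beta in \[0, 1\] (green =
#' unmethylated, red = methylated). Purely presentational.
#'
#' @param bm A [BetaMatrix-class].
#' @param probes Probe ids to display.
#' @param ... Passed through to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plotCandidateHeatmap <- function(bm, probes, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("package 'pheatmap' is required for rendering", call. = FALSE)
    ord <- heatmapOrder(bm, probes)
    b <- betaValues(bm)[ord$probes, ord$samples, drop = FALSE]
    pal <- grDevices::colorRampPalette(c("green", "black", "red"))(50)
    invisible(pheatmap::pheatmap(b, color = pal, cluster_rows = FALSE,
                                 cluster_cols = FALSE,
                                 breaks = seq(0, 1, length.out = 51), ...))
}
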