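## Data-overview computations: the numbers behind the histogram, boxplot,
## heatmap and PCA/k-means figures.

#' Log2 transform with a floor at intensity 1
#'
#' Missing values are assigned an intensity of 1 before the log2 transform,
#' so they map to 0; an observed intensity of exactly 1 is therefore
#' indistinguishable from missing in the transformed matrix (documented
#' behaviour, acceptable for display purposes only).
#'
#' @param m non-negative intensity matrix, `NA` allowed.
#' @return complete log2 matrix.
#' @export
log2WithFloor <- function(m) {
    if (any(m < 0, na.rm = TRUE)) stop("negative intensities")
    m[is.na(m)] <- 1
    log2(m)
}

#' Hierarchical clustering for the overview heatmaps
#'
#' Complete-linkage agglomeration on Euclidean distances, over matrix rows
#' (sites) or columns (samples). The heatmaps come in two variants: samples
#' only, and samples plus sites; both are driven by this function.
#'
#' @param m complete numeric matrix (use [log2WithFloor()] first).
#' @param axis cluster `"columns"` (samples) or `"rows"`.
#' @return an [stats::hclust] object.
#' @export
overviewClustering <- function(m, axis = c("columns", "rows")) {
    axis <- match.arg(axis)
    if (axis == "columns") m <- t(m)
    if (nrow(m) < 2L) stop("need at least two items to cluster")
    if (anyNA(m)) stop("matrix must be complete; apply log2WithFloor() first")
    stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' PCA with k-means clustering of samples
#'
#' Principal components of centred sample profiles, followed by k-means on
#' the score matrix with `k` set to the reference classification's group
#' count plus one. The first three components back both the 2D and 3D PCA
#' views.
#'
#' @param m complete log2 matrix, sites x samples.
#' @param design a [GroupDesign-class]; its reference classification fixes
#'   `k`.
#' @param nComponents number of principal components to keep.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return list with `scores` (samples x components), `sdev`,
#'   `varianceExplained`, `k` and `clusters` (named integer vector).
#' @export
pcaKmeans <- function(m, design, nComponents = 3L, seed = 1L, nstart = 10L) {
    if (anyNA(m)) stop("matrix must be complete")
    ref <- classifications(design)[[referenceClassification(design)]]
    k <- length(unique(ref)) + 1L
    if (k > ncol(m))
        stop("k = ", k, " exceeds the number of samples (", ncol(m), ")")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    nComponents <- min(nComponents, ncol(pc$x))
    scores <- pc$x[, seq_len(nComponents), drop = FALSE]
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(pc$x, centers = k, nstart = nstart)
    clusters <- km$cluster
    names(clusters) <- colnames(m)
    list(scores = scores, sdev = pc$sdev,
         varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
         k = k, clusters = clusters)
}

restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble the overview bundle
#'
#' Runs [log2WithFloor()], the two clustering variants and [pcaKmeans()] on
#' a raw-intensity [PhosphoSet-class] and returns the figure-ready pieces.
#'
#' @param x a [PhosphoSet-class] with raw intensities.
#' @param design a [GroupDesign-class].
#' @param seed RNG seed for k-means.
#' @param clusterRows also cluster sites (can be slow for very large sets).
#' @return list with `log2`, `sampleClustering`, `siteClustering` (or
#'   `NULL`), and the [pcaKmeans()] fields.
#' @export
overviewBundle <- function(x, design, seed = 1L, clusterRows = TRUE) {
    lg <- log2WithFloor(intensities(x))
    pk <- pcaKmeans(lg, design, seed = seed)
    list(log2 = lg,
         sampleClustering = overviewClustering(lg, "columns"),
         siteClustering = if (clusterRows && nrow(lg) >= 2L)
             overviewClustering(lg, "rows") else NULL,
         scores = pk$scores, varianceExplained = pk$varianceExplained,
         k = pk$k, clusters = pk$clusters)
}
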