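## Missingness filtering, normalization and low-rank imputation.

#' Filter rows/columns by missing-value fraction
#'
#' Rows are filtered first; column missing fractions are then recomputed on
#' the surviving rows, so a column can be rescued by the removal of a bad
#' row. An item is dropped when its missing fraction strictly exceeds the
#' threshold.
#'
#' @param m numeric matrix with `NA` for missing values.
#' @param rowMaxMissing,colMaxMissing maximum tolerated missing fraction, in
#'   `[0, 1]`. 1 disables the filter.
#' @return list with `matrix` (the filtered matrix), `keptRows`, `keptCols`
#'   (logical vectors on the input dimensions) and `droppedRows`,
#'   `droppedCols` (names or indices of removed items).
#' @export
filterMissing <- function(m, rowMaxMissing = 0.5, colMaxMissing = 1) {
    for (thr in c(rowMaxMissing, colMaxMissing))
        if (!is.numeric(thr) || is.na(thr) || thr < 0 || thr > 1)
            stop("missingness thresholds must lie in [0, 1]")
    rowFrac <- rowMeans(is.na(m))
    keepR <- rowFrac <= rowMaxMissing
    m2 <- m[keepR, , drop = FALSE]
    colFrac <- colMeans(is.na(m2))
    keepC <- colFrac <= colMaxMissing
    idOf <- function(nm, idx) if (is.null(nm)) which(idx) else nm[idx]
    list(matrix = m2[, keepC, drop = FALSE],
         keptRows = keepR, keptCols = keepC,
         droppedRows = idOf(rownames(m), !keepR),
         droppedCols = idOf(colnames(m), !keepC))
}

#' Median normalization of a log2 matrix
#'
#' Shifts each column so that all column medians equal the global mean of
#' the original column medians; missingness is untouched and the overall
#' intensity level is preserved.
#'
#' @param m numeric matrix on the log2 scale.
#' @return normalized matrix.
#' @export
medianNormalize <- function(m) {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    if (any(is.na(med))) stop("column(s) with no observed values: ",
                              paste(which(is.na(med)), collapse = ", "))
    sweep(m, 2, med - mean(med))
}

#' Quantile normalization of a log2 matrix
#'
#' Forces every column onto the common distribution given by the across-
#' column mean of order statistics. Ties share the mean of the quantile
#' values they span; missing entries are excluded from ranking (interpolated
#' quantiles) and stay missing. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param m numeric matrix on the log2 scale, `>= 2` columns.
#' @return normalized matrix with the same dimnames and missingness pattern.
#' @export
quantileNormalize <- function(m) {
    if (ncol(m) < 2L) stop("quantile normalization needs >= 2 columns")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Low-rank approximation imputation
#'
#' Fills missing entries by iterative truncated-SVD completion: missing
#' cells are initialised with row means, then the rank-`rank` SVD of the
#' completed matrix is computed and its reconstruction overwrites only the
#' missing cells, iterating until the maximum relative change of the imputed
#' values drops below `tol` or `maxIter` is reached. Observed entries are
#' never modified. Every row must carry at least four observed values;
#' offending rows abort with an error naming them so the caller can fall
#' back to a normalization-only mode.
#'
#' @param m numeric matrix (log2 scale recommended).
#' @param rank target rank of the approximation.
#' @param tol relative-change convergence tolerance.
#' @param maxIter iteration cap.
#' @return completed matrix.
#' @export
lowRankImpute <- function(m, rank = 2L, tol = 1e-5, maxIter = 500L) {
    if (rank < 1L) stop("rank must be >= 1")
    nObs <- rowSums(!is.na(m))
    if (any(nObs < 4L)) {
        bad <- if (is.null(rownames(m))) which(nObs < 4L) else
            rownames(m)[nObs < 4L]
        stop("imputation requires at least four observed values per row; ",
             "offending row(s): ", paste(utils::head(bad, 10L), collapse = ", "),
             if (sum(nObs < 4L) > 10L) " ..." else "")
    }
    miss <- is.na(m)
    if (!any(miss)) return(m)
    x <- m
    rm <- rowMeans(m, na.rm = TRUE)
    x[miss] <- rm[row(m)[miss]]
    rank <- min(rank, nrow(m), ncol(m))
    prev <- x[miss]
    for (it in seq_len(maxIter)) {
        sv <- svd(x, nu = rank, nv = rank)
        fit <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
        x[miss] <- fit[miss]
        cur <- x[miss]
        delta <- max(abs(cur - prev) / pmax(abs(prev), 1e-12))
        if (delta < tol) break
        prev <- cur
    }
    x
}

#' Preprocess a PhosphoSet
#'
#' Applies, in order: missingness filtering, log2 transformation, then the
#' chosen normalization mode — `"none"`, `"normalize"` (median
#' normalization) or `"normalize_impute"` (quantile normalization followed
#' by low-rank imputation). The returned object's intensities are on the
#' log2 scale; the raw-scale filtered matrix is kept in
#' `metadata(x)$raw_intensity`.
#'
#' @param x a [PhosphoSet-class] with raw intensities.
#' @param mode preprocessing mode (see above).
#' @param rowMaxMissing,colMaxMissing see [filterMissing()].
#' @param imputeRank,imputeTol,imputeMaxIter see [lowRankImpute()].
#' @return a list: `set` (the preprocessed [PhosphoSet-class], log2 scale),
#'   `report` (character log of the steps applied).
#' @export
preprocess <- function(x, mode = c("none", "normalize", "normalize_impute"),
                       rowMaxMissing = 0.5, colMaxMissing = 1,
                       imputeRank = 2L, imputeTol = 1e-5,
                       imputeMaxIter = 500L) {
    mode <- match.arg(mode)
    flt <- filterMissing(intensities(x), rowMaxMissing, colMaxMissing)
    report <- c(sprintf("missingness filter (row <= %g, col <= %g): dropped %d row(s), %d column(s)",
                        rowMaxMissing, colMaxMissing,
                        sum(!flt$keptRows), sum(!flt$keptCols)))
    y <- x[flt$keptRows, flt$keptCols]
    raw <- intensities(y)
    lg <- log2(raw)
    if (mode == "normalize") {
        lg <- medianNormalize(lg)
        report <- c(report, "median normalization (log2 scale)")
    } else if (mode == "normalize_impute") {
        lg <- quantileNormalize(lg)
        nObs <- rowSums(!is.na(lg))
        if (any(nObs < 4L))
            stop("imputation requires at least four observed values per row (",
                 sum(nObs < 4L), " row(s) violate this); rerun with mode ",
                 "'none' or 'normalize'")
        lg <- lowRankImpute(lg, rank = imputeRank, tol = imputeTol,
                            maxIter = imputeMaxIter)
        report <- c(report,
                    "quantile normalization (log2 scale)",
                    sprintf("low-rank imputation (rank %d, tol %g)",
                            imputeRank, imputeTol))
    } else report <- c(report, "no normalization")
    metadata(y)$raw_intensity <- raw
    metadata(y)$log2 <- TRUE
    intensities(y) <- lg
    list(set = y, report = report)
}
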