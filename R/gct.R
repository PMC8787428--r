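## GCT v1.3 I/O. The site-enrichment stage converts site statistics into
## GCT input files; a minimal, strict reader/writer keeps the round trip
## byte-stable.

#' Write a GCT v1.3 file
#'
#' Layout: `#1.3` header; a dimension line `nrow ncol n_row_meta
#' n_col_meta`; a column-header line (`id`, row-metadata names, column
#' ids); one line per column-metadata field; one line per data row.
#' Numbers are written with 17 significant digits so that
#' `writeGCT(readGCT(f), f2)` reproduces `f` byte for byte.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param rowMeta data.frame of row metadata (or `NULL`).
#' @param colMeta data.frame of column metadata (or `NULL`).
#' @return `path`, invisibly.
#' @export
writeGCT <- function(mat, path, rowMeta = NULL, colMeta = NULL) {
    if (is.null(rownames(mat)) || is.null(colnames(mat)))
        stop("matrix must have dimnames")
    nrm <- if (is.null(rowMeta)) 0L else ncol(rowMeta)
    ncm <- if (is.null(colMeta)) 0L else ncol(colMeta)
    if (nrm && nrow(rowMeta) != nrow(mat)) stop("rowMeta dimension mismatch")
    if (ncm && nrow(colMeta) != ncol(mat)) stop("colMeta dimension mismatch")
    fmt <- function(x) {
        out <- sprintf("%.17g", x); out[is.na(x)] <- "NA"; out
    }
    con <- file(path, "wb")  # binary: fixed \n endings for byte stability
    on.exit(close(con))
    wl <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
    wl("#1.3")
    wl(paste(nrow(mat), ncol(mat), nrm, ncm, sep = "\t"))
    wl(paste(c("id", colnames(rowMeta), colnames(mat)), collapse = "\t"))
    if (ncm) for (j in seq_len(ncm))
        wl(paste(c(colnames(colMeta)[j], rep("", nrm),
                   as.character(colMeta[[j]])), collapse = "\t"))
    for (i in seq_len(nrow(mat))) {
        meta <- if (nrm) vapply(seq_len(nrm), function(j)
            as.character(rowMeta[i, j]), character(1)) else character()
        wl(paste(c(rownames(mat)[i], meta, fmt(mat[i, ])), collapse = "\t"))
    }
    invisible(path)
}

#' Read a GCT v1.3 file
#'
#' @param path GCT path.
#' @return list: `mat` (numeric matrix), `rowMeta`, `colMeta` (data.frames
#'   or `NULL`).
#' @export
readGCT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || trimws(lines[1]) != "#1.3")
        stop("malformed GCT header (expected '#1.3')")
    dims <- as.integer(strsplit(lines[2], "\t")[[1]])
    if (length(dims) != 4L || anyNA(dims))
        stop("malformed GCT dimension line")
    nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
    expected <- 3L + ncm + nr
    if (length(lines) < expected)
        stop("GCT body has fewer lines than the declared dimensions")
    hdr <- strsplit(lines[3], "\t")[[1]]
    if (length(hdr) != 1L + nrm + nc) stop("GCT header width mismatch")
    rmNames <- if (nrm) hdr[2:(1 + nrm)] else character()
    cids <- hdr[(2 + nrm):length(hdr)]
    colMeta <- NULL
    if (ncm) {
        cm <- lapply(seq_len(ncm), function(j) {
            f <- strsplit(lines[3 + j], "\t")[[1]]
            stats::setNames(list(f[(2 + nrm):(1 + nrm + nc)]), f[1])
        })
        colMeta <- as.data.frame(do.call(c, cm), stringsAsFactors = FALSE,
                                 check.names = FALSE)
    }
    body <- strsplit(lines[(4 + ncm):(3 + ncm + nr)], "\t")
    widths <- lengths(body)
    if (any(widths != 1L + nrm + nc)) stop("GCT data row width mismatch")
    rids <- vapply(body, `[`, character(1), 1L)
    rowMeta <- NULL
    if (nrm) {
        rowMeta <- as.data.frame(
            do.call(rbind, lapply(body, function(f) f[2:(1 + nrm)])),
            stringsAsFactors = FALSE)
        colnames(rowMeta) <- rmNames
    }
    mat <- do.call(rbind, lapply(body, function(f)
        suppressWarnings(as.numeric(f[(2 + nrm):(1 + nrm + nc)]))))
    dimnames(mat) <- list(rids, cids)
    list(mat = mat, rowMeta = rowMeta, colMeta = colMeta)
}
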