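## Readers for phosphosite tables and the experimental design.

mqIntensityPattern <- "^Intensity (.+)___([123])$"

readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    if (!nrow(df)) stop("empty table: ", path)
    df
}

## Centre a sequence window on its middle residue and coerce to 15-mer.
## MaxQuant writes 31-mers; the pipeline standardises on +/-7.
trimWindow <- function(w) {
    n <- nchar(w)
    out <- w
    wide <- n > WINDOW_LEN
    if (any(wide)) {
        mid <- (n[wide] + 1L) %/% 2L
        out[wide] <- substr(w[wide], mid - 7L, mid + 7L)
    }
    short <- nchar(out) < WINDOW_LEN
    if (any(short)) # pad symmetrically; callers should supply padded windows
        out[short] <- vapply(out[short], function(s) {
            left <- (WINDOW_LEN - nchar(s)) %/% 2L
            paste0(strrep(WINDOW_PAD, left), s,
                   strrep(WINDOW_PAD, WINDOW_LEN - nchar(s) - left))
        }, character(1))
    out
}

#' Parse a MaxQuant Phospho (STY)Sites table
#'
#' Reads the tab-separated `Phospho (STY)Sites.txt` dialect and applies the
#' standard clean-up: reverse-database rows are always removed; potential
#' contaminants are removed unless `mode = "keep_contaminants"`. Intensities
#' are reported per multiplicity (`___1/___2/___3` column suffixes):
#' `"summed"` (and `"keep_contaminants"`) adds the three multiplicity channels
#' per sample, treating missing as zero but leaving the result missing when
#' all three are missing; `"expanded"` emits one row per (site, multiplicity),
#' dropping rows whose chosen multiplicity is missing in every sample.
#'
#' @param path path to the TSV file.
#' @param mode one of `"summed"`, `"expanded"`, `"keep_contaminants"`.
#' @return a [PhosphoSet-class]; `multiplicity` is 0 for summed rows, 1-3 for
#'   expanded rows.
#' @export
parseMaxQuantSites <- function(path,
                               mode = c("summed", "expanded",
                                        "keep_contaminants")) {
    mode <- match.arg(mode)
    df <- readTsv(path)
    accCol <- intersect(c("Proteins", "Protein", "Leading proteins"),
                        colnames(df))[1]
    if (is.na(accCol))
        stop("format error: missing required column 'Proteins'")
    for (col in c("Position", "Amino acid", "Sequence window"))
        if (!col %in% colnames(df))
            stop("format error: missing required column '", col, "'")
    intCols <- grep(mqIntensityPattern, colnames(df), value = TRUE)
    if (!length(intCols))
        stop("format error: missing required column 'Intensity <sample>___k'")
    samples <- unique(sub(mqIntensityPattern, "\\1", intCols))
    flag <- function(col) if (col %in% colnames(df))
        !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
    rev <- flag("Reverse")
    con <- flag("Potential contaminant")
    keep <- !rev & (mode == "keep_contaminants" | !con)
    df <- df[keep, , drop = FALSE]
    con <- con[keep]
    if (!nrow(df)) stop("no rows left after reverse/contaminant removal")

    ## sites x samples x multiplicity array
    arr <- array(NA_real_, c(nrow(df), length(samples), 3L))
    for (k in 1:3) for (j in seq_along(samples)) {
        col <- sprintf("Intensity %s___%d", samples[j], k)
        if (col %in% colnames(df)) {
            v <- suppressWarnings(as.numeric(df[[col]]))
            v[!is.na(v) & v == 0] <- NA_real_  # MaxQuant writes 0 for absent
            arr[, j, k] <- v
        }
    }
    info <- data.frame(
        accession = vapply(strsplit(as.character(df[[accCol]]), ";"),
                           `[`, character(1), 1L),
        gene = if ("Gene names" %in% colnames(df))
            as.character(df[["Gene names"]]) else NA_character_,
        position = as.integer(df[["Position"]]),
        residue = as.character(df[["Amino acid"]]),
        window = trimWindow(as.character(df[["Sequence window"]])),
        reverse = FALSE, contaminant = con,
        stringsAsFactors = FALSE)
    if ("id" %in% colnames(df)) info$maxquant_id <- as.character(df[["id"]])

    if (mode == "expanded") {
        pieces <- lapply(1:3, function(k) {
            m <- arr[, , k, drop = FALSE]
            dim(m) <- dim(arr)[1:2]
            keepRow <- rowSums(!is.na(m)) > 0L
            if (!any(keepRow)) return(NULL)
            inf <- info[keepRow, , drop = FALSE]
            inf$multiplicity <- k
            list(info = inf, m = m[keepRow, , drop = FALSE])
        })
        pieces <- Filter(Negate(is.null), pieces)
        info <- do.call(rbind, lapply(pieces, `[[`, "info"))
        m <- do.call(rbind, lapply(pieces, `[[`, "m"))
    } else {
        nObs <- rowSums(!is.na(arr), dims = 2L)
        m <- rowSums(arr, dims = 2L, na.rm = TRUE)
        m[nObs == 0L] <- NA_real_
        info$multiplicity <- 0L
    }
    colnames(m) <- samples
    info$site_id <- siteKey(info$accession, info$position, info$residue,
                            info$multiplicity)
    PhosphoSet(m, info)
}

#' Parse a generic phosphosite table
#'
#' Ingests preprocessed site tables from platforms other than MaxQuant
#' (Progenesis, Spectronaut, openMS, PEAKS, ...). No clean-up is applied;
#' the table is assumed already filtered. Rows whose sequence window is not
#' a 15-mer are rejected with a warning naming them.
#'
#' @param path CSV (`.csv`) or TSV file.
#' @param schema named list mapping the fields `accession`, `position`,
#'   `residue`, `window` (mandatory) and `gene`, `site_id` (optional) to
#'   column names, plus `samples`: the intensity column names (default: all
#'   unmapped columns).
#' @return a [PhosphoSet-class] with `multiplicity = 0`.
#' @export
parseGenericSites <- function(path, schema = list()) {
    defaults <- list(accession = "accession", position = "position",
                     residue = "residue", window = "window")
    schema <- utils::modifyList(defaults, schema)
    df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    else readTsv(path)
    if (!nrow(df)) stop("empty table: ", path)
    for (field in c("accession", "position", "residue", "window"))
        if (!schema[[field]] %in% colnames(df))
            stop("format error: unmapped mandatory column '", field,
                 "' (expected file column '", schema[[field]], "')")
    mapped <- unlist(schema[names(schema) != "samples"], use.names = FALSE)
    samples <- schema$samples
    if (is.null(samples)) samples <- setdiff(colnames(df), mapped)
    if (!length(samples)) stop("no intensity columns identified")
    info <- data.frame(
        accession = as.character(df[[schema$accession]]),
        position = as.integer(df[[schema$position]]),
        residue = as.character(df[[schema$residue]]),
        window = as.character(df[[schema$window]]),
        multiplicity = 0L, stringsAsFactors = FALSE)
    if (!is.null(schema$gene) && schema$gene %in% colnames(df))
        info$gene <- as.character(df[[schema$gene]])
    if (!is.null(schema$site_id) && schema$site_id %in% colnames(df))
        info$site_id <- as.character(df[[schema$site_id]])
    bad <- nchar(info$window) != WINDOW_LEN |
        substr(info$window, WINDOW_CENTER, WINDOW_CENTER) != info$residue
    if (any(bad)) {
        warning(sum(bad), " row(s) rejected (window not a 15-mer centred on ",
                "the site residue): ",
                paste(utils::head(siteKey(info$accession[bad],
                                          info$position[bad],
                                          info$residue[bad]), 5L),
                      collapse = ", "))
        info <- info[!bad, , drop = FALSE]
        df <- df[!bad, , drop = FALSE]
    }
    ids <- if (!is.null(info$site_id)) info$site_id else
        siteKey(info$accession, info$position, info$residue)
    if (anyDuplicated(ids))
        stop("duplicate site id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    info$site_id <- ids
    m <- as.matrix(df[, samples, drop = FALSE])
    storage.mode(m) <- "double"
    PhosphoSet(m, info)
}

#' Load a group/comparison design file
#'
#' The design file is a sectioned CSV. A `[groups]` section lists
#' `classification,sample,group` rows; a `[comparisons]` section lists
#' `classification,groups,paired` rows where `groups` is a
#' semicolon-separated list of group indices (two for a pairwise test, three
#' or more for a multi-group test); an optional `[meta]` section carries
#' `organism` and `reference_classification` key,value rows.
#'
#' @param path design file path.
#' @param table a [PhosphoSet-class]; every design sample must be a column.
#' @return a validated [GroupDesign-class].
#' @export
readDesign <- function(path, table) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    section <- ""
    groups <- list(); comps <- list()
    organismName <- "other"; refCls <- NA_character_
    for (ln in lines) {
        if (grepl("^\\[", ln)) {
            section <- gsub("\\[|\\]", "", ln)
            next
        }
        f <- trimws(strsplit(ln, ",")[[1]])
        if (section == "groups") {
            if (identical(tolower(f[1]), "classification")) next
            groups[[length(groups) + 1L]] <-
                list(cls = f[1], sample = f[2], group = as.integer(f[3]))
        } else if (section == "comparisons") {
            if (identical(tolower(f[1]), "classification")) next
            comps[[length(comps) + 1L]] <- list(
                classification = f[1],
                groups = as.integer(strsplit(f[2], ";")[[1]]),
                paired = toupper(f[3]) %in% c("TRUE", "T", "YES", "1"))
        } else if (section == "meta") {
            if (identical(tolower(f[1]), "organism")) organismName <- f[2]
            if (identical(tolower(f[1]), "reference_classification"))
                refCls <- f[2]
        }
    }
    if (!length(groups)) stop("design file has no [groups] section")
    cls <- list()
    for (g in groups) {
        v <- cls[[g$cls]]
        v[g$sample] <- g$group
        cls[[g$cls]] <- v
    }
    cls <- lapply(cls, function(v) { w <- as.integer(v); names(w) <- names(v); w })
    missSamp <- setdiff(unique(unlist(lapply(cls, names))), colnames(table))
    if (length(missSamp))
        stop("design sample(s) absent from the site table: ",
             paste(missSamp, collapse = ", "))
    if (is.na(refCls)) refCls <- names(cls)[1]
    GroupDesign(cls, comps, organism = organismName,
                referenceClassification = refCls)
}

#' Write / read a PhosphoSet as CSV
#'
#' `writeSiteTable()` serialises site metadata and intensities to a single
#' CSV with 17 significant digits so that `readSiteTable()` round-trips the
#' object exactly.
#'
#' @param x a [PhosphoSet-class].
#' @param path CSV path.
#' @return `readSiteTable()` returns a [PhosphoSet-class];
#'   `writeSiteTable()` returns `path` invisibly.
#' @export
writeSiteTable <- function(x, path) {
    info <- siteInfo(x)
    m <- intensities(x)
    num <- matrix(sprintf("%.17g", m), nrow(m))
    num[is.na(m)] <- ""
    colnames(num) <- paste0("intensity.", colnames(m))
    metaCols <- c("site_id", "accession", "gene", "position", "residue",
                  "window", "multiplicity", "reverse", "contaminant")
    out <- cbind(as.data.frame(lapply(info[metaCols], as.character),
                               stringsAsFactors = FALSE), num)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    intCols <- grep("^intensity\\.", colnames(df), value = TRUE)
    m <- vapply(intCols, function(cn) {
        v <- df[[cn]]; v[v == ""] <- NA_character_; as.numeric(v)
    }, numeric(nrow(df)))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1L,
                                    dimnames = list(NULL, intCols))
    colnames(m) <- sub("^intensity\\.", "", intCols)
    info <- data.frame(
        site_id = df$site_id, accession = df$accession,
        gene = ifelse(df$gene == "" | is.na(df$gene), NA_character_, df$gene),
        position = as.integer(df$position), residue = df$residue,
        window = df$window, multiplicity = as.integer(df$multiplicity),
        reverse = df$reverse == "TRUE", contaminant = df$contaminant == "TRUE",
        stringsAsFactors = FALSE)
    PhosphoSet(m, info)
}
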