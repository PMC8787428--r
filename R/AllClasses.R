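#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData assayNames
NULL

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "Y", "W", "V")
WINDOW_PAD <- "_"
WINDOW_LEN <- 15L
WINDOW_CENTER <- 8L

#' PhosphoSet: phosphosite intensity container
#'
#' An S4 container for a phosphosite-by-sample intensity matrix together with
#' per-site metadata, extending
#' [SummarizedExperiment::SummarizedExperiment-class]. Rows are phosphosites,
#' columns are samples; the single assay `"intensity"` holds non-negative raw
#' (or, after preprocessing, log2) intensities with `NA` for missing values.
#'
#' Row metadata columns (all always present):
#' \describe{
#'   \item{accession}{protein accession}
#'   \item{gene}{gene symbol, may be `NA`}
#'   \item{position}{1-based residue position of the phosphoacceptor}
#'   \item{residue}{one of S, T, Y}
#'   \item{window}{15-mer sequence window centred on the site, `_`-padded at
#'     protein termini}
#'   \item{multiplicity}{phosphocount supporting the quantification: 1, 2, 3,
#'     or 0 meaning "summed over multiplicities"}
#'   \item{reverse, contaminant}{quality-control flags}
#' }
#'
#' @name PhosphoSet-class
#' @aliases PhosphoSet
#' @exportClass PhosphoSet
setClass("PhosphoSet", contains = "SummarizedExperiment")

setValidity("PhosphoSet", function(object) {
    msg <- character()
    if (!("intensity" %in% assayNames(object)))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- rowData(object)
    need <- c("accession", "gene", "position", "residue", "window",
              "multiplicity", "reverse", "contaminant")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        return(paste("missing row metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "site ids (rownames) must be present and unique")
    if (nrow(object)) {
        if (any(nchar(rd$window) != WINDOW_LEN))
            msg <- c(msg, sprintf("all windows must be %d characters",
                                  WINDOW_LEN))
        if (!all(rd$residue %in% c("S", "T", "Y")))
            msg <- c(msg, "residue must be one of S, T, Y")
        if (!all(rd$multiplicity %in% 0:3))
            msg <- c(msg, "multiplicity must be in {0,1,2,3}")
        if (any(rd$position < 1L, na.rm = TRUE))
            msg <- c(msg, "position must be >= 1")
        ## raw intensities are non-negative; once log2-transformed (flagged
        ## in metadata) negative values are legitimate
        if (!isTRUE(metadata(object)$log2)) {
            x <- assay(object, "intensity")
            if (any(x < 0, na.rm = TRUE))
                msg <- c(msg, "intensities must be non-negative or missing")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PhosphoSet
#'
#' @param intensities numeric matrix, sites x samples, `NA` allowed. Column
#'   names are sample names; row names (if any) are used as site ids.
#' @param siteInfo data.frame with one row per site. Columns `accession`,
#'   `position`, `residue`, `window` are mandatory; `gene`, `multiplicity`,
#'   `reverse`, `contaminant`, `site_id` are optional.
#' @return a [PhosphoSet-class] object.
#' @examples
#' m <- matrix(2^rnorm(8, 20), 2, 4,
#'             dimnames = list(NULL, paste0("S", 1:4)))
#' info <- data.frame(accession = c("P1", "P2"), position = c(10L, 22L),
#'                    residue = c("S", "Y"),
#'                    window = c("AAAAAAASAAAAAAA", "TTTTTTTYTTTTTTT"))
#' ps <- PhosphoSet(m, info)
#' @export
PhosphoSet <- function(intensities, siteInfo) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    siteInfo <- as.data.frame(siteInfo, stringsAsFactors = FALSE)
    if (nrow(siteInfo) != nrow(intensities))
        stop("siteInfo rows and intensity rows differ")
    for (col in c("accession", "position", "residue", "window"))
        if (is.null(siteInfo[[col]]))
            stop("siteInfo is missing mandatory column '", col, "'")
    if (is.null(siteInfo$gene)) siteInfo$gene <- NA_character_
    if (is.null(siteInfo$multiplicity)) siteInfo$multiplicity <- 0L
    if (is.null(siteInfo$reverse)) siteInfo$reverse <- FALSE
    if (is.null(siteInfo$contaminant)) siteInfo$contaminant <- FALSE
    siteInfo$position <- as.integer(siteInfo$position)
    siteInfo$multiplicity <- as.integer(siteInfo$multiplicity)
    ids <- siteInfo$site_id
    if (is.null(ids)) ids <- rownames(intensities)
    if (is.null(ids))
        ids <- siteKey(siteInfo$accession, siteInfo$position,
                       siteInfo$residue, siteInfo$multiplicity)
    if (anyDuplicated(ids))
        stop("duplicate site id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    siteInfo$site_id <- NULL
    canon <- c("accession", "gene", "position", "residue", "window",
               "multiplicity", "reverse", "contaminant")
    siteInfo <- siteInfo[, c(canon, setdiff(colnames(siteInfo), canon)),
                         drop = FALSE]
    rownames(intensities) <- ids
    se <- SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = DataFrame(siteInfo, row.names = ids))
    new("PhosphoSet", se)
}

#' Canonical site key
#'
#' Builds the identity key used throughout the pipeline:
#' `accession;position;residue`, with `;k` appended for an explicit
#' multiplicity k in {1,2,3} (summed rows, multiplicity 0, carry no suffix).
#'
#' @param accession,position,residue,multiplicity vectors, recycled.
#' @return character vector of keys.
#' @export
siteKey <- function(accession, position, residue, multiplicity = 0L) {
    key <- paste(accession, position, residue, sep = ";")
    extra <- multiplicity != 0L
    key[extra] <- paste(key[extra], multiplicity[extra], sep = ";")
    key
}

#' GroupDesign: sample grouping and comparisons
#'
#' Holds one or more group classifications (named sample-to-group-index maps),
#' a list of comparisons to test, the organism, and which classification the
#' overview k-means uses as reference.
#'
#' @slot classifications named list; each element is a named integer vector
#'   mapping sample name to group index (1-based).
#' @slot comparisons list of lists with elements `classification` (name),
#'   `groups` (integer vector, length >= 2) and `paired` (logical).
#' @slot organism scientific name, e.g. `"Mus musculus"`.
#' @slot referenceClassification classification used for overview k-means.
#' @name GroupDesign-class
#' @aliases GroupDesign
#' @exportClass GroupDesign
setClass("GroupDesign", representation(
    classifications = "list",
    comparisons = "list",
    organism = "character",
    referenceClassification = "character"))

setValidity("GroupDesign", function(object) {
    msg <- character()
    cls <- object@classifications
    if (!length(cls) || is.null(names(cls)))
        return("at least one named classification is required")
    for (nm in names(cls)) {
        v <- cls[[nm]]
        if (is.null(names(v)) || !is.numeric(v))
            msg <- c(msg, sprintf(
                "classification '%s' must be a named integer vector", nm))
        else if (any(v < 1))
            msg <- c(msg, sprintf("group indices in '%s' must be >= 1", nm))
    }
    for (cmp in object@comparisons) {
        if (!all(c("classification", "groups", "paired") %in% names(cmp))) {
            msg <- c(msg, "comparison missing a field")
            next
        }
        if (!cmp$classification %in% names(cls)) {
            msg <- c(msg, sprintf("comparison uses unknown classification '%s'",
                                  cmp$classification))
            next
        }
        have <- unique(cls[[cmp$classification]])
        bad <- setdiff(cmp$groups, have)
        if (length(bad))
            msg <- c(msg, sprintf(
                "comparison names group(s) %s absent from '%s'",
                paste(bad, collapse = ","), cmp$classification))
        if (isTRUE(cmp$paired)) {
            sizes <- table(cls[[cmp$classification]][
                cls[[cmp$classification]] %in% cmp$groups])
            if (length(unique(as.integer(sizes))) > 1L)
                msg <- c(msg, "paired comparison requires equal group sizes")
        }
    }
    if (length(object@referenceClassification) &&
        !object@referenceClassification %in% names(cls))
        msg <- c(msg, "referenceClassification not among classifications")
    if (length(msg)) msg else TRUE
})

#' Construct a GroupDesign
#'
#' @param classifications named list of named integer vectors (sample ->
#'   group index).
#' @param comparisons list of comparisons; each a list with
#'   `classification`, `groups` (integer vector) and `paired` flag.
#' @param organism scientific name.
#' @param referenceClassification name of the classification whose group
#'   count drives the overview k-means (defaults to the first).
#' @return a [GroupDesign-class] object.
#' @export
GroupDesign <- function(classifications, comparisons = list(),
                        organism = "other",
                        referenceClassification = names(classifications)[1]) {
    classifications <- lapply(classifications, function(v) {
        out <- as.integer(v); names(out) <- names(v); out
    })
    comparisons <- lapply(comparisons, function(cmp) {
        cmp$groups <- as.integer(cmp$groups)
        cmp$paired <- isTRUE(cmp$paired)
        cmp
    })
    new("GroupDesign", classifications = classifications,
        comparisons = comparisons, organism = organism,
        referenceClassification = referenceClassification)
}
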