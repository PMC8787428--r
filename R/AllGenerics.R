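#' @rdname PhosphoSet-accessors
#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @rdname PhosphoSet-accessors
#' @export
setGeneric("intensities<-",
           function(x, ..., value) standardGeneric("intensities<-"))

#' @rdname PhosphoSet-accessors
#' @export
setGeneric("siteInfo", function(x, ...) standardGeneric("siteInfo"))

#' @rdname PhosphoSet-accessors
#' @export
setGeneric("siteKeys", function(x, ...) standardGeneric("siteKeys"))

#' @rdname GroupDesign-accessors
#' @export
setGeneric("classifications", function(x) standardGeneric("classifications"))

#' @rdname GroupDesign-accessors
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))

#' @rdname GroupDesign-accessors
#' @export
setGeneric("organism", function(object) standardGeneric("organism"))

#' @rdname GroupDesign-accessors
#' @export
setGeneric("referenceClassification",
           function(x) standardGeneric("referenceClassification"))

#' Accessors for PhosphoSet
#'
#' `intensities()` returns (or replaces) the sites x samples intensity
#' matrix; `siteInfo()` the per-site metadata as a `data.frame`;
#' `siteKeys()` the canonical `accession;position;residue[;multiplicity]`
#' keys (see [siteKey()]).
#'
#' @param x a [PhosphoSet-class] (or [GroupDesign-class]) object.
#' @param object a [GroupDesign-class] object.
#' @param value replacement intensity matrix with matching dimensions.
#' @param ... unused.
#' @name PhosphoSet-accessors
NULL

#' @rdname PhosphoSet-accessors
#' @export
setMethod("intensities", "PhosphoSet", function(x, ...)
    assay(x, "intensity"))

#' @rdname PhosphoSet-accessors
#' @export
setReplaceMethod("intensities", "PhosphoSet", function(x, ..., value) {
    assay(x, "intensity") <- value
    validObject(x)
    x
})

#' @rdname PhosphoSet-accessors
#' @export
setMethod("siteInfo", "PhosphoSet", function(x, ...) {
    df <- as.data.frame(rowData(x))
    df$site_id <- rownames(x)
    df
})

#' @rdname PhosphoSet-accessors
#' @export
setMethod("siteKeys", "PhosphoSet", function(x, ...) {
    rd <- rowData(x)
    siteKey(rd$accession, rd$position, rd$residue, rd$multiplicity)
})

setMethod("show", "PhosphoSet", function(object) {
    x <- assay(object, "intensity")
    cat(sprintf("PhosphoSet: %d phosphosites x %d samples\n",
                nrow(object), ncol(object)))
    cat(sprintf("  proteins: %d | missing: %.1f%% | multiplicity-expanded: %s\n",
                length(unique(rowData(object)$accession)),
                100 * mean(is.na(x)),
                if (any(rowData(object)$multiplicity > 0L)) "yes" else "no"))
    if (ncol(object))
        cat("  samples:", paste(utils::head(colnames(object), 6L),
                                collapse = ", "),
            if (ncol(object) > 6L) "..." else "", "\n")
})

#' Accessors for GroupDesign
#'
#' @param x,object a [GroupDesign-class].
#' @name GroupDesign-accessors
NULL

#' @rdname GroupDesign-accessors
#' @export
setMethod("classifications", "GroupDesign", function(x) x@classifications)

#' @rdname GroupDesign-accessors
#' @export
setMethod("comparisons", "GroupDesign", function(x) x@comparisons)

#' @rdname GroupDesign-accessors
#' @export
setMethod("organism", "GroupDesign", function(object) object@organism)

#' @rdname GroupDesign-accessors
#' @export
setMethod("referenceClassification", "GroupDesign",
          function(x) x@referenceClassification)

setMethod("show", "GroupDesign", function(object) {
    cat(sprintf("GroupDesign (%s): %d classification(s), %d comparison(s)\n",
                object@organism, length(object@classifications),
                length(object@comparisons)))
    for (nm in names(object@classifications)) {
        v <- object@classifications[[nm]]
        cat(sprintf("  %s: %d samples in %d groups%s\n", nm, length(v),
                    length(unique(v)),
                    if (identical(nm, object@referenceClassification))
                        " [reference]" else ""))
    }
})

#' Samples belonging to one group of a classification
#'
#' @param design a [GroupDesign-class].
#' @param classification classification name.
#' @param group group index.
#' @return character vector of sample names, in classification order.
#' @export
groupSamples <- function(design, classification, group) {
    v <- classifications(design)[[classification]]
    if (is.null(v)) stop("unknown classification '", classification, "'")
    names(v)[v == group]
}
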