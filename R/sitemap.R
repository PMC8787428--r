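## Phosphosite coordinate translation across accessions/species via global
## pairwise alignment. Databases hosting site annotations key on reviewed
## (Swiss-Prot) accessions; measured data often carry unreviewed or
## non-human accessions. Aligning the two sequences lets every site be
## expressed in the coordinates of its reviewed/ortholog counterpart.

validAAPattern <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Global pairwise protein alignment with coordinate map
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a length-L
#' gap costs `gapOpen + L * gapExtend`), via
#' [Biostrings::pairwiseAlignment()]. Returns the gapped strings, the
#' identity score (matches / alignment length, gap columns included) and a
#' strictly increasing query-to-target coordinate map with `NA` at
#' positions aligned to gaps.
#'
#' @param seqA,seqB amino-acid sequences (20-letter alphabet plus X).
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   BLOSUM62).
#' @param gapOpen,gapExtend affine gap parameters (positive costs).
#' @return list of class `"AlignmentMap"`: `alignedA`, `alignedB`, `score`,
#'   `identity`, `map` (integer vector over query positions), `rmap` (the
#'   inverse map over target positions).
#' @export
globalAlign <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5) {
    for (s in c(seqA, seqB)) {
        if (!nzchar(s)) stop("empty sequence")
        if (!grepl(validAAPattern, s))
            stop("non-amino-acid character in sequence")
    }
    if (is.character(substitutionMatrix)) {
        e <- new.env()
        utils::data(list = substitutionMatrix, package = "Biostrings",
                    envir = e)
        substitutionMatrix <- get(substitutionMatrix, envir = e)
    }
    pa <- Biostrings::pairwiseAlignment(
        seqA, seqB, type = "global",
        substitutionMatrix = substitutionMatrix,
        gapOpening = gapOpen, gapExtension = gapExtend)
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    map <- rep(NA_integer_, nchar(seqA))
    rmap <- rep(NA_integer_, nchar(seqB))
    ia <- 0L; ib <- 0L
    for (j in seq_along(ca)) {
        ga <- ca[j] == "-"; gb <- cb[j] == "-"
        if (!ga) ia <- ia + 1L
        if (!gb) ib <- ib + 1L
        if (!ga && !gb) { map[ia] <- ib; rmap[ib] <- ia }
    }
    structure(list(alignedA = a, alignedB = b,
                   score = Biostrings::score(pa),
                   identity = sum(ca == cb & ca != "-") / length(ca),
                   map = map, rmap = rmap),
              class = "AlignmentMap")
}

#' Map one site position through an alignment
#'
#' @param alignment an `"AlignmentMap"` from [globalAlign()].
#' @param position 1-based query position.
#' @return list: `query_position`, `query_residue`, `target_position` (`NA`
#'   when the query residue aligns to a gap), `target_residue` and
#'   `conservation` — `"exact"` (same residue), `"phospho_compatible"`
#'   (target is S/T/Y), `"mismatch"`, or `"unmapped"`.
#' @export
mapSite <- function(alignment, position) {
    if (position < 1L || position > length(alignment$map))
        stop("position out of range")
    qseq <- gsub("-", "", alignment$alignedA)
    tseq <- gsub("-", "", alignment$alignedB)
    qres <- substr(qseq, position, position)
    tpos <- alignment$map[position]
    if (is.na(tpos))
        return(list(query_position = position, query_residue = qres,
                    target_position = NA_integer_,
                    target_residue = NA_character_,
                    conservation = "unmapped"))
    tres <- substr(tseq, tpos, tpos)
    cons <- if (tres == qres) "exact"
        else if (tres %in% c("S", "T", "Y")) "phospho_compatible"
        else "mismatch"
    list(query_position = position, query_residue = qres,
         target_position = tpos, target_residue = tres,
         conservation = cons)
}

## 15-mer window around pos on seq, '_'-padded beyond the termini
extractWindow <- function(seq, pos) {
    n <- nchar(seq)
    idx <- (pos - 7L):(pos + 7L)
    chars <- ifelse(idx < 1L | idx > n, WINDOW_PAD,
                    substring(seq, idx, idx))
    paste(chars, collapse = "")
}

#' Translate all sites of a table to target accessions
#'
#' Aligns each query accession's sequence to its paired target sequence
#' (alignments cached per accession pair) and maps every phosphosite,
#' reporting the alignment identity so low-identity mappings can be treated
#' with caution. Sites whose accession lacks a pairing or a sequence are
#' emitted as unmapped with a reason. The target-side 15-mer window is
#' recomputed from the target sequence so mapped sites can feed kinase
#' scoring directly.
#'
#' @param x a [PhosphoSet-class] (or a `siteInfo`-shaped data.frame).
#' @param seqDb named character vector of protein sequences, an
#'   `AAStringSet`, or a FASTA file path.
#' @param pairing data.frame with columns `query_acc`, `target_acc`.
#' @param ... passed to [globalAlign()].
#' @return data.frame with one row per site: query identity columns, target
#'   accession/position/residue/window, `conservation`, `identity`,
#'   `reason`.
#' @export
translateSites <- function(x, seqDb, pairing, ...) {
    info <- if (is(x, "PhosphoSet")) siteInfo(x) else x
    if (is.character(seqDb) && length(seqDb) == 1L && file.exists(seqDb))
        seqDb <- Biostrings::readAAStringSet(seqDb)
    if (is(seqDb, "XStringSet")) {
        nm <- sub("\\s.*", "", names(seqDb))
        seqDb <- stats::setNames(as.character(seqDb), nm)
    }
    tgt <- stats::setNames(as.character(pairing$target_acc),
                           pairing$query_acc)
    cache <- new.env()
    out <- vector("list", nrow(info))
    for (i in seq_len(nrow(info))) {
        acc <- info$accession[i]
        base <- list(site_id = info$site_id[i], accession = acc,
                     position = info$position[i], residue = info$residue[i],
                     target_accession = NA_character_,
                     target_position = NA_integer_,
                     target_residue = NA_character_,
                     target_window = NA_character_,
                     conservation = "unmapped", identity = NA_real_,
                     reason = "")
        ta <- tgt[acc]
        if (is.na(ta)) { base$reason <- "no pairing"; out[[i]] <- base; next }
        if (is.na(seqDb[acc]) || is.na(seqDb[ta])) {
            base$reason <- "no sequence"; out[[i]] <- base; next
        }
        aln <- cache[[paste(acc, ta)]]
        if (is.null(aln)) {
            aln <- globalAlign(seqDb[[acc]], seqDb[[ta]], ...)
            cache[[paste(acc, ta)]] <- aln
        }
        base$target_accession <- ta
        base$identity <- aln$identity
        if (info$position[i] > nchar(seqDb[[acc]])) {
            base$reason <- "position beyond sequence"; out[[i]] <- base; next
        }
        ms <- mapSite(aln, info$position[i])
        base$target_position <- ms$target_position
        base$target_residue <- ms$target_residue
        base$conservation <- ms$conservation
        if (!is.na(ms$target_position))
            base$target_window <- extractWindow(seqDb[[ta]],
                                                ms$target_position)
        else base$reason <- "aligned to gap"
        out[[i]] <- base
    }
    do.call(rbind, lapply(out, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
}
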