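## Protein-level over-representation analysis and site-level signed
## signature enrichment.

#' Over-representation analysis (hypergeometric)
#'
#' Upper-tail hypergeometric test of each gene/protein set against a stated
#' background. The pipeline runs it twice per significant list: once with a
#' universal background (e.g. all annotated proteins) and once with the
#' dataset background (all measured proteins).
#'
#' @param significant character vector of significant identifiers;
#'   identifiers outside the background are dropped with a warning.
#' @param background character vector: the background universe.
#' @param sets named list of identifier sets (e.g. from [readGMT()]).
#' @param minOverlap minimum overlap for a set to count as reportable.
#' @return data.frame per set: `set`, `N` (background size), `K` (set size
#'   within background), `n` (draw size), `k` (overlap), `p`
#'   (`P(X >= k)`), `fdr` (BH across sets), `significant` (`k >=
#'   minOverlap & fdr <= 0.05`), `members` (semicolon-joined overlap).
#' @export
oraTest <- function(significant, background, sets, minOverlap = 1L) {
    background <- unique(background)
    if (!length(background)) stop("empty background")
    significant <- unique(significant)
    outside <- setdiff(significant, background)
    if (length(outside)) {
        warning(length(outside),
                " significant id(s) outside the background dropped")
        significant <- intersect(significant, background)
    }
    N <- length(background); n <- length(significant)
    rows <- lapply(names(sets), function(nm) {
        inBg <- intersect(unique(sets[[nm]]), background)
        K <- length(inBg)
        hit <- intersect(inBg, significant)
        k <- length(hit)
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
                   members = paste(sort(hit), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p)
    out$significant <- out$k >= minOverlap & out$fdr <= 0.05
    out[order(out$p, out$set),
        c("set", "N", "K", "n", "k", "p", "fdr", "significant", "members")]
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (one named set per line: name, description,
#'   members).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Read a direction-tagged phosphosite signature file
#'
#' GMT-dialect file whose members are site keys suffixed with `;u` or `;d`
#' (`accession;position;residue;u`), marking the direction of
#' phosphorylation change the signature's perturbation induces. Duplicate
#' site keys within a signature keep their first occurrence.
#'
#' @param path signature file path.
#' @return named list; each element a data.frame with `site` and
#'   `direction` (`"u"`/`"d"`).
#' @export
readSignatures <- function(path) {
    raw <- readGMT(path)
    lapply(raw, function(members) {
        dir <- sub(".*;", "", members)
        if (!all(dir %in% c("u", "d")))
            stop("signature member without ;u/;d direction tag")
        site <- sub(";[ud]$", "", members)
        keep <- !duplicated(site)
        if (any(!keep))
            warning("duplicate site key(s) in a signature; first kept")
        data.frame(site = site[keep], direction = dir[keep],
                   stringsAsFactors = FALSE)
    })
}

## Weighted KS enrichment score of a member set inside a ranked list.
## absW: |stat|^weight in ranked order; pos: member positions (ranked
## coordinates). Hits climb by their weight share, misses fall by
## 1/(N - nHits); the ES is the signed extremum of the running sum.
wksES <- function(absW, pos) {
    N <- length(absW)
    m <- length(pos)
    if (m == 0L || m >= N) return(NA_real_)
    pos <- sort(pos)
    hw <- absW[pos]
    tot <- sum(hw)
    if (tot == 0) hw <- rep(1 / m, m) else hw <- hw / tot
    miss <- 1 / (N - m)
    H <- cumsum(hw)
    j <- seq_len(m)
    atHit <- H - (pos - j) * miss                 # just after each hit
    beforeNext <- H - (c(pos[-1], N + 1L) - 1L - j) * miss  # deepest after
    cand <- c(atHit, beforeNext, 0)
    cand[which.max(abs(cand))]
}

#' Site-level signed signature enrichment
#'
#' Scores each direction-tagged signature against the full dataset's signed
#' site statistic using a weighted Kolmogorov-Smirnov running sum: the
#' signature's `u` members are scored on the list ranked by the statistic
#' descending, its `d` members on the list ranked by the negated statistic
#' (equivalently, `d` members have their statistic negated before ranking),
#' and the two subset scores are combined by matched-member-count
#' weighting. This per-subset form makes the score exactly invariant to
#' negating every statistic while swapping all `u`/`d` tags. Hit increments
#' are `|s|^weight` shares; misses decrement by `1/(N - |hits|)`.
#' Significance and normalization come from `nPerm` permutations of the
#' site labels, sign-stratified as in standard GSEA practice.
#'
#' @param siteStat named numeric vector: signed statistic per site key for
#'   the entire dataset (e.g. `sign(log2fc) * -log10(p)`).
#' @param signatures named list from [readSignatures()].
#' @param weight hit-weight exponent (0 = unweighted KS).
#' @param nPerm permutations (warning below 100).
#' @param seed RNG seed.
#' @return data.frame per scored signature: `signature`, `n_u`, `n_d`
#'   (matched member counts), `ES`, `NES`, `p`, `fdr`, `pct_up`,
#'   `pct_down` (percentage of matched members observed up-/
#'   down-regulated). Signatures with no matched member are skipped and
#'   listed in attribute `"skipped"`.
#' @export
ptmSEA <- function(siteStat, signatures, weight = 1, nPerm = 1000L,
                   seed = 1L) {
    if (nPerm < 100L) warning("nPerm < 100 gives unstable p-values")
    siteStat <- siteStat[!is.na(siteStat)]
    N <- length(siteStat)
    ordUp <- order(siteStat, decreasing = TRUE)
    ordDn <- order(-siteStat, decreasing = TRUE)
    rankUp <- integer(N); rankUp[ordUp] <- seq_len(N)
    rankDn <- integer(N); rankDn[ordDn] <- seq_len(N)
    wUp <- abs(siteStat[ordUp])^weight
    wDn <- abs(siteStat[ordDn])^weight
    keys <- names(siteStat)

    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)

    combES <- function(posU, posD) {
        nu <- length(posU); nd <- length(posD)
        esU <- if (nu) wksES(wUp, posU) else NA_real_
        esD <- if (nd) wksES(wDn, posD) else NA_real_
        if (nu && nd) (nu * esU + nd * esD) / (nu + nd)
        else if (nu) esU else esD
    }

    skipped <- character()
    rows <- list()
    for (nm in names(signatures)) {
        sig <- signatures[[nm]]
        iu <- match(sig$site[sig$direction == "u"], keys)
        id <- match(sig$site[sig$direction == "d"], keys)
        iu <- iu[!is.na(iu)]; id <- id[!is.na(id)]
        nu <- length(iu); nd <- length(id)
        if (nu + nd == 0L || nu + nd >= N) { skipped <- c(skipped, nm); next }
        es <- combES(rankUp[iu], rankDn[id])
        nullES <- vapply(seq_len(nPerm), function(i) {
            idx <- sample.int(N, nu + nd)
            combES(rankUp[idx[seq_len(nu)]],
                   rankDn[idx[nu + seq_len(nd)]])
        }, numeric(1))
        same <- if (es >= 0) nullES[nullES >= 0] else -nullES[nullES < 0]
        absES <- abs(es)
        p <- (1 + sum(same >= absES)) / (1 + length(same))
        nes <- if (length(same)) es / mean(same) else NA_real_
        memberStat <- c(siteStat[iu], -siteStat[id])  # tag-adjusted
        obsUp <- c(siteStat[iu] > 0, siteStat[id] > 0)
        rows[[nm]] <- data.frame(
            signature = nm, n_u = nu, n_d = nd, ES = es, NES = nes, p = p,
            pct_up = 100 * sum(obsUp) / (nu + nd),
            pct_down = 100 * sum(!obsUp) / (nu + nd),
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
        out <- data.frame(signature = character(), n_u = integer(),
                          n_d = integer(), ES = numeric(), NES = numeric(),
                          p = numeric(), fdr = numeric(), pct_up = numeric(),
                          pct_down = numeric(), stringsAsFactors = FALSE)
        attr(out, "skipped") <- skipped
        return(out)
    }
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p)
    rownames(out) <- NULL
    out <- out[, c("signature", "n_u", "n_d", "ES", "NES", "p", "fdr",
                   "pct_up", "pct_down")]
    attr(out, "skipped") <- skipped
    out
}
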