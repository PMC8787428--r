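## Rank product test.
##
## For a two-group comparison, fold changes are computed per sample pair —
## all between-group pairs when unpaired, matched pairs when paired.
## Within each pair the sites are ranked (rank 1 = most up for the
## up-regulation statistic, most down for the down-regulation one) and the
## rank product is the geometric mean of a site's ranks across pairs;
## small values indicate consistent regulation.
##
## Significance comes from a permutation null that shuffles site labels
## within every sample independently and recomputes the rank matrix. When
## the pair columns are independent (paired designs) this null is exactly
## the classical "independent uniform ranks" null; for all-pairs unpaired
## designs it additionally preserves the correlation among pairs that
## share a sample, which the iid-rank null ignores (making that null
## anti-conservative). p-values are pooled across sites with the +1
## correction.

pairIndices <- function(groups, paired) {
    i1 <- which(groups == 1L); i2 <- which(groups == 2L)
    if (!length(i1) || !length(i2)) stop("both groups need samples")
    if (paired) {
        if (length(i1) != length(i2))
            stop("paired comparison requires equal group sizes")
        cbind(a = i2, b = i1)
    } else as.matrix(expand.grid(a = i2, b = i1))
}

pairRankMatrices <- function(m, pairs) {
    fc <- m[, pairs[, "a"], drop = FALSE] - m[, pairs[, "b"], drop = FALSE]
    list(up = apply(fc, 2, function(v) rank(-v, na.last = "keep")),
         down = apply(fc, 2, function(v) rank(v, na.last = "keep")))
}

rankProductFromRanks <- function(R) {
    R <- as.matrix(R)
    nObs <- rowSums(!is.na(R))
    out <- exp(rowSums(log(R), na.rm = TRUE) / nObs)
    out[nObs == 0L] <- NA_real_
    out
}

#' Rank product test
#'
#' @param m log2-scale intensity matrix (sites x samples).
#' @param groups integer vector (1/2) assigning columns to groups; "up"
#'   means up in group 2 (the higher-numbered group).
#' @param nperm number of permutations (>= 1; a warning is issued below
#'   100).
#' @param seed RNG seed.
#' @param paired use matched pairs (i-th sample of each group) instead of
#'   all between-group pairs.
#' @return list with `rp_up`, `rp_down` (rank products), `p_up`, `p_down`
#'   (pooled permutation tail probabilities with the +1 correction),
#'   `pfp_up`, `pfp_down` (percentage-false-prediction estimates) and
#'   `n_pairs`.
#' @export
rankProductTest <- function(m, groups, nperm = 1000L, seed = 1L,
                            paired = FALSE) {
    if (nperm < 1L) stop("nperm must be >= 1")
    if (nperm < 100L) warning("nperm < 100 gives unstable p-values")
    pairs <- pairIndices(groups, paired)
    nSites <- nrow(m)
    obs <- pairRankMatrices(m, pairs)
    rpUp <- rankProductFromRanks(obs$up)
    rpDown <- rankProductFromRanks(obs$down)

    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    used <- sort(unique(as.vector(pairs)))
    nullUp <- numeric(nperm * nSites)
    nullDown <- numeric(nperm * nSites)
    for (r in seq_len(nperm)) {
        perm <- m
        for (j in used) perm[, j] <- m[sample.int(nSites), j]
        R <- pairRankMatrices(perm, pairs)
        at <- ((r - 1L) * nSites + 1L):(r * nSites)
        nullUp[at] <- rankProductFromRanks(R$up)
        nullDown[at] <- rankProductFromRanks(R$down)
    }
    pTail <- function(rp, nullRP) {
        ns <- sort(nullRP[!is.na(nullRP)])
        N <- length(ns)
        p <- rep(NA_real_, length(rp))
        ok <- !is.na(rp)
        ## left tail: count of null rank products <= observed (ties count)
        cntLE <- findInterval(rp[ok] + 1e-9 * pmax(rp[ok], 1), ns)
        p[ok] <- (1 + cntLE) / (1 + N)
        p
    }
    pUp <- pTail(rpUp, nullUp); pDown <- pTail(rpDown, nullDown)
    pfp <- function(p, rp) {
        r <- rank(rp, na.last = "keep")
        p * sum(!is.na(rp)) / r
    }
    list(rp_up = rpUp, rp_down = rpDown, p_up = pUp, p_down = pDown,
         pfp_up = pfp(pUp, rpUp), pfp_down = pfp(pDown, rpDown),
         n_pairs = nrow(pairs))
}

#' Exact null tail probability of a rank product
#'
#' Enumerates all `nSites^nPairs` equally likely tuples of independent
#' uniform ranks and returns the probability that their geometric mean is
#' at most `rp`. This is the exact null when the pair columns are
#' independent (e.g. paired designs); tractable only for tiny instances,
#' it serves as an independent check of the permutation p-values.
#'
#' @param rp observed rank product.
#' @param nSites number of sites (ranks run 1..nSites per pair).
#' @param nPairs number of pair columns.
#' @return exact tail probability.
#' @export
rankProductExactP <- function(rp, nSites, nPairs) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(nSites)), nPairs)))
    vals <- exp(rowMeans(log(grid)))
    mean(vals <= rp + 1e-9)
}
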