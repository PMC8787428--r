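## Reproducibility-optimized test statistic (ROTS-style).
##
## The statistic family is d = |m1 - m2| / (a1 + a2 * s), where s is the
## pooled standard error of the mean difference. The stabilization pair
## (a1, a2) is selected by maximizing the bootstrap reproducibility z-score
## of top-k site lists against a group-label-permuted null, then p-values
## come from a label permutation of the selected statistic, pooled across
## sites for resolution.

rotsStat <- function(m, idx1, idx2) {
    x1 <- m[, idx1, drop = FALSE]; x2 <- m[, idx2, drop = FALSE]
    n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
    m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
    v1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
    v2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
    sp2 <- (v1 + v2) / pmax(n1 + n2 - 2, 1)
    s <- sqrt(sp2 * (1 / pmax(n1, 1) + 1 / pmax(n2, 1)))
    d <- abs(m1 - m2)
    d[n1 < 2 | n2 < 2] <- NA_real_
    list(d = d, s = s)
}

## Statistic matrix over the candidate grid: first column is the a2 = 0
## family (all a1 > 0 give the same ranking), remaining columns a2 = 1 with
## a1 along aGrid (a1 = 0 is the ordinary t point).
rotsStatMatrix <- function(ds, aGrid) {
    D <- cbind(ds$d, vapply(aGrid, function(a) ds$d / (a + ds$s),
                            numeric(length(ds$d))))
    D[!is.finite(D)] <- 0
    D
}

rotsOverlaps <- function(D1, D2, K) {
    m <- nrow(D1)
    out <- matrix(0, ncol(D1), length(K))
    for (j in seq_len(ncol(D1))) {
        r1 <- integer(m); r1[order(D1[, j], decreasing = TRUE)] <- seq_len(m)
        r2 <- integer(m); r2[order(D2[, j], decreasing = TRUE)] <- seq_len(m)
        for (ki in seq_along(K))
            out[j, ki] <- sum(r1 <= K[ki] & r2 <= K[ki]) / K[ki]
    }
    out
}

#' Reproducibility-optimized two-group test
#'
#' @param m log2-scale intensity matrix (sites x samples).
#' @param groups integer vector (values 1 and 2) assigning each column to a
#'   group; group 2 is the higher-numbered (numerator) group.
#' @param B number of bootstrap pairs used to measure top-list
#'   reproducibility.
#' @param K top-list sizes; default a log-spaced grid up to half the number
#'   of sites (capped at 2000).
#' @param aGrid grid of a1 candidates for the a2 = 1 family; the a2 = 0
#'   (fold-change-ranking) family and the ordinary-t point (a1 = 0) are
#'   always included.
#' @param nperm label permutations for the p-value.
#' @param seed RNG seed.
#' @return list: `d` (selected statistic per site), `p`, `fdr`, `a1`, `a2`,
#'   `z` (the winning reproducibility z-score), `k` (the winning top-list
#'   size).
#' @export
rotsTest <- function(m, groups, B = 100L, K = NULL,
                     aGrid = seq(0, 5, by = 0.01), nperm = 1000L, seed = 1L) {
    if (B < 2L) stop("B must be >= 2")
    idx1 <- which(groups == 1L); idx2 <- which(groups == 2L)
    if (length(idx1) < 2L || length(idx2) < 2L)
        stop("need >= 2 samples per group")
    nSites <- nrow(m)
    if (is.null(K)) {
        kmax <- min(nSites %/% 2L, 2000L)
        K <- unique(pmin(kmax, c(5L, 10L, 25L, 50L, 100L, 250L, 500L,
                                 1000L, 2000L)))
        K <- K[K >= 1L]
    }
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)

    nA <- length(aGrid) + 1L
    obsSum <- matrix(0, nA, length(K))
    nullArr <- array(0, c(B, nA, length(K)))
    boot <- function(ix) ix[sample.int(length(ix), replace = TRUE)]
    for (b in seq_len(B)) {
        D1 <- rotsStatMatrix(rotsStat(m, boot(idx1), boot(idx2)), aGrid)
        D2 <- rotsStatMatrix(rotsStat(m, boot(idx1), boot(idx2)), aGrid)
        obsSum <- obsSum + rotsOverlaps(D1, D2, K)
        lab <- sample(groups)
        p1 <- which(lab == 1L); p2 <- which(lab == 2L)
        N1 <- rotsStatMatrix(rotsStat(m, boot(p1), boot(p2)), aGrid)
        N2 <- rotsStatMatrix(rotsStat(m, boot(p1), boot(p2)), aGrid)
        nullArr[b, , ] <- rotsOverlaps(N1, N2, K)
    }
    R <- obsSum / B
    R0 <- apply(nullArr, c(2, 3), mean)
    S0 <- apply(nullArr, c(2, 3), stats::sd)
    Z <- (R - R0) / pmax(S0, 1e-8)
    best <- which(Z == max(Z), arr.ind = TRUE)[1, ]
    a1 <- if (best[1] == 1L) 1 else aGrid[best[1] - 1L]
    a2 <- if (best[1] == 1L) 0 else 1

    ds <- rotsStat(m, idx1, idx2)
    d <- ds$d / (a1 + a2 * ds$s)
    d[!is.finite(d)] <- 0

    nullD <- numeric(nperm * nSites)
    for (r in seq_len(nperm)) {
        lab <- sample(groups)
        dn <- rotsStat(m, which(lab == 1L), which(lab == 2L))
        v <- dn$d / (a1 + a2 * dn$s)
        v[!is.finite(v)] <- 0
        nullD[((r - 1L) * nSites + 1L):(r * nSites)] <- v
    }
    ns <- sort(nullD)
    N <- length(ns)
    ## count of null values >= d (equal values count; tiny downward nudge)
    cntGE <- N - findInterval(d - 1e-12 * pmax(abs(d), 1), ns)
    p <- (1 + cntGE) / (1 + N)
    list(d = d, p = p, fdr = bhAdjust(p), a1 = a1, a2 = a2,
         z = max(Z), k = K[best[2]])
}
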