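## Two-group and multi-group differential statistics.
##
## Sign convention for fold changes: within a comparison the group with the
## LARGER group number is the numerator, so a positive log2 fold change means
## "up in the higher-numbered group".

#' Per-site log2 fold change
#'
#' `log2(mean(higher-numbered group) / mean(lower-numbered group))`, means
#' taken over observed raw-scale intensities. A site with no observed value
#' in either group gets `NA`.
#'
#' @param m raw-scale intensity matrix.
#' @param lowerSamples,higherSamples column names of the lower- and
#'   higher-numbered group.
#' @return numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(m, lowerSamples, higherSamples) {
    lo <- rowMeans(m[, lowerSamples, drop = FALSE], na.rm = TRUE)
    hi <- rowMeans(m[, higherSamples, drop = FALSE], na.rm = TRUE)
    fc <- log2(hi / lo)
    fc[is.nan(fc)] <- NA_real_
    fc
}

welchP <- function(x, y, paired = FALSE, varEqual = FALSE) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (paired) stop("use pairedTP for paired data")
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) return(NA_real_)
    d <- mean(x) - mean(y)
    v1 <- stats::var(x); v2 <- stats::var(y)
    if (varEqual) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2)); df <- n1 + n2 - 2
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    }
    if (!is.finite(se) || se == 0) return(if (d == 0) 1 else 0)
    2 * stats::pt(-abs(d / se), df)
}

pairedTP <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    d <- x[ok] - y[ok]
    if (length(d) < 2L) return(NA_real_)
    se <- stats::sd(d) / sqrt(length(d))
    if (!is.finite(se) || se == 0) return(if (mean(d) == 0) 1 else 0)
    2 * stats::pt(-abs(mean(d) / se), length(d) - 1)
}

wilcoxP <- function(x, y, paired = FALSE) {
    if (paired) {
        ok <- !is.na(x) & !is.na(y)
        x <- x[ok]; y <- y[ok]
        if (length(x) < 1L || all(x == y)) return(if (length(x)) 1 else NA_real_)
        ex <- length(x) <= 25L
        p <- tryCatch(suppressWarnings(
            stats::wilcox.test(x, y, paired = TRUE, exact = ex,
                               correct = TRUE)$p.value),
            error = function(e) NA_real_)
    } else {
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) return(NA_real_)
        ex <- max(length(x), length(y)) <= 25L
        p <- tryCatch(suppressWarnings(
            stats::wilcox.test(x, y, exact = ex, correct = TRUE)$p.value),
            error = function(e) NA_real_)
    }
    p
}

#' Row-wise two-group tests
#'
#' Two-sided p-values per site. `"t"` is Welch's t (Student's with
#' `varEqual = TRUE`) unpaired, or the paired t; `"wilcoxon"` is the
#' rank-sum test unpaired and the signed-rank test paired, exact for small
#' samples (`<= 25` per group, no ties) and a continuity-corrected normal
#' approximation otherwise. Sites without enough observations yield `NA`.
#'
#' @param m log2-scale intensity matrix.
#' @param lowerSamples,higherSamples group sample names; for paired tests
#'   the i-th samples of each vector form a pair.
#' @param test `"t"` or `"wilcoxon"`.
#' @param paired logical.
#' @param varEqual use the pooled-variance Student t instead of Welch.
#' @return numeric vector of p-values.
#' @export
twoGroupTest <- function(m, lowerSamples, higherSamples,
                         test = c("t", "wilcoxon"), paired = FALSE,
                         varEqual = FALSE) {
    test <- match.arg(test)
    if (paired && length(lowerSamples) != length(higherSamples))
        stop("paired comparison requires equal group sizes")
    X <- m[, higherSamples, drop = FALSE]
    Y <- m[, lowerSamples, drop = FALSE]
    vapply(seq_len(nrow(m)), function(i) {
        if (test == "t") {
            if (paired) pairedTP(X[i, ], Y[i, ])
            else welchP(X[i, ], Y[i, ], varEqual = varEqual)
        } else wilcoxP(X[i, ], Y[i, ], paired = paired)
    }, numeric(1))
}

#' Row-wise multi-group tests with post hoc pairwise comparisons
#'
#' Unpaired: one-way ANOVA with Tukey HSD pairwise p-values. Paired:
#' repeated-measures ANOVA with a subject blocking factor (the exact linear
#' mixed-model equivalent under compound symmetry) and Tukey HSD on the
#' within-subject error term; the i-th samples of every group are assumed to
#' come from the same subject.
#'
#' @param m log2-scale intensity matrix.
#' @param sampleGroups named integer vector, sample -> group index, for the
#'   groups in the comparison.
#' @param paired logical.
#' @return list: `p` (overall p per site) and `pairwise` (sites x
#'   group-pair matrix of Tukey-adjusted p-values).
#' @export
multiGroupTest <- function(m, sampleGroups, paired = FALSE) {
    samples <- names(sampleGroups)
    grp <- factor(sampleGroups)
    if (nlevels(grp) < 2L) stop("need at least two groups")
    subj <- factor(stats::ave(seq_along(grp), grp, FUN = seq_along))
    if (paired && length(unique(table(grp))) > 1L)
        stop("paired comparison requires equal group sizes")
    lv <- levels(grp)
    pairNames <- utils::combn(rev(lv), 2L, function(ab)
        paste(ab[1], ab[2], sep = "-"))
    pw <- matrix(NA_real_, nrow(m), length(pairNames),
                 dimnames = list(rownames(m), pairNames))
    pOverall <- rep(NA_real_, nrow(m))
    sub <- m[, samples, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
        v <- sub[i, ]
        ok <- !is.na(v)
        if (paired) {
            keepSubj <- names(which(tapply(ok, subj, all)))
            ok <- ok & subj %in% keepSubj
        }
        if (any(table(grp[ok]) < 2L) || length(unique(grp[ok])) < 2L) next
        df <- data.frame(value = v[ok], group = droplevels(grp[ok]),
                         subject = droplevels(subj[ok]))
        if (stats::var(df$value) == 0) {   # no variation at all: F = 0
            pOverall[i] <- 1
            pw[i, ] <- 1
            next
        }
        fit <- if (paired) stats::aov(value ~ subject + group, data = df)
        else stats::aov(value ~ group, data = df)
        tab <- summary(fit)[[1]]
        p <- tab[match("group", trimws(rownames(tab))), "Pr(>F)"]
        if (is.na(p) && stats::var(df$value) == 0) p <- 1
        pOverall[i] <- p
        tk <- tryCatch(stats::TukeyHSD(fit, "group")$group,
                       error = function(e) NULL)
        if (!is.null(tk)) {
            idx <- match(rownames(tk), pairNames)
            swap <- is.na(idx)
            if (any(swap)) {
                parts <- strsplit(rownames(tk)[swap], "-")
                idx[swap] <- match(vapply(parts, function(ab)
                    paste(ab[2], ab[1], sep = "-"), character(1)), pairNames)
            }
            pw[i, idx[!is.na(idx)]] <- tk[!is.na(idx), "p adj"]
        }
    }
    list(p = pOverall, pairwise = pw)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH FDR; missing p-values are excluded from the family size and
#' returned as missing.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Run all requested tests for one comparison
#'
#' Orchestrates fold change and the chosen tests for a two-group comparison
#' (or overall + pairwise statistics for a multi-group one) and attaches BH
#' FDRs per test family.
#'
#' @param x a (preprocessed) [PhosphoSet-class].
#' @param design a [GroupDesign-class].
#' @param comparison index into `comparisons(design)`.
#' @param tests subset of `"t"`, `"wilcoxon"`, `"rots"`, `"rankprod"`
#'   (two-group only).
#' @param seed RNG seed for the resampling-based tests.
#' @param rotsB,rotsNperm,rankprodNperm resampling sizes.
#' @param varEqual use Student rather than Welch t.
#' @return a `data.frame` ("StatResult"): `site_id`, `log2fc`, one `p_*` and
#'   `fdr_*` column per test; for multi-group comparisons `p_overall`,
#'   `fdr_overall` and Tukey-adjusted `p_<i>.vs.<j>` columns. The comparison
#'   definition is attached as attribute `"comparison"`.
#' @export
compareGroups <- function(x, design, comparison = 1L,
                          tests = c("t", "wilcoxon"), seed = 1L,
                          rotsB = 100L, rotsNperm = 1000L,
                          rankprodNperm = 1000L, varEqual = FALSE) {
    cmp <- comparisons(design)[[comparison]]
    if (is.null(cmp)) stop("no such comparison")
    cls <- classifications(design)[[cmp$classification]]
    lg <- intensities(x)
    raw <- metadata(x)$raw_intensity
    if (isTRUE(metadata(x)$log2)) {
        if (is.null(raw)) raw <- 2^lg
    } else {
        raw <- lg; lg <- log2(lg)
    }
    res <- data.frame(site_id = rownames(x), stringsAsFactors = FALSE)
    if (length(cmp$groups) == 2L) {
        gLo <- min(cmp$groups); gHi <- max(cmp$groups)
        sLo <- groupSamples(design, cmp$classification, gLo)
        sHi <- groupSamples(design, cmp$classification, gHi)
        res$log2fc <- log2FoldChange(raw, sLo, sHi)
        grp <- c(rep(1L, length(sLo)), rep(2L, length(sHi)))
        sub <- lg[, c(sLo, sHi), drop = FALSE]
        for (tst in tests) {
            p <- switch(tst,
                t = twoGroupTest(lg, sLo, sHi, "t", paired = cmp$paired,
                                 varEqual = varEqual),
                wilcoxon = twoGroupTest(lg, sLo, sHi, "wilcoxon",
                                        paired = cmp$paired),
                rots = rotsTest(sub, grp, B = rotsB, nperm = rotsNperm,
                                seed = seed)$p,
                rankprod = NULL)
            if (tst == "rankprod") {
                rp <- rankProductTest(sub, grp, nperm = rankprodNperm,
                                      seed = seed, paired = cmp$paired)
                res$p_rankprod_up <- rp$p_up
                res$p_rankprod_down <- rp$p_down
                p <- pmin(1, 2 * pmin(rp$p_up, rp$p_down))
            }
            res[[paste0("p_", tst)]] <- p
            res[[paste0("fdr_", tst)]] <- bhAdjust(p)
        }
    } else {
        mg <- multiGroupTest(lg, cls[cls %in% cmp$groups],
                             paired = cmp$paired)
        res$p_overall <- mg$p
        res$fdr_overall <- bhAdjust(mg$p)
        colnames(mg$pairwise) <- paste0("p_", gsub("-", ".vs.",
                                                   colnames(mg$pairwise)))
        res <- cbind(res, as.data.frame(mg$pairwise))
    }
    attr(res, "comparison") <- cmp
    res
}

#' Select significant sites
#'
#' Applies a metric threshold (`p` or `fdr` of a chosen test) and an
#' optional fold-change magnitude cutoff; the result is ordered by the
#' metric ascending with ties broken by site id.
#'
#' @param stat a result from [compareGroups()].
#' @param metric `"p"` or `"fdr"`.
#' @param threshold significance cutoff in `(0, 1]`.
#' @param fcMin minimum raw-scale fold-change magnitude (`>= 1`), or `NULL`.
#' @param test which test's values to use (e.g. `"t"`, `"rankprod"`,
#'   `"overall"`).
#' @return the passing rows of `stat`, ordered.
#' @export
selectSignificant <- function(stat, metric = c("fdr", "p"), threshold = 0.05,
                              fcMin = NULL, test = "t") {
    metric <- match.arg(metric)
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    col <- paste0(metric, "_", test)
    if (!col %in% colnames(stat)) stop("column '", col, "' not in stat")
    v <- stat[[col]]
    keep <- !is.na(v) & v <= threshold
    if (!is.null(fcMin)) {
        if (fcMin < 1) stop("fcMin is a raw-scale magnitude >= 1")
        keep <- keep & !is.na(stat$log2fc) &
            abs(stat$log2fc) >= log2(fcMin)
    }
    out <- stat[keep, , drop = FALSE]
    out[order(out[[col]], out$site_id), , drop = FALSE]
}

#' Volcano plot data
#'
#' x = log2 fold change, y = -log10(metric). Significant points are flagged
#' for text labels only when the total number of significant points across
#' the (at most four) comparisons in the figure is at most 60.
#'
#' @param stats a single [compareGroups()] result or a named list of up to
#'   four of them.
#' @param metric,threshold,fcMin,test as in [selectSignificant()].
#' @return `data.frame` with `comparison`, `site_id`, `log2fc`, `neg_log10`,
#'   `significant`, `label`.
#' @export
volcanoData <- function(stats, metric = c("fdr", "p"), threshold = 0.05,
                        fcMin = NULL, test = "t") {
    metric <- match.arg(metric)
    if (is.data.frame(stats)) stats <- list(comparison1 = stats)
    if (length(stats) > 4L)
        stop("at most 4 comparisons can share a volcano figure")
    col <- paste0(metric, "_", test)
    tabs <- lapply(names(stats), function(nm) {
        st <- stats[[nm]]
        v <- st[[col]]
        sig <- !is.na(v) & v <= threshold
        if (!is.null(fcMin))
            sig <- sig & !is.na(st$log2fc) & abs(st$log2fc) >= log2(fcMin)
        data.frame(comparison = nm, site_id = st$site_id,
                   log2fc = st$log2fc, neg_log10 = -log10(v),
                   significant = sig, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    out$label <- out$significant & sum(out$significant) <= 60L
    out
}
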