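test_that("log2 fold change follows the higher-group-numerator convention", {
    m <- matrix(c(4, 4, 16, 16,
                  8, 8, 8, 8), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"), paste0("S", 1:4)))
    fc <- log2FoldChange(m, c("S1", "S2"), c("S3", "S4"))
    expect_equal(unname(fc), c(2, 0))
    ## swapping group roles flips the sign exactly
    expect_equal(log2FoldChange(m, c("S3", "S4"), c("S1", "S2")), -fc)
    ## all-missing group -> NA
    m2 <- m; m2[1, 3:4] <- NA
    expect_true(is.na(log2FoldChange(m2, c("S1", "S2"), c("S3", "S4"))[1]))
})

test_that("Welch and Wilcoxon p-values match hand-computed references", {
    ## Welch on x=(10,12,14), y=(11,13,15,17): hand formula
    x <- c(10, 12, 14); y <- c(11, 13, 15, 17)
    se <- sqrt(var(x) / 3 + var(y) / 4)
    df <- se^4 / (var(x)^2 / (9 * 2) + var(y)^2 / (16 * 3))
    pHand <- 2 * pt(-abs((mean(x) - mean(y)) / se), df)
    mm <- `colnames<-`(matrix(c(x, y), 1), paste0("S", 1:7))
    p <- twoGroupTest(mm, paste0("S", 1:3), paste0("S", 4:7), "t")
    expect_equal(p, pHand)
    ## identical groups -> p = 1
    eq <- `colnames<-`(matrix(c(1, 1, 1, 1, 1, 1), 1), paste0("S", 1:6))
    expect_equal(twoGroupTest(eq, paste0("S", 1:3), paste0("S", 4:6), "t"), 1)
    ## exact rank-sum: x=(1,2,3) vs y=(4,5,6): two-sided p = 2/C(6,3) = 0.1
    rs <- `colnames<-`(matrix(c(1, 2, 3, 4, 5, 6), 1), paste0("S", 1:6))
    expect_equal(twoGroupTest(rs, paste0("S", 1:3), paste0("S", 4:6),
                              "wilcoxon"), 0.1)
    ## insufficient data -> NA
    na1 <- `colnames<-`(matrix(c(1, NA, NA, 2, 3, 4), 1), paste0("S", 1:6))
    expect_true(is.na(twoGroupTest(na1, paste0("S", 1:3), paste0("S", 4:6),
                                   "t")))
})

test_that("multi-group ANOVA matches the hand sum-of-squares decomposition", {
    v <- c(1, 2, 3, 2, 3, 4, 7, 8, 9)
    m <- matrix(v, 1, dimnames = list("s", paste0("S", 1:9)))
    grp <- setNames(rep(1:3, each = 3), paste0("S", 1:9))
    mg <- multiGroupTest(m, grp)
    gm <- mean(v); means <- c(2, 3, 8)
    ssb <- 3 * sum((means - gm)^2); ssw <- sum(c(2, 2, 2))
    Fh <- (ssb / 2) / (ssw / 6)
    expect_equal(mg$p[1], pf(Fh, 2, 6, lower.tail = FALSE))
    expect_equal(dim(mg$pairwise), c(1L, 3L))
    ## all-equal values -> F = 0, p = 1
    flat <- matrix(5, 1, 9, dimnames = list("s", paste0("S", 1:9)))
    expect_equal(multiGroupTest(flat, grp)$p, 1)
    ## group with < 2 observations -> NA
    m2 <- m; m2[1, 1:2] <- NA
    expect_true(is.na(multiGroupTest(m2, grp)$p))
})

test_that("paired two-group blocked ANOVA reduces to the squared paired t", {
    set.seed(21)
    m <- matrix(rnorm(8), 1, dimnames = list("s", paste0("S", 1:8)))
    grp <- setNames(rep(1:2, each = 4), paste0("S", 1:8))
    mg <- multiGroupTest(m, grp, paired = TRUE)
    tp <- 2 * pt(-abs(mean(m[1, 5:8] - m[1, 1:4]) /
                      (sd(m[1, 5:8] - m[1, 1:4]) / 2)), 3)
    expect_equal(mg$p[1], tp, tolerance = 1e-10)
})

test_that("BH adjustment matches hand computation and is monotone", {
    expect_equal(bhAdjust(0.02), 0.02)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    ## NA excluded from the family size
    expect_equal(bhAdjust(c(0.01, NA, 0.02)), c(0.02, NA, 0.02))
    ## monotone: decreasing one p never increases any output
    set.seed(1)
    p <- runif(20)
    f1 <- bhAdjust(p)
    p2 <- p; p2[7] <- p[7] / 10
    expect_true(all(bhAdjust(p2) <= f1 + 1e-12))
})

test_that("significance selection applies metric and fold-change rules deterministically", {
    stat <- data.frame(
        site_id = paste0("s", 1:10),
        log2fc = c(3, -2, 0.9, 1.5, -3, 0.2, 2.5, -1.2, 4, -0.5),
        p_t = c(0.001, 0.02, 0.001, 0.2, 0.03, 0.04, 0.06, 0.01, 0.001,
                0.9))
    stat$fdr_t <- bhAdjust(stat$p_t)
    ## threshold 1, no fc: all with non-missing metric
    expect_equal(nrow(selectSignificant(stat, "p", 1, test = "t")), 10L)
    ## hand count: p <= 0.05 & |fc| >= 1 -> s1, s2, s5, s8, s9 (s3 fails fc)
    sel <- selectSignificant(stat, "p", 0.05, fcMin = 2, test = "t")
    expect_setequal(sel$site_id, c("s1", "s2", "s5", "s8", "s9"))
    ## fc_min 2 removes |log2fc| = 0.9 even at p = 0.001
    expect_false("s3" %in% sel$site_id)
    ## deterministic order: metric ascending, ties by site id
    expect_equal(sel$site_id[1:2], c("s1", "s9"))
})

test_that("volcano labelling obeys the 60-point rule and the 4-comparison cap", {
    mk <- function(n, p = 0.01) data.frame(
        site_id = sprintf("s%03d", seq_len(n)), log2fc = 2,
        p_t = p, fdr_t = p)
    v59 <- volcanoData(mk(59), metric = "p", threshold = 0.05, test = "t")
    expect_equal(sum(v59$label), 59L)
    v60 <- volcanoData(mk(60), metric = "p", threshold = 0.05, test = "t")
    expect_equal(sum(v60$label), 60L)
    v61 <- volcanoData(mk(61), metric = "p", threshold = 0.05, test = "t")
    expect_equal(sum(v61$label), 0L)
    expect_equal(sum(v61$significant), 61L)
    five <- setNames(replicate(5, mk(3), simplify = FALSE), paste0("c", 1:5))
    expect_error(volcanoData(five, metric = "p", test = "t"), "at most 4")
})

test_that("ROTS reduces to fold-change ranking on the restricted grid and handles degenerate rows", {
    set.seed(2)
    m <- matrix(rnorm(30 * 6), 30, 6)
    m[5, ] <- 7  # constant row
    g <- rep(1:2, each = 3)
    r <- rotsTest(m, g, B = 5, aGrid = numeric(0), nperm = 100, seed = 1)
    ## aGrid empty -> only the a2 = 0 family: ranking by |mean diff|
    expect_equal(r$a2, 0)
    d <- abs(rowMeans(m[, 4:6]) - rowMeans(m[, 1:3]))
    expect_equal(order(-r$d), order(-d))
    expect_equal(r$d[5], 0)  # constant row scores 0
    expect_true(all(r$p >= 0 & r$p <= 1))
})

test_that("rank product attains its minimum for an always-top site and matches enumeration", {
    ## site ranked 1 in every pair -> RP = 1
    m <- matrix(c(10, 10, 1, 1,
                  20, 20, 2, 2,
                  1, 1, 10, 10,
                  2, 3, 4, 3.5), 4, 4, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), paste0("S", 1:4)))
    rp <- suppressWarnings(rankProductTest(m, c(2, 2, 1, 1), nperm = 50,
                                           seed = 1))
    expect_equal(unname(rp$rp_up[1]), 2)  # site 2 doubles it everywhere
    expect_equal(unname(rp$rp_up[2]), 1)  # rank 1 in all four pairs
    ## permutation p converges to the exact enumeration on a tiny paired
    ## instance (continuous data, no ties)
    set.seed(9)
    m6 <- matrix(rnorm(6 * 4), 6, 4,
                 dimnames = list(NULL, paste0("S", 1:4)))
    rp6 <- rankProductTest(m6, c(1, 1, 2, 2), nperm = 4000, seed = 4,
                           paired = TRUE)
    ex <- vapply(seq_len(6), function(i)
        rankProductExactP(rp6$rp_up[i], 6, 2), numeric(1))
    expect_lt(max(abs(rp6$p_up - ex)), 0.01)
})

test_that("compareGroups assembles fold changes, tests and FDRs per comparison", {
    ps <- toyPhosphoSet(n = 20, nSamples = 8, seed = 10)
    design <- GroupDesign(
        list(condition = setNames(rep(1:2, each = 4), paste0("S", 1:8))),
        list(list(classification = "condition", groups = 1:2,
                  paired = FALSE)))
    st <- compareGroups(ps, design, 1, tests = c("t", "wilcoxon"))
    expect_true(all(c("log2fc", "p_t", "fdr_t", "p_wilcoxon",
                      "fdr_wilcoxon") %in% colnames(st)))
    expect_true(all(st$fdr_t >= st$p_t - 1e-12, na.rm = TRUE))
    expect_equal(nrow(st), 20L)

    ## multi-group route
    design3 <- GroupDesign(
        list(condition = setNames(c(1, 1, 1, 2, 2, 2, 3, 3),
                                  paste0("S", 1:8))),
        list(list(classification = "condition", groups = 1:3,
                  paired = FALSE)))
    st3 <- compareGroups(ps, design3, 1)
    expect_true("p_overall" %in% colnames(st3))
    expect_true(any(grepl("^p_.*vs", colnames(st3))))
})
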