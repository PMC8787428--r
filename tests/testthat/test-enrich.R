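test_that("ORA returns the closed-form hypergeometric tail", {
    bg <- paste0("P", 1:20)
    sets <- list(S = paste0("P", 1:5))
    out <- oraTest(c(paste0("P", 1:4), "P10"), bg, sets)
    expect_equal(out$p, 76 / 15504, tolerance = 1e-9)
    expect_equal(out$k, 4L)
    ## zero overlap -> p = 1
    out0 <- oraTest(paste0("P", 10:14), bg, list(S = paste0("P", 1:5)))
    expect_equal(out0$p, 1)
    ## shrinking the background from 1000 to 100 changes p as the closed
    ## form dictates
    bigBg <- paste0("X", 1:1000)
    sets2 <- list(S = paste0("X", 1:20))
    sig <- paste0("X", 1:10)
    pBig <- oraTest(sig, bigBg, sets2)$p
    pSmall <- oraTest(sig, paste0("X", 1:100), sets2)$p
    expect_equal(pBig, phyper(9, 20, 980, 10, lower.tail = FALSE))
    expect_equal(pSmall, phyper(9, 20, 80, 10, lower.tail = FALSE))
    expect_gt(pSmall, pBig)
    expect_error(oraTest("a", character(), sets), "empty")
    expect_warning(oraTest(c("P1", "NOPE"), bg, sets), "outside")
})

test_that("ORA p-values match exact draw enumeration on tiny universes", {
    set.seed(4)
    for (rep in 1:5) {
        N <- sample(8:12, 1)
        bg <- paste0("G", seq_len(N))
        K <- sample(2:5, 1); n <- sample(2:5, 1)
        st <- sample(bg, K)
        sig <- sample(bg, n)
        p <- oraTest(sig, bg, list(S = st))$p
        ## enumerate every possible draw of size n
        draws <- combn(N, n)
        k <- length(intersect(st, sig))
        tail <- mean(apply(draws, 2, function(ix)
            length(intersect(bg[ix], st)) >= k))
        expect_equal(p, tail, tolerance = 1e-12)
    }
})

test_that("signature enrichment reproduces the unweighted KS hand example", {
    st <- setNames(c(6, 5, 4, 3, 2, 1), paste0("s", 1:6))
    sigs <- list(TOP2 = data.frame(site = c("s1", "s2"), direction = "u"))
    r <- suppressWarnings(ptmSEA(st, sigs, weight = 0, nPerm = 200,
                                 seed = 1))
    expect_equal(r$ES, 1)  # running sum peaks right after the second hit
    expect_equal(r$pct_up, 100)
    ## disjoint signature skipped and reported
    sigs2 <- c(sigs, list(GONE = data.frame(site = "nope",
                                            direction = "u")))
    r2 <- suppressWarnings(ptmSEA(st, sigs2, weight = 0, nPerm = 200,
                                  seed = 1))
    expect_equal(attr(r2, "skipped"), "GONE")
})

test_that("signature enrichment symmetries hold exactly", {
    set.seed(3)
    st <- setNames(rnorm(40), paste0("x", 1:40))
    sigs <- list(
        A = data.frame(site = paste0("x", 1:8),
                       direction = c(rep("u", 5), rep("d", 3))),
        B = data.frame(site = paste0("x", 10:15), direction = "d"))
    swap <- function(s) {
        s$direction <- ifelse(s$direction == "u", "d", "u"); s
    }
    rA <- ptmSEA(st, sigs, weight = 1, nPerm = 100, seed = 5)
    rB <- ptmSEA(-st, lapply(sigs, swap), weight = 1, nPerm = 100,
                 seed = 5)
    expect_equal(rA$ES, rB$ES, tolerance = 1e-12)
    ## doubling |stat| leaves unweighted ES unchanged
    r0 <- ptmSEA(st, sigs, weight = 0, nPerm = 100, seed = 5)
    r0b <- ptmSEA(2 * st, sigs, weight = 0, nPerm = 100, seed = 5)
    expect_equal(r0$ES, r0b$ES, tolerance = 1e-12)
})

test_that("signature enrichment p-values are calibrated under a random null", {
    set.seed(12)
    st <- setNames(rnorm(300), paste0("x", 1:300))
    sigs <- lapply(seq_len(100), function(i) {
        n <- 12
        data.frame(site = sample(names(st), n),
                   direction = sample(c("u", "d"), n, replace = TRUE))
    })
    names(sigs) <- paste0("R", seq_len(100))
    r <- ptmSEA(st, sigs, weight = 1, nPerm = 200, seed = 6)
    expect_gte(mean(r$p <= 0.05), 0.02)
    expect_lte(mean(r$p <= 0.05), 0.08)
})

test_that("GCT v1.3 round-trips byte-stably and validates its header", {
    set.seed(2)
    mat <- matrix(rnorm(12), 3, 4,
                  dimnames = list(paste0("r", 1:3), paste0("c", 1:4)))
    f1 <- withr::local_tempfile(fileext = ".gct")
    f2 <- withr::local_tempfile(fileext = ".gct")
    writeGCT(mat, f1, rowMeta = data.frame(kind = c("a", "b", "c")),
             colMeta = data.frame(group = c("g1", "g1", "g2", "g2")))
    lines <- readLines(f1)
    expect_equal(lines[1], "#1.3")
    expect_equal(lines[2], "3\t4\t1\t1")
    g <- readGCT(f1)
    expect_identical(g$mat, mat)
    writeGCT(g$mat, f2, rowMeta = g$rowMeta, colMeta = g$colMeta)
    expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
    ## 2x2 no metadata: dimension line "2 2 0 0"
    m2 <- matrix(1:4 + 0.5, 2, 2, dimnames = list(c("a", "b"),
                                                  c("x", "y")))
    writeGCT(m2, f1)
    expect_equal(readLines(f1)[2], "2\t2\t0\t0")
    ## declared dims exceeding the body -> error
    writeLines(c("#1.3", "3\t2\t1\t0", "id\tm\tc1\tc2",
                 "r1\ta\t1\t2", "r2\tb\t3\t4"), f1)
    expect_error(readGCT(f1), "fewer lines")
    writeLines(c("#1.2", "1\t1\t0\t0"), f1)
    expect_error(readGCT(f1), "header")
})

test_that("signature reader parses direction tags and GMT sets load", {
    tf <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("SIG1\tdesc\tP1;10;S;u\tP2;20;T;d",
                 "SIG2\tdesc\tP3;5;Y;u"), tf)
    sigs <- readSignatures(tf)
    expect_equal(names(sigs), c("SIG1", "SIG2"))
    expect_equal(sigs$SIG1$site, c("P1;10;S", "P2;20;T"))
    expect_equal(sigs$SIG1$direction, c("u", "d"))
    writeLines("BAD\tdesc\tP1;10;S", tf)
    expect_error(readSignatures(tf), "direction")
})
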