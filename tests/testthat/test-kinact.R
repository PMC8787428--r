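uniformPWM <- function() {
    list(kinase = "U",
         mat = matrix(1 / 20, 15, 20, dimnames = list(NULL, aaLetters)),
         n_sequences = 1L, pseudocount = 0)
}

test_that("PWM construction matches hand-counted probabilities", {
    ## single window, no pseudocount: probability 1 at observed letters
    p1 <- buildPWM(list(K = "AAAAAAASAAAAAAA"), pseudocount = 0)$K
    expect_equal(unname(p1$mat[1, "A"]), 1)
    expect_equal(unname(p1$mat[8, "S"]), 1)
    expect_true(all(abs(rowSums(p1$mat) - 1) < 1e-9))
    ## two windows differing at position 1
    p2 <- buildPWM(list(K = c("AAAAAAASAAAAAAA", "SAAAAAASAAAAAAA")),
                   pseudocount = 0)$K
    expect_equal(unname(p2$mat[1, "A"]), 0.5)
    expect_equal(unname(p2$mat[1, "S"]), 0.5)
    ## pseudocount 1, one window: observed 2/21, others 1/21
    p3 <- buildPWM(list(K = "AAAAAAASAAAAAAA"), pseudocount = 1)$K
    expect_equal(unname(p3$mat[1, "A"]), 2 / 21)
    expect_equal(unname(p3$mat[1, "R"]), 1 / 21)
    ## pad characters are excluded from counts
    p4 <- buildPWM(list(K = "___AAAASAAAAAAA"), pseudocount = 0)$K
    expect_equal(unname(p4$mat[4, "A"]), 1)
    expect_true(all(abs(rowSums(p4$mat) - 1) < 1e-9))
})

test_that("peptide scoring is a log-odds sum with zero-contribution pads", {
    expect_equal(scorePeptide(uniformPWM(), "ARNDCQEGHSLKMFP"), 0)
    m <- uniformPWM()$mat
    m[3, ] <- 0.5 / 19; m[3, "R"] <- 0.5
    pwm <- list(kinase = "K", mat = m, n_sequences = 1, pseudocount = 0)
    expect_equal(scorePeptide(pwm, "AARAAAASAAAAAAA"), log2(0.5 / 0.05),
                 tolerance = 1e-9)
    ## '_'-padded positions contribute nothing
    expect_equal(scorePeptide(uniformPWM(), "___DCQEGHSLKMFP"), 0)
    expect_error(scorePeptide(uniformPWM(), "AAAAAAA"), "15")
    expect_error(scorePeptide(uniformPWM(), "AAAAAAA1AAAAAAA"),
                 "alphabet")
    expect_error(scorePeptide(uniformPWM(),
                              paste(rep("_", 15), collapse = "")),
                 "all-pad")
})

test_that("library consensus outscores single-letter perturbations", {
    set.seed(3)
    lib <- list(K = replicate(30, {
        ch <- sample(aaLetters, 15, replace = TRUE)
        ch[8] <- "S"; ch[c(3, 5)] <- "R"
        paste(ch, collapse = "")
    }))
    pwm <- buildPWM(lib, pseudocount = 0.1)$K
    consensus <- paste(aaLetters[apply(pwm$mat, 1, which.max)],
                       collapse = "")
    base <- scorePeptide(pwm, consensus)
    for (pos in c(3, 5, 8)) {
        pert <- consensus
        substr(pert, pos, pos) <- "W"
        expect_gte(base, scorePeptide(pwm, pert))
    }
})

test_that("match p-values agree with exhaustive null enumeration", {
    ## degenerate data windows: null pool per position is tiny, so the
    ## sampled null can be compared with exhaustive enumeration
    wins <- c(a = "AAAAAAASAAAAAAA", b = "RRRRRRRSRRRRRRR")
    pwm <- buildPWM(list(K = wins[["a"]]), pseudocount = 0.5)
    set.seed(2)
    res <- pwmPValues(pwm, wins, nDraws = 10000, seed = 5)
    ## exhaustive null: positions 1-7 and 9-15 draw A or R with prob 1/2;
    ## the centre pool holds S only
    lo <- log2(pwm$K$mat / (1 / 20))
    flank <- c(1:7, 9:15)
    nullScores <- vapply(0:(2^14 - 1), function(code) {
        bits <- as.integer(intToBits(code))[1:14]
        lo[8, "S"] +
            sum(ifelse(bits == 1, lo[cbind(flank, match("R", aaLetters))],
                       lo[cbind(flank, match("A", aaLetters))]))
    }, numeric(1))
    for (w in names(wins)) {
        obs <- scorePeptide(pwm$K, wins[[w]])
        exact <- mean(nullScores >= obs - 1e-9)
        expect_lt(abs(res$p["K", w] - exact), 0.01)
    }
    ## estimator bounds
    expect_gte(min(res$p), 1 / 10001)
    expect_lte(max(res$p), 1)
})

test_that("swing scores follow the counting formula and flip with fold-change sign", {
    set.seed(8)
    nS <- 40
    keys <- paste0("s", seq_len(nS))
    mp <- matrix(1, 2, nS, dimnames = list(c("KA", "KB"), keys))
    mp["KA", 1:10] <- 0.01           # KA's substrates: sites 1-10
    fc <- setNames(c(rep(2, 10), rnorm(30)), keys)
    sp <- setNames(c(rep(0.001, 10), runif(30, 0.2, 1)), keys)
    sw <- swingScores(mp, fc, sp, nPerm = 300, seed = 2)
    ka <- sw[sw$kinase == "KA", ]
    expect_equal(ka$pos, 10)
    expect_equal(ka$neg, 0)
    expect_equal(ka$swing_raw, log2(11 / 1) * sqrt(10), tolerance = 1e-12)
    expect_lte(ka$p_greater, 0.05)
    ## kinase without substrates -> NA scores
    kb <- sw[sw$kinase == "KB", ]
    expect_equal(kb$all, 0)
    expect_true(is.na(kb$swing_raw))
    ## pos == neg -> raw 0
    mp2 <- matrix(1, 1, nS, dimnames = list("KC", keys))
    mp2[1, 1:4] <- 0.01
    fc2 <- fc; fc2[1:2] <- 2; fc2[3:4] <- -2
    sp2 <- sp; sp2[1:4] <- 0.001
    sw2 <- swingScores(mp2, fc2, sp2, nPerm = 100, seed = 1)
    expect_equal(sw2$swing_raw, 0)
    ## exact antisymmetry under global fold-change negation
    swNeg <- swingScores(mp, -fc, sp, nPerm = 300, seed = 2)
    expect_equal(swNeg$swing_raw, -sw$swing_raw)
})

test_that("kinase edge extraction ranks, caps and tie-breaks deterministically", {
    nS <- 300
    keys <- sprintf("P%03d;%d;S", seq_len(nS), seq_len(nS))
    mp <- matrix(0.01, 1, nS, dimnames = list("K", keys))
    fc <- setNames(rep(2, nS), keys)
    ## all significant with distinct p: cap at 250 smallest
    sp <- setNames(seq(0.0001, 0.04, length.out = nS), keys)
    ed <- kinaseEdges(mp, fc, sp, topN = 250)
    expect_equal(nrow(ed), 250L)
    expect_setequal(ed$site_id, keys[order(sp)][1:250])
    ## 10 significant -> all retained
    sp2 <- setNames(rep(1, nS), keys); sp2[1:10] <- 0.01
    ed2 <- kinaseEdges(mp, fc, sp2, topN = 250)
    expect_equal(nrow(ed2), 10L)
    ## tie at the boundary: deterministic by site id, count stays 250
    sp3 <- setNames(rep(0.01, nS), keys)
    ed3 <- kinaseEdges(mp, fc, sp3, topN = 250)
    expect_equal(nrow(ed3), 250L)
    expect_setequal(ed3$site_id, sort(keys)[1:250])
})

test_that("kinase library reader validates windows and kinases", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("KINASE\tSITE_+/-7_AA",
                 "K1\tAAAAAAASAAAAAAA",
                 "K1\tAAAAAAATAAAAAAA",
                 "K2\tSHORT",
                 "K3\tAAAAAAAAAAAAAAA"), tf)  # K3 centre not S/T/Y
    lib <- suppressWarnings(readKinaseLibrary(tf))
    expect_equal(names(lib), "K1")
    expect_length(lib$K1, 2L)
    ## a single invalid window alongside valid ones warns without
    ## dropping the kinase
    tf2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("KINASE\tSITE_+/-7_AA",
                 "K1\tAAAAAAASAAAAAAA",
                 "K1\tSHORT"), tf2)
    expect_warning(lib2 <- readKinaseLibrary(tf2), "dropped")
    expect_length(lib2$K1, 1L)
})
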