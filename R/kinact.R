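## Kinase-substrate inference. A kinase's known substrate 15-mers define a
## position weight matrix (PWM); data windows are scored against each PWM
## with a log-odds sum; match significance comes from column-wise resampled
## null peptides; and per-comparison kinase activity change is summarised
## by a swing score: a count-weighted log odds of up- vs down-regulated
## predicted substrates, z-normalized by joint permutation of the site
## statistics.

#' Read a kinase-substrate library
#'
#' Tab-separated file with columns `KINASE` and `SITE_+/-7_AA`
#' (PhosphoSitePlus-style): one row per known substrate 15-mer, centred on
#' the phosphoacceptor. Windows that are not 15 long or whose centre is not
#' S/T/Y are dropped with a warning, as are kinases left without windows.
#'
#' @param path TSV path.
#' @return named list: kinase -> character vector of 15-mer windows.
#' @export
readKinaseLibrary <- function(path) {
    df <- readTsv(path)
    for (col in c("KINASE", "SITE_+/-7_AA"))
        if (!col %in% colnames(df))
            stop("format error: missing required column '", col, "'")
    win <- toupper(df[["SITE_+/-7_AA"]])
    bad <- nchar(win) != WINDOW_LEN |
        !substr(win, WINDOW_CENTER, WINDOW_CENTER) %in% c("S", "T", "Y")
    if (any(bad)) {
        warning(sum(bad), " library window(s) dropped (not a 15-mer ",
                "centred on S/T/Y)")
        df <- df[!bad, , drop = FALSE]; win <- win[!bad]
    }
    lib <- split(win, df$KINASE)
    empty <- lengths(lib) == 0L
    if (any(empty)) {
        warning("kinase(s) without usable windows skipped: ",
                paste(names(lib)[empty], collapse = ", "))
        lib <- lib[!empty]
    }
    lib
}

#' Build position weight matrices from a kinase library
#'
#' `PWM[p, a] = (count of letter a at position p + pseudocount) /
#' (n_p + 20 * pseudocount)`, where `n_p` counts the non-pad letters at
#' position p (the `_` pad is excluded from counts).
#'
#' @param library named list of 15-mer window vectors (see
#'   [readKinaseLibrary()]).
#' @param pseudocount additive smoothing constant (`> 0` guarantees
#'   strictly positive probabilities).
#' @return named list of PWM objects, each a list with `kinase`, `mat`
#'   (15 x 20 probability matrix, rows sum to 1), `n_sequences`,
#'   `pseudocount`.
#' @export
buildPWM <- function(library, pseudocount = 1) {
    out <- lapply(names(library), function(kin) {
        wins <- library[[kin]]
        if (!length(wins)) return(NULL)
        chars <- matrix(unlist(strsplit(wins, "")), ncol = WINDOW_LEN,
                        byrow = TRUE)
        mat <- matrix(0, WINDOW_LEN, length(AA_ALPHABET20),
                      dimnames = list(NULL, AA_ALPHABET20))
        for (p in seq_len(WINDOW_LEN)) {
            cnt <- table(factor(chars[, p], levels = AA_ALPHABET20))
            np <- sum(cnt)  # '_' and unknown letters excluded
            denom <- np + length(AA_ALPHABET20) * pseudocount
            mat[p, ] <- if (denom > 0)
                (as.numeric(cnt) + pseudocount) / denom
            else 1 / length(AA_ALPHABET20)  # position seen only as pad
        }
        list(kinase = kin, mat = mat, n_sequences = length(wins),
             pseudocount = pseudocount)
    })
    names(out) <- names(library)
    Filter(Negate(is.null), out)
}

## letters -> column index in the 15 x 21 log-odds table; '_' scores 0
pwmLogOdds <- function(pwm, background) {
    lo <- log2(sweep(pwm$mat, 2, background, "/"))
    cbind(lo, `_` = 0)
}

#' Score a peptide window against a PWM
#'
#' Sum over non-pad positions of `log2(PWM[p, letter] /
#' background[letter])`; `_` positions contribute 0.
#'
#' @param pwm a PWM object from [buildPWM()].
#' @param window a 15-mer (pad `_` allowed, but not everywhere).
#' @param background per-letter background probabilities (default uniform
#'   1/20), named by amino acid or in [AA_ALPHABET20] order.
#' @return numeric log-odds score.
#' @export
scorePeptide <- function(pwm, window, background = NULL) {
    scoreWindows(pwm, window, background)[1]
}

#' @rdname scorePeptide
#' @param windows character vector of 15-mers (vectorised form).
#' @export
scoreWindows <- function(pwm, windows, background = NULL) {
    if (is.null(background))
        background <- rep(1 / 20, 20)
    if (!is.null(names(background)))
        background <- background[AA_ALPHABET20]
    if (any(nchar(windows) != WINDOW_LEN))
        stop("windows must be 15 characters")
    lo <- pwmLogOdds(pwm, background)
    chars <- matrix(unlist(strsplit(windows, "")), ncol = WINDOW_LEN,
                    byrow = TRUE)
    idx <- matrix(match(chars, colnames(lo)), nrow(chars))
    if (anyNA(idx)) stop("letter outside the amino-acid alphabet: ",
                         paste(unique(chars[is.na(idx)]), collapse = ", "))
    if (any(rowSums(chars != WINDOW_PAD) == 0L))
        stop("all-pad window cannot be scored")
    sc <- numeric(length(windows))
    for (p in seq_len(WINDOW_LEN)) sc <- sc + lo[p, idx[, p]]
    unname(sc)
}

#' Permutation p-values for kinase-window matches
#'
#' For each kinase, null scores are generated by composing `nDraws` random
#' windows whose letter at each position is drawn from the pool of letters
#' observed at that position across the data windows (preserving positional
#' composition, including pads). The match p-value is
#' `(1 + #\{null >= observed\}) / (1 + nDraws)`.
#'
#' @param pwms list of PWM objects.
#' @param dataWindows character vector of the dataset's 15-mers, named by
#'   site key.
#' @param nDraws number of null windows (warning below 100).
#' @param seed RNG seed.
#' @param background see [scorePeptide()].
#' @return list: `p` (kinase x window matrix of match p-values), `score`
#'   (the observed score matrix).
#' @export
pwmPValues <- function(pwms, dataWindows, nDraws = 1000L, seed = 1L,
                       background = NULL) {
    if (length(dataWindows) < 2L) stop("need >= 2 data windows")
    if (nDraws < 100L) warning("nDraws < 100 gives unstable p-values")
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    chars <- matrix(unlist(strsplit(dataWindows, "")), ncol = WINDOW_LEN,
                    byrow = TRUE)
    nullChars <- vapply(seq_len(WINDOW_LEN), function(p)
        sample(chars[, p], nDraws, replace = TRUE), character(nDraws))
    nullWins <- apply(nullChars, 1, paste, collapse = "")
    pm <- matrix(NA_real_, length(pwms), length(dataWindows),
                 dimnames = list(names(pwms), names(dataWindows)))
    sm <- pm
    for (kin in names(pwms)) {
        obs <- scoreWindows(pwms[[kin]], dataWindows, background)
        nul <- sort(scoreWindows(pwms[[kin]], nullWins, background))
        cntGE <- length(nul) -
            findInterval(obs - 1e-9 * pmax(abs(obs), 1), nul)
        sm[kin, ] <- obs
        pm[kin, ] <- (1 + cntGE) / (1 + nDraws)
    }
    list(p = pm, score = sm)
}

#' Kinase swing scores
#'
#' For each kinase the predicted substrates are the sites whose PWM match
#' p-value is at most `alphaPWM`. Among these, `pos` counts substrates
#' significantly up (site p <= `alphaSite`, fold change > 0) and `neg`
#' significantly down; the raw swing is
#' `log2((pos + pseudo) / (neg + pseudo)) * sqrt(pos + neg)`. The (fold
#' change, site p) rows are jointly permuted across sites `nPerm` times to
#' give a z-score and one-sided permutation p-values with the +1
#' correction.
#'
#' @param matchP kinase x site matrix of match p-values (from
#'   [pwmPValues()]); column names are site keys.
#' @param fc,siteP numeric vectors named by site key: signed log2 fold
#'   change and the site p-value of the chosen test.
#' @param alphaPWM,alphaSite significance cutoffs.
#' @param pseudo pseudocount of the log odds.
#' @param nPerm number of joint permutations.
#' @param seed RNG seed.
#' @return data.frame per kinase: `kinase`, `pos`, `neg`, `all` (number of
#'   predicted substrates), `swing_raw`, `z`, `p_greater`, `p_less`,
#'   `n_perm`. Kinases without substrates carry `NA` scores.
#' @export
swingScores <- function(matchP, fc, siteP, alphaPWM = 0.05,
                        alphaSite = 0.05, pseudo = 1, nPerm = 1000L,
                        seed = 1L) {
    keys <- colnames(matchP)
    fc <- fc[keys]; siteP <- siteP[keys]
    M <- matchP <= alphaPWM
    M[is.na(M)] <- FALSE
    nSub <- rowSums(M)
    sigUp <- as.numeric(!is.na(siteP) & siteP <= alphaSite &
                        !is.na(fc) & fc > 0)
    sigDn <- as.numeric(!is.na(siteP) & siteP <= alphaSite &
                        !is.na(fc) & fc < 0)
    Mn <- M * 1
    rawOf <- function(pos, neg)
        log2((pos + pseudo) / (neg + pseudo)) * sqrt(pos + neg)
    pos <- as.numeric(Mn %*% sigUp)
    neg <- as.numeric(Mn %*% sigDn)
    raw <- rawOf(pos, neg)

    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    S <- length(keys)
    permIdx <- vapply(seq_len(nPerm), function(i) sample.int(S),
                      integer(S))
    posPerm <- Mn %*% matrix(sigUp[permIdx], S)
    negPerm <- Mn %*% matrix(sigDn[permIdx], S)
    rawPerm <- rawOf(posPerm, negPerm)
    mu <- rowMeans(rawPerm)
    sdv <- apply(rawPerm, 1, stats::sd)
    z <- (raw - mu) / sdv
    pg <- (1 + rowSums(rawPerm >= raw)) / (1 + nPerm)
    pl <- (1 + rowSums(rawPerm <= raw)) / (1 + nPerm)
    none <- nSub == 0L
    raw[none] <- z[none] <- pg[none] <- pl[none] <- NA_real_
    data.frame(kinase = rownames(matchP), pos = pos, neg = neg,
               all = nSub, swing_raw = raw, z = z, p_greater = pg,
               p_less = pl, n_perm = nPerm, stringsAsFactors = FALSE)
}

#' Top kinase-substrate network edges
#'
#' Significant substrate sites (site p <= `alphaSite`, matched by at least
#' one kinase at `alphaPWM`) are ranked by site p ascending (ties broken by
#' site key) and the top `topN` retained; one edge is emitted per (kinase,
#' retained site) match, grouped by substrate protein.
#'
#' @inheritParams swingScores
#' @param topN maximum number of substrate sites retained.
#' @return data.frame: `kinase`, `site_id`, `protein`, `direction`
#'   (`"up"`/`"down"`), `site_p`, ordered by protein then site p.
#' @export
kinaseEdges <- function(matchP, fc, siteP, topN = 250L, alphaPWM = 0.05,
                        alphaSite = 0.05) {
    keys <- colnames(matchP)
    fc <- fc[keys]; siteP <- siteP[keys]
    M <- matchP <= alphaPWM
    M[is.na(M)] <- FALSE
    cand <- which(!is.na(siteP) & siteP <= alphaSite & colSums(M) > 0L)
    if (!length(cand))
        return(data.frame(kinase = character(), site_id = character(),
                          protein = character(), direction = character(),
                          site_p = numeric(), stringsAsFactors = FALSE))
    ord <- cand[order(siteP[cand], keys[cand])]
    keep <- utils::head(ord, topN)
    edges <- which(M[, keep, drop = FALSE], arr.ind = TRUE)
    out <- data.frame(
        kinase = rownames(matchP)[edges[, 1]],
        site_id = keys[keep][edges[, 2]],
        protein = vapply(strsplit(keys[keep][edges[, 2]], ";"),
                         `[`, character(1), 1L),
        direction = ifelse(fc[keys[keep][edges[, 2]]] > 0, "up", "down"),
        site_p = siteP[keys[keep][edges[, 2]]],
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$protein, out$site_p, out$site_id, out$kinase), ]
}
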