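## Shared builders for the test suite. Everything is generated in code; no
## stored binary fixtures.

aaLetters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "Y", "W", "V")

toyWindow <- function(res = "S", fill = "A") {
    paste0(strrep(fill, 7), res, strrep(fill, 7))
}

toyPhosphoSet <- function(n = 6, nSamples = 4, seed = 1) {
    set.seed(seed)
    m <- matrix(2^rnorm(n * nSamples, 20, 1), n, nSamples,
                dimnames = list(NULL, paste0("S", seq_len(nSamples))))
    info <- data.frame(
        accession = paste0("P", rep(seq_len(ceiling(n / 2)), each = 2)[1:n]),
        position = seq(10, by = 20, length.out = n),
        residue = rep(c("S", "T", "Y"), length.out = n),
        window = vapply(rep(c("S", "T", "Y"), length.out = n), toyWindow,
                        character(1)),
        stringsAsFactors = FALSE)
    PhosphoSet(m, info)
}

## Hand-written MaxQuant-dialect file: 3 sites on 4 samples with known
## multiplicity channels, one reverse row, one contaminant row.
writeToyMaxQuant <- function(path) {
    samples <- c("A", "B")
    hdr <- c("Proteins", "Gene names", "Position", "Amino acid",
             "Sequence window", "Reverse", "Potential contaminant", "id",
             as.vector(outer(samples, 1:3, function(s, k)
                 sprintf("Intensity %s___%d", s, k))))
    rows <- list(
        ## site 1: A: 100 + 50 + missing = 150; B: all missing
        c("P1", "G1", "10", "S", toyWindow("S"), "", "", "1",
          "100", "", "50", "", "", ""),
        ## site 2: A: 30; B: 10+20+30 = 60
        c("P2", "G2", "20", "T", toyWindow("T"), "", "", "2",
          "30", "10", "", "20", "", "30"),
        ## site 3: reverse -> always dropped
        c("REV__P3", "G3", "5", "S", toyWindow("S"), "+", "", "3",
          "7", "7", "", "", "", ""),
        ## site 4: contaminant -> dropped unless kept
        c("CON__P4", "G4", "8", "Y", toyWindow("Y"), "", "+", "4",
          "5", "", "", "", "", ""))
    writeLines(c(paste(hdr, collapse = "\t"),
                 vapply(rows, paste, character(1), collapse = "\t")), path)
    path
}

writeToyDesign <- function(path, samples, groups,
                           comparisons = "condition,1;2,FALSE",
                           organism = "Mus musculus") {
    writeLines(c("[groups]", "classification,sample,group",
                 paste("condition", samples, groups, sep = ","),
                 "[comparisons]", "classification,groups,paired",
                 comparisons,
                 "[meta]", paste0("organism,", organism),
                 "reference_classification,condition"), path)
    path
}

## Independent affine-gap Needleman-Wunsch oracle (Gotoh three-state DP;
## a length-L gap costs gapOpen + L * gapExtend).
bruteAlignScore <- function(a, b, sub, gapOpen = 10, gapExtend = 0.5) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B); NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
    M[1, 1] <- 0
    for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExtend * (j - 1)
    for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExtend * (i - 1)
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        s <- sub[A[i - 1], B[j - 1]]
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                       Y[i - 1, j - 1]) + s
        X[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                       X[i - 1, j] - gapExtend,
                       Y[i - 1, j] - gapOpen - gapExtend)
        Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                       Y[i, j - 1] - gapExtend,
                       X[i, j - 1] - gapOpen - gapExtend)
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

randomAASeq <- function(len) paste(sample(aaLetters, len, replace = TRUE),
                                   collapse = "")

## A complete, small pipeline configuration over simulated inputs.
pipelineFixture <- function(dir, nSites = 80, seed = 5) {
    spec <- simSpec(nSites = nSites)
    kf <- simulateKnowledgeFiles(spec, dir, seed = seed)
    mq <- file.path(dir, "sites.txt")
    simulateMaxQuantFile(spec, mq, seed = seed)
    writeToyDesign(file.path(dir, "design.csv"), paste0("S", 1:12),
                   rep(1:2, each = 6))
    list(input = mq, format = "maxquant",
         design = file.path(dir, "design.csv"),
         output = file.path(dir, "out"), organism = "Mus musculus",
         seed = 7, preprocess = list(mode = "normalize"),
         tests = c("t", "rankprod"),
         rankprod = list(nperm = 200L),
         kinase = list(n_perm = 200L, n_draws = 300L),
         ptm_sea = list(weight = 1, n_perm = 200L),
         network = list(n_controls = 200L, hub_rule = "mean_plus_sd",
                        min_conf = 0.4),
         knowledge = kf$paths, plots = FALSE)
}
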