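## Synthetic-data generators. Every input format the pipeline reads can be
## fabricated with known ground truth, making the full analysis testable
## offline: a log-normal intensity model with planted differential sites,
## planted kinase substrate motifs embedded in consistent protein
## sequences, a planted network hub, and direction-tagged signatures built
## from the planted regulation.

#' Simulation specification
#'
#' @param nSites number of phosphosites.
#' @param groupSizes integer vector of samples per group (two groups for
#'   the planted two-group contrast).
#' @param nDE number of differential sites; a fraction `deFractionDown`
#'   are shifted down, the rest up.
#' @param effectLog2fc planted log2 effect in group 2.
#' @param noiseSd within-group log2 standard deviation.
#' @param missingRate MCAR missingness probability.
#' @param sitesPerProtein average number of sites per protein.
#' @param deFractionDown fraction of differential sites shifted down.
#' @param kinases named list of planted kinase motifs; each a list with
#'   `positions` (window coordinates 1-15, excluding the centre),
#'   `letters`, `nSubstrates`, `direction` (`"up"`/`"down"`) and
#'   `nLibraryWindows`.
#' @param consensusProb probability a motif position carries its consensus
#'   letter in library and substrate windows.
#' @param edgeDensity background interaction density of the toy
#'   interactome.
#' @param hubDegree planted degree of the hub protein among the
#'   differential proteins.
#' @param nRandomSignatures random site signatures alongside the planted
#'   up/down signatures.
#' @param nRandomSets random gene sets alongside the planted set.
#' @return a list of class `"SimSpec"`.
#' @export
simSpec <- function(nSites = 300L, groupSizes = c(6L, 6L), nDE = 20L,
                    effectLog2fc = 2, noiseSd = 0.5, missingRate = 0.05,
                    sitesPerProtein = 3L, deFractionDown = 0.5,
                    kinases = list(
                        KIN_UP = list(positions = c(5L, 6L, 12L),
                                      letters = c("R", "R", "L"),
                                      nSubstrates = 10L, direction = "up",
                                      nLibraryWindows = 20L),
                        KIN_DOWN = list(positions = c(3L, 10L, 13L),
                                        letters = c("P", "E", "E"),
                                        nSubstrates = 10L,
                                        direction = "down",
                                        nLibraryWindows = 20L)),
                    consensusProb = 0.9, edgeDensity = 0.05,
                    hubDegree = 8L, nRandomSignatures = 3L,
                    nRandomSets = 4L) {
    if (nDE > nSites) stop("nDE must not exceed nSites")
    if (missingRate < 0 || missingRate > 1) stop("missingRate in [0,1]")
    structure(as.list(environment()), class = "SimSpec")
}

randomSeq <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                               collapse = "")

## overwrite protein letters so the site's 15-mer shows the kinase motif
plantMotif <- function(seq, pos, motif, consensusProb) {
    ch <- strsplit(seq, "")[[1]]
    for (j in seq_along(motif$positions)) {
        p <- pos + motif$positions[j] - WINDOW_CENTER
        if (p >= 1L && p <= length(ch) && stats::runif(1) <= consensusProb)
            ch[p] <- motif$letters[j]
    }
    paste(ch, collapse = "")
}

#' Simulate a phosphosite table with ground truth
#'
#' Protein sequences are generated first; sites are placed on them (with
#' S/T/Y acceptors written into the sequence) so that windows, FASTA and
#' kinase motifs stay mutually consistent. Intensities follow a log-normal
#' model: per-site baseline `~ N(20, 2)` on the log2 scale, within-group
#' noise `noiseSd`, the first `nDE` sites shifted by `effectLog2fc`
#' (up- or down-wards) in group 2, and MCAR missingness.
#'
#' @param spec a [simSpec()].
#' @param seed RNG seed; the generator is a pure function of `(spec,
#'   seed)`.
#' @return list: `set` (a [PhosphoSet-class]), `design`
#'   ([GroupDesign-class] with the two-group comparison), `truth`
#'   (per-site `de`/`direction` labels, substrate assignments, protein
#'   sequences, channel structure used by [simulateMaxQuantFile()]).
#' @export
simulateSiteTable <- function(spec, seed = 1L) {
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    nS <- spec$nSites
    nProt <- ceiling(nS / spec$sitesPerProtein)
    acc <- sprintf("SYNP%03d", seq_len(nProt))
    protLen <- sample(80:160, nProt, replace = TRUE)
    seqs <- stats::setNames(vapply(protLen, randomSeq, character(1)), acc)

    siteProt <- rep(seq_len(nProt), length.out = nS)
    position <- integer(nS); residue <- character(nS)
    used <- vector("list", nProt)
    for (i in seq_len(nS)) {
        pr <- siteProt[i]
        tries <- 0L
        repeat {
            pos <- sample(8:(protLen[pr] - 8L), 1L)
            tries <- tries + 1L
            if (!any(abs(pos - unlist(used[[pr]])) < 16L) || tries > 200L)
                break
        }
        used[[pr]] <- c(used[[pr]], pos)
        position[i] <- pos
        residue[i] <- sample(c("S", "T", "Y"), 1L)
        s <- seqs[[pr]]
        substr(s, pos, pos) <- residue[i]
        seqs[[pr]] <- s
    }

    ## planted regulation
    direction <- rep("none", nS)
    nDown <- round(spec$nDE * spec$deFractionDown)
    nUp <- spec$nDE - nDown
    if (nUp > 0L) direction[seq_len(nUp)] <- "up"
    if (nDown > 0L) direction[nUp + seq_len(nDown)] <- "down"

    ## plant kinase substrate motifs on regulated sites
    substrateOf <- rep(NA_character_, nS)
    for (kin in names(spec$kinases)) {
        mot <- spec$kinases[[kin]]
        pool <- which(direction == mot$direction &
                      is.na(substrateOf))
        take <- utils::head(pool, mot$nSubstrates)
        for (i in take) {
            seqs[siteProt[i]] <- plantMotif(seqs[siteProt[i]], position[i],
                                            mot, spec$consensusProb)
            substrateOf[i] <- kin
        }
    }
    windows <- vapply(seq_len(nS), function(i)
        extractWindow(seqs[[siteProt[i]]], position[i]), character(1))

    nPer <- spec$groupSizes
    samples <- paste0("S", seq_len(sum(nPer)))
    grp <- rep(seq_along(nPer), nPer)
    base <- stats::rnorm(nS, 20, 2)
    shift <- ifelse(direction == "up", spec$effectLog2fc,
                    ifelse(direction == "down", -spec$effectLog2fc, 0))
    lg <- matrix(stats::rnorm(nS * length(samples), 0, spec$noiseSd),
                 nS, length(samples)) + base
    lg[, grp == 2L] <- lg[, grp == 2L] + shift
    m <- 2^lg
    m[matrix(stats::runif(length(m)) < spec$missingRate, nS)] <- NA_real_
    colnames(m) <- samples

    ## per-site multiplicity channel structure for the MaxQuant dialect
    nChan <- sample(1:3, nS, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    chanW <- lapply(nChan, function(k) {
        w <- stats::runif(k); w / sum(w)
    })

    info <- data.frame(accession = acc[siteProt], gene = acc[siteProt],
                       position = position, residue = residue,
                       window = windows, multiplicity = 0L,
                       stringsAsFactors = FALSE)
    ps <- PhosphoSet(m, info)
    design <- GroupDesign(
        list(condition = stats::setNames(grp, samples)),
        list(list(classification = "condition", groups = c(1L, 2L),
                  paired = FALSE)),
        organism = "Mus musculus", referenceClassification = "condition")
    truth <- list(direction = direction, de = direction != "none",
                  substrateOf = substrateOf, sequences = seqs,
                  siteProtein = acc[siteProt], channels = chanW,
                  baseline = base)
    list(set = ps, design = design, truth = truth)
}

#' Write a synthetic MaxQuant Phospho (STY)Sites file
#'
#' Serialises [simulateSiteTable()] output in the MaxQuant dialect:
#' per-sample `Intensity <sample>___1/2/3` columns (each site's intensity
#' split over its simulated multiplicity channels), plus one planted
#' reverse row and one planted potential-contaminant row.
#'
#' @param spec a [simSpec()].
#' @param path output TSV path.
#' @param seed RNG seed (same seed, same table, as
#'   [simulateSiteTable()]).
#' @return invisibly, the [simulateSiteTable()] result used.
#' @export
simulateMaxQuantFile <- function(spec, path, seed = 1L) {
    sim <- simulateSiteTable(spec, seed)
    m <- intensities(sim$set)
    info <- siteInfo(sim$set)
    samples <- colnames(m)
    nS <- nrow(m)
    df <- data.frame(
        Proteins = info$accession, `Gene names` = info$gene,
        Position = info$position, `Amino acid` = info$residue,
        `Sequence window` = info$window,
        Reverse = "", `Potential contaminant` = "",
        id = seq_len(nS), check.names = FALSE, stringsAsFactors = FALSE)
    for (s in samples) for (k in 1:3)
        df[[sprintf("Intensity %s___%d", s, k)]] <- rep(NA_real_, nS)
    for (i in seq_len(nS)) {
        w <- sim$truth$channels[[i]]
        for (k in seq_along(w))
            df[[sprintf("Intensity %s___%d", samples[1], k)]][i] <- 0
        for (s in samples) {
            v <- m[i, s]
            if (is.na(v)) next
            for (k in seq_along(w))
                df[[sprintf("Intensity %s___%d", s, k)]][i] <- v * w[k]
        }
    }
    decoys <- df[c(1L, 2L), ]
    decoys$Proteins <- c("REV__SYNP900", "CON__SYNP901")
    decoys$Reverse <- c("+", "")
    decoys$`Potential contaminant` <- c("", "+")
    decoys$id <- nS + 1:2
    out <- rbind(df, decoys)
    num <- vapply(out, is.numeric, logical(1)) &
        grepl("^Intensity", colnames(out))
    for (cn in colnames(out)[num])
        out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                            sprintf("%.6f", out[[cn]]))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(sim)
}

#' Write the synthetic knowledge flat-files
#'
#' Produces the offline stand-ins for the live databases, all mutually
#' consistent with [simulateSiteTable()] under the same seed: the kinase
#' library (planted motifs plus decoy kinases), the protein FASTA
#' including +10-residue N-terminally extended synthetic orthologs with a
#' pairing table, gene sets (one enriched in the differential proteins),
#' direction-tagged site signatures (planted up/down plus random), and a
#' confidence-scored interaction edge table containing the planted hub.
#'
#' @param spec a [simSpec()].
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return list: `paths` (named file paths), `truth` (the generator
#'   truth, extended with `hub` and planted set/signature names), `sim`
#'   (the [simulateSiteTable()] result).
#' @export
simulateKnowledgeFiles <- function(spec, dir, seed = 1L) {
    sim <- simulateSiteTable(spec, seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed + 1000L)
    truth <- sim$truth
    info <- siteInfo(sim$set)
    keys <- siteKeys(sim$set)
    paths <- list()

    ## kinase library: planted motif windows + decoys
    libRows <- list()
    for (kin in names(spec$kinases)) {
        mot <- spec$kinases[[kin]]
        wins <- vapply(seq_len(mot$nLibraryWindows), function(i) {
            ch <- sample(AA_ALPHABET20, WINDOW_LEN, replace = TRUE)
            ch[WINDOW_CENTER] <- sample(c("S", "T", "Y"), 1L)
            hit <- stats::runif(length(mot$positions)) <= spec$consensusProb
            ch[mot$positions[hit]] <- mot$letters[hit]
            paste(ch, collapse = "")
        }, character(1))
        libRows[[kin]] <- data.frame(KINASE = kin, `SITE_+/-7_AA` = wins,
                                     check.names = FALSE)
    }
    for (kin in c("DECOY_A", "DECOY_B")) {
        wins <- vapply(1:15, function(i) {
            ch <- sample(AA_ALPHABET20, WINDOW_LEN, replace = TRUE)
            ch[WINDOW_CENTER] <- sample(c("S", "T", "Y"), 1L)
            paste(ch, collapse = "")
        }, character(1))
        libRows[[kin]] <- data.frame(KINASE = kin, `SITE_+/-7_AA` = wins,
                                     check.names = FALSE)
    }
    paths$kinase_library <- file.path(dir, "kinase_library.tsv")
    utils::write.table(do.call(rbind, libRows), paths$kinase_library,
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## FASTA with +10 N-terminal-extension orthologs and pairing table
    orth <- stats::setNames(
        vapply(truth$sequences, function(s)
            paste0("M", randomSeq(9L), s), character(1)),
        paste0("H_", names(truth$sequences)))
    allSeq <- c(truth$sequences, orth)
    paths$fasta <- file.path(dir, "proteins.fasta")
    writeLines(paste0(">", names(allSeq), "\n", unname(allSeq)),
               paths$fasta)
    paths$pairing <- file.path(dir, "pairing.csv")
    utils::write.csv(data.frame(query_acc = names(truth$sequences),
                                target_acc = paste0("H_", names(truth$sequences))),
                     paths$pairing, row.names = FALSE, quote = FALSE)

    ## gene sets: one enriched in differential proteins + random sets
    deProt <- unique(truth$siteProtein[truth$de])
    allProt <- unique(truth$siteProtein)
    sets <- c(list(PLANTED_DE_SET = deProt),
              stats::setNames(lapply(seq_len(spec$nRandomSets), function(i)
                  sample(allProt, min(8L, length(allProt)))),
                  paste0("RANDOM_SET_", seq_len(spec$nRandomSets))))
    paths$gene_sets <- file.path(dir, "genesets.gmt")
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"),
        character(1)), paths$gene_sets)

    ## direction-tagged signatures from planted regulation + random ones
    upKeys <- keys[truth$direction == "up"]
    dnKeys <- keys[truth$direction == "down"]
    sigs <- list(
        PLANTED_UP = paste0(upKeys, ";u"),
        PLANTED_DOWN = paste0(dnKeys, ";d"))
    for (i in seq_len(spec$nRandomSignatures))
        sigs[[paste0("RANDOM_SIG_", i)]] <-
            paste0(sample(keys, min(10L, length(keys))), ";",
                   sample(c("u", "d"), min(10L, length(keys)),
                          replace = TRUE))
    paths$signatures <- file.path(dir, "signatures.gmt")
    writeLines(vapply(names(sigs), function(nm)
        paste(c(nm, "synthetic", sigs[[nm]]), collapse = "\t"),
        character(1)), paths$signatures)

    ## interaction edge table with a planted hub
    hub <- deProt[1]
    partners <- utils::head(setdiff(deProt, hub), spec$hubDegree)
    eA <- character(); eB <- character(); conf <- numeric()
    if (length(partners)) {
        eA <- rep(hub, length(partners)); eB <- partners
        conf <- stats::runif(length(partners), 0.7, 0.99)
    }
    others <- t(utils::combn(allProt, 2L))
    pick <- stats::runif(nrow(others)) < spec$edgeDensity
    eA <- c(eA, others[pick, 1]); eB <- c(eB, others[pick, 2])
    conf <- c(conf, stats::runif(sum(pick), 0.1, 0.9))
    edgeTab <- data.frame(protein_a = eA, protein_b = eB,
                          confidence = round(conf, 3),
                          stringsAsFactors = FALSE)
    key <- paste(pmin(edgeTab$protein_a, edgeTab$protein_b),
                 pmax(edgeTab$protein_a, edgeTab$protein_b))
    edgeTab <- edgeTab[!duplicated(key), ]
    paths$edges <- file.path(dir, "interactions.tsv")
    utils::write.table(edgeTab, paths$edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth$hub <- hub
    truth$hubPartners <- partners
    truth$plantedSet <- "PLANTED_DE_SET"
    truth$plantedSignatures <- c("PLANTED_UP", "PLANTED_DOWN")
    list(paths = paths, truth = truth, sim = sim)
}
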