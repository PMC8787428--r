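## Config-driven orchestration. The original workflow is interactive; here
## every choice lives in a declarative YAML config so runs are reproducible
## and scriptable. The output tree mirrors the documented folder layout:
## Group Information, Overview Figure, Statistical Analysis, Enrichment
## (with a "PhosphoSite enrichment" subfolder per comparison), Kinase
## Analysis, Network, Annotation.

#' Organisms supported by the annotation-dependent stages
#'
#' Eighteen common model organisms; the list only gates which stages run
#' (kinase and site-signature enrichment additionally require human, mouse
#' or rat), never the computation itself, and can be overridden in the
#' config.
#' @export
supportedOrganisms <- c(
    "Homo sapiens", "Mus musculus", "Rattus norvegicus",
    "Danio rerio", "Drosophila melanogaster", "Caenorhabditis elegans",
    "Saccharomyces cerevisiae", "Gallus gallus", "Bos taurus",
    "Sus scrofa", "Canis lupus familiaris", "Macaca mulatta",
    "Pan troglodytes", "Xenopus tropicalis", "Oryctolagus cuniculus",
    "Ovis aries", "Equus caballus", "Felis catus")

kinaseOrganisms <- c("Homo sapiens", "Mus musculus", "Rattus norvegicus")

pipelineDefaults <- function() list(
    format = "maxquant", mode = "summed", steps = "all",
    organism = "other", seed = 1L,
    preprocess = list(mode = "none", row_max_missing = 0.5,
                      col_max_missing = 1, impute_rank = 2L,
                      impute_tol = 1e-5, impute_max_iter = 500L),
    tests = c("t", "wilcoxon"),
    significance = list(metric = "fdr", threshold = 0.05, fc_min = NULL,
                        test = "t"),
    rots = list(B = 100L, nperm = 1000L),
    rankprod = list(nperm = 1000L),
    kinase = list(alpha_pwm = 0.05, alpha_site = 0.05, pseudo = 1,
                  n_perm = 1000L, n_draws = 1000L, pseudocount = 1),
    ptm_sea = list(weight = 1, n_perm = 1000L),
    network = list(min_conf = 0.4, hub_rule = "mean_plus_sd",
                   n_controls = 1000L),
    knowledge = list(), plots = TRUE)

#' Read a pipeline run configuration
#'
#' YAML file with keys `input`, `format` (`maxquant`/`generic`/
#' `sitetable`), `mode` (MaxQuant parse mode), `design`, `output`,
#' `organism`, `seed`, `steps` (`"all"` or a subset of `overview`,
#' `differential`, `annotation`, `enrichment`, `kinase`, `network`),
#' `preprocess`, `tests`, `significance`, `knowledge` (paths:
#' `kinase_library`, `fasta`, `pairing`, `gene_sets`, `signatures`,
#' `edges`, optional `universal_background`), and tuning blocks `rots`,
#' `rankprod`, `kinase`, `ptm_sea`, `network`. Unset keys fall back to
#' defaults.
#'
#' @param path YAML config path.
#' @return a named list ("RunConfig").
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    utils::modifyList(pipelineDefaults(), cfg)
}

#' Validate a run configuration
#'
#' Report-only checks: unknown steps, missing input/knowledge files for
#' enabled stages, organism gating (kinase and site-signature enrichment
#' are only run for human, mouse and rat; other annotation-dependent
#' stages for the supported-organism list), and, when a parsed table is
#' supplied, whether imputation is admissible (every row needs at least
#' four observed values, otherwise the mode is forced to
#' normalization-only).
#'
#' @param config a config list (see [readRunConfig()]).
#' @param table optionally, the parsed [PhosphoSet-class], to check the
#'   imputation precondition.
#' @return list: `errors`, `warnings`, `config` (with disabled stages
#'   and forced fallbacks applied).
#' @export
validateConfig <- function(config, table = NULL) {
    config <- utils::modifyList(pipelineDefaults(), config)
    errors <- character(); warnings <- character()
    allSteps <- c("overview", "differential", "annotation", "enrichment",
                  "kinase", "network")
    steps <- config$steps
    if (identical(steps, "all")) steps <- allSteps
    unknown <- setdiff(steps, allSteps)
    if (length(unknown))
        errors <- c(errors, paste("unknown step(s):",
                                  paste(unknown, collapse = ", ")))
    steps <- intersect(steps, allSteps)
    if (!is.null(config$input) && !file.exists(config$input))
        errors <- c(errors, paste("input file not found:", config$input))
    if (!is.null(config$design) && !file.exists(config$design))
        errors <- c(errors, paste("design file not found:", config$design))
    needs <- list(annotation = c("fasta", "pairing"),
                  enrichment = c("gene_sets", "signatures"),
                  kinase = "kinase_library", network = "edges")
    for (st in intersect(names(needs), steps)) {
        for (k in needs[[st]]) {
            pth <- config$knowledge[[k]]
            if (is.null(pth))
                errors <- c(errors, sprintf(
                    "step '%s' enabled but knowledge file '%s' not configured",
                    st, k))
            else if (!file.exists(pth))
                errors <- c(errors, sprintf(
                    "knowledge file '%s' not found: %s", k, pth))
        }
    }
    if (any(c("kinase", "enrichment") %in% steps) &&
        !config$organism %in% kinaseOrganisms) {
        drop <- intersect(steps, "kinase")
        if (length(drop)) {
            warnings <- c(warnings, sprintf(
                "kinase analysis is only available for %s; stage disabled for organism '%s'",
                paste(kinaseOrganisms, collapse = ", "), config$organism))
            steps <- setdiff(steps, "kinase")
        }
        if ("enrichment" %in% steps) {
            warnings <- c(warnings, sprintf(
                "site-signature enrichment is only available for human/mouse/rat; skipped for organism '%s'",
                config$organism))
            config$ptm_sea$enabled <- FALSE
        }
    }
    if (!is.null(table) && config$preprocess$mode == "normalize_impute") {
        nObs <- rowSums(!is.na(intensities(table)))
        if (any(nObs < 4L)) {
            warnings <- c(warnings, sprintf(
                "%d row(s) have fewer than four observed values; imputation is not possible and the mode is forced to 'normalize'",
                sum(nObs < 4L)))
            config$preprocess$mode <- "normalize"
        }
    }
    config$steps <- steps
    list(errors = errors, warnings = warnings, config = config)
}

writeCsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
}

canPlot <- function(config)
    isTRUE(config$plots) && isTRUE(unname(capabilities("png")))

#' Run the full pipeline
#'
#' Executes the configured stages in order — parse, design, preprocess,
#' overview, differential statistics, annotation (site translation),
#' enrichment (protein ORA with dual backgrounds plus site-signature
#' enrichment with GCT conversion), kinase activity and kinase-substrate
#' edges, interaction network and hub analysis — writing every result as
#' CSV (and PNG figures where a graphics device is available) into the
#' documented folder layout under `config$output`. All randomness derives
#' from `config$seed`, so a rerun with the same config is byte-identical
#' on every CSV.
#'
#' @param config a config list from [readRunConfig()] or built in code.
#' @return invisibly, a list with the main in-memory results (`set`,
#'   `design`, `stats`, `significant`, per-stage tables) and `log`, the
#'   run-log lines.
#' @export
runPipeline <- function(config) {
    vc <- validateConfig(config)
    if (length(vc$errors))
        stop("invalid configuration:\n  ", paste(vc$errors, collapse = "\n  "))
    config <- vc$config
    steps <- config$steps
    out <- config$output
    if (is.null(out)) stop("config$output is required")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log <- c("phosflow run log",
             sprintf("seed: %d", config$seed),
             sprintf("steps: %s", paste(steps, collapse = ", ")),
             vc$warnings)

    ## --- ingest -------------------------------------------------------
    ps <- switch(config$format,
        maxquant = parseMaxQuantSites(config$input, config$mode),
        generic = parseGenericSites(config$input, config$schema),
        sitetable = readSiteTable(config$input),
        stop("unknown input format: ", config$format))
    design <- readDesign(config$design, ps)
    log <- c(log, sprintf("input: %s (%s, %d sites x %d samples)",
                          config$input, config$format, nrow(ps), ncol(ps)))

    dGI <- file.path(out, "Group Information")
    dir.create(dGI, showWarnings = FALSE)
    grpTab <- do.call(rbind, lapply(names(classifications(design)),
        function(nm) data.frame(
            classification = nm,
            sample = names(classifications(design)[[nm]]),
            group = unname(classifications(design)[[nm]]))))
    writeCsv(grpTab, file.path(dGI, "groups.csv"))
    cmpTab <- do.call(rbind, lapply(seq_along(comparisons(design)),
        function(i) {
            cmp <- comparisons(design)[[i]]
            data.frame(comparison = paste0("Comparison", i),
                       classification = cmp$classification,
                       groups = paste(cmp$groups, collapse = ";"),
                       paired = cmp$paired)
        }))
    if (!is.null(cmpTab)) writeCsv(cmpTab, file.path(dGI, "comparisons.csv"))

    ## --- preprocess ---------------------------------------------------
    vc2 <- validateConfig(config, table = ps)
    config <- vc2$config
    log <- c(log, vc2$warnings)
    pp <- preprocess(ps, mode = config$preprocess$mode,
                     rowMaxMissing = config$preprocess$row_max_missing,
                     colMaxMissing = config$preprocess$col_max_missing,
                     imputeRank = config$preprocess$impute_rank,
                     imputeTol = config$preprocess$impute_tol,
                     imputeMaxIter = config$preprocess$impute_max_iter)
    set <- pp$set
    log <- c(log, paste("preprocess:", pp$report))
    results <- list(set = set, design = design)

    ## --- overview -----------------------------------------------------
    if ("overview" %in% steps) {
        dOV <- file.path(out, "Overview Figure")
        dir.create(dOV, showWarnings = FALSE)
        raw <- metadata(set)$raw_intensity
        ov <- overviewBundle(PhosphoSet(raw, siteInfo(set)), design,
                             seed = config$seed,
                             clusterRows = nrow(set) <= 5000L)
        writeCsv(data.frame(sample = rownames(ov$scores), ov$scores,
                            cluster = ov$clusters[rownames(ov$scores)]),
                 file.path(dOV, "pca_kmeans.csv"))
        mrg <- ov$sampleClustering$merge
        writeCsv(data.frame(step = seq_len(nrow(mrg)), left = mrg[, 1],
                            right = mrg[, 2],
                            height = ov$sampleClustering$height),
                 file.path(dOV, "sample_dendrogram.csv"))
        writeCsv(data.frame(site_id = rownames(ov$log2), ov$log2,
                            check.names = FALSE),
                 file.path(dOV, "log2_intensities.csv"))
        if (canPlot(config)) {
            grDevices::png(file.path(dOV, "heatmap.png"), 900, 900)
            pheatmap::pheatmap(ov$log2,
                               cluster_rows = !is.null(ov$siteClustering),
                               cluster_cols = TRUE,
                               clustering_method = "complete",
                               show_rownames = FALSE, silent = TRUE)
            grDevices::dev.off()
            df <- data.frame(PC1 = ov$scores[, 1],
                             PC2 = ov$scores[, min(2L, ncol(ov$scores))],
                             cluster = factor(ov$clusters))
            p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                                  colour = .data$cluster)) +
                ggplot2::geom_point(size = 3) + ggplot2::theme_bw()
            ggplot2::ggsave(file.path(dOV, "pca.png"), p,
                            width = 6, height = 5, dpi = 120)
        }
        results$overview <- ov
        log <- c(log, sprintf("overview: k-means k = %d", ov$k))
    }

    ## --- differential -------------------------------------------------
    stats <- list(); sigLists <- list()
    if ("differential" %in% steps && length(comparisons(design))) {
        dST <- file.path(out, "Statistical Analysis")
        dir.create(dST, showWarnings = FALSE)
        sg <- config$significance
        for (i in seq_along(comparisons(design))) {
            nm <- paste0("Comparison", i)
            st <- compareGroups(set, design, i, tests = config$tests,
                                seed = config$seed,
                                rotsB = config$rots$B,
                                rotsNperm = config$rots$nperm,
                                rankprodNperm = config$rankprod$nperm)
            stats[[nm]] <- st
            full <- cbind(siteInfo(set)[match(st$site_id,
                                              siteInfo(set)$site_id),
                                        c("accession", "gene", "position",
                                          "residue", "window")],
                          st)
            writeCsv(full, file.path(dST, paste0(nm, "_statistics.csv")))
            if (length(comparisons(design)[[i]]$groups) == 2L &&
                paste0(sg$metric, "_", sg$test) %in% colnames(st)) {
                sig <- selectSignificant(st, metric = sg$metric,
                                         threshold = sg$threshold,
                                         fcMin = sg$fc_min, test = sg$test)
                sigLists[[nm]] <- sig
                writeCsv(sig, file.path(dST, paste0(nm, "_significant.csv")))
            }
        }
        twoGrp <- names(stats)[vapply(stats, function(s)
            "log2fc" %in% colnames(s), logical(1))]
        if (length(twoGrp)) {
            vd <- volcanoData(stats[utils::head(twoGrp, 4L)],
                              metric = sg$metric, threshold = sg$threshold,
                              fcMin = sg$fc_min, test = sg$test)
            writeCsv(vd, file.path(dST, "volcano_data.csv"))
            if (canPlot(config)) {
                p <- ggplot2::ggplot(vd, ggplot2::aes(
                        .data$log2fc, .data$neg_log10,
                        colour = .data$significant)) +
                    ggplot2::geom_point(alpha = 0.6) +
                    ggplot2::facet_wrap(~comparison) +
                    ggplot2::theme_bw() +
                    ggplot2::labs(x = "log2 fold change",
                                  y = sprintf("-log10(%s)", sg$metric))
                ggplot2::ggsave(file.path(dST, "volcano.png"), p,
                                width = 7, height = 5, dpi = 120)
            }
        }
        results$stats <- stats
        results$significant <- sigLists
        log <- c(log, sprintf("differential: %d comparison(s), tests: %s",
                              length(stats),
                              paste(config$tests, collapse = ", ")))
    }

    ## --- annotation (site translation) --------------------------------
    if ("annotation" %in% steps) {
        dAN <- file.path(out, "Annotation")
        dir.create(dAN, showWarnings = FALSE)
        pairing <- utils::read.csv(config$knowledge$pairing,
                                   stringsAsFactors = FALSE)
        tr <- translateSites(set, config$knowledge$fasta, pairing)
        writeCsv(tr, file.path(dAN, "site_translation.csv"))
        results$annotation <- tr
        log <- c(log, sprintf("annotation: %d/%d sites mapped",
                              sum(tr$conservation != "unmapped"), nrow(tr)))
    }

    ## --- enrichment ---------------------------------------------------
    if ("enrichment" %in% steps && length(sigLists)) {
        dEN <- file.path(out, "Enrichment")
        dir.create(dEN, showWarnings = FALSE)
        sets <- readGMT(config$knowledge$gene_sets)
        info <- siteInfo(set)
        dataBg <- unique(info$accession)
        uniBg <- if (!is.null(config$knowledge$universal_background))
            readLines(config$knowledge$universal_background)
        else unique(c(dataBg, unlist(sets, use.names = FALSE)))
        for (nm in names(sigLists)) {
            sigProt <- unique(info$accession[match(sigLists[[nm]]$site_id,
                                                   info$site_id)])
            for (bg in c("dataset", "universal")) {
                bgIds <- if (bg == "dataset") dataBg else uniBg
                ora <- suppressWarnings(oraTest(sigProt, bgIds, sets))
                writeCsv(ora, file.path(dEN, sprintf(
                    "%s_ORA_%s_background.csv", nm, bg)))
                writeCsv(ora[ora$significant, , drop = FALSE],
                         file.path(dEN, sprintf(
                             "%s_ORA_%s_background_significant.csv", nm, bg)))
            }
        }
        log <- c(log, "enrichment: protein ORA (dataset + universal backgrounds)")
        if (!isFALSE(config$ptm_sea$enabled)) {
            dPS <- file.path(dEN, "PhosphoSite enrichment")
            dir.create(dPS, showWarnings = FALSE)
            sigs <- readSignatures(config$knowledge$signatures)
            sg <- config$significance
            for (nm in names(stats)) {
                st <- stats[[nm]]
                if (!"log2fc" %in% colnames(st)) next
                pcol <- paste0("p_", sg$test)
                if (!pcol %in% colnames(st)) next
                dCmp <- file.path(dPS, nm)
                dir.create(dCmp, showWarnings = FALSE)
                stat <- sign(st$log2fc) * -log10(st[[pcol]])
                names(stat) <- siteKey(
                    info$accession[match(st$site_id, info$site_id)],
                    info$position[match(st$site_id, info$site_id)],
                    info$residue[match(st$site_id, info$site_id)])
                stat <- stat[!is.na(stat)]
                stat <- stat[!duplicated(names(stat))]
                gmat <- matrix(stat, ncol = 1,
                               dimnames = list(names(stat), nm))
                writeGCT(gmat, file.path(dCmp, "input.gct"))
                sea <- suppressWarnings(ptmSEA(
                    stat, sigs, weight = config$ptm_sea$weight,
                    nPerm = config$ptm_sea$n_perm,
                    seed = config$seed))
                writeCsv(sea, file.path(dCmp, "signature_enrichment.csv"))
            }
            log <- c(log, "enrichment: site-signature enrichment on the full dataset")
        }
    }

    ## --- kinase -------------------------------------------------------
    if ("kinase" %in% steps && length(stats)) {
        dKA <- file.path(out, "Kinase Analysis")
        dir.create(dKA, showWarnings = FALSE)
        dNW <- file.path(out, "Network")
        dir.create(dNW, showWarnings = FALSE)
        lib <- readKinaseLibrary(config$knowledge$kinase_library)
        pwms <- buildPWM(lib, pseudocount = config$kinase$pseudocount)
        info <- siteInfo(set)
        wins <- stats::setNames(info$window, info$site_id)
        wins <- wins[grepl(validAAPattern, gsub("_", "", wins))]
        mp <- pwmPValues(pwms, wins, nDraws = config$kinase$n_draws,
                         seed = config$seed)
        kc <- config$kinase
        sg <- config$significance
        for (nm in names(stats)) {
            st <- stats[[nm]]
            if (!"log2fc" %in% colnames(st)) next
            pcol <- paste0("p_", sg$test)
            if (!pcol %in% colnames(st)) next
            fc <- stats::setNames(st$log2fc, st$site_id)
            sp <- stats::setNames(st[[pcol]], st$site_id)
            sw <- swingScores(mp$p, fc, sp, alphaPWM = kc$alpha_pwm,
                              alphaSite = kc$alpha_site,
                              pseudo = kc$pseudo, nPerm = kc$n_perm,
                              seed = config$seed)
            writeCsv(sw, file.path(dKA, paste0(nm, "_swingscore.csv")))
            ke <- kinaseEdges(mp$p, fc, sp, alphaPWM = kc$alpha_pwm,
                              alphaSite = kc$alpha_site)
            writeCsv(ke, file.path(dNW, paste0(
                nm, "_significant_kinaseNetwork.csv")))
            results$swing[[nm]] <- sw
        }
        log <- c(log, sprintf("kinase: %d PWM(s), %d data window(s)",
                              length(pwms), length(wins)))
    }

    ## --- network / hubs ----------------------------------------------
    if ("network" %in% steps && length(sigLists)) {
        dNW <- file.path(out, "Network")
        dir.create(dNW, showWarnings = FALSE)
        edges <- utils::read.delim(config$knowledge$edges,
                                   stringsAsFactors = FALSE)
        info <- siteInfo(set)
        nw <- config$network
        for (nm in names(sigLists)) {
            sigProt <- unique(info$accession[match(sigLists[[nm]]$site_id,
                                                   info$site_id)])
            if (length(sigProt) < 2L) next
            g <- buildNetwork(sigProt, edges, minConf = nw$min_conf)
            hubs <- findHubs(g, rule = nw$hub_rule)
            writeCsv(hubs, file.path(dNW, paste0(nm, "_degrees.csv")))
            hubIds <- hubs$protein[hubs$hub]
            if (length(hubIds)) {
                he <- hubEnrichment(hubIds, sigProt,
                                    unique(info$accession), edges,
                                    nControls = nw$n_controls,
                                    seed = config$seed,
                                    minConf = nw$min_conf)
                writeCsv(he, file.path(dNW, paste0(nm, "_hubs.csv")))
                results$hubs[[nm]] <- he
            }
        }
        log <- c(log, "network: interaction network + hub permutation test")
    }

    writeLines(log, file.path(out, "run_log.txt"))
    results$log <- log
    invisible(results)
}
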