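## Interaction-network construction, hub detection, and hub
## interaction-enrichment by control-network permutation.

#' Build the interaction network of a protein set
#'
#' Induced subgraph of the confidence-filtered edge table on the query
#' proteins. Only edges with confidence strictly greater than `minConf`
#' are kept; query proteins without any retained interaction stay in the
#' network with degree 0. Self-loops and duplicate edges are removed.
#'
#' @param query character vector of protein ids (e.g. the significant
#'   list's accessions).
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `confidence` (in `[0, 1]`).
#' @param minConf confidence cutoff (strict).
#' @return an [igraph::graph] with vertex attribute `name` and edge
#'   attribute `confidence`.
#' @export
buildNetwork <- function(query, edges, minConf = 0.4) {
    if (any(edges$confidence < 0 | edges$confidence > 1, na.rm = TRUE))
        stop("confidences must lie in [0, 1]")
    query <- unique(query)
    keep <- edges$confidence > minConf &
        edges$protein_a %in% query & edges$protein_b %in% query &
        edges$protein_a != edges$protein_b
    e <- edges[keep, , drop = FALSE]
    key <- paste(pmin(e$protein_a, e$protein_b),
                 pmax(e$protein_a, e$protein_b))
    e <- e[!duplicated(key), , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        e[, c("protein_a", "protein_b")], directed = FALSE,
        vertices = data.frame(name = sort(query)))
    igraph::E(g)$confidence <- e$confidence
    g
}

#' Detect hubs in a network
#'
#' Two rules: `"top10"` keeps the `ceiling(0.10 * n)` highest-degree nodes
#' plus all nodes tied with the boundary degree; `"mean_plus_sd"` keeps
#' nodes whose degree strictly exceeds the mean plus one sample standard
#' deviation.
#'
#' @param network an [igraph::graph] from [buildNetwork()].
#' @param rule `"mean_plus_sd"` or `"top10"`.
#' @return data.frame: `protein`, `degree`, `hub` (logical), sorted by
#'   degree descending.
#' @export
findHubs <- function(network, rule = c("mean_plus_sd", "top10")) {
    rule <- match.arg(rule)
    deg <- igraph::degree(network)
    if (!length(deg)) stop("network has no nodes")
    if (rule == "top10") {
        nTop <- ceiling(0.10 * length(deg))
        thr <- sort(deg, decreasing = TRUE)[nTop]
        hub <- deg >= thr
    } else {
        thr <- mean(deg) + stats::sd(deg)
        hub <- if (is.na(thr)) rep(FALSE, length(deg)) else deg > thr
    }
    out <- data.frame(protein = names(deg), degree = as.integer(deg),
                      hub = hub, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(-out$degree, out$protein), ]
}

#' Hub interaction enrichment by control networks
#'
#' For every hub, `nControls` control networks are built: each draws
#' `|query| - 1` proteins from the background without replacement, forces
#' the hub in, and records the hub's degree in the induced
#' confidence-filtered network. The p-value is
#' `(1 + #\{control degree >= observed\}) / (1 + nControls)`; BH FDR is
#' computed across the supplied hubs.
#'
#' @param hubs character vector of hub proteins (must be in `query`).
#' @param query the significant protein set defining the observed network.
#' @param background the protein universe to draw controls from (the
#'   measured dataset's proteins); must contain `query`.
#' @param edges confidence edge table (see [buildNetwork()]).
#' @param nControls number of control networks per hub.
#' @param seed RNG seed.
#' @param minConf confidence cutoff.
#' @return data.frame: `protein`, `observed`, `control_mean`, `p`, `fdr`;
#'   the full control-degree matrix is attached as attribute
#'   `"control_degrees"` (hubs x controls).
#' @export
hubEnrichment <- function(hubs, query, background, edges,
                          nControls = 1000L, seed = 1L, minConf = 0.4) {
    query <- unique(query); background <- unique(background)
    if (!all(hubs %in% query)) stop("every hub must be in the query set")
    if (length(setdiff(query, background)))
        stop("query must be a subset of the background")
    if (length(background) < length(query))
        stop("background smaller than the query set")
    e <- edges[edges$confidence > minConf &
               edges$protein_a != edges$protein_b, , drop = FALSE]
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    g <- buildNetwork(query, edges, minConf)
    obsDeg <- igraph::degree(g)
    ctrl <- matrix(0L, length(hubs), nControls,
                   dimnames = list(hubs, NULL))
    drawSize <- length(query) - 1L
    for (h in hubs) {
        nb <- unique(c(e$protein_b[e$protein_a == h],
                       e$protein_a[e$protein_b == h]))
        pool <- setdiff(background, h)
        for (i in seq_len(nControls)) {
            ctl <- if (drawSize) sample(pool, drawSize) else character()
            ctrl[h, i] <- sum(ctl %in% nb)
        }
    }
    obs <- as.integer(obsDeg[hubs])
    p <- (1 + rowSums(ctrl >= obs)) / (1 + nControls)
    out <- data.frame(protein = hubs, observed = obs,
                      control_mean = rowMeans(ctrl), p = p,
                      fdr = bhAdjust(p), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "control_degrees") <- ctrl
    out
}
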