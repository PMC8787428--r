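test_that("network construction applies the strict confidence cutoff", {
    ed <- data.frame(protein_a = c("A", "A", "B", "C"),
                     protein_b = c("B", "C", "C", "D"),
                     confidence = c(0.9, 0.9, 0.9, 0.4))
    g <- buildNetwork(c("A", "B", "C", "D"), ed, minConf = 0.4)
    deg <- igraph::degree(g)
    expect_equal(unname(deg[c("A", "B", "C")]), c(2, 2, 2))  # triangle
    expect_equal(unname(deg["D"]), 0)  # 0.4 edge excluded, node retained
    expect_error(buildNetwork("A", data.frame(protein_a = "A",
                                              protein_b = "B",
                                              confidence = 2)),
                 "\\[0, 1\\]")
    ## hand-counted degree sequence on a 6-node table with duplicates and
    ## a self-loop
    ed2 <- data.frame(
        protein_a = c("P1", "P1", "P2", "P2", "P3", "P5", "P1", "P4"),
        protein_b = c("P2", "P3", "P3", "P4", "P1", "P6", "P2", "P4"),
        confidence = c(0.9, 0.8, 0.7, 0.5, 0.8, 0.9, 0.9, 0.9))
    g2 <- buildNetwork(paste0("P", 1:6), ed2)
    expect_equal(unname(igraph::degree(g2)[paste0("P", 1:6)]),
                 c(2, 3, 2, 1, 1, 1))
})

test_that("hub rules match hand-computed thresholds", {
    ## degrees (1,1,1,5): mean 2, sample sd 2 -> only the 5 passes
    ed <- data.frame(
        protein_a = c("H", "H", "H", "H", "H", "N1"),
        protein_b = c("N1", "N2", "N3", "N4", "N5", "N2"),
        confidence = 0.9)
    g <- buildNetwork(c("H", paste0("N", 1:5)), ed)
    sub <- igraph::induced_subgraph(g, c("H", "N3", "N4", "N5"))
    expect_equal(sort(unname(igraph::degree(sub))), c(1, 1, 1, 3))
    h <- findHubs(g, "mean_plus_sd")
    ## degrees: H=5, N1=2, N2=2, N3=N4=N5=1: mean 2, sd ~1.55 -> H only
    expect_equal(h$protein[h$hub], "H")
    ## top10 on 20 nodes keeps 2 (plus boundary ties)
    ed20 <- data.frame(protein_a = rep("Q1", 10),
                       protein_b = paste0("Q", 2:11), confidence = 0.9)
    ed20 <- rbind(ed20, data.frame(protein_a = "Q2",
                                   protein_b = paste0("Q", 3:8),
                                   confidence = 0.9))
    g20 <- buildNetwork(paste0("Q", 1:20), ed20)
    h20 <- findHubs(g20, "top10")
    expect_equal(sum(h20$hub), 2L)
    expect_equal(h20$protein[h20$hub], c("Q1", "Q2"))
    ## all-equal degrees: no mean+sd hubs
    edEq <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"),
                       confidence = 0.9)
    hEq <- findHubs(buildNetwork(c("A", "B", "C", "D"), edEq),
                    "mean_plus_sd")
    expect_equal(sum(hEq$hub), 0L)
})

test_that("hub enrichment handles degenerate and constructed nulls", {
    ## background == query: the only control set is the query itself
    ed <- data.frame(protein_a = rep("H", 4),
                     protein_b = paste0("N", 1:4), confidence = 0.9)
    q <- c("H", paste0("N", 1:4))
    he <- hubEnrichment("H", q, q, ed, nControls = 100, seed = 1)
    expect_equal(he$p, 1)
    ## star graph where every background protein touches the hub: control
    ## degree always equals observed -> p = 1
    bg <- c(q, paste0("B", 1:4))
    edStar <- data.frame(protein_a = "H",
                         protein_b = setdiff(bg, "H"), confidence = 0.9)
    heStar <- hubEnrichment("H", q, bg, edStar, nControls = 200, seed = 2)
    expect_equal(heStar$p, 1)
    ## variant: background proteins NOT connected to the hub -> observed
    ## degree is maximal and beaten only by ties
    edQ <- data.frame(protein_a = "H", protein_b = paste0("N", 1:4),
                      confidence = 0.9)
    heQ <- hubEnrichment("H", q, bg, edQ, nControls = 200, seed = 3)
    expect_lt(heQ$p, 0.05)
    expect_error(hubEnrichment("H", q, q[1:3], ed), "subset")
    expect_error(hubEnrichment("Z", q, bg, ed), "hub")
})

test_that("sampled hub p matches exhaustive control-set enumeration", {
    set.seed(8)
    prots <- paste0("Q", 1:7)
    ed <- expand.grid(protein_a = prots, protein_b = prots,
                      stringsAsFactors = FALSE)
    ed <- ed[ed$protein_a < ed$protein_b, ]
    ed$confidence <- round(runif(nrow(ed)), 2)
    query <- paste0("Q", 1:4)
    he <- hubEnrichment("Q1", query, prots, ed, nControls = 10000,
                        seed = 2)
    nb <- ed[ed$confidence > 0.4 &
             (ed$protein_a == "Q1" | ed$protein_b == "Q1"), ]
    nbs <- setdiff(unique(c(nb$protein_a, nb$protein_b)), "Q1")
    obs <- sum(query[-1] %in% nbs)
    ctrl <- combn(setdiff(prots, "Q1"), 3)
    exact <- mean(apply(ctrl, 2, function(s) sum(s %in% nbs)) >= obs)
    expect_lt(abs(he$p - exact), 0.02)
    ## determinism: same seed, bit-identical result
    he2 <- hubEnrichment("Q1", query, prots, ed, nControls = 1000,
                         seed = 9)
    he3 <- hubEnrichment("Q1", query, prots, ed, nControls = 1000,
                         seed = 9)
    expect_identical(he2, he3)
})
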