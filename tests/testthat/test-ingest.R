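test_that("MaxQuant summed mode drops reverse/contaminant rows and sums multiplicities", {
    tf <- withr::local_tempfile(fileext = ".txt")
    writeToyMaxQuant(tf)
    ps <- parseMaxQuantSites(tf, "summed")
    expect_s4_class(ps, "PhosphoSet")
    expect_equal(nrow(ps), 2L)          # reverse + contaminant gone
    m <- intensities(ps)
    expect_equal(unname(m["P1;10;S", "A"]), 150)  # 100 + 50, missing as 0
    expect_true(is.na(m["P1;10;S", "B"]))         # all three missing
    expect_equal(unname(m["P2;20;T", "B"]), 60)
    expect_true(all(siteInfo(ps)$multiplicity == 0L))
})

test_that("MaxQuant expanded mode enumerates multiplicities and conserves totals", {
    tf <- withr::local_tempfile(fileext = ".txt")
    writeToyMaxQuant(tf)
    ex <- parseMaxQuantSites(tf, "expanded")
    ## hand enumeration of the toy file: P1 carries values in channels 1-2
    ## only; P2 in channels 1 (A,B), 2 (B) and 3 (B) -> 5 rows
    expect_setequal(rownames(ex),
                    c("P1;10;S;1", "P1;10;S;2", "P2;20;T;1", "P2;20;T;2",
                      "P2;20;T;3"))
    sm <- parseMaxQuantSites(tf, "summed")
    ## conservation: summed equals sum over expanded rows per site/sample
    exm <- intensities(ex)
    for (sid in rownames(sm)) {
        sub <- exm[startsWith(rownames(exm), paste0(sid, ";")), ,
                   drop = FALSE]
        tot <- colSums(sub, na.rm = TRUE)
        tot[colSums(!is.na(sub)) == 0L] <- NA_real_
        expect_equal(tot, intensities(sm)[sid, ])
    }
})

test_that("keep_contaminants retains flagged rows but never reverse rows", {
    tf <- withr::local_tempfile(fileext = ".txt")
    writeToyMaxQuant(tf)
    ps <- parseMaxQuantSites(tf, "keep_contaminants")
    expect_equal(nrow(ps), 3L)
    expect_true(any(siteInfo(ps)$contaminant))
    expect_false(any(grepl("REV__", siteInfo(ps)$accession)))
})

test_that("MaxQuant parser reports missing required columns by name", {
    tf <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("Proteins\tPosition", "P1\t10"), tf)
    expect_error(parseMaxQuantSites(tf), "Amino acid")
    tf2 <- withr::local_tempfile(fileext = ".txt")
    writeLines("Proteins\tPosition\tAmino acid\tSequence window", tf2)
    expect_error(parseMaxQuantSites(tf2), "empty")
})

test_that("generic parser ingests as-is, rejects bad windows and duplicate ids", {
    tf <- withr::local_tempfile(fileext = ".csv")
    df <- data.frame(accession = paste0("P", 1:5), position = 1:5 * 10,
                     residue = "S", window = toyWindow("S"),
                     s1 = 1:5, s2 = 6:10, s3 = 11:15, s4 = 16:20)
    write.csv(df, tf, row.names = FALSE)
    ps <- parseGenericSites(tf)
    expect_equal(dim(ps), c(5L, 4L))
    expect_true(all(siteInfo(ps)$multiplicity == 0L))

    df2 <- df; df2$window[2] <- "SHORT"
    write.csv(df2, tf, row.names = FALSE)
    expect_warning(ps2 <- parseGenericSites(tf), "rejected")
    expect_equal(nrow(ps2), 4L)

    df3 <- df; df3$accession <- "P1"; df3$position <- 10; df3$residue <- "S"
    write.csv(df3, tf, row.names = FALSE)
    expect_error(parseGenericSites(tf), "duplicate")

    df4 <- df; colnames(df4)[1] <- "prot"
    write.csv(df4, tf, row.names = FALSE)
    expect_error(parseGenericSites(tf), "accession")
})

test_that("design loading validates samples, groups and pairing", {
    ps <- toyPhosphoSet(nSamples = 8)
    tf <- withr::local_tempfile(fileext = ".csv")
    writeToyDesign(tf, paste0("S", 1:8), rep(1:2, each = 4))
    d <- readDesign(tf, ps)
    expect_s4_class(d, "GroupDesign")
    expect_length(comparisons(d), 1L)
    expect_equal(organism(d), "Mus musculus")
    expect_equal(groupSamples(d, "condition", 2), paste0("S", 5:8))

    ## unknown group in a comparison
    writeToyDesign(tf, paste0("S", 1:8), rep(1:2, each = 4),
                   comparisons = "condition,1;3,FALSE")
    expect_error(readDesign(tf, ps), "group")

    ## sample absent from the table
    writeToyDesign(tf, paste0("S", c(1:7, 99)), rep(1:2, each = 4))
    expect_error(readDesign(tf, ps), "absent")

    ## paired with unequal sizes
    writeToyDesign(tf, paste0("S", 1:7), c(1, 1, 1, 1, 2, 2, 2),
                   comparisons = "condition,1;2,TRUE")
    expect_error(readDesign(tf, ps), "paired")
    ## paired 4 vs 4 accepted
    writeToyDesign(tf, paste0("S", 1:8), rep(1:2, each = 4),
                   comparisons = "condition,1;2,TRUE")
    expect_s4_class(readDesign(tf, ps), "GroupDesign")
})

test_that("site tables round-trip exactly through CSV", {
    ps <- toyPhosphoSet(n = 8, nSamples = 5, seed = 42)
    m <- intensities(ps); m[2, 3] <- NA; intensities(ps) <- m
    tf <- withr::local_tempfile(fileext = ".csv")
    writeSiteTable(ps, tf)
    ps2 <- readSiteTable(tf)
    expect_identical(intensities(ps2), intensities(ps))
    expect_identical(siteInfo(ps2), siteInfo(ps))
})

test_that("PhosphoSet validity enforces the site invariants", {
    ps <- toyPhosphoSet()
    expect_error(PhosphoSet(matrix(1, 1, 1),
                            data.frame(accession = "P", position = 1,
                                       residue = "B",
                                       window = toyWindow("B"))),
                 "residue")
    expect_error(PhosphoSet(matrix(-1, 1, 1),
                            data.frame(accession = "P", position = 1,
                                       residue = "S",
                                       window = toyWindow("S"))),
                 "non-negative")
    expect_true(validObject(ps))
})
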