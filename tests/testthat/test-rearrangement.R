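test_that("consecutive pairs carry absolute TSS distances and trans flags", {
    df <- makeOrthoDf(c("a", "b"), "chr1", c(100, 500),
                      target_tss = c(2000, 2600))
    p <- consecutiveDistancePairs(readOrtho(df))
    expect_equal(nrow(p), 1L)
    expect_equal(p$ref_distance, 400)
    expect_equal(p$target_distance, 600)
    expect_true(p$same_target_seq)

    df2 <- makeOrthoDf(c("a", "b"), "chr1", c(100, 500),
                       target_seq = c("s1", "s2"))
    p2 <- consecutiveDistancePairs(readOrtho(df2))
    expect_false(p2$same_target_seq)
    expect_true(is.na(p2$target_distance))

    # single gene per sequence: no pairs
    df3 <- makeOrthoDf(c("a", "b"), c("chr1", "chr2"), c(100, 100),
                       target_id = c("t1", "t2"))
    expect_equal(nrow(consecutiveDistancePairs(readOrtho(df3))), 0L)
})

test_that("pair distances match a brute-force oracle on a 5-gene fixture", {
    set.seed(9)
    rtss <- sort(sample.int(1e6, 5))
    ttss <- sort(sample.int(1e6, 5))
    df <- makeOrthoDf(sprintf("g%d", 1:5), "chr1", rtss, target_tss = ttss)
    p <- consecutiveDistancePairs(readOrtho(df))
    expect_equal(nrow(p), 4L)
    for (i in 1:4) {
        expect_equal(p$ref_distance[i], abs(rtss[i + 1] - rtss[i]))
        expect_equal(p$target_distance[i], abs(ttss[i + 1] - ttss[i]))
    }
})

test_that("candidate classification separates single-gene events from block splits", {
    # gene X far from both neighbours on the target; neighbours stay close
    df <- makeOrthoDf(c("A", "X", "B", "C"), "chr1",
                      c(1e5, 2e5, 2.5e5, 3e5),
                      target_tss = c(1e5, 9e7, 1.5e5, 2e5))
    cand <- classifyCandidates(consecutiveDistancePairs(readOrtho(df)),
                               gapThresholdBp = 1e7)
    expect_true(all(cand$class == "single_gene_repositioning"))
    expect_equal(unique(na.omit(cand$repositioned_gene)), "X")

    # a run of genes jumping together is a block split at the boundary pair
    df2 <- makeOrthoDf(sprintf("g%02d", 1:16), "chr1", (1:16) * 1e5,
                       target_tss = c((1:8) * 1e5, 6e7 + (1:8) * 1e5))
    cand2 <- classifyCandidates(consecutiveDistancePairs(readOrtho(df2)),
                                gapThresholdBp = 1e7)
    expect_equal(nrow(cand2), 1L)
    expect_equal(cand2$class, "block_split")
    expect_equal(c(cand2$ref_gene_a, cand2$ref_gene_b), c("g08", "g09"))

    # nothing over the threshold: empty candidate list
    df3 <- makeOrthoDf(c("a", "b", "c"), "chr1", c(1e5, 2e5, 3e5))
    expect_equal(nrow(classifyCandidates(
        consecutiveDistancePairs(readOrtho(df3)))), 0L)

    expect_error(classifyCandidates(consecutiveDistancePairs(readOrtho(df3)),
                                    gapThresholdBp = 0), "positive")
})

test_that("identity mappings never produce a split (no false positives)", {
    for (s in 1:5) {
        g <- generateSplitGenomes(generatorSpec(seed = s, plan = "none"))
        tab <- filterOrthologs(g$table)
        call <- callClusterSplit(tab, g$cluster)
        expect_identical(splitStatus(call), "syntenic")
    }
})

test_that("planted splits are recovered with the true flank pair and span", {
    g <- generateSplitGenomes(generatorSpec(seed = 17))
    tab <- filterOrthologs(g$table)
    call <- callClusterSplit(tab, g$cluster)
    expect_identical(splitStatus(call), "split")
    expect_identical(breakpointFlanks(call), g$truth$flanks)
    expect_equal(call@insertSpanBp, g$truth$insert_span)
    expect_false(call@insertLowerBound)
    expect_equal(sum(call@subClusterSizes), length(call@clusterGenes))
    expect_equal(as.integer(call@subClusterSizes), c(16L, 9L))
    expect_match(call@insertSource, "^chrD:")
})

test_that("cross-scaffold splits use the foreign-neighbourhood rule", {
    g <- generateSplitGenomes(generatorSpec(seed = 23, crossScaffold = TRUE))
    tab <- filterOrthologs(g$table)
    call <- callClusterSplit(tab, g$cluster)
    expect_identical(splitStatus(call), "split")
    expect_identical(breakpointFlanks(call), g$truth$flanks)
    expect_true(call@insertLowerBound)
    expect_gt(call@insertSpanBp, 0)
    expect_match(call@insertSource, "^chrD:")
})

test_that("clusters with too few orthologues are unresolved with a reason", {
    df <- makeOrthoDf(sprintf("g%d", 1:6), "chr1", (1:6) * 1e5)
    tab <- readOrtho(df)
    cl <- clusterInterval("lonely", "chr1", 90000, 110000)  # 1 gene
    call <- callClusterSplit(tab, cl)
    expect_identical(splitStatus(call), "unresolved")
    expect_match(call@note, "fewer than 2")
})

test_that("insert span is exact by construction and translation-invariant", {
    # cluster of 6 genes split after gene 3 by 50 foreign genes 100 kb apart
    clTss <- c(1:3 * 1e5, 5.4e6 + (1:3) * 1e5)
    insTss <- 4e5 + (0:49) * 1e5
    df <- rbind(
        makeOrthoDf(sprintf("c%d", 1:6), "chr1", (1:6) * 1e5,
                    target_seq = "scafT", target_tss = clTss),
        makeOrthoDf(sprintf("f%02d", 1:50), "chr9", (1:50) * 1e5,
                    target_id = sprintf("tf%02d", 1:50),
                    target_seq = "scafT", target_tss = insTss))
    tab <- readOrtho(df)
    cl <- clusterInterval("cl", "chr1", 1e5, 6e5)
    call <- callClusterSplit(tab, cl, gapThresholdBp = 2e6)
    expect_identical(splitStatus(call), "split")
    expect_equal(call@insertSpanBp, 4.9e6)

    # uniform translation of all target coordinates leaves the span alone
    df2 <- df
    df2$target_tss <- df2$target_tss + 7.5e6
    call2 <- callClusterSplit(readOrtho(df2), cl, gapThresholdBp = 2e6)
    expect_equal(call2@insertSpanBp, 4.9e6)

    expect_error(measureInsert(callClusterSplit(tab,
        clusterInterval("syn", "chr9", 1e5, 50e5), gapThresholdBp = 2e6),
        tab), "split call")
})

test_that("swapping genome roles yields the same candidate set", {
    # symmetric fixture: one chromosome in each genome, one 60 Mb gap
    df <- makeOrthoDf(sprintf("g%02d", 1:16), "chr1", (1:16) * 1e5,
                      target_tss = c((1:8) * 1e5, 6e7 + (1:8) * 1e5))
    rows <- orthologRows(readOrtho(df))
    swapped <- rows
    names(swapped) <- names(rows)[c(6, 2, 7, 8, 9, 1, 3, 4, 5, 10)]
    cA <- classifyCandidates(consecutiveDistancePairs(readOrtho(df)))
    cB <- classifyCandidates(consecutiveDistancePairs(readOrtho(swapped)))
    expect_equal(nrow(cA), 1L)
    expect_equal(nrow(cB), 1L)
    expect_equal(cB$ref_gene_a, paste0("t", cA$ref_gene_a))
    expect_equal(cA$class, cB$class)
    # the gap simply changes axes: distances swap roles
    expect_equal(cB$ref_distance, cA$target_distance)
    expect_equal(cB$target_distance, cA$ref_distance)
})

test_that("synteny pairs reproduce diagonals, inversions and empty overlaps", {
    df <- makeOrthoDf(sprintf("g%02d", 1:20), "chr1", (1:20) * 1e5)
    tab <- readOrtho(df)
    sp <- syntenyPairs(tab)
    expect_equal(sp$ref_tss, sp$target_tss)   # identity: on the diagonal

    # planted inversion of 10 genes: anti-diagonal segment
    inv <- df
    inv$target_tss[6:15] <- rev(inv$target_tss[6:15])
    sp2 <- syntenyPairs(readOrtho(inv))
    seg <- sp2[6:15, ]
    expect_equal(seg$target_tss, rev(seg$ref_tss))
    expect_equal(stats::cor(seg$ref_tss, seg$target_tss), -1)

    dfB <- makeOrthoDf(sprintf("h%02d", 1:5), "chr2", (1:5) * 1e5)
    expect_warning(out <- syntenyPairs(tab, readOrtho(dfB)), "share no")
    expect_equal(nrow(out), 0L)

    # dual-view: shared genes paired across the two targets, ref order
    dfC <- df
    dfC$target_tss <- df$target_tss * 2
    both <- syntenyPairs(tab, readOrtho(dfC))
    expect_equal(both$target_tss, both$ref_tss * 2)
})
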