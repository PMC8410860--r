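test_that("bedGraph round trip drops malformed lines with a count", {
    f <- tempfile()
    writeLines(c("track type=bedGraph name=x", "# comment",
                 "chr1\t0\t100\t5", "chr1\t100\t200\t-1.5",
                 "chr1\tnot\tnumbers\t1", "chr1\t300\t250\t1",
                 "chr1 200 300 2.25"), f)
    bg <- readBedGraph(f)
    expect_equal(nrow(bg), 3L)
    expect_equal(attr(bg, "dropped"), 2L)
    expect_equal(bg$value, c(5, -1.5, 2.25))

    out <- tempfile()
    writeBedGraph(bg, out)
    again <- readBedGraph(out)
    expect_equal(again$start, bg$start)
    expect_equal(again$value, bg$value)
})

test_that("track binning apportions by overlap and conserves sums", {
    # an interval exactly covering one bin keeps its value under mean
    t1 <- data.frame(seq = "c", start = 0, end = 100, value = 5)
    expect_equal(binTrack(t1, 100, "mean")$value, 5)
    # straddling two bins equally with a constant value: both bins get it
    t2 <- data.frame(seq = "c", start = 50, end = 150, value = 4)
    expect_equal(binTrack(t2, 100, "mean")$value, c(4, 4))

    # per-base oracle on a 10-interval fixture (non-overlapping, as in
    # a well-formed bedGraph)
    set.seed(6)
    bounds <- sort(sample.int(1000, 20))
    iv <- data.frame(seq = "c", start = bounds[seq(1, 19, 2)],
                     end = bounds[seq(2, 20, 2)],
                     value = sample(-5:10, 10, TRUE))
    res <- 50
    bt <- binTrack(iv, res, "sum")
    base <- rep(0, max(iv$end))          # one slot per base (0-based index+1)
    cov <- rep(FALSE, max(iv$end))
    for (k in seq_len(nrow(iv))) {
        sel <- (iv$start[k] + 1):iv$end[k]
        base[sel] <- base[sel] + iv$value[k]
        cov[sel] <- TRUE
    }
    for (b in seq_len(nrow(bt))) {
        sel <- (bt$bin_start[b] + 1):bt$bin_end[b]
        sel <- sel[sel <= length(base)]
        expected <- if (any(cov[sel])) sum(base[sel]) else NA_real_
        expect_equal(bt$value[b], expected)
    }
    # total conservation under the sum aggregator, exactly
    expect_equal(sum(bt$value, na.rm = TRUE),
                 sum(iv$value * (iv$end - iv$start)))

    # mean aggregator equals the per-base mean over covered bases
    btm <- binTrack(iv, res, "mean")
    for (b in seq_len(nrow(btm))) {
        sel <- (btm$bin_start[b] + 1):btm$bin_end[b]
        sel <- sel[sel <= length(base)]
        if (any(cov[sel]))
            expect_equal(btm$value[b], sum(base[sel]) / sum(cov[sel]))
    }
})

test_that("GC track counts bases, skips Ns and is strand-symmetric", {
    library(Biostrings)
    s <- DNAStringSet(c(sq = paste0(strrep("GC", 50), strrep("AT", 50),
                                    strrep("N", 100))))
    g <- gcTrack(s, window = 100, smoothBinwidth = 2)
    expect_equal(g$value, c(100, 0, NA))
    expect_equal(attr(g, "smoothed")$sq, 50)

    set.seed(14)
    seq3 <- paste(sample(c("A", "C", "G", "T", "N"), 3000, TRUE,
                         prob = c(0.3, 0.2, 0.2, 0.25, 0.05)),
                  collapse = "")
    ss <- DNAStringSet(c(chr = seq3))
    g3 <- gcTrack(ss, window = 1000)
    # single-pass counting oracle
    ch <- strsplit(seq3, "")[[1]]
    for (b in 1:3) {
        w <- ch[((b - 1) * 1000 + 1):(b * 1000)]
        expect_equal(g3$value[b],
                     100 * sum(w %in% c("G", "C")) / sum(w != "N"))
    }
    rc <- Biostrings::reverseComplement(ss)
    names(rc) <- names(ss)
    expect_equal(sort(gcTrack(rc, window = 3000)$value),
                 sort(gcTrack(ss, window = 3000)$value))
    expect_error(gcTrack(DNAStringSet()), "empty")
})

test_that("rank test reports exact p, z, eta squared and Cohen's d", {
    r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$U, 0)
    expect_equal(r$p_two_sided, 0.1)
    expect_true(r$exact)
    expect_equal(r$z, (0 - 4.5) / sqrt(9 * 7 / 12), tolerance = 1e-12)
    expect_equal(r$eta_squared, r$z^2 / 6, tolerance = 1e-12)

    # identical samples: d = 0 and tiny effect
    r0 <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(r0$cohens_d, 0)
    expect_equal(r0$U, 8)          # mid-ranks under full ties
    expect_equal(r0$z, 0)

    rd <- mannWhitney(c(1, 2, 3), c(2, 3, 4))
    expect_equal(rd$cohens_d, -1)

    # z and eta^2 are invariant under strictly monotone transforms; d is not
    set.seed(3)
    x <- rnorm(8); y <- rnorm(9) + 0.8
    a <- mannWhitney(x, y)
    b <- mannWhitney(exp(x), exp(y))
    expect_equal(a$z, b$z)
    expect_equal(a$eta_squared, b$eta_squared)
    expect_equal(a$p_two_sided, b$p_two_sided)
    expect_false(isTRUE(all.equal(a$cohens_d, b$cohens_d)))

    expect_error(mannWhitney(1, c(1, 2)), "at least 2")
    expect_error(mannWhitney(c(2, 2), c(2, 2)), "zero variance")
})

test_that("exact rank p-values agree with enumeration on small samples", {
    set.seed(10)
    for (n1 in c(2, 4, 6)) for (n2 in c(3, 5)) {
        x <- rnorm(n1); y <- rnorm(n2) + 0.5
        r <- mannWhitney(x, y)
        expect_equal(r$p_two_sided, mwEnumOracle(x, y), tolerance = 1e-12)
    }
})

test_that("region-vs-flank tests run pooled, per-flank and parametric", {
    region <- list(seq = "chrS", start = 20e6 + 1, end = 27e6)
    flanks <- list(list(seq = "chrS", start = 1, end = 20e6),
                   list(seq = "chrS", start = 27e6 + 1, end = 47e6))
    tr <- generateTracks(generatorSpec(seed = 33, trackDelta = 3))
    bt <- binTrack(tr, 1e6)
    pooled <- regionVsFlankTest(bt, region, flanks)
    expect_equal(pooled$n1, 7)
    expect_equal(pooled$n2, 40)
    expect_lt(pooled$p_two_sided, 0.001)
    expect_gt(pooled$cohens_d, 1)
    expect_true(pooled$pooled_flanks)

    per <- regionVsFlankTest(bt, region, flanks, poolFlanks = FALSE)
    expect_named(per, c("upstream", "downstream"))
    expect_equal(per$upstream$n2, 20)

    tt <- regionVsFlankTest(bt, region, flanks, test = "t_test")
    expect_equal(tt$method, "t_test")
    expect_lt(tt$p_two_sided, 0.001)
    # effect sizes are reported by both branches
    expect_true(is.finite(tt$eta_squared) && is.finite(tt$cohens_d))

    empty <- list(seq = "chrZ", start = 1, end = 1e6)
    expect_error(regionVsFlankTest(bt, empty, flanks), "no non-missing")
})

test_that("CNE loss proportions and baseline contrasts behave", {
    pres <- data.frame(base = rep("present", 10),
                       sp = c(rep("lost", 3), rep("present", 7)))
    r <- cneLoss(pres, "base", windowSize = 5)
    expect_equal(unname(r$proportion), c(0, 0.3))

    allp <- data.frame(base = rep("present", 20), sp = rep("present", 20))
    r2 <- cneLoss(allp, "base", windowSize = 5)
    expect_equal(unname(r2$proportion), c(0, 0))
    expect_equal(r2$tests$p, 1)

    nod <- data.frame(base = rep("present", 4), sp = rep(NA_character_, 4))
    expect_warning(cneLoss(nod, "base", windowSize = 2), "no data")

    # planted differential loss (0.1 vs 0.4) is detected across seeds
    hits <- 0
    for (s in 1:20) {
        set.seed(s)
        n <- 20 * 50
        pr <- data.frame(
            base = ifelse(runif(n) < 0.1, "lost", "present"),
            oth = ifelse(runif(n) < 0.4, "lost", "present"))
        rr <- cneLoss(pr, "base", windowSize = 50)
        if (rr$tests$p < 0.05 && rr$tests$mean_diff > 0) hits <- hits + 1
    }
    expect_gte(hits, 19)
})
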