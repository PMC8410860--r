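em <- function(v, state = "raw") {
    if (is.null(rownames(v))) rownames(v) <- paste0("g", seq_len(nrow(v)))
    expressionMatrix(v, state = state)
}

test_that("rpkm follows its definition", {
    expect_equal(exprValues(rpkm(matrix(10, 1, 1,
        dimnames = list("g", "s")), 1000, 1e6))[1, 1], 10)
    expect_equal(exprValues(rpkm(matrix(0, 1, 1,
        dimnames = list("g", "s")), 500, 2e6))[1, 1], 0)
    # 3x2 fixture against hand arithmetic
    counts <- matrix(c(100, 200, 50, 80, 40, 10), 3, 2,
                     dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    len <- c(2000, 500, 1000)
    lib <- c(1e6, 2e6)
    r <- exprValues(rpkm(counts, len, lib))
    expect_equal(r, counts / (len / 1e3) / rep(lib / 1e6, each = 3))
    expect_error(rpkm(counts, c(0, 1, 1), lib), "positive")
    expect_error(rpkm(counts, len, c(0, 1)), "positive")
})

test_that("quantile normalization gives identical sorted columns", {
    m <- cbind(c(1, 2, 3), c(4, 5, 6))
    rownames(m) <- c("a", "b", "c")
    q <- exprValues(quantileNormalize(m))
    expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
    expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))

    single <- matrix(c(3, 1, 2), dimnames = list(c("a", "b", "c"), "s"))
    expect_equal(exprValues(quantileNormalize(single)), single)

    set.seed(5)
    for (i in 1:10) {
        m <- matrix(rexp(60), 12, 5, dimnames = list(paste0("g", 1:12), NULL))
        q <- exprValues(quantileNormalize(m))
        shared <- unname(sort(q[, 1]))
        for (j in 2:5) expect_equal(unname(sort(q[, j])), shared)
        # ranks preserved within each column
        for (j in 1:5) expect_equal(order(q[, j]), order(m[, j]))
    }
})

test_that("co-expression entries are Pearson correlations in gene order", {
    set.seed(2)
    v <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    v[2, ] <- v[1, ]          # duplicate gene
    v[3, ] <- -v[1, ] + 2     # negated gene
    v2 <- v - min(v)          # correlations are shift-invariant
    cm <- matrixValues(coexpressionMatrix(em(v2)))
    expect_equal(cm[1, 2], 1)
    expect_equal(cm[1, 3], -1)
    # full matrix against a direct covariance/sd computation
    for (i in 1:5) for (j in 1:5) {
        o <- mean((v2[i, ] - mean(v2[i, ])) * (v2[j, ] - mean(v2[j, ]))) /
            (sqrt(mean((v2[i, ] - mean(v2[i, ]))^2)) *
             sqrt(mean((v2[j, ] - mean(v2[j, ]))^2)))
        expect_equal(cm[i, j], o, tolerance = 1e-12)
    }
    expect_error(coexpressionMatrix(em(v2[, 1:2])), "3 samples")

    # zero-variance genes give missing entries and are reported
    vz <- v2; vz[4, ] <- 5
    cmz <- coexpressionMatrix(em(vz))
    expect_true(all(is.na(matrixValues(cmz)[4, -4])))
    expect_equal(attr(cmz, "zero_variance"), "g4")
})

test_that("stencil smoothing matches per-cell evaluation and conserves constants", {
    const <- matrix(3.7, 6, 6)
    expect_equal(smoothMatrix(const, iterations = 1), const)
    expect_equal(smoothMatrix(const, iterations = 3), const)
    one <- matrix(2.2, 1, 1)
    expect_equal(smoothMatrix(one, iterations = 3), one)

    set.seed(4)
    m <- matrix(rnorm(16), 4, 4)
    m <- (m + t(m)) / 2
    s1 <- smoothMatrix(m, iterations = 1)
    expect_equal(s1, stencilOracle(m), tolerance = 1e-14)
    s3 <- smoothMatrix(m, iterations = 3)
    expect_equal(s3, stencilOracle(stencilOracle(stencilOracle(m))),
                 tolerance = 1e-14)

    # variance never increases under smoothing
    big <- matrix(rnorm(400), 20, 20); big <- (big + t(big)) / 2
    v0 <- var(as.vector(big))
    for (k in 1:3) {
        big2 <- smoothMatrix(big, iterations = k)
        expect_lte(var(as.vector(big2)), v0 + 1e-12)
        v0 <- var(as.vector(big2))
    }

    # optional re-symmetrization returns a symmetric matrix
    r <- smoothMatrix(m, iterations = 1, resymmetrize = TRUE)
    expect_equal(r, t(r))
})

test_that("leading singular vector recovers structure and flags degeneracy", {
    v <- c(3, 1, 4, 1, 5)
    sv <- leadingSingularVector(tcrossprod(v))
    expect_equal(as.numeric(sv) / max(sv), v / max(v), tolerance = 1e-10)
    expect_false(attr(sv, "degenerate"))

    svI <- leadingSingularVector(diag(4))
    expect_true(attr(svI, "degenerate"))

    # two uncorrelated blocks: the leading vector lives on the stronger one
    b <- matrix(0, 10, 10)
    b[1:6, 1:6] <- 0.9; b[7:10, 7:10] <- 0.3
    diag(b) <- 1
    svB <- leadingSingularVector(b)
    expect_gt(mean(abs(svB[1:6])), mean(abs(svB[7:10])))

    expect_error(leadingSingularVector(matrix(NA_real_, 2, 2)), "no defined")
})

test_that("expression divergence hits its analytic endpoints", {
    set.seed(8)
    x <- matrix(rexp(35), 5, 7, dimnames = list(paste0("g", 1:5),
                                                paste0("t", 1:7)))
    d0 <- expressionDivergence(em(x), em(x))$d
    expect_equal(unname(d0), rep(0, 5), tolerance = 1e-12)

    y <- -x + max(x) + 1      # per-gene negation plus constant
    d2 <- expressionDivergence(em(x), em(y))$d
    expect_equal(unname(d2), rep(2, 5), tolerance = 1e-12)

    # invariance to positive-slope affine rescaling of either species
    y2 <- 3.2 * x + 7
    expect_equal(unname(expressionDivergence(em(x), em(y2))$d), rep(0, 5),
                 tolerance = 1e-12)

    # smoothed profile has n - w + 1 entries and equals the window means
    set.seed(9)
    xa <- matrix(rexp(210), 30, 7, dimnames = list(paste0("g", 1:30),
                                                   paste0("t", 1:7)))
    xb <- matrix(rexp(210), 30, 7, dimnames = dimnames(xa))
    pr <- expressionDivergence(em(xa), em(xb), binwidth = 10)
    expect_length(pr$smoothed, 21L)
    expect_equal(pr$smoothed[1], mean(pr$d[1:10]))
    expect_equal(pr$smoothed[21], mean(pr$d[21:30]))

    # mismatched tissue sets are an explicit error naming the difference
    colnames(xb) <- c(paste0("t", 1:6), "spleen")
    expect_error(expressionDivergence(em(xa), em(xb)), "spleen")
})

test_that("divergence-distance correlation behaves at its endpoints", {
    v <- 1:10
    r <- expressionVsBreakpoint(v, v * 2)
    expect_equal(r$rho, 1)
    expect_lt(r$p, 1e-10)
    expect_true(is.na(expressionVsBreakpoint(rep(1, 5), 1:5)$rho))
    expect_true(is.na(expressionVsBreakpoint(1:2, 1:2)$rho))

    # shuffled distances: correlation centred on zero
    set.seed(12)
    val <- rnorm(50); dist <- rnorm(50)
    rs <- replicate(300, expressionVsBreakpoint(val, sample(dist))$rho)
    expect_lt(abs(mean(rs)), 0.03)
})

test_that("relative expression rate is null-centred and guarded", {
    set.seed(21)
    base <- matrix(rexp(700), 100, 7, dimnames = list(paste0("g", 1:100),
                                                      paste0("t", 1:7)))
    noise <- function() base * matrix(exp(rnorm(700, sd = 0.2)), 100, 7)
    tEM <- em(noise()); rEM <- tEM; oEM <- em(noise())
    r0 <- relativeExpressionRate(tEM, rEM, oEM, B = 300, seed = 4)
    expect_equal(r0$z, 0, tolerance = 1e-9)   # test == reference exactly
    expect_equal(r0$delta, 0)

    expect_error(relativeExpressionRate(tEM, rEM, oEM, B = 1), "B >= 2")
    expect_error(relativeExpressionRate(tEM, rEM, oEM,
                                        window = paste0("g", 1:4), B = 10),
                 "fewer than 5")
    expect_error(relativeExpressionRate(tEM, rEM, oEM,
                                        window = "nope", B = 10), "absent")
})

test_that("running mean uses a trailing window of the stated length", {
    expect_equal(runningMean(1:10, 3), as.numeric(2:9))
    expect_equal(runningMean(c(4, 4, 4), 3), 4)
    expect_length(runningMean(1:5, 6), 0L)
    expect_equal(runningMean(1:4, 1), as.numeric(1:4))
})
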