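#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with gene rownames in
#'   reference-chromosome order and sample colnames.
#' @param state normalization state: `"raw"`, `"rpkm"` or `"quantile"`.
#' @return An [ExpressionMatrix-class].
#' @export
expressionMatrix <- function(values, state = "raw") {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    new("ExpressionMatrix", values = values, state = state)
}

#' Reads-per-kilobase-per-million normalization
#'
#' `value = count / (gene length / 1e3) / (library size / 1e6)`.
#'
#' @param counts genes x samples read-count matrix with gene rownames.
#' @param geneLengths gene lengths in bp (recycled along rows).
#' @param librarySizes total mapped reads per sample (along columns).
#' @return An [ExpressionMatrix-class] with state `"rpkm"`.
#' @examples
#' rpkm(matrix(10, 1, 1, dimnames = list("g", "s")), 1000, 1e6)
#' @export
rpkm <- function(counts, geneLengths, librarySizes) {
    counts <- as.matrix(counts)
    if (any(geneLengths <= 0)) stop("gene lengths must be positive")
    if (any(librarySizes <= 0)) stop("library sizes must be positive")
    v <- sweep(counts / (geneLengths / 1e3), 2L, librarySizes / 1e6, "/")
    expressionMatrix(v, state = "rpkm")
}

#' Quantile normalization across samples
#'
#' Forces every column onto the shared distribution of row-wise means of the
#' sorted columns, preserving within-column ranks; tied ranks receive the
#' mean of the corresponding sorted-mean values.
#'
#' @param x an [ExpressionMatrix-class] or plain matrix.
#' @return Same shape, state `"quantile"`; every output column is a
#'   permutation of one shared value vector.
#' @export
quantileNormalize <- function(x) {
    v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    q <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(q) <- dimnames(v)
    expressionMatrix(q, state = "quantile")
}

#' Gene-by-gene Pearson co-expression matrix
#'
#' Correlations across samples between all gene pairs, over the gene order
#' of the expression matrix (the reference chromosome order). Genes with
#' zero expression variance yield missing rows/columns, reported in the
#' `"zero_variance"` attribute.
#'
#' @param x an [ExpressionMatrix-class] with at least 3 samples.
#' @return A [SymMatrix-class] of kind `"coexpression"`.
#' @export
coexpressionMatrix <- function(x) {
    stopifnot(is(x, "ExpressionMatrix"))
    v <- exprValues(x)
    if (ncol(v) < 3L) stop("co-expression needs at least 3 samples per gene")
    sds <- apply(v, 1L, stats::sd)
    zero <- rownames(v)[sds == 0]
    cc <- suppressWarnings(stats::cor(t(v)))
    diag(cc)[!is.na(diag(cc))] <- 1
    out <- new("SymMatrix", values = cc, kind = "coexpression",
               smoothed = 0L)
    attr(out, "zero_variance") <- zero
    out
}

## one application of the 5-term smoothing stencil
## n[i,j] = (2 m[i,j] + m[i-1,j] + m[i,j-1] + m[i+1,j+1] + m[i,j+1]) / 6
## with absent/missing neighbours dropped and the divisor reduced to the
## sum of the remaining weights
.stencilOnce <- function(m) {
    n <- nrow(m)
    shift <- function(di, dj) {
        out <- matrix(NA_real_, n, n)
        ri <- seq_len(n) + di; cj <- seq_len(n) + dj
        ok_i <- ri >= 1 & ri <= n; ok_j <- cj >= 1 & cj <= n
        out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
        out
    }
    terms <- list(list(w = 2, v = m),
                  list(w = 1, v = shift(-1, 0)),
                  list(w = 1, v = shift(0, -1)),
                  list(w = 1, v = shift(1, 1)),
                  list(w = 1, v = shift(0, 1)))
    num <- matrix(0, n, n); den <- matrix(0, n, n)
    for (t in terms) {
        ok <- !is.na(t$v)
        num[ok] <- num[ok] + t$w * t$v[ok]
        den[ok] <- den[ok] + t$w
    }
    res <- num / den
    res[den == 0] <- NA_real_
    dimnames(res) <- dimnames(m)
    res
}

#' Stencil smoothing of a gene-ordered square matrix
#'
#' Applies, sequentially, the five-term smoothing stencil
#' `n[i,j] = (2 m[i,j] + m[i-1,j] + m[i,j-1] + m[i+1,j+1] + m[i,j+1]) / 6`.
#' At matrix borders the missing neighbours are dropped and the divisor
#' becomes the sum of the remaining weights, so a constant matrix is left
#' exactly unchanged. The stencil is asymmetric by construction (it reaches
#' `m[i+1,j+1]` but not `m[i+1,j]`); it is applied verbatim, with an
#' optional post-hoc re-symmetrization `(n + t(n)) / 2` (off by default).
#'
#' @param m a [SymMatrix-class] or square matrix.
#' @param iterations sequential applications (default 3).
#' @param resymmetrize average with the transpose after the last iteration.
#' @return Same type as the input; a [SymMatrix-class] gains `smoothed`
#'   iterations.
#' @export
smoothMatrix <- function(m, iterations = 3, resymmetrize = FALSE) {
    isS4 <- is(m, "SymMatrix")
    v <- if (isS4) matrixValues(m) else as.matrix(m)
    stopifnot(nrow(v) == ncol(v), iterations >= 0)
    for (k in seq_len(iterations)) v <- .stencilOnce(v)
    if (resymmetrize) v <- (v + t(v)) / 2
    if (isS4)
        new("SymMatrix", values = v, kind = m@kind,
            smoothed = m@smoothed + as.integer(iterations))
    else v
}

#' Leading singular vector (compartment score)
#'
#' First left singular vector of a gene-ordered co-expression or normalized
#' contact matrix, sign-oriented so the entry of largest magnitude is
#' positive. A localized run of high values marks a block of genes whose
#' co-regulation (or spatial contact) is self-contained relative to the rest
#' of the chromosome. Missing entries are imputed as 0 for the
#' decomposition.
#'
#' @param m a [SymMatrix-class] or square matrix.
#' @return Named numeric score vector, one entry per gene. Attribute
#'   `"degenerate"` is `TRUE` when the two leading singular values tie, in
#'   which case the vector is an arbitrary member of the tied subspace.
#' @export
leadingSingularVector <- function(m) {
    v <- if (is(m, "SymMatrix")) matrixValues(m) else as.matrix(m)
    if (all(is.na(v))) stop("matrix has no defined entries")
    v[is.na(v)] <- 0
    s <- svd(v)
    u <- s$u[, 1L]
    k <- which.max(abs(u))
    if (u[k] < 0) u <- -u
    names(u) <- rownames(v)
    attr(u, "degenerate") <-
        length(s$d) > 1L && (s$d[1] - s$d[2]) <= 1e-8 * max(s$d[1], 1e-300)
    u
}

#' Trailing running mean
#'
#' Simple moving average over `binwidth` consecutive values; the output has
#' `length(x) - binwidth + 1` entries, one per complete window.
#'
#' @param x numeric vector.
#' @param binwidth window size in entries.
#' @return Numeric vector of window means (empty when `x` is shorter than
#'   the window).
#' @export
runningMean <- function(x, binwidth = 10) {
    stopifnot(binwidth >= 1)
    if (length(x) < binwidth) return(numeric(0))
    as.numeric(igraph::running_mean(x, binwidth))
}

.matchTissues <- function(x, y, tissues = NULL) {
    vx <- exprValues(x); vy <- exprValues(y)
    if (is.null(tissues)) {
        if (!identical(colnames(vx), colnames(vy)))
            stop("tissue sets differ; only in x: ",
                 paste(setdiff(colnames(vx), colnames(vy)), collapse = ","),
                 "; only in y: ",
                 paste(setdiff(colnames(vy), colnames(vx)), collapse = ","),
                 ". Pass an explicit `tissues` matching.")
        tissues <- data.frame(x = colnames(vx), y = colnames(vy))
    }
    if (!all(tissues$x %in% colnames(vx)) ||
        !all(tissues$y %in% colnames(vy)))
        stop("tissue matching names columns absent from the matrices")
    if (nrow(tissues) < 3L) stop("need at least 3 matched tissues")
    if (!identical(rownames(vx), rownames(vy)))
        stop("gene sets/order differ between the two matrices")
    list(x = vx[, tissues$x, drop = FALSE],
         y = vy[, tissues$y, drop = FALSE])
}

#' Cross-species expression divergence profile
#'
#' Per-gene divergence `d_i = 1 - cor(x_i, y_i)` between the two species'
#' expression profiles across matched tissues (`d_i` in `[0, 2]`), with a
#' trailing running-mean smoothing along the reference gene order and,
#' optionally, each gene's distance to the nearest rearrangement breakpoint.
#'
#' @param x,y [ExpressionMatrix-class] objects over the same genes in the
#'   same (reference) order.
#' @param tissues optional `data.frame(x, y)` matching column names of `x`
#'   to column names of `y`; required whenever the column names differ.
#' @param binwidth running-mean window in genes (default 10).
#' @param positions optional per-gene TSS positions (bp) for breakpoint
#'   distances.
#' @param breakpoints optional breakpoint positions (bp).
#' @return list of class `DivergenceProfile`: `d` (named per-gene
#'   divergence), `smoothed` (length `n - binwidth + 1`), `binwidth`,
#'   `distance` (bp to nearest breakpoint, or `NULL`).
#' @export
expressionDivergence <- function(x, y, tissues = NULL, binwidth = 10,
                                 positions = NULL, breakpoints = NULL) {
    m <- .matchTissues(x, y, tissues)
    d <- 1 - vapply(seq_len(nrow(m$x)), function(i)
        suppressWarnings(stats::cor(m$x[i, ], m$y[i, ])), numeric(1))
    names(d) <- rownames(m$x)
    dist <- NULL
    if (!is.null(positions) && !is.null(breakpoints) && length(breakpoints))
        dist <- vapply(positions,
                       function(p) min(abs(p - breakpoints)), numeric(1))
    structure(list(d = d, smoothed = runningMean(d[!is.na(d)], binwidth),
                   binwidth = binwidth, distance = dist),
              class = "DivergenceProfile")
}

#' Correlate a per-gene value with distance to the nearest breakpoint
#'
#' Pearson correlation (with the two-sided t-distribution p-value) between a
#' per-gene statistic — divergence or mean expression — and the gene's
#' distance to the nearest rearrangement breakpoint.
#'
#' @param values per-gene numeric vector, or a `DivergenceProfile` (its `d`
#'   and stored distances are used).
#' @param distances per-gene distance to the nearest breakpoint (bp);
#'   ignored when `values` is a profile carrying distances.
#' @return list `rho`, `p`, `n`. With fewer than 3 complete pairs or
#'   zero-variance input, `rho` and `p` are `NA` and `reason` says why.
#' @export
expressionVsBreakpoint <- function(values, distances = NULL) {
    if (inherits(values, "DivergenceProfile")) {
        if (is.null(distances)) distances <- values$distance
        values <- values$d
    }
    ok <- is.finite(values) & is.finite(distances)
    v <- values[ok]; d <- distances[ok]
    if (length(v) < 3L)
        return(list(rho = NA_real_, p = NA_real_, n = length(v),
                    reason = "fewer than 3 genes with defined distances"))
    if (stats::sd(v) == 0 || stats::sd(d) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = length(v),
                    reason = "zero-variance input"))
    ct <- stats::cor.test(v, d, method = "pearson")
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(v))
}

#' Lineage-specific relative expression-rate contrast
#'
#' Simplified relative-rate test of expression divergence over a gene
#' window: with `D(a, b)` the mean over genes of `1 - cor(a_i, b_i)` across
#' matched tissues, the contrast is `Delta = D(test, outgroup) -
#' D(reference, outgroup)`. The standard error of `Delta` is estimated by a
#' seeded bootstrap over genes and the result reported as `Z = Delta / SE`
#' with a two-sided normal p-value. This is the mean-divergence contrast
#' only, labelled simplified; no trait-evolution model is fitted.
#'
#' @param test,reference,outgroup [ExpressionMatrix-class] objects over the
#'   same genes and matched tissues (identical column names).
#' @param window gene ids or indices restricting the contrast (default: all
#'   genes); at least 5 genes.
#' @param B bootstrap replicates over genes (default 1000; at least 2).
#' @param seed RNG seed for the bootstrap.
#' @return list `z`, `p`, `delta`, `se`, `d_test`, `d_reference`, `n_genes`,
#'   `B`.
#' @export
relativeExpressionRate <- function(test, reference, outgroup, window = NULL,
                                   B = 1000, seed = NULL) {
    if (B < 2) stop("bootstrap needs B >= 2 replicates")
    mt <- .matchTissues(test, outgroup)
    mr <- .matchTissues(reference, outgroup)
    genes <- rownames(mt$x)
    if (is.null(window)) window <- genes
    idx <- if (is.character(window)) match(window, genes) else as.integer(window)
    if (anyNA(idx)) stop("window names genes absent from the matrices")
    if (length(idx) < 5L)
        stop("gene window has fewer than 5 genes; refusing the contrast")
    dvec <- function(a, b) 1 - vapply(idx, function(i)
        suppressWarnings(stats::cor(a[i, ], b[i, ])), numeric(1))
    dT <- dvec(mt$x, mt$y)
    dR <- dvec(mr$x, mr$y)
    ok <- is.finite(dT) & is.finite(dR)
    dT <- dT[ok]; dR <- dR[ok]
    if (length(dT) < 5L) stop("fewer than 5 genes with defined divergence")
    delta <- mean(dT) - mean(dR)
    if (!is.null(seed)) set.seed(seed)
    n <- length(dT)
    boot <- vapply(seq_len(B), function(b) {
        s <- sample.int(n, n, replace = TRUE)
        mean(dT[s]) - mean(dR[s])
    }, numeric(1))
    se <- stats::sd(boot)
    z <- if (se > 0) delta / se else 0
    list(z = z, p = 2 * stats::pnorm(-abs(z)), delta = delta, se = se,
         d_test = mean(dT), d_reference = mean(dR), n_genes = n, B = B)
}
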