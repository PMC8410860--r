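## lambda-transformed Brownian covariance: off-diagonals scaled by lambda
.lambdaCov <- function(C, lambda) {
    V <- lambda * C
    diag(V) <- diag(C)
    V
}

.isPD <- function(V) {
    !inherits(tryCatch(chol(V), error = function(e) e), "error")
}

## largest lambda keeping the transformed covariance positive-definite.
## The PD set in lambda is an interval, so bisection is valid.
.lambdaMaxC <- function(C, cap = 1e3, tol = 1e-6) {
    if (!.isPD(.lambdaCov(C, 1))) {
        lo <- 0; hi <- 1
    } else {
        hi <- 1
        while (hi < cap && .isPD(.lambdaCov(C, hi * 2))) hi <- hi * 2
        if (hi >= cap) return(cap)
        lo <- hi; hi <- hi * 2
    }
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (.isPD(.lambdaCov(C, mid))) lo <- mid else hi <- mid
    }
    lo
}

#' Upper bound of Pagel's lambda for a tree
#'
#' Largest lambda for which the lambda-transformed among-tip Brownian
#' covariance stays positive-definite, found numerically. For ultrametric
#' trees this exceeds 1 (so estimates above 1 are admissible); for
#' non-ultrametric trees it may fall below 1.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return Numeric bound (capped at 1000).
#' @export
lambdaUpperBound <- function(tree) {
    .lambdaMaxC(ape::vcv(tree))
}

.profileLogLik <- function(C, x, lambda) {
    V <- .lambdaCov(C, lambda)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    n <- length(x)
    Vi <- chol2inv(L)
    one <- rep(1, n)
    mu <- sum(Vi %*% x) / sum(Vi)
    r <- x - mu
    s2 <- drop(crossprod(r, Vi %*% r)) / n
    if (s2 <= 0) return(list(ll = -Inf))
    logdet <- 2 * sum(log(diag(L)))
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
    list(ll = ll, mu = mu, s2 = s2)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the multivariate-normal Brownian model whose among-tip covariance
#' has off-diagonal entries (shared path lengths) scaled by lambda. The
#' root state and Brownian rate are profiled analytically; lambda is
#' optimized by bounded scalar search (tolerance 1e-8) on
#' `[0, lambdaUpperBound(tree)]`, restarted on each half of the interval
#' and compared against the endpoints and lambda = 1, since the profile can
#' be bimodal near the bound. Lambda near 1 means trait similarity tracks
#' phylogeny as Brownian motion predicts; near 0, no phylogenetic signal.
#'
#' @param tree an [ape::phylo] tree (>= 4 tips, positive root-to-tip
#'   depths). Non-ultrametric trees are accepted with a warning that the
#'   admissible upper bound may fall below 1.
#' @param traits named numeric vector (names = tip labels), e.g. log10 body
#'   mass.
#' @return A [LambdaEstimate-class]. On a star phylogeny the likelihood is
#'   flat in lambda and the estimate is flagged non-identifiable
#'   (`lambda = NA`).
#' @examples
#' set.seed(1)
#' tr <- ape::rcoal(20)
#' x <- simulateBMTraits(tr, sigma2 = 1, seed = 1)
#' pagelsLambda(tr, x)
#' @export
pagelsLambda <- function(tree, traits) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(names(traits)))
        stop("traits must be named by tip label")
    miss <- setdiff(names(traits), tree$tip.label)
    if (length(miss))
        stop("trait species absent from the tree: ",
             paste(miss, collapse = ", "))
    tree <- ape::keep.tip(tree, names(traits))
    if (ape::Ntip(tree) < 4L) stop("lambda estimation needs >= 4 tips")
    C <- ape::vcv(tree)
    x <- as.numeric(traits[rownames(C)])
    if (any(diag(C) <= 0))
        stop("non-positive root-to-tip depth for tip(s): ",
             paste(rownames(C)[diag(C) <= 0], collapse = ", "))
    ## duplicate tips at zero phylogenetic distance make C singular
    D2 <- outer(diag(C), diag(C), "+") - 2 * C
    diag(D2) <- Inf
    if (any(D2 <= 1e-12)) {
        ij <- which(D2 <= 1e-12, arr.ind = TRUE)[1, ]
        stop("tips at zero phylogenetic distance: ",
             rownames(C)[ij[1]], ", ", rownames(C)[ij[2]])
    }
    offmax <- max(abs(C[upper.tri(C)]))
    if (offmax <= 1e-12 * max(diag(C))) {
        fit0 <- .profileLogLik(C, x, 0)
        return(new("LambdaEstimate", lambda = NA_real_, sigma2 = fit0$s2,
                   mu = fit0$mu, logLik = fit0$ll, lambdaMax = Inf,
                   convergence = TRUE, identifiable = FALSE))
    }
    if (!isTRUE(all.equal(max(diag(C)), min(diag(C)),
                          tolerance = 1e-6)))
        warning("non-ultrametric tree: the admissible lambda upper bound ",
                "may fall below 1")
    lmax <- .lambdaMaxC(C)
    f <- function(l) .profileLogLik(C, x, l)$ll
    eps <- min(1e-9, lmax * 1e-9)
    hi <- lmax - eps
    cand <- list()
    for (iv in list(c(0, hi), c(0, hi / 2), c(hi / 2, hi)))
        cand <- c(cand, list(stats::optimize(f, iv, maximum = TRUE,
                                             tol = 1e-8)))
    lams <- c(vapply(cand, `[[`, 0, "maximum"), 0, min(1, hi), hi)
    lls <- c(vapply(cand, `[[`, 0, "objective"), f(0), f(min(1, hi)), f(hi))
    best <- which.max(lls)
    lhat <- lams[best]
    fit <- .profileLogLik(C, x, lhat)
    new("LambdaEstimate", lambda = lhat, sigma2 = fit$s2, mu = fit$mu,
        logLik = fit$ll, lambdaMax = lmax,
        convergence = is.finite(fit$ll), identifiable = TRUE)
}

#' Simulate Brownian traits on a tree
#'
#' One multivariate-normal draw with covariance `sigma2 * C_lambda`, where
#' `C_lambda` is the shared-path-length matrix with off-diagonals scaled by
#' `lambda` — the generating model whose parameters [pagelsLambda()]
#' recovers.
#'
#' @param tree an [ape::phylo] tree with finite branch lengths.
#' @param sigma2 Brownian rate (>= 0; 0 returns the root value at every
#'   tip).
#' @param rootValue trait value at the root.
#' @param lambda covariance scaling in `[0, lambdaUpperBound(tree)]`.
#' @param seed RNG seed for reproducibility.
#' @return Named numeric vector of tip trait values.
#' @export
simulateBMTraits <- function(tree, sigma2 = 1, rootValue = 0, lambda = 1,
                             seed = NULL) {
    stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
    C <- ape::vcv(tree)
    n <- nrow(C)
    if (sigma2 == 0)
        return(stats::setNames(rep(rootValue, n), rownames(C)))
    if (lambda < 0 || (lambda > 1 && !.isPD(.lambdaCov(C, lambda))))
        stop("lambda outside [0, lambdaUpperBound(tree)]")
    V <- sigma2 * .lambdaCov(C, lambda)
    L <- tryCatch(chol(V), error = function(e)
        stop("transformed covariance not positive-definite"))
    if (!is.null(seed)) set.seed(seed)
    x <- rootValue + drop(crossprod(L, stats::rnorm(n)))
    stats::setNames(x, rownames(C))
}
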