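#' @import methods
NULL

## canonical column set of the internal orthologue table representation
.ORTHO_COLS <- c("ref_gene_id", "ref_symbol", "ref_seq", "ref_tss",
                 "ref_strand", "target_gene_id", "target_seq", "target_tss",
                 "target_strand", "homology_type")

#' OrthologTable: paired gene orders of two genomes
#'
#' Ordered records of reference-genome genes together with the coordinates of
#' their orthologues in a target genome, as exported from a biomart-style
#' orthologue query. Rows are kept sorted by reference sequence name and
#' transcription start site (TSS) so that consecutive rows are consecutive
#' genes on the reference.
#'
#' @slot refSpecies,targetSpecies species labels.
#' @slot rows `data.frame` with columns `ref_gene_id`, `ref_symbol`,
#'   `ref_seq`, `ref_tss`, `ref_strand`, `target_gene_id`, `target_seq`,
#'   `target_tss`, `target_strand`, `homology_type`. Coordinates are 1-based
#'   TSS positions in bp.
#' @slot report list of parse/filter bookkeeping: counts of dropped rows and
#'   the offending identifiers or lines.
#'
#' @aliases OrthologTable-class
#' @exportClass OrthologTable
setClass("OrthologTable",
    representation(refSpecies = "character", targetSpecies = "character",
                   rows = "data.frame", report = "list"))

setValidity("OrthologTable", function(object) {
    r <- object@rows
    miss <- setdiff(.ORTHO_COLS, names(r))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(r)) {
        if (any(!is.finite(r$ref_tss)) || any(!is.finite(r$target_tss)))
            return("non-finite TSS coordinates")
        if (any(r$ref_tss < 1) || any(r$target_tss < 1))
            return("TSS coordinates must be >= 1 (1-based)")
        if (any(!nzchar(r$ref_seq)) || any(!nzchar(r$target_seq)))
            return("empty sequence names")
        o <- order(r$ref_seq, r$ref_tss, r$ref_gene_id)
        if (!identical(o, seq_len(nrow(r))))
            return("rows are not sorted by (ref_seq, ref_tss)")
    }
    TRUE
})

#' SplitCall: verdict on a named gene cluster
#'
#' Result of testing whether a reference gene cluster is contiguous
#' (syntenic) in a target genome, interrupted by a block of genes orthologous
#' to another reference locus (split), or unresolvable on a fragmented
#' assembly.
#'
#' @slot clusterName cluster label.
#' @slot status one of `"syntenic"`, `"split"`, `"unresolved"`.
#' @slot breakpointFlanks the two cluster genes flanking the breakpoint, in
#'   reference order; `character(0)` unless split.
#' @slot insertSource description of the reference locus whose orthologues
#'   interpose between the sub-clusters ("" if none).
#' @slot insertSpanBp target-genome span (bp) of the interposed foreign
#'   block; 0 when syntenic, `NA` until [measureInsert()] completes it.
#' @slot insertLowerBound `TRUE` when the span is only a lower bound (foreign
#'   block truncated by a scaffold end or sub-clusters on different
#'   scaffolds).
#' @slot subClusterSizes mapped-gene counts on each side of the breakpoint.
#' @slot clusterGenes ids of the cluster genes mapped in the table, in
#'   reference order.
#' @slot note free-text reason (used for unresolved calls).
#'
#' @aliases SplitCall-class
#' @exportClass SplitCall
setClass("SplitCall",
    representation(clusterName = "character", status = "character",
                   breakpointFlanks = "character", insertSource = "character",
                   insertSpanBp = "numeric", insertLowerBound = "logical",
                   subClusterSizes = "integer", clusterGenes = "character",
                   note = "character"))

setValidity("SplitCall", function(object) {
    if (!object@status %in% c("syntenic", "split", "unresolved"))
        return("status must be syntenic, split or unresolved")
    if (object@status == "split") {
        if (length(object@breakpointFlanks) != 2L)
            return("split call needs two breakpoint flank genes")
        if (sum(object@subClusterSizes) != length(object@clusterGenes))
            return("sub-cluster sizes must sum to the mapped cluster size")
    }
    TRUE
})

#' ExpressionMatrix: genes x samples expression values
#'
#' Non-negative expression values with genes in reference-chromosome order
#' (rows) and tissue/sample labels as columns. The `state` flag records the
#' normalization stage.
#'
#' @slot values numeric matrix, rownames = gene ids (reference order),
#'   colnames = sample labels.
#' @slot state one of `"raw"`, `"rpkm"`, `"quantile"`.
#'
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", state = "character"))

setValidity("ExpressionMatrix", function(object) {
    if (!object@state %in% c("raw", "rpkm", "quantile"))
        return("state must be raw, rpkm or quantile")
    v <- object@values
    if (is.null(rownames(v))) return("values must carry gene rownames")
    if (any(v < 0, na.rm = TRUE) && object@state != "quantile")
        return("negative expression values")
    TRUE
})

#' SymMatrix: square gene-ordered matrix
#'
#' A co-expression (Pearson correlation) or normalized contact matrix over a
#' fixed gene order, supporting stencil smoothing and singular-vector
#' compartment scoring. Smoothing uses an asymmetric stencil, so symmetry is
#' only required (within tolerance) before smoothing.
#'
#' @slot values square numeric matrix with identical row/col gene names.
#' @slot kind `"coexpression"` or `"contact"`.
#' @slot smoothed number of smoothing iterations already applied.
#'
#' @aliases SymMatrix-class
#' @exportClass SymMatrix
setClass("SymMatrix",
    representation(values = "matrix", kind = "character",
                   smoothed = "integer"))

setValidity("SymMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (!object@kind %in% c("coexpression", "contact"))
        return("kind must be coexpression or contact")
    if (object@smoothed == 0L) {
        d <- max(abs(v - t(v)), na.rm = TRUE)
        if (is.finite(d) && d > 1e-8)
            return("unsmoothed matrix must be symmetric")
        if (object@kind == "coexpression" && nrow(v)) {
            dg <- diag(v)
            if (any(abs(dg[!is.na(dg)] - 1) > 1e-8))
                return("co-expression diagonal must equal 1")
        }
    }
    TRUE
})

#' LambdaEstimate: maximum-likelihood phylogenetic signal
#'
#' Pagel's lambda fit of a continuous trait on a phylogeny, with the Brownian
#' rate and root state profiled analytically at the optimum.
#'
#' @slot lambda ML estimate of lambda on `[0, lambdaMax]`.
#' @slot sigma2 profiled Brownian rate at the optimum.
#' @slot mu profiled root state at the optimum.
#' @slot logLik log-likelihood at the optimum.
#' @slot lambdaMax upper bound used (largest lambda keeping the transformed
#'   covariance positive-definite, found numerically; may exceed 1).
#' @slot convergence `TRUE` when the bounded search converged.
#' @slot identifiable `FALSE` on a star phylogeny, where the likelihood is
#'   flat in lambda.
#'
#' @aliases LambdaEstimate-class
#' @exportClass LambdaEstimate
setClass("LambdaEstimate",
    representation(lambda = "numeric", sigma2 = "numeric", mu = "numeric",
                   logLik = "numeric", lambdaMax = "numeric",
                   convergence = "logical", identifiable = "logical"))

setValidity("LambdaEstimate", function(object) {
    if (object@identifiable &&
        (object@lambda < 0 || object@lambda > object@lambdaMax + 1e-8))
        return("lambda outside [0, lambdaMax]")
    TRUE
})

setMethod("show", "OrthologTable", function(object) {
    cat(sprintf("OrthologTable: %s -> %s, %d orthologue pairs\n",
                object@refSpecies, object@targetSpecies, nrow(object@rows)))
    cat(sprintf("  ref seqs: %d  target seqs: %d  homology: %s\n",
                length(unique(object@rows$ref_seq)),
                length(unique(object@rows$target_seq)),
                paste(unique(object@rows$homology_type), collapse = ",")))
    if (length(object@report))
        cat(sprintf("  parse report: %d dropped row(s)\n",
                    object@report$dropped %||% 0L))
})

setMethod("show", "SplitCall", function(object) {
    cat(sprintf("SplitCall '%s': %s\n", object@clusterName, object@status))
    if (object@status == "split") {
        cat(sprintf("  breakpoint flanks: %s | %s\n",
                    object@breakpointFlanks[1], object@breakpointFlanks[2]))
        cat(sprintf("  sub-clusters: %s genes; insert from %s, span %s bp%s\n",
                    paste(object@subClusterSizes, collapse = " + "),
                    object@insertSource,
                    format(object@insertSpanBp, big.mark = ","),
                    if (isTRUE(object@insertLowerBound)) " (lower bound)"
                    else ""))
    } else if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
                nrow(object@values), ncol(object@values), object@state))
})

setMethod("show", "SymMatrix", function(object) {
    cat(sprintf("SymMatrix (%s): %d x %d, %d smoothing iteration(s)\n",
                object@kind, nrow(object@values), ncol(object@values),
                object@smoothed))
})

setMethod("show", "LambdaEstimate", function(object) {
    cat(sprintf("Pagel's lambda = %.6g  (sigma2 = %.4g, mu = %.4g)\n",
                object@lambda, object@sigma2, object@mu))
    cat(sprintf("  logLik %.4f on [0, %.4g]%s%s\n", object@logLik,
                object@lambdaMax,
                if (object@convergence) "" else "  [not converged]",
                if (object@identifiable) "" else "  [non-identifiable]"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
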