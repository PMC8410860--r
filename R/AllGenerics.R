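#' Accessors for synsplit classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a synsplit object.
#' @return The slot contents: a `data.frame` of orthologue rows, a species
#'   label, a parse/filter report list, a numeric matrix of expression or
#'   correlation values, a normalization-state string, a split status, or the
#'   breakpoint flank gene pair.
#' @name accessors
#' @aliases orthologRows refSpecies targetSpecies parseReport exprValues
#'   exprState matrixValues splitStatus breakpointFlanks
#' @examples
#' tab <- .exampleOrthologTable()
#' head(orthologRows(tab))
#' refSpecies(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("orthologRows", function(x) standardGeneric("orthologRows"))
#' @rdname accessors
#' @export
setGeneric("refSpecies", function(x) standardGeneric("refSpecies"))
#' @rdname accessors
#' @export
setGeneric("targetSpecies", function(x) standardGeneric("targetSpecies"))
#' @rdname accessors
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))
#' @rdname accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname accessors
#' @export
setGeneric("splitStatus", function(x) standardGeneric("splitStatus"))
#' @rdname accessors
#' @export
setGeneric("breakpointFlanks", function(x) standardGeneric("breakpointFlanks"))

#' @rdname accessors
setMethod("orthologRows", "OrthologTable", function(x) x@rows)
#' @rdname accessors
setMethod("refSpecies", "OrthologTable", function(x) x@refSpecies)
#' @rdname accessors
setMethod("targetSpecies", "OrthologTable", function(x) x@targetSpecies)
#' @rdname accessors
setMethod("parseReport", "OrthologTable", function(x) x@report)
#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("exprState", "ExpressionMatrix", function(x) x@state)
#' @rdname accessors
setMethod("matrixValues", "SymMatrix", function(x) x@values)
#' @rdname accessors
setMethod("splitStatus", "SplitCall", function(x) x@status)
#' @rdname accessors
setMethod("breakpointFlanks", "SplitCall", function(x) x@breakpointFlanks)

#' @export
setMethod("length", "OrthologTable", function(x) nrow(x@rows))

#' Tiny built-in example table
#'
#' Three-gene identity mapping used in accessor examples.
#' @return An [OrthologTable-class] with three rows.
#' @keywords internal
#' @export
.exampleOrthologTable <- function() {
    g <- data.frame(ref_gene_id = c("g1", "g2", "g3"),
                    ref_symbol = c("A", "B", "C"),
                    ref_seq = "chr1", ref_tss = c(100, 500, 900),
                    ref_strand = "+",
                    target_gene_id = c("t1", "t2", "t3"),
                    target_seq = "scaf1", target_tss = c(100, 500, 900),
                    target_strand = "+", homology_type = "one2one",
                    stringsAsFactors = FALSE)
    new("OrthologTable", refSpecies = "refA", targetSpecies = "spB",
        rows = g, report = list(dropped = 0L))
}
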