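#' Column-name map for biomart-style orthologue exports
#'
#' Maps the canonical internal column names onto the header names of an
#' Ensembl biomart orthologue export. Override any entry to read other
#' dialects; `ref_symbol`, strand and `homology_type` entries are optional
#' in the file (homology type defaults to `one2one` when absent).
#'
#' @param target prefix used by biomart for the homologue columns, e.g.
#'   `"Naked mole-rat"`; ignored for entries you override explicitly.
#' @param ... canonical = file-column-name overrides.
#' @return Named character vector mapping canonical names to file columns.
#' @examples
#' biomartDialect(target = "Naked mole-rat")
#' @export
biomartDialect <- function(target = "Target", ...) {
    d <- c(ref_gene_id   = "Gene stable ID",
           ref_symbol    = "Gene name",
           ref_seq       = "Chromosome/scaffold name",
           ref_tss       = "Gene start (bp)",
           ref_strand    = "Strand",
           target_gene_id = paste(target, "gene stable ID"),
           target_seq    = paste(target, "chromosome/scaffold name"),
           target_tss    = paste(target, "chromosome/scaffold start (bp)"),
           target_strand = NA_character_,
           homology_type = paste(target, "homology type"))
    ov <- c(...)
    d[names(ov)] <- ov
    d
}

.normStrand <- function(s) {
    s <- as.character(s)
    out <- rep("unknown", length(s))
    out[s %in% c("+", "1", "+1")] <- "+"
    out[s %in% c("-", "-1", "−")] <- "-"
    out
}

## sort rows into canonical reference order; TSS ties break lexicographically
## on gene id (the input never states how equal-TSS genes were ordered)
.sortRef <- function(rows) {
    rows[order(rows$ref_seq, rows$ref_tss, rows$ref_gene_id), , drop = FALSE]
}

#' Read an orthologue coordinate table
#'
#' Parses a tab-separated biomart-style export of paired gene coordinates
#' into an [OrthologTable-class]. Malformed rows (non-numeric TSS, missing
#' sequence name, missing gene id) are dropped and counted in the parse
#' report. When a reference gene id appears on several rows, the row with
#' the smallest reference TSS is kept (deterministic and order-independent)
#' and the discarded ids are logged.
#'
#' @param path TSV file with a header row.
#' @param dialect named character vector mapping canonical column names to
#'   file header names; see [biomartDialect()]. Defaults to the canonical
#'   names themselves (`ref_gene_id`, `ref_seq`, `ref_tss`,
#'   `target_gene_id`, `target_seq`, `target_tss`, optional `ref_symbol`,
#'   `ref_strand`, `target_strand`, `homology_type`).
#' @param refSpecies,targetSpecies species labels stored on the object.
#' @return An [OrthologTable-class], rows sorted by reference position;
#'   `parseReport(x)` holds `dropped`, `rejected_lines` (first few),
#'   `duplicate_ref_ids`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(orthologRows(.exampleOrthologTable()), f, sep = "\t",
#'             quote = FALSE, row.names = FALSE)
#' tab <- readOrthologTable(f)
#' length(tab)
#' @export
readOrthologTable <- function(path, dialect = NULL, refSpecies = "reference",
                              targetSpecies = "target") {
    if (!file.exists(path)) stop("cannot read orthologue table: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "")
    canon <- .ORTHO_COLS
    if (is.null(dialect)) dialect <- stats::setNames(canon, canon)
    required <- c("ref_gene_id", "ref_seq", "ref_tss",
                  "target_gene_id", "target_seq", "target_tss")
    for (col in required) {
        fc <- dialect[[col]]
        if (is.null(fc) || is.na(fc) || !fc %in% names(raw))
            stop("required column '", col, "' (file header '", fc,
                 "') not found in ", path)
    }
    pick <- function(col, default = NA_character_) {
        fc <- if (col %in% names(dialect)) dialect[[col]] else col
        if (!is.na(fc) && fc %in% names(raw)) raw[[fc]]
        else rep(default, nrow(raw))
    }
    rows <- data.frame(
        ref_gene_id   = pick("ref_gene_id"),
        ref_symbol    = pick("ref_symbol", ""),
        ref_seq       = pick("ref_seq"),
        ref_tss       = suppressWarnings(as.numeric(pick("ref_tss"))),
        ref_strand    = .normStrand(pick("ref_strand", "unknown")),
        target_gene_id = pick("target_gene_id"),
        target_seq    = pick("target_seq"),
        target_tss    = suppressWarnings(as.numeric(pick("target_tss"))),
        target_strand = .normStrand(pick("target_strand", "unknown")),
        homology_type = pick("homology_type", "one2one"),
        stringsAsFactors = FALSE)
    rows$ref_symbol[is.na(rows$ref_symbol)] <- ""
    rows$homology_type[is.na(rows$homology_type) |
                       !nzchar(rows$homology_type)] <- "one2one"

    bad <- !is.finite(rows$ref_tss) | !is.finite(rows$target_tss) |
        is.na(rows$ref_seq) | !nzchar(rows$ref_seq) |
        is.na(rows$target_seq) | !nzchar(rows$target_seq) |
        is.na(rows$ref_gene_id) | !nzchar(rows$ref_gene_id) |
        is.na(rows$target_gene_id) | !nzchar(rows$target_gene_id)
    bad[!bad] <- rows$ref_tss[!bad] < 1 | rows$target_tss[!bad] < 1
    rejected <- utils::head(which(bad), 3L)
    rejLines <- if (length(rejected))
        paste0("line ", rejected + 1L, ": ",
               apply(raw[rejected, , drop = FALSE], 1L, paste,
                     collapse = "\t"))
    else character(0)
    rows <- rows[!bad, , drop = FALSE]
    if (!nrow(rows))
        stop("no valid rows in ", path, "; first rejected lines:\n",
             paste(rejLines, collapse = "\n"))

    ## duplicate reference ids: keep the smallest-TSS row
    rows <- rows[order(rows$ref_gene_id, rows$ref_tss,
                       rows$target_gene_id), , drop = FALSE]
    dupIdx <- duplicated(rows$ref_gene_id)
    dupIds <- unique(rows$ref_gene_id[dupIdx])
    rows <- rows[!dupIdx, , drop = FALSE]
    rows <- .sortRef(rows)
    rownames(rows) <- NULL

    new("OrthologTable", refSpecies = refSpecies,
        targetSpecies = targetSpecies, rows = rows,
        report = list(dropped = sum(bad), rejected_lines = rejLines,
                      duplicate_ref_ids = dupIds,
                      duplicates_removed = sum(dupIdx)))
}

#' Write an orthologue table in the canonical TSV dialect
#'
#' @param x an [OrthologTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOrthologTable <- function(x, path) {
    stopifnot(is(x, "OrthologTable"))
    utils::write.table(orthologRows(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Filter an orthologue table for synteny mapping
#'
#' Retains one-to-one orthologues only, then removes every row whose target
#' scaffold carries fewer than `minScaffoldGenes` retained genes (small
#' scaffolds carry no usable order information). The threshold applies to
#' target-genome scaffolds only; the reference is assumed chromosome-level.
#' Idempotent: filtering a filtered table changes nothing.
#'
#' @param x an [OrthologTable-class].
#' @param minScaffoldGenes minimum retained genes per target scaffold
#'   (default 5).
#' @return Filtered [OrthologTable-class]; the report gains
#'   `dropped_homology`, `dropped_scaffold`, `dropped_duplicate_target`.
#' @examples
#' filterOrthologs(.exampleOrthologTable(), minScaffoldGenes = 2)
#' @export
filterOrthologs <- function(x, minScaffoldGenes = 5) {
    stopifnot(is(x, "OrthologTable"), minScaffoldGenes >= 1)
    r <- orthologRows(x)
    keep <- r$homology_type == "one2one"
    nHom <- sum(!keep)
    r <- r[keep, , drop = FALSE]
    ## one2one implies unique targets, but enforce it for malformed inputs
    dupT <- duplicated(r$target_gene_id)
    r <- r[!dupT, , drop = FALSE]
    cnt <- table(r$target_seq)
    small <- names(cnt)[cnt < minScaffoldGenes]
    nScaf <- sum(r$target_seq %in% small)
    r <- r[!r$target_seq %in% small, , drop = FALSE]
    rownames(r) <- NULL
    rep <- x@report
    rep$dropped_homology <- nHom
    rep$dropped_duplicate_target <- sum(dupT)
    rep$dropped_scaffold <- nScaf
    new("OrthologTable", refSpecies = x@refSpecies,
        targetSpecies = x@targetSpecies, rows = r, report = rep)
}
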