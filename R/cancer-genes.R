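#' Read a cancer-gene annotation list
#'
#' Two-column TSV (gene symbol or id, role) with roles `TSG` and/or `POG`; a
#' gene may appear on one line per role, so dual-labelled genes are allowed
#' and counted in both tracks.
#'
#' @param path TSV file, no header required (a header line whose second
#'   field is not TSG/POG is skipped).
#' @return `data.frame(gene, label)` with one row per (gene, label).
#' @export
readGeneAnnotations <- function(path) {
    a <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("gene", "label"))
    a <- a[a$label %in% c("TSG", "POG"), , drop = FALSE]
    unique(a)
}

.matchLabels <- function(ids, annotations, label) {
    ann <- annotations$gene[annotations$label == label]
    hit <- ids %in% ann
    ## case-insensitive fallback for symbol-matched lists
    miss <- !hit
    hit[miss] <- tolower(ids[miss]) %in% tolower(ann)
    hit
}

#' Bin cancer-gene density along a genome
#'
#' Assigns each gene to one fixed-size bin by TSS and reports
#' tumour-suppressor (TSG) and proto-oncogene (POG) counts under both
#' normalizations: count divided by the genome-wide label total
#' (`*_frac_global`) and count divided by the genes in the bin
#' (`*_frac_local`, `NA` for empty bins). Bins are half-open internally, so
#' a gene exactly on a boundary belongs to the bin whose start it equals.
#'
#' @param genes `data.frame` with `gene_id`, `seq_name` (or `ref_seq`) and
#'   `tss` (or `ref_tss`); optionally `symbol`.
#' @param annotations from [readGeneAnnotations()]; matching is by gene id
#'   with a case-insensitive fallback, then by symbol if present.
#' @param binSize bin width in bp (default 5 Mb).
#' @return `data.frame(seq_name, bin_start, bin_end, gene_count, tsg_count,
#'   pog_count, tsg_frac_global, pog_frac_global, tsg_frac_local,
#'   pog_frac_local)`, bins tiling each sequence from position 1 to the last
#'   gene. Attribute `"dual_labelled"` lists genes carrying both labels;
#'   attribute `"unmatched"` the annotation entries never seen.
#' @export
binGeneDensity <- function(genes, annotations, binSize = 5e6) {
    stopifnot(binSize > 0)
    g <- .canonGenes(genes)
    isT <- .matchLabels(g$gene_id, annotations, "TSG") |
        (nzchar(g$symbol) & .matchLabels(g$symbol, annotations, "TSG"))
    isP <- .matchLabels(g$gene_id, annotations, "POG") |
        (nzchar(g$symbol) & .matchLabels(g$symbol, annotations, "POG"))
    totT <- sum(isT); totP <- sum(isP)
    out <- list()
    for (sq in unique(g$seq_name)) {
        sel <- g$seq_name == sq
        tss <- g$tss[sel]
        bin <- floor((tss - 1) / binSize)           # 0-based half-open bins
        nb <- max(bin) + 1L
        bcount <- tabulate(bin + 1L, nb)
        tcount <- tabulate(bin[isT[sel]] + 1L, nb)
        pcount <- tabulate(bin[isP[sel]] + 1L, nb)
        out[[sq]] <- data.frame(
            seq_name = sq,
            bin_start = (seq_len(nb) - 1L) * binSize + 1,
            bin_end = seq_len(nb) * binSize,
            gene_count = bcount, tsg_count = tcount, pog_count = pcount,
            tsg_frac_global = if (totT) tcount / totT else NA_real_,
            pog_frac_global = if (totP) pcount / totP else NA_real_,
            tsg_frac_local = ifelse(bcount > 0, tcount / bcount, NA_real_),
            pog_frac_local = ifelse(bcount > 0, pcount / bcount, NA_real_),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    dual <- g$gene_id[isT & isP]
    seen <- c(g$gene_id, g$symbol)
    attr(res, "dual_labelled") <- dual
    attr(res, "unmatched") <- setdiff(annotations$gene, seen)
    res
}

.canonGenes <- function(genes) {
    nm <- names(genes)
    gid <- genes[[if ("gene_id" %in% nm) "gene_id" else "ref_gene_id"]]
    sq <- genes[[if ("seq_name" %in% nm) "seq_name" else "ref_seq"]]
    tss <- genes[[if ("tss" %in% nm) "tss" else "ref_tss"]]
    sym <- if ("symbol" %in% nm) genes$symbol
           else if ("ref_symbol" %in% nm) genes$ref_symbol
           else rep("", length(gid))
    data.frame(gene_id = gid, symbol = sym, seq_name = sq, tss = tss,
               stringsAsFactors = FALSE)
}

#' Count labelled genes in a cluster, per sub-cluster after a split
#'
#' Without a split, returns one TSG/POG count for the cluster. With a split
#' call, the cluster's genes are partitioned at the breakpoint flanks (in
#' reference order) and counts are reported for each side, together with the
#' gene identity lists. Sub-cluster counts always sum to the whole-cluster
#' count.
#'
#' @param clusterGenes character vector of cluster gene ids/symbols in
#'   reference order.
#' @param annotations from [readGeneAnnotations()].
#' @param split optional [SplitCall-class]; its flank genes must be cluster
#'   members.
#' @return list with `tsg`, `pog` (total counts), and for a split
#'   `tsg_sides`, `pog_sides` (two counts each) plus `sides` (the gene id
#'   lists).
#' @export
clusterLabelCounts <- function(clusterGenes, annotations, split = NULL) {
    isT <- .matchLabels(clusterGenes, annotations, "TSG")
    isP <- .matchLabels(clusterGenes, annotations, "POG")
    res <- list(tsg = sum(isT), pog = sum(isP))
    if (is.null(split)) return(res)
    stopifnot(is(split, "SplitCall"))
    if (splitStatus(split) != "split") return(res)
    fl <- breakpointFlanks(split)
    i <- match(fl[1], clusterGenes)
    j <- match(fl[2], clusterGenes)
    if (is.na(i) || is.na(j))
        stop("breakpoint flank genes ", paste(fl, collapse = "/"),
             " are not members of the cluster")
    left <- seq_len(i)
    right <- setdiff(seq_along(clusterGenes), left)
    res$tsg_sides <- c(sum(isT[left]), sum(isT[right]))
    res$pog_sides <- c(sum(isP[left]), sum(isP[right]))
    res$sides <- list(clusterGenes[left], clusterGenes[right])
    res
}
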