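#' Distances between consecutive orthologous gene pairs
#'
#' For every pair of adjacent reference genes on the same reference sequence,
#' computes the distance between their TSSs on the reference and the distance
#' between their orthologues' TSSs on the target. When the two orthologues
#' land on different target scaffolds the pair is flagged trans
#' (`same_target_seq = FALSE`) and the target distance is undefined.
#'
#' @param x a filtered, reference-sorted [OrthologTable-class].
#' @return `data.frame` with one row per consecutive reference pair:
#'   `ref_gene_a`, `ref_gene_b`, `ref_seq`, `ref_tss_a`, `ref_tss_b`,
#'   `target_seq_a`, `target_seq_b`, `target_tss_a`, `target_tss_b`,
#'   `ref_distance`, `target_distance` (`NA` for trans pairs),
#'   `same_target_seq`. Empty when no reference sequence has two genes.
#' @examples
#' consecutiveDistancePairs(.exampleOrthologTable())
#' @export
consecutiveDistancePairs <- function(x) {
    stopifnot(is(x, "OrthologTable"))
    r <- orthologRows(x)
    if (nrow(r) < 2L) return(.emptyPairs())
    a <- r[-nrow(r), , drop = FALSE]
    b <- r[-1L, , drop = FALSE]
    same <- a$ref_seq == b$ref_seq
    a <- a[same, , drop = FALSE]; b <- b[same, , drop = FALSE]
    if (!nrow(a)) return(.emptyPairs())
    cis <- a$target_seq == b$target_seq
    td <- ifelse(cis, abs(b$target_tss - a$target_tss), NA_real_)
    data.frame(ref_gene_a = a$ref_gene_id, ref_gene_b = b$ref_gene_id,
               ref_seq = a$ref_seq,
               ref_tss_a = a$ref_tss, ref_tss_b = b$ref_tss,
               target_seq_a = a$target_seq, target_seq_b = b$target_seq,
               target_tss_a = a$target_tss, target_tss_b = b$target_tss,
               ref_distance = abs(b$ref_tss - a$ref_tss),
               target_distance = td, same_target_seq = cis,
               stringsAsFactors = FALSE)
}

.emptyPairs <- function() {
    data.frame(ref_gene_a = character(0), ref_gene_b = character(0),
               ref_seq = character(0), ref_tss_a = numeric(0),
               ref_tss_b = numeric(0), target_seq_a = character(0),
               target_seq_b = character(0), target_tss_a = numeric(0),
               target_tss_b = numeric(0), ref_distance = numeric(0),
               target_distance = numeric(0), same_target_seq = logical(0),
               stringsAsFactors = FALSE)
}

#' Classify rearrangement candidates from distance pairs
#'
#' A cis pair is a candidate when one genome's distance reaches
#' `gapThresholdBp` while the other's stays below `refGapCap` (proximal
#' genes that became distant, or vice versa). A candidate is downgraded to
#' single-gene repositioning when one shared gene accounts for two flanking
#' candidate pairs and removing it leaves its former neighbours mutually
#' proximal on both genomes; remaining candidates are block splits. Trans
#' pairs (orthologues on different target scaffolds) are reported as
#' `trans_event`.
#'
#' @param pairs output of [consecutiveDistancePairs()].
#' @param gapThresholdBp distance (bp) that marks a rearrangement-scale gap
#'   (default 10 Mb).
#' @param refGapCap distance (bp) below which the other genome's gap counts
#'   as proximal (default 1 Mb).
#' @return The candidate subset of `pairs` with columns `class` (one of
#'   `single_gene_repositioning`, `block_split`, `trans_event`) and
#'   `repositioned_gene` (the shared gene of a single-gene event, else `NA`).
#' @export
classifyCandidates <- function(pairs, gapThresholdBp = 1e7,
                               refGapCap = 1e6) {
    if (!is.finite(gapThresholdBp) || gapThresholdBp <= 0)
        stop("gapThresholdBp must be positive")
    if (!is.finite(refGapCap) || refGapCap <= 0)
        stop("refGapCap must be positive")
    if (!nrow(pairs)) {
        pairs$class <- character(0)
        pairs$repositioned_gene <- character(0)
        return(pairs)
    }
    cisCand <- pairs$same_target_seq &
        ((pairs$target_distance >= gapThresholdBp &
          pairs$ref_distance < refGapCap) |
         (pairs$ref_distance >= gapThresholdBp &
          pairs$target_distance < refGapCap))
    cisCand[is.na(cisCand)] <- FALSE
    cls <- rep(NA_character_, nrow(pairs))
    gene <- rep(NA_character_, nrow(pairs))
    cls[cisCand] <- "block_split"
    cls[!pairs$same_target_seq] <- "trans_event"
    ## single-gene rule: pairs i and i+1 both candidates sharing gene X,
    ## and the outer neighbours A,B are proximal on both genomes without X
    idx <- which(cisCand)
    for (i in idx) {
        j <- i + 1L
        if (!(j %in% idx)) next
        if (pairs$ref_gene_b[i] != pairs$ref_gene_a[j]) next
        refAB <- abs(pairs$ref_tss_b[j] - pairs$ref_tss_a[i])
        tgtOk <- pairs$target_seq_a[i] == pairs$target_seq_b[j] &&
            abs(pairs$target_tss_b[j] - pairs$target_tss_a[i]) <
                gapThresholdBp
        if (refAB < gapThresholdBp && tgtOk) {
            cls[c(i, j)] <- "single_gene_repositioning"
            gene[c(i, j)] <- pairs$ref_gene_b[i]
        }
    }
    out <- pairs[!is.na(cls), , drop = FALSE]
    out$class <- cls[!is.na(cls)]
    out$repositioned_gene <- gene[!is.na(cls)]
    rownames(out) <- NULL
    out
}

#' Define a named reference cluster interval
#'
#' @param name cluster label.
#' @param seq reference sequence name.
#' @param start,end 1-based inclusive bounds (bp).
#' @return list of class `clusterInterval`.
#' @export
clusterInterval <- function(name, seq, start, end) {
    stopifnot(start >= 1, end >= start)
    structure(list(name = name, seq = seq, start = start, end = end),
              class = "clusterInterval")
}

#' Read a named cluster interval from a BED file
#'
#' BED is 0-based half-open; the interval is converted to the internal
#' 1-based inclusive convention.
#'
#' @param path BED file; first record's name column (4th) is the cluster
#'   name.
#' @return [clusterInterval()] for the first record.
#' @export
readClusterBed <- function(path) {
    b <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(b) < 4L) stop("cluster BED needs 4 columns (chrom start end name)")
    clusterInterval(b[1, 4], b[1, 1], as.numeric(b[1, 2]) + 1,
                    as.numeric(b[1, 3]))
}

.inCluster <- function(rows, cluster) {
    rows$ref_seq == cluster$seq & rows$ref_tss >= cluster$start &
        rows$ref_tss <= cluster$end
}

## foreign = reference orthologue outside the cluster's chromosome arm;
## with no arm table, whole-chromosome granularity is used
.isForeign <- function(rows, cluster, arms = NULL) {
    if (is.null(arms)) return(rows$ref_seq != cluster$seq)
    armOf <- function(seq, pos) {
        hit <- arms$seq == seq & arms$start <= pos & arms$end >= pos
        if (any(hit)) arms$arm[which(hit)[1]] else paste0(seq, ":noarm")
    }
    clArm <- armOf(cluster$seq, (cluster$start + cluster$end) / 2)
    vapply(seq_len(nrow(rows)),
           function(i) armOf(rows$ref_seq[i], rows$ref_tss[i]) != clArm,
           logical(1))
}

.refLocusLabel <- function(rows) {
    if (!nrow(rows)) return("")
    sq <- names(sort(table(rows$ref_seq), decreasing = TRUE))[1]
    r <- rows[rows$ref_seq == sq, , drop = FALSE]
    sprintf("%s:%d-%d", sq, as.integer(min(r$ref_tss)),
            as.integer(max(r$ref_tss)))
}

#' Call whether a gene cluster is split in the target genome
#'
#' Applies the split rule to a named reference cluster: the cluster is split
#' when (a) a consecutive within-cluster gene pair is a block-split
#' candidate on one target scaffold, or (b) the cluster's genes map to two
#' or more target scaffolds and, among the `neighborhoodK` genes adjacent to
#' a cluster gene on its target scaffold, at least one gene's reference
#' orthologue lies outside the cluster's reference chromosome (arm, when an
#' arm table is given) — "genes from elsewhere". Clusters scattered over
#' multiple scaffolds with no foreign neighbours are reported unresolved
#' (fragmented assembly). Single-gene repositioning events are removed
#' before the split rule is applied.
#'
#' @param x a filtered [OrthologTable-class].
#' @param cluster a [clusterInterval()].
#' @param neighborhoodK genes examined on each side of a cluster gene on its
#'   target scaffold (default 5).
#' @param gapThresholdBp,refGapCap see [classifyCandidates()].
#' @param arms optional `data.frame(seq, start, end, arm)` assigning
#'   chromosome arms (1-based inclusive) for the foreign-gene test.
#' @return A [SplitCall-class].
#' @export
callClusterSplit <- function(x, cluster, neighborhoodK = 5,
                             gapThresholdBp = 1e7, refGapCap = 1e6,
                             arms = NULL) {
    stopifnot(is(x, "OrthologTable"), inherits(cluster, "clusterInterval"))
    rows <- orthologRows(x)
    rows <- rows[rows$homology_type == "one2one", , drop = FALSE]

    ## single-gene repositioning removal precedes split calling
    pairs <- consecutiveDistancePairs(x)
    cand <- classifyCandidates(pairs, gapThresholdBp, refGapCap)
    sgr <- unique(stats::na.omit(cand$repositioned_gene))
    if (length(sgr)) {
        rows <- rows[!rows$ref_gene_id %in% sgr, , drop = FALSE]
        x2 <- new("OrthologTable", refSpecies = x@refSpecies,
                  targetSpecies = x@targetSpecies, rows = rows,
                  report = x@report)
        pairs <- consecutiveDistancePairs(x2)
        cand <- classifyCandidates(pairs, gapThresholdBp, refGapCap)
    }

    inCl <- .inCluster(rows, cluster)
    clRows <- rows[inCl, , drop = FALSE]
    clIds <- clRows$ref_gene_id
    mk <- function(status, flanks = character(0), src = "", span = NA_real_,
                   lb = FALSE, sizes = integer(0), note = "") {
        new("SplitCall", clusterName = cluster$name, status = status,
            breakpointFlanks = flanks, insertSource = src,
            insertSpanBp = span, insertLowerBound = lb,
            subClusterSizes = sizes, clusterGenes = clIds, note = note)
    }
    if (length(clIds) < 2L)
        return(mk("unresolved",
                  note = "fewer than 2 mapped one-to-one orthologues"))

    ## rule (a): within-cluster consecutive block-split candidate (cis)
    inPair <- cand$ref_gene_a %in% clIds & cand$ref_gene_b %in% clIds
    blk <- cand[inPair & cand$class == "block_split", , drop = FALSE]
    if (nrow(blk)) {
        bp <- blk[1L, ]
        i <- match(bp$ref_gene_a, clIds)
        sizes <- c(i, length(clIds) - i)
        ## interposing block: genes between the sub-clusters on the target
        scaf <- bp$target_seq_a
        lo <- min(bp$target_tss_a, bp$target_tss_b)
        hi <- max(bp$target_tss_a, bp$target_tss_b)
        mid <- rows[rows$target_seq == scaf & rows$target_tss > lo &
                    rows$target_tss < hi &
                    !rows$ref_gene_id %in% clIds, , drop = FALSE]
        call <- mk("split", c(bp$ref_gene_a, bp$ref_gene_b),
                   src = .refLocusLabel(mid), sizes = as.integer(sizes))
        return(measureInsert(call, x))
    }

    nScaf <- length(unique(clRows$target_seq))
    if (nScaf >= 2L) {
        ## rule (b): foreign genes in the target-scaffold neighbourhood
        foreignRows <- list()
        for (scaf in unique(clRows$target_seq)) {
            onScaf <- rows[rows$target_seq == scaf, , drop = FALSE]
            onScaf <- onScaf[order(onScaf$target_tss,
                                   onScaf$target_gene_id), , drop = FALSE]
            pos <- which(onScaf$ref_gene_id %in% clIds)
            nb <- unique(unlist(lapply(pos, function(p)
                setdiff(max(1, p - neighborhoodK):
                        min(nrow(onScaf), p + neighborhoodK), pos))))
            if (!length(nb)) next
            nbRows <- onScaf[nb, , drop = FALSE]
            frn <- .isForeign(nbRows, cluster, arms)
            if (any(frn))
                foreignRows[[scaf]] <- nbRows[frn, , drop = FALSE]
        }
        if (length(foreignRows)) {
            ## breakpoint flanks: first consecutive cluster pair (ref order)
            ## whose genes land on different target scaffolds
            tseq <- clRows$target_seq
            brk <- which(tseq[-length(tseq)] != tseq[-1L])[1]
            if (is.na(brk)) brk <- 1L
            sizes <- c(brk, length(clIds) - brk)
            call <- mk("split", c(clIds[brk], clIds[brk + 1L]),
                       src = .refLocusLabel(do.call(rbind, foreignRows)),
                       lb = TRUE, sizes = as.integer(sizes))
            return(measureInsert(call, x))
        }
        return(mk("unresolved",
                  note = sprintf(
                      "cluster genes on %d scaffolds, no foreign neighbours",
                      nScaf)))
    }
    mk("syntenic", span = 0)
}

#' Measure the interposed foreign block of a split call
#'
#' Completes the insert-span fields of a split [SplitCall-class]: the span is
#' the target-genome extent (max minus min TSS) of the maximal contiguous
#' block of non-cluster genes lying between the two sub-clusters. When the
#' sub-clusters sit on different scaffolds the block is truncated by a
#' scaffold end, so the within-scaffold extent is reported and flagged as a
#' lower bound.
#'
#' @param call a [SplitCall-class] with `status == "split"`.
#' @param x the [OrthologTable-class] the call came from.
#' @return The call with `insertSpanBp`, `insertLowerBound` and (if empty)
#'   `insertSource` completed.
#' @export
measureInsert <- function(call, x) {
    stopifnot(is(call, "SplitCall"), is(x, "OrthologTable"))
    if (splitStatus(call) != "split")
        stop("measureInsert needs a split call")
    rows <- orthologRows(x)
    clIds <- call@clusterGenes
    n1 <- call@subClusterSizes[1]
    side1 <- rows[rows$ref_gene_id %in% clIds[seq_len(n1)], , drop = FALSE]
    side2 <- rows[rows$ref_gene_id %in% clIds[-seq_len(n1)], , drop = FALSE]
    scafOf <- function(s) names(sort(table(s$target_seq),
                                     decreasing = TRUE))[1]
    s1 <- scafOf(side1); s2 <- scafOf(side2)

    blockSpan <- function(blk) {
        if (!nrow(blk)) return(0)
        max(blk$target_tss) - min(blk$target_tss)
    }
    ## maximal contiguous run of non-cluster genes within a sorted frame
    maxForeignRun <- function(onScaf) {
        if (!nrow(onScaf)) return(onScaf)
        frn <- !onScaf$ref_gene_id %in% clIds
        r <- rle(frn)
        if (!any(r$values)) return(onScaf[0, , drop = FALSE])
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        spans <- vapply(runs, function(k)
            blockSpan(onScaf[starts[k]:ends[k], , drop = FALSE]), 0)
        k <- runs[which.max(spans)]
        onScaf[starts[k]:ends[k], , drop = FALSE]
    }

    if (identical(s1, s2)) {
        on <- rows[rows$target_seq == s1, , drop = FALSE]
        on <- on[order(on$target_tss, on$target_gene_id), , drop = FALSE]
        e1 <- range(side1$target_tss[side1$target_seq == s1])
        e2 <- range(side2$target_tss[side2$target_seq == s1])
        bounds <- sort(c(min(max(e1), max(e2)), max(min(e1), min(e2))))
        mid <- on[on$target_tss > bounds[1] & on$target_tss < bounds[2], ,
                  drop = FALSE]
        blk <- maxForeignRun(mid)
        call@insertSpanBp <- blockSpan(blk)
        call@insertLowerBound <- FALSE
    } else {
        spans <- c(0, 0); blks <- list()
        for (k in 1:2) {
            scaf <- c(s1, s2)[k]
            side <- list(side1, side2)[[k]]
            on <- rows[rows$target_seq == scaf, , drop = FALSE]
            on <- on[order(on$target_tss, on$target_gene_id), , drop = FALSE]
            ext <- range(side$target_tss[side$target_seq == scaf])
            out1 <- on[on$target_tss < ext[1], , drop = FALSE]
            out2 <- on[on$target_tss > ext[2], , drop = FALSE]
            b1 <- maxForeignRun(out1); b2 <- maxForeignRun(out2)
            blk <- if (blockSpan(b1) >= blockSpan(b2)) b1 else b2
            spans[k] <- blockSpan(blk); blks[[k]] <- blk
        }
        k <- which.max(spans)
        call@insertSpanBp <- spans[k]
        call@insertLowerBound <- TRUE
        if (!nzchar(call@insertSource))
            call@insertSource <- .refLocusLabel(blks[[k]])
    }
    validObject(call)
    call
}

#' Paired TSS coordinates of shared orthologues for synteny plots
#'
#' Pairs, over the reference genes shared by two tables (or the reference
#' and target of a single table), the TSS coordinates of the orthologues in
#' each genome, in reference order — the raw material of dot plots and
#' ribbon maps. No coordinates are interpolated or invented.
#'
#' @param a an [OrthologTable-class].
#' @param b optional second table sharing reference gene ids with `a`; when
#'   omitted, `a`'s own reference and target coordinates are paired.
#' @return `data.frame(ref_gene_id, ref_tss, target_tss, ref_seq,
#'   target_seq)` in reference order; with `b`, the "ref" columns carry
#'   `a`'s target coordinates and the "target" columns `b`'s. Empty (with a
#'   warning) when the tables share no genes.
#' @export
syntenyPairs <- function(a, b = NULL) {
    stopifnot(is(a, "OrthologTable"))
    ra <- orthologRows(a)
    if (is.null(b))
        return(data.frame(ref_gene_id = ra$ref_gene_id,
                          ref_tss = ra$ref_tss, target_tss = ra$target_tss,
                          ref_seq = ra$ref_seq, target_seq = ra$target_seq,
                          stringsAsFactors = FALSE))
    stopifnot(is(b, "OrthologTable"))
    rb <- orthologRows(b)
    shared <- intersect(ra$ref_gene_id, rb$ref_gene_id)
    if (!length(shared)) {
        warning("tables share no reference genes")
        return(data.frame(ref_gene_id = character(0), ref_tss = numeric(0),
                          target_tss = numeric(0), ref_seq = character(0),
                          target_seq = character(0)))
    }
    ra <- ra[ra$ref_gene_id %in% shared, , drop = FALSE]
    ia <- match(ra$ref_gene_id, rb$ref_gene_id)
    data.frame(ref_gene_id = ra$ref_gene_id, ref_tss = ra$target_tss,
               target_tss = rb$target_tss[ia], ref_seq = ra$target_seq,
               target_seq = rb$target_seq[ia], stringsAsFactors = FALSE)
}
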