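## counter-based seed fan-out: each generator component gets its own child
## seed, so adding a component never perturbs the draws of existing ones
.childSeed <- function(seed, component) {
    offset <- c(genomes = 1, expression = 2, tracks = 3, tree = 4)[component]
    as.integer((as.numeric(seed) + 77777 * offset) %% 2147483647)
}

#' Specification of a synthetic comparative-genomics dataset
#'
#' Bundles all tunable parameters of the synthetic generators: gene counts
#' and log-normal inter-gene spacing of the reference chromosome and a
#' donor chromosome, the cluster definition, the rearrangement plan, the
#' expression plan (tissue count, within-cluster latent correlation,
#' divergence bump near the breakpoint), the signal-track plan (baseline,
#' region shift, noise) and the tree plan. Defaults emulate the structure
#' of the human 3p21.31 analysis: a 25-gene cluster, a breakpoint after
#' cluster gene 16, a 50-gene interposed block, seven shared tissues.
#'
#' @param seed global seed; per-component seeds are derived from it.
#' @param nGenes genes on the reference (cluster-bearing) chromosome.
#' @param donorGenes genes on the donor chromosome supplying the insert.
#' @param spacingMeanlog,spacingSdlog log-normal inter-gene spacing (bp) on
#'   both chromosomes.
#' @param clusterStart,clusterLength cluster position (gene index) and size.
#' @param plan `"split"`, `"none"` or `"single_gene"`.
#' @param breakpointIndex cluster-gene index after which the insert lands.
#' @param insertGenes donor genes interposed at the breakpoint.
#' @param insertSpacingMeanlog,insertSpacingSdlog spacing of the interposed
#'   block (defaults give a span of roughly 70 Mb, the scale of the
#'   interposed block the split rule is built for).
#' @param crossScaffold place the two sub-clusters on different target
#'   scaffolds (the foreign block adjacent to the second sub-cluster).
#' @param singleGeneIndex reference gene repositioned under plan
#'   `"single_gene"`.
#' @param nTissues shared tissues of the pseudo-species.
#' @param rhoBlock latent co-expression of cluster genes, in `[0, 1)`.
#' @param baseDivergence baseline expression-divergence weight of every
#'   species pair, in `[0, 1)`.
#' @param bumpAmplitude,bumpDecay extra divergence of the test species near
#'   the breakpoint: `amplitude * exp(-distance / decay)` (decay in bp).
#' @param trackBaseline,trackDelta,trackNoiseSd,trackResolution signal-track
#'   plan: baseline mean, region mean shift, Gaussian noise SD, bin size.
#' @param nTips,birth,death birth-death tree plan for trait simulations.
#' @return Validated list of class `GeneratorSpec`.
#' @export
generatorSpec <- function(seed = 1, nGenes = 300, donorGenes = 150,
                          spacingMeanlog = log(6e4), spacingSdlog = 0.8,
                          clusterStart = 100, clusterLength = 25,
                          plan = c("split", "none", "single_gene"),
                          breakpointIndex = 16, insertGenes = 50,
                          insertSpacingMeanlog = log(1.25e6),
                          insertSpacingSdlog = 0.5, crossScaffold = FALSE,
                          singleGeneIndex = 50, nTissues = 7,
                          rhoBlock = 0.7, baseDivergence = 0.1,
                          bumpAmplitude = 0.5, bumpDecay = 2e6,
                          trackBaseline = 0, trackDelta = 0,
                          trackNoiseSd = 1, trackResolution = 1e6,
                          nTips = 200, birth = 1, death = 0.5) {
    plan <- match.arg(plan)
    stopifnot(nGenes > 0, donorGenes > 0, clusterLength >= 2,
              clusterStart >= 1,
              clusterStart + clusterLength - 1 <= nGenes,
              breakpointIndex >= 1, breakpointIndex < clusterLength,
              nTissues >= 3, rhoBlock >= 0, rhoBlock < 1,
              baseDivergence >= 0, baseDivergence < 1,
              bumpAmplitude >= 0, trackNoiseSd >= 0, nTips >= 4)
    if (insertGenes > donorGenes)
        stop("insert larger than the donor chromosome")
    structure(as.list(environment()), class = "GeneratorSpec")
}

.drawTss <- function(n, meanlog, sdlog) {
    cumsum(pmax(1, round(stats::rlnorm(n, meanlog, sdlog))))
}

#' Generate a genome pair with a planted rearrangement
#'
#' Builds a reference genome (cluster chromosome `chrR` plus donor
#' chromosome `chrD`) and a target genome identical in gene order except
#' for the planted plan: a cluster split with an interposed donor block, a
#' single-gene repositioning, or nothing. The tables are emitted in the
#' canonical TSV dialect and re-read through [readOrthologTable()], so the
#' generator exercises the public I/O path. Deterministic per seed.
#'
#' @param spec a [generatorSpec()].
#' @return list: `table` (the [OrthologTable-class]), `cluster` (the
#'   [clusterInterval()]), `truth` (plan, true breakpoint flank gene pair,
#'   true insert span and source, repositioned gene, breakpoint reference
#'   position).
#' @export
generateSplitGenomes <- function(spec) {
    stopifnot(inherits(spec, "GeneratorSpec"))
    set.seed(.childSeed(spec$seed, "genomes"))
    nR <- spec$nGenes; nD <- spec$donorGenes
    refIds <- sprintf("G%04d", seq_len(nR))
    donIds <- sprintf("D%04d", seq_len(nD))
    refTss <- .drawTss(nR, spec$spacingMeanlog, spec$spacingSdlog)
    donTss <- .drawTss(nD, spec$spacingMeanlog, spec$spacingSdlog)
    clIdx <- spec$clusterStart:(spec$clusterStart + spec$clusterLength - 1)
    cb <- clIdx[spec$breakpointIndex]          # global breakpoint index

    mkRows <- function(ids, seqs, tss, tids, tseqs, ttss) {
        data.frame(ref_gene_id = ids, ref_symbol = "", ref_seq = seqs,
                   ref_tss = tss, ref_strand = "+",
                   target_gene_id = tids, target_seq = tseqs,
                   target_tss = ttss, target_strand = "+",
                   homology_type = "one2one", stringsAsFactors = FALSE)
    }
    truth <- list(plan = spec$plan, flanks = character(0),
                  insert_span = 0, insert_source = "",
                  repositioned_gene = NA_character_,
                  breakpoint_ref_pos = NA_real_)

    if (spec$plan == "none") {
        rows <- rbind(
            mkRows(refIds, "chrR", refTss, paste0("t", refIds), "scafR",
                   refTss),
            mkRows(donIds, "chrD", donTss, paste0("t", donIds), "scafD",
                   donTss))
    } else if (spec$plan == "single_gene") {
        tgtTss <- refTss
        far <- max(refTss) + 5e7
        tgtTss[spec$singleGeneIndex] <- far
        rows <- rbind(
            mkRows(refIds, "chrR", refTss, paste0("t", refIds), "scafR",
                   tgtTss),
            mkRows(donIds, "chrD", donTss, paste0("t", donIds), "scafD",
                   donTss))
        truth$repositioned_gene <- refIds[spec$singleGeneIndex]
    } else {
        ins <- seq_len(spec$insertGenes)
        insIds <- donIds[ins]
        restDon <- donIds[-ins]
        insGaps <- pmax(1, round(stats::rlnorm(
            spec$insertGenes, spec$insertSpacingMeanlog,
            spec$insertSpacingSdlog)))
        truth$flanks <- refIds[c(cb, cb + 1L)]
        truth$insert_source <- "chrD"
        truth$breakpoint_ref_pos <- mean(refTss[c(cb, cb + 1L)])
        if (!spec$crossScaffold) {
            ## one scaffold: ref order with donor block interposed at cb
            order_ids <- c(refIds[1:cb], insIds, refIds[(cb + 1L):nR])
            gaps <- pmax(1, round(stats::rlnorm(
                length(order_ids), spec$spacingMeanlog, spec$spacingSdlog)))
            pos <- seq_along(order_ids) %in% (cb + seq_len(spec$insertGenes))
            gaps[which(pos)[-1]] <- insGaps[seq_len(spec$insertGenes - 1L)]
            ttss <- cumsum(gaps)
            truth$insert_span <- ttss[cb + spec$insertGenes] - ttss[cb + 1L]
            tmap <- stats::setNames(ttss, order_ids)
            rows <- rbind(
                mkRows(refIds, "chrR", refTss, paste0("t", refIds),
                       "scafT", unname(tmap[refIds])),
                mkRows(insIds, "chrD", donTss[ins], paste0("t", insIds),
                       "scafT", unname(tmap[insIds])),
                mkRows(restDon, "chrD", donTss[-ins], paste0("t", restDon),
                       "scafD", donTss[-ins]))
        } else {
            ## two scaffolds: sub-cluster 2 lands next to the foreign block
            ids1 <- refIds[1:cb]
            ids2 <- c(insIds, refIds[(cb + 1L):nR])
            t1 <- .drawTss(length(ids1), spec$spacingMeanlog,
                           spec$spacingSdlog)
            gaps2 <- pmax(1, round(stats::rlnorm(
                length(ids2), spec$spacingMeanlog, spec$spacingSdlog)))
            gaps2[2:spec$insertGenes] <- insGaps[seq_len(spec$insertGenes - 1L)]
            t2 <- cumsum(gaps2)
            truth$insert_span <- t2[spec$insertGenes] - t2[1L]
            tmap <- c(stats::setNames(t1, ids1), stats::setNames(t2, ids2))
            smap <- c(stats::setNames(rep("scafT1", length(ids1)), ids1),
                      stats::setNames(rep("scafT2", length(ids2)), ids2))
            allIds <- c(refIds, donIds)
            refAll <- c(refTss, donTss)
            seqAll <- rep(c("chrR", "chrD"), c(nR, nD))
            tseq <- ifelse(allIds %in% names(smap), smap[allIds], "scafD")
            ttss <- ifelse(allIds %in% names(tmap), tmap[allIds],
                           refAll)
            rows <- mkRows(allIds, seqAll, refAll, paste0("t", allIds),
                           unname(tseq), unname(ttss))
        }
    }
    f <- tempfile(fileext = ".tsv")
    on.exit(unlink(f))
    utils::write.table(rows, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tab <- readOrthologTable(f, refSpecies = "refgenome",
                             targetSpecies = "targetgenome")
    cl <- clusterInterval("cluster", "chrR", refTss[clIdx[1]],
                          refTss[clIdx[length(clIdx)]])
    list(table = tab, cluster = cl, truth = truth)
}

#' Generate expression matrices for pseudo-species
#'
#' Builds genes x tissues expression for three pseudo-species sharing the
#' reference chromosome's gene order: cluster genes load on one latent
#' tissue factor with weight `sqrt(rhoBlock)` (block co-expression), every
#' species carries independent baseline divergence, and the test species
#' receives extra divergence `bumpAmplitude * exp(-d / bumpDecay)` with
#' `d` the gene's distance to the planted breakpoint. Values are
#' exponentiated (log-normal, RPKM-like). Deterministic per seed.
#'
#' @param spec a [generatorSpec()].
#' @param genomes output of [generateSplitGenomes()] (same spec).
#' @return list of [ExpressionMatrix-class]: `test`, `reference`,
#'   `outgroup`, plus `distance` (per-gene bp to the breakpoint; `Inf`
#'   without one) and `genes`.
#' @export
generateExpressionData <- function(spec, genomes) {
    stopifnot(inherits(spec, "GeneratorSpec"))
    set.seed(.childSeed(spec$seed, "expression"))
    rows <- orthologRows(genomes$table)
    rows <- rows[rows$ref_seq == "chrR", , drop = FALSE]
    g <- rows$ref_gene_id; tss <- rows$ref_tss
    n <- length(g); Tn <- spec$nTissues
    inCl <- .inCluster(rows, genomes$cluster)
    fac <- stats::rnorm(Tn)                      # latent tissue factor
    base <- matrix(stats::rnorm(n * Tn), n, Tn)
    base[inCl, ] <- sqrt(spec$rhoBlock) * matrix(fac, sum(inCl), Tn,
                                                 byrow = TRUE) +
        sqrt(1 - spec$rhoBlock) * base[inCl, , drop = FALSE]
    bp <- genomes$truth$breakpoint_ref_pos
    dist <- if (is.finite(bp)) abs(tss - bp) else rep(Inf, n)
    w0 <- spec$baseDivergence
    wTest <- pmin(0.95, w0 + spec$bumpAmplitude * exp(-dist / spec$bumpDecay))
    species <- function(w) {
        eps <- matrix(stats::rnorm(n * Tn), n, Tn)
        v <- sqrt(1 - w) * base + sqrt(w) * eps
        dimnames(v) <- list(g, paste0("tissue", seq_len(Tn)))
        expressionMatrix(exp(v), state = "rpkm")
    }
    list(test = species(wTest), reference = species(rep(w0, n)),
         outgroup = species(rep(w0, n)), distance = dist, genes = g)
}

#' Generate a binned signal track with a region-level mean shift
#'
#' Gaussian baseline values in fixed bins tiling the region and
#' `flankBins` bins on each side, with mean shifted by `trackDelta` inside
#' the region — the structure the region-versus-flank tests assume.
#' Deterministic per seed.
#'
#' @param spec a [generatorSpec()].
#' @param region list(`seq`, `start`, `end`), 1-based inclusive; defaults
#'   to a 7-bin region.
#' @param flankBins bins generated on each side of the region (default 20).
#' @return `data.frame(seq, start, end, value)` in 0-based half-open
#'   bedGraph convention, bin width `spec$trackResolution`.
#' @export
generateTracks <- function(spec, region = NULL, flankBins = 20) {
    stopifnot(inherits(spec, "GeneratorSpec"))
    set.seed(.childSeed(spec$seed, "tracks"))
    res <- spec$trackResolution
    if (is.null(region))
        region <- list(seq = "chrS", start = flankBins * res + 1,
                       end = (flankBins + 7) * res)
    lo <- max(0, floor((region$start - 1) / res) - flankBins)
    hi <- ceiling(region$end / res) + flankBins
    starts <- (lo:(hi - 1)) * res
    mid <- starts + res / 2
    inRegion <- mid >= region$start - 1 & mid <= region$end
    value <- stats::rnorm(length(starts), spec$trackBaseline,
                          spec$trackNoiseSd) + spec$trackDelta * inRegion
    data.frame(seq = region$seq, start = starts, end = starts + res,
               value = value, stringsAsFactors = FALSE)
}

#' Generate a birth-death tree for trait simulations
#'
#' @param spec a [generatorSpec()]; uses `nTips`, `birth`, `death` and the
#'   tree child seed.
#' @return An [ape::phylo] tree with `nTips` tips.
#' @export
generateTree <- function(spec) {
    stopifnot(inherits(spec, "GeneratorSpec"))
    set.seed(.childSeed(spec$seed, "tree"))
    ape::rphylo(spec$nTips, spec$birth, spec$death)
}
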