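#' Read a bedGraph signal track
#'
#' Plain-text bedGraph (0-based half-open intervals, 4th column value).
#' `track`/`browser`/comment lines are skipped; malformed data lines
#' (wrong field count, non-numeric coordinates or value, end <= start) are
#' dropped and counted. Negative values are allowed (e.g. replication-timing
#' log-ratios).
#'
#' @param path bedGraph file.
#' @return `data.frame(seq, start, end, value)`; attribute `"dropped"`
#'   counts malformed lines.
#' @export
readBedGraph <- function(path) {
    if (!file.exists(path)) stop("cannot read bedGraph: ", path)
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    ln <- ln[!grepl("^(track|browser|#)", ln)]
    f <- strsplit(ln, "[ \t]+")
    ok4 <- lengths(f) == 4L
    f4 <- f[ok4]
    sq <- vapply(f4, `[[`, "", 1L)
    st <- suppressWarnings(as.numeric(vapply(f4, `[[`, "", 2L)))
    en <- suppressWarnings(as.numeric(vapply(f4, `[[`, "", 3L)))
    va <- suppressWarnings(as.numeric(vapply(f4, `[[`, "", 4L)))
    good <- is.finite(st) & is.finite(en) & is.finite(va) & en > st & st >= 0
    out <- data.frame(seq = sq[good], start = st[good], end = en[good],
                      value = va[good], stringsAsFactors = FALSE)
    attr(out, "dropped") <- sum(!ok4) + sum(!good)
    out
}

#' Write a bedGraph track
#'
#' @param track `data.frame(seq, start, end, value)` in 0-based half-open
#'   coordinates (the `bin_*` column names of [binTrack()] output are also
#'   accepted).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    nm <- names(track)
    sq <- track[[if ("seq" %in% nm) "seq" else "seq_name"]]
    st <- track[[if ("start" %in% nm) "start" else "bin_start"]]
    en <- track[[if ("end" %in% nm) "end" else "bin_end"]]
    va <- track[[if ("value" %in% nm) "value" else nm[length(nm)]]]
    keep <- is.finite(va)
    utils::write.table(
        data.frame(sq, format(st, scientific = FALSE, trim = TRUE),
                   format(en, scientific = FALSE, trim = TRUE), va)[keep, ],
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Bin a signal track at fixed resolution
#'
#' Apportions interval values to fixed-size bins by overlap length and
#' aggregates: `"sum"` accumulates value x overlapped-bases per bin (so the
#' total signal is conserved exactly); `"mean"` is the per-base
#' (length-weighted) mean over the covered bases of the bin. Bins with no
#' coverage are missing.
#'
#' @param track `data.frame(seq, start, end, value)`, 0-based half-open (as
#'   from [readBedGraph()]).
#' @param resolution bin width in bp.
#' @param aggregator `"mean"` or `"sum"`.
#' @return `data.frame(seq_name, bin_start, bin_end, value)` with 0-based
#'   half-open bins tiling each sequence from 0 to the last covered bin.
#' @export
binTrack <- function(track, resolution, aggregator = c("mean", "sum")) {
    aggregator <- match.arg(aggregator)
    stopifnot(resolution > 0)
    track <- track[order(track$seq, track$start), , drop = FALSE]
    out <- list()
    for (sq in unique(track$seq)) {
        tr <- track[track$seq == sq, , drop = FALSE]
        nb <- ceiling(max(tr$end) / resolution)
        bins <- GenomicRanges::GRanges(sq, IRanges::IRanges(
            start = (seq_len(nb) - 1L) * resolution + 1,
            end = seq_len(nb) * resolution))
        iv <- GenomicRanges::GRanges(sq, IRanges::IRanges(
            start = tr$start + 1, end = tr$end))
        ov <- GenomicRanges::findOverlaps(iv, bins)
        w <- GenomicRanges::width(GenomicRanges::pintersect(
            iv[S4Vectors::queryHits(ov)], bins[S4Vectors::subjectHits(ov)]))
        b <- S4Vectors::subjectHits(ov)
        contrib <- tr$value[S4Vectors::queryHits(ov)] * w
        sumv <- rep(NA_real_, nb)
        sv <- rowsum(contrib, b)
        sw <- rowsum(w, b)
        ii <- as.integer(rownames(sv))
        sumv[ii] <- if (aggregator == "sum") sv else sv / sw
        out[[sq]] <- data.frame(
            seq_name = sq, bin_start = (seq_len(nb) - 1L) * resolution,
            bin_end = seq_len(nb) * resolution, value = sumv,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' GC-content track from sequence
#'
#' Percentage of G+C among non-N bases in fixed windows along each sequence,
#' with a trailing running-mean smoothing. All-N windows are missing.
#' Reverse-complementing the sequence leaves GC% unchanged.
#'
#' @param sequence path to a (plain or gzipped) FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @param window window size in bp (default 100 kb).
#' @param smoothBinwidth running-mean window in bins (default 10).
#' @return `data.frame(seq_name, bin_start, bin_end, value)` with 0-based
#'   half-open windows and GC% values; attribute `"smoothed"` holds a named
#'   list of smoothed per-sequence profiles (length `nbins - binwidth + 1`).
#' @export
gcTrack <- function(sequence, window = 1e5, smoothBinwidth = 10) {
    stopifnot(window > 0)
    seqs <- if (is(sequence, "DNAStringSet")) sequence
            else Biostrings::readDNAStringSet(sequence)
    if (!length(seqs) || all(Biostrings::width(seqs) == 0))
        stop("empty sequence input")
    out <- list(); smoothed <- list()
    for (k in seq_along(seqs)) {
        nm <- sub("\\s.*", "", names(seqs)[k])
        len <- Biostrings::width(seqs)[k]
        if (len == 0) next
        nb <- ceiling(len / window)
        starts <- (seq_len(nb) - 1L) * window + 1      # 1-based inclusive
        ends <- pmin(seq_len(nb) * window, len)
        v <- Biostrings::Views(seqs[[k]], start = starts, end = ends)
        freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
        acgt <- rowSums(freq)
        gc <- ifelse(acgt > 0, 100 * (freq[, "G"] + freq[, "C"]) / acgt,
                     NA_real_)
        out[[nm]] <- data.frame(seq_name = nm, bin_start = starts - 1,
                                bin_end = ends, value = gc,
                                stringsAsFactors = FALSE)
        smoothed[[nm]] <- runningMean(gc[is.finite(gc)], smoothBinwidth)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "smoothed") <- smoothed
    res
}

#' Mann-Whitney U test with rank-based effect size
#'
#' Two-sided rank-sum test reporting the U statistic of the first sample,
#' the normal-approximation score `z = (U - mU) / sigmaU` with
#' `mU = n1 n2 / 2` and `sigmaU = sqrt(n1 n2 (n1 + n2 + 1) / 12)` (no tie
#' correction, no continuity correction), the effect size
#' `eta^2 = z^2 / N`, and Cohen's d from the pooled standard deviation.
#' The p-value is exact (distribution of U enumerated) when the samples are
#' tie-free and `n1 * n2 <= 1e4`; otherwise the normal approximation with
#' tie-corrected variance is used. `eta^2` always uses the uncorrected
#' `sigmaU` above.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list `n1`, `n2`, `U`, `z`, `p_two_sided`, `eta_squared`,
#'   `cohens_d`, `direction` (sign of the median shift `x` vs `y`),
#'   `exact` (logical).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitney <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
    pooled <- c(x, y)
    if (stats::sd(pooled) == 0)
        stop("pooled data have zero variance; test is undefined")
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mU <- n1 * n2 / 2
    sU <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- (U - mU) / sU
    N <- n1 + n2
    eta2 <- z^2 / N
    ties <- any(duplicated(pooled))
    if (!ties && n1 * n2 <= 1e4) {
        pLo <- stats::pwilcox(U, n1, n2)
        pHi <- 1 - stats::pwilcox(U - 1, n1, n2)
        p <- min(1, 2 * min(pLo, pHi))
        exact <- TRUE
    } else {
        tt <- table(pooled)
        corr <- sum(tt^3 - tt) / (N * (N - 1))
        sCorr <- sqrt(n1 * n2 / 12 * ((N + 1) - corr))
        p <- 2 * stats::pnorm(-abs((U - mU) / sCorr))
        exact <- FALSE
    }
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
    d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
    list(n1 = n1, n2 = n2, U = U, z = z, p_two_sided = p,
         eta_squared = eta2, cohens_d = d,
         direction = sign(stats::median(x) - stats::median(y)),
         exact = exact)
}

.binsIn <- function(track, interval) {
    mid <- (track$bin_start + track$bin_end) / 2      # 0-based bins
    sel <- track$seq_name == interval$seq & mid >= interval$start - 1 &
        mid <= interval$end
    v <- track$value[sel]
    v[is.finite(v)]
}

#' Test a region's signal against its flanks
#'
#' Compares the binned signal inside a region with the signal in two
#' flanking intervals, either pooled into one flank sample or tested one
#' flank at a time. The rank-sum branch reports the Mann-Whitney p-value
#' with `eta^2`; the t-test branch an unpaired two-tailed Student p-value.
#' Cohen's d and `eta^2` are reported by both branches. Note `eta^2` and
#' `z` are invariant under strictly monotone transforms of the data;
#' Cohen's d is not.
#'
#' @param track binned track from [binTrack()] or [gcTrack()].
#' @param region [clusterInterval()]-style list(`seq`, `start`, `end`),
#'   1-based inclusive.
#' @param flanks list of two such intervals (upstream, downstream).
#' @param test `"mann_whitney"` or `"t_test"`.
#' @param poolFlanks pool both flanks into one comparison sample (default);
#'   otherwise a result per flank is returned.
#' @return A result list (see [mannWhitney()]) with added `method` and
#'   `pooled_flanks`; when `poolFlanks = FALSE`, a list of two such results
#'   named `upstream`/`downstream`.
#' @export
regionVsFlankTest <- function(track, region, flanks,
                              test = c("mann_whitney", "t_test"),
                              poolFlanks = TRUE) {
    test <- match.arg(test)
    rv <- .binsIn(track, region)
    fv <- lapply(flanks, .binsIn, track = track)
    if (!length(rv) || !sum(lengths(fv)))
        stop("region or flank intervals contain no non-missing bins")
    run1 <- function(fl) {
        res <- mannWhitney(rv, fl)
        if (test == "t_test")
            res$p_two_sided <- stats::t.test(rv, fl,
                                             var.equal = TRUE)$p.value
        res$method <- test
        res$pooled_flanks <- poolFlanks
        res
    }
    if (poolFlanks) return(run1(unlist(fv)))
    list(upstream = run1(fv[[1]]), downstream = run1(fv[[2]]))
}

#' Conserved non-coding element loss proportions
#'
#' Per-species proportion of CNEs lost (partially or fully deleted at the
#' orthologous position), plus two-tailed t-tests comparing each species
#' with a designated baseline over per-window loss proportions, the windows
#' being consecutive blocks of CNEs along the region.
#'
#' @param presence `data.frame`/matrix, rows = CNEs (in positional order),
#'   columns = species, entries `"present"` or `"lost"` (`NA` allowed).
#' @param baseline column name of the baseline species.
#' @param windowSize CNEs per window (default 50).
#' @return list `proportion` (named per-species lost fraction), `tests`
#'   (`data.frame(species, p, mean_diff)` vs baseline; `p = 1` when both
#'   window profiles are identical), `windows` (windows x species
#'   proportion matrix). Species columns with no data are skipped with a
#'   warning.
#' @export
cneLoss <- function(presence, baseline, windowSize = 50) {
    presence <- as.data.frame(presence)
    stopifnot(baseline %in% names(presence))
    empty <- vapply(presence, function(col) all(is.na(col)), logical(1))
    if (any(empty)) {
        warning("skipping species with no data: ",
                paste(names(presence)[empty], collapse = ", "))
        presence <- presence[, !empty, drop = FALSE]
    }
    lost <- function(col) mean(col == "lost", na.rm = TRUE)
    prop <- vapply(presence, lost, numeric(1))
    n <- nrow(presence)
    wid <- rep(seq_len(ceiling(n / windowSize)), each = windowSize)[seq_len(n)]
    win <- apply(presence, 2L, function(col)
        tapply(col == "lost", wid, mean, na.rm = TRUE))
    win <- matrix(win, ncol = ncol(presence),
                  dimnames = list(NULL, names(presence)))
    others <- setdiff(names(presence), baseline)
    tests <- data.frame(species = others,
                        p = rep(NA_real_, length(others)),
                        mean_diff = rep(NA_real_, length(others)),
                        stringsAsFactors = FALSE)
    for (k in seq_along(others)) {
        a <- win[, baseline]; b <- win[, others[k]]
        tests$mean_diff[k] <- mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE)
        if (isTRUE(all.equal(a, b)) ||
            (stats::sd(a, na.rm = TRUE) == 0 &&
             stats::sd(b, na.rm = TRUE) == 0))
            tests$p[k] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1
                          else 0
        else
            tests$p[k] <- stats::t.test(b, a, var.equal = TRUE)$p.value
    }
    list(proportion = prop, tests = tests, windows = win)
}
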