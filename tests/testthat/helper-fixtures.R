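# fixture builders shared across test files; everything is generated in code

makeOrthoDf <- function(ref_id, ref_seq, ref_tss,
                        target_id = paste0("t", ref_id),
                        target_seq = "scaf1", target_tss = ref_tss,
                        homology = "one2one", symbol = "") {
    data.frame(ref_gene_id = ref_id, ref_symbol = symbol,
               ref_seq = ref_seq, ref_tss = ref_tss, ref_strand = "+",
               target_gene_id = target_id, target_seq = target_seq,
               target_tss = target_tss, target_strand = "+",
               homology_type = homology, stringsAsFactors = FALSE)
}

writeOrthoTSV <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

readOrtho <- function(df, ...) {
    readOrthologTable(writeOrthoTSV(df), ...)
}

# direct cell-by-cell evaluation of the 5-term smoothing stencil, written
# independently of the package implementation
stencilOracle <- function(m) {
    n <- nrow(m)
    out <- matrix(NA_real_, n, n)
    at <- function(i, j) if (i >= 1 && i <= n && j >= 1 && j <= n) m[i, j]
                         else NA_real_
    for (i in seq_len(n)) for (j in seq_len(n)) {
        vals <- c(at(i, j), at(i - 1, j), at(i, j - 1), at(i + 1, j + 1),
                  at(i, j + 1))
        w <- c(2, 1, 1, 1, 1)
        ok <- !is.na(vals)
        out[i, j] <- if (any(ok)) sum(w[ok] * vals[ok]) / sum(w[ok])
                     else NA_real_
    }
    out
}

# exhaustive rank-assignment enumeration of the two-sided Mann-Whitney
# p-value: all C(n1+n2, n1) assignments of the pooled ranks to sample 1
mwEnumOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sets <- combn(n1 + n2, n1)
    us <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    pLo <- mean(us <= uObs + 1e-9)
    pHi <- mean(us >= uObs - 1e-9)
    min(1, 2 * min(pLo, pHi))
}
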