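---
title: "Detecting gene-cluster splits and their genomic correlates"
author: "synsplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-cluster splits and their genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synsplit)
```

## The problem

Some mammalian genomes carry dense clusters of functionally related genes —
the human 3p21.31 band, with its ~25 tumour-suppressor genes (TSGs), is the
motivating example — whose integrity, co-expression and chromatin context
can change dramatically between lineages. `synsplit` implements, as
reusable and fully testable components, the comparative analysis needed to
ask whether such a cluster is intact or split in another genome, and
whether the split coincides with shifts in cancer-gene density, gene
co-expression, expression divergence, local genomic signals (accessibility,
replication timing, GC content, conserved-element retention) and the
phylogenetic signal of organismal traits.

Because target genomes are often scaffold-level assemblies, the package
works entirely from gene order: an orthologue coordinate table pairing each
reference gene (by transcription start site, TSS) with its one-to-one
orthologue in the target.

## Orthologue tables and the split rule

`readOrthologTable()` parses biomart-style TSV exports; `filterOrthologs()`
keeps one-to-one orthologues and discards target scaffolds carrying fewer
than five retained genes, which carry no usable order information. Rows are
always kept in reference order `(seq, TSS)`; equal-TSS ties are broken
lexicographically by gene id, a convention we fixed because exports do not
specify one. Duplicated reference ids keep the smallest-TSS row — a
deterministic, order-independent rule — and everything dropped at any stage
is counted in the parse report.

`consecutiveDistancePairs()` contrasts the TSS distance of each adjacent
reference gene pair with the distance of their orthologues.
`classifyCandidates()` flags pairs where one genome's distance reaches
`gapThresholdBp` (default 10 Mb) while the other stays below `refGapCap`
(default 1 Mb). The defaults were chosen so that rearrangements at the
scale of interest — interposed blocks of tens of Mb — pass while ordinary
intergenic spacing (tens to hundreds of kb) does not; both are plain
configuration parameters. A candidate collapses to *single-gene
repositioning* (typically retrotransposition or an assembly artefact) when
one shared gene explains two flanking candidate pairs and its removal
leaves the outer neighbours mutually proximal; such genes are removed
before split calling, because they break local synteny without a
block-scale rearrangement.

`callClusterSplit()` then applies the split rule to a named cluster
interval. The cluster is **split** when either

1. a consecutive within-cluster pair is a block-split candidate on one
   target scaffold (the interposed-block case), or
2. the cluster's genes map to two or more target scaffolds *and* the
   `neighborhoodK` (default 5) genes adjacent to a cluster gene on its
   scaffold include at least one gene whose reference orthologue lies
   outside the cluster's chromosome (or chromosome arm, when an arm table
   is supplied) — "genes from elsewhere".

Clusters scattered over scaffolds with no foreign neighbours are
**unresolved**: on a fragmented assembly a multi-scaffold mapping alone is
not evidence of rearrangement, so we deliberately read that situation
conservatively. `neighborhoodK = 5` is the smallest window robust to a
single local annotation error. `measureInsert()` completes the call with
the target-genome extent of the maximal contiguous block of non-cluster
genes between the sub-clusters; when the sub-clusters sit on different
scaffolds the within-scaffold extent is reported and flagged as a lower
bound, since the true block is truncated by a scaffold end.

## Cancer-gene density

`binGeneDensity()` bins TSG/proto-oncogene annotations (5-Mb bins by
default) under two normalizations — per genome-wide label total and per
genes-in-bin — because the two answer different questions (where the labels
are, versus how enriched a bin is). Bins are half-open, so a gene on a
boundary belongs to the bin whose start it equals. Dual-labelled genes
count in both tracks and are listed rather than de-duplicated.
`clusterLabelCounts()` partitions a cluster's labels at the breakpoint
flanks of a split call, with sub-cluster counts guaranteed to sum to the
cluster total.

## Co-expression, compartment scores and divergence

Expression is normalized by `rpkm()` and `quantileNormalize()` (every
column forced onto the shared distribution of sorted-row means; tied ranks
receive the mean of the tied values). `coexpressionMatrix()` computes the
gene-by-gene Pearson matrix over the reference gene order.

`smoothMatrix()` applies, three times by default, the five-term stencil

$$n_{i,j} = \frac{2m_{i,j} + m_{i-1,j} + m_{i,j-1} + m_{i+1,j+1} + m_{i,j+1}}{6}$$

with border neighbours dropped and the divisor reduced accordingly, so a
constant matrix is preserved exactly. The stencil is asymmetric — it
reaches $m_{i+1,j+1}$ but not $m_{i+1,j}$ — and we implement it verbatim
rather than symmetrizing it, because fidelity to the operator's exact
definition matters more than aesthetic symmetry; an optional `(n + n^T)/2`
re-symmetrization is available and off by default.

`leadingSingularVector()` returns the first left singular vector of a
co-expression or normalized contact matrix, sign-oriented so the
largest-magnitude entry is positive (an SVD is sign-ambiguous; this makes
runs comparable). A localized run of high values marks a block whose
co-regulation or spatial contact is self-contained. Ties between the two
leading singular values are flagged degenerate. Missing entries
(zero-variance genes) are imputed as 0 for the decomposition only and
reported as missing.

Cross-species divergence of gene $i$ is $d_i = 1 - \rho(x_i, y_i)$ over
matched tissues, so $d_i \in [0, 2]$, 0 for identical profiles and 2 for
perfectly anti-correlated ones. Tissue matching is always explicit — if
column names differ the function refuses and lists the mismatch — because
guessing a tissue correspondence silently would be worse than failing.
Profiles are smoothed with a trailing running mean (binwidth 10 genes,
output aligned to the window's last gene, length $n - w + 1$, the
convention of the classical `running.mean` routine).
`expressionVsBreakpoint()` correlates any per-gene value with the distance
to the nearest breakpoint. `relativeExpressionRate()` contrasts mean
divergence to an outgroup between a test and a reference lineage over a
gene window, with a seeded bootstrap over genes for the standard error and
a normal Z test; this is deliberately the *simplified* mean-divergence
contrast — no Ornstein–Uhlenbeck trait model is fitted — and its outputs
say so.

## Region-versus-flank tests

`binTrack()` apportions bedGraph interval values to fixed bins by overlap
length (sum conserves total signal exactly; mean is the per-base weighted
mean). `gcTrack()` computes GC% over non-N bases in 100-kb windows.
`regionVsFlankTest()` compares region bins against two flanks, pooled or
per flank — published figures use both, so the result records which was
used. The rank test reports

$$z = \frac{U - n_1 n_2 / 2}{\sqrt{n_1 n_2 (n_1 + n_2 + 1)/12}},
\qquad \eta^2 = z^2 / N,
\qquad d = \frac{m_1 - m_2}{S_{\mathrm{pooled}}}.$$

The p-value uses the exact distribution of $U$ whenever the data are
tie-free and $n_1 n_2 \le 10^4$, and the normal approximation with
tie-corrected variance otherwise; no continuity correction is applied,
and $\eta^2$ always uses the uncorrected $\sigma_U$ printed above, even
in the presence of ties. $z$ and $\eta^2$ are invariant under strictly
monotone transforms of the data; Cohen's $d$ is not — both are always
reported so the reader can compare like with like. `cneLoss()` converts a
per-species presence/lost table of conserved non-coding elements into loss
proportions and windowed baseline contrasts (two identical window profiles
give $p = 1$ rather than an error).

## Phylogenetic signal

`pagelsLambda()` is a from-scratch maximum-likelihood implementation:
under the Brownian model the tip covariance is the shared-path-length
matrix $C$; Pagel's transform scales its off-diagonals by $\lambda$. The
root state and rate are profiled analytically, and $\lambda$ is optimized
by bounded scalar search (tolerance $10^{-8}$) on $[0, \lambda_{\max}]$,
restarted on each half-interval and compared against the endpoints and
$\lambda = 1$, because the profile likelihood can be bimodal near the
bound. $\lambda_{\max}$ is found numerically as the largest value keeping
the transformed covariance positive-definite — for ultrametric trees it
exceeds 1, so estimates slightly above 1 are legitimate; the bound is a
numerical reconstruction of that convention and is reported alongside the
estimate. Star phylogenies
make the likelihood flat in $\lambda$ and are flagged non-identifiable
instead of returning an arbitrary number; tips at zero phylogenetic
distance make $C$ singular and are refused by name. `simulateBMTraits()`
draws from exactly the generating model and serves as the estimator's
oracle in the test suite, alongside an independent cross-check against
`phytools::phylosig`.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions under which every pipeline
stage is validated, with no downloads:

* `generateSplitGenomes()` — a 300-gene reference chromosome with
  log-normal inter-gene spacing (median 60 kb, log-SD 0.8, the scale of
  typical mammalian gene spacing), a 25-gene cluster starting at gene 100,
  and a 150-gene donor chromosome. The default plan interposes 50 donor
  genes after cluster gene 16 with ~1.25 Mb median spacing, giving a
  ~70 Mb foreign block — the scale of the rearrangement the split rule was
  designed for, and mirroring the 16 + 9 sub-cluster structure of the
  motivating locus. Tables are round-tripped through the public TSV
  reader, so the generator exercises the same I/O path as real data.
* `generateExpressionData()` — seven shared tissues; cluster genes load on
  one latent tissue factor with weight $\sqrt{\rho}$ ($\rho = 0.7$),
  every species pair carries baseline divergence 0.1, and the test species
  receives extra divergence $0.5\,e^{-d/2\,\mathrm{Mb}}$ with $d$ the
  distance to the planted breakpoint. Values are exponentiated to an
  RPKM-like scale.
* `generateTracks()` — Gaussian bin values (SD 1) with a mean shift
  $\delta$ inside a 7-bin region flanked by 20 bins each side at 1 Mb
  resolution, matching the region/flank geometry of the signal analyses.
* `generateTree()` — a 200-tip birth–death tree (birth 1, death 0.5).

One global seed fans out to fixed per-component child seeds, so adding a
generator never perturbs existing fixtures, and every generator is
byte-reproducible per seed.

These generators deliberately do **not** emulate: realistic sequence
evolution or indels, assembly fragmentation beyond a single scaffold break
at the breakpoint, one-to-many orthology noise, tissue-specific expression
programmes, or spatially autocorrelated signal tracks. Passing tests
therefore demonstrate that the algorithms recover exactly the structures
they claim to detect under clean, known conditions — not that any
particular biological dataset will be as well behaved.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (biomart convention);
  BED/bedGraph output is 0-based half-open.
* Strand is carried but ignored by all distance computations, which use
  TSS positions only.
* Consecutive genes with equal TSS have distance 0 and can never become
  rearrangement candidates.
* Zero-variance samples make rank tests refuse explicitly rather than
  return `NaN`; empty bins and all-N windows are missing, not zero.
* The bootstrap in `relativeExpressionRate()` refuses `B < 2` and windows
  of fewer than five genes, where a standard error over genes is
  meaningless.
* Raw p-values are reported throughout (no multiplicity correction is
  applied by default), matching how such region tests are conventionally
  presented; users can adjust externally.

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at desk scale: 100
generator seeds for split recovery, exhaustive rank-assignment enumeration
for all $n_1, n_2 \le 7$, $10^4$ genes for divergence calibration, 100
Brownian and 100 signal-free simulations on a 200-tip tree for
$\lambda$ recovery, and 1000 null plus 500 shifted tracks for region-test
calibration — sizes chosen to give stable rates while keeping a full run
in minutes on one core.

## Known limitations

* The split rule detects interposition and foreign-neighbourhood
  structure; it does not type inversions or build whole-genome
  rearrangement graphs.
* Arm-level "foreign" granularity requires a user-supplied arm table;
  without one, whole-chromosome granularity is used, which under-calls
  intra-chromosomal inserts in the cross-scaffold branch (the
  interposed-block branch is unaffected).
* `relativeExpressionRate()` is a mean-divergence contrast, not a full
  evolutionary-rate model.
* On non-ultrametric trees $\lambda_{\max}$ may fall below 1; the fit
  warns accordingly.
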