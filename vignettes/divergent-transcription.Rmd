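---
title: "Quantifying divergent noncoding transcription around binding-site anchors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying divergent noncoding transcription around binding-site anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtx)
```

## The problem

Many sequence-specific transcription factors do more at a promoter than
activate the downstream coding gene: they also repress initiation of a
divergent (antisense-oriented) noncoding transcript from the same
nucleosome-depleted region. Depleting such a factor de-represses those
cryptic promoters, and the signature is strand-asymmetric: RNA-seq signal
appears on the strand *opposite* the coding gene, just upstream of the
factor's binding motif, while sense-strand signal stays flat or falls.

`divtx` implements the computational side of that experiment for budding
yeast-scale genomes. Everything is anchored on a single coordinate per
binding site (the motif midpoint) and oriented by the paired coding gene:

1. strand-separated windows of half-width $w \in \{50, 100, 200, 500\}$ bp
   around each anchor, counted separately for Watson and Crick strands;
2. QC filtering of paired-end reverse-stranded RNA-seq into transcript-
   stranded fragments;
3. transcriptome (median-of-ratios) normalization and a transparent
   log2 fold-change estimator with a strict $\log_2 \mathrm{FC} > 1$
   increase rule;
4. TSS-seq 5′-end tracks per million mapped reads, TSS cluster calling
   with mode peaks, and signed anchor-to-nearest-TSS distances;
5. anchor-centered heatmap matrices, k-means clustering of change
   profiles, and MNase-seq metagene profiles of the promoter NDR.

A ground-truthed synthetic-data generator reproduces the statistical
structure the analysis assumes, so every stage is testable without any
sequencing download.

## Coordinates and anchors

All internal coordinates are 0-based half-open (BED convention); SAM and
GTF inputs are converted at the boundary. The anchor of a binding-site
interval $[s, e)$ is $\lfloor (s+e)/2 \rfloor$: source intervals from
high-resolution ChIP data are a few bases wide and nothing downstream
depends on sub-interval placement, while a midpoint keeps the two strand
windows symmetric. Sites within 500 bp of a chromosome end are removed
before window construction so that every half-width up to 500 bp stays on
the chromosome; `build_stranded_windows()` refuses to build windows that
would run off an end rather than silently truncating them.

Promoter–site pairing is automated rather than curated: each gene is
paired with the nearest anchor within `max_promoter_distance` (default
1000 bp) of its TSS, ties broken by distance and then lexicographic site
id. A window is *sense* when its strand equals the paired gene's coding
strand and *antisense* otherwise; anchors without a pairing stay
unassigned. For factors without mapped sites, `approximate_control_sites()`
places a surrogate anchor a fixed offset (default 250 bp) upstream of each
annotated gene start.

## Alignment filters

RNA-seq pairs are kept when they are unspliced (no reference-skip `N` in
either CIGAR; indels are allowed), primary, uniquely mapped, properly
paired, and have $|\mathrm{TLEN}| \le 500$ bp. "Uniquely mapped" is
operationalized as MAPQ $\ge 1$ and, when present, `NH == 1`, which
tolerates both BWA-style and STAR-style conventions. The library is
reverse-stranded (dUTP), so the transcript strand is the opposite of the
first-in-pair mate's alignment strand, and the counted unit is the full
fragment span (both mates plus the inner gap). Because the 500-bp insert
filter is applied once upstream, a later, looser counting-stage bound
(600 bp) would be vacuous and is not re-implemented.

TSS-seq is single-end: mapped, primary, MAPQ $\ge 1$ reads contribute the
genomic position of their 5′-most transcribed base (alignment start on
`+`, rightmost aligned base on `-`). MNase-seq pairs additionally require
at most two mismatches per read (`NM` tag; records lacking the tag are
rejected by default, configurable) and an insert of 120–200 bp
(mononucleosome selection); duplicates are retained. Every filter emits a
per-rule QC table whose rejected counts plus passing records equal the
input record count.

## Counting and the fold-change estimator

A fragment adds 1 to every window it overlaps by at least 1 bp on the
matching strand (and at most 1 per window); fragments spanning several
windows count in each. The implementation uses `GenomicRanges` interval
overlap, but its contract is the naive double loop over (fragment,
window) pairs, and the test suite enforces exact equality against that
oracle on random instances.

Per-sample size factors come from gene-level counts (union gene body,
stranded, multi-gene overlaps counted in each gene — a deliberately
simple, stable transcriptome summary; isoform-aware estimation would
change the factors by well under the precision that a threshold
classification needs). For sample $j$,

$$ s_j = \operatorname*{median}_{g:\ \forall k\, c_{gk} > 0}
   \frac{c_{gj}}{(\prod_k c_{gk})^{1/m}} . $$

The median is taken on the ratio scale. This matters at even counts of
qualifying genes: interpolating between two ratios on the ratio scale
(giving 0.75 for ratios $\{0.5, 1\}$) differs from interpolating their
logarithms (0.707). Only factor *ratios* are identifiable: scaling one
sample's column by $c$ scales its factor relative to every other sample's
by exactly $c$, while the geometric-mean denominator absorbs a common
$c^{1/m}$.

Fold changes are deliberately transparent rather than shrunken: counts are
divided by size factors, averaged per condition across replicates
(arithmetic mean), and compared as

$$ \log_2 \mathrm{FC} = \log_2 \frac{\bar n_{\mathrm{alt}} + p}
   {\bar n_{\mathrm{ref}} + p}, \qquad p = 1 \text{ (configurable)} . $$

The quantities this package reproduces are threshold classifications and
distribution shapes, not moderated effect sizes, so no dispersion
estimation or hypothesis testing is performed. An "increase" is strictly
$\log_2 \mathrm{FC} > 1$ (a value of exactly 1 is not an increase), and a
*site* is increased when either of its two strand windows is — the OR
rule; per-window fractions by strand, orientation, and window size are
emitted alongside so both summaries are available. Distribution summaries
use type-7 (linear interpolation) quartiles with whiskers at the most
extreme values within 1.5 × IQR of the hinges.

## TSS-seq quantification

5′-end tracks are sparse per-base signals scaled to reads per million
mapped reads; replicate tracks are merged by position-wise arithmetic mean
with absent positions treated as zero, so per-million units are preserved.
Reads are counted toward an annotated TSS when their 5′ base lies within
±75 bp (inclusive) on the same strand; per-million values are
counts-per-million (the windows share a fixed 151-bp width, so length
normalization would be a constant).

TSS clusters group track positions with signal ≥ `min_signal` (default
1 per-million unit) whose consecutive kept positions are ≤ `max_gap`
(default 25 bp) apart. The defaults replace a manual annotation step that
published no thresholds; both are exposed as arguments. The cluster mode
is the position of maximum signal, ties resolved toward the cluster
midpoint and then the lowest coordinate, so mode calling is deterministic.

Nearest-TSS distances exclude the paired gene's own annotated coding TSS
(clusters whose mode falls within ±75 bp of it on the gene strand), since
a canonical coding start is not a cryptic TSS. The search is bounded at
500 bp by default. Distances are signed in gene-coding orientation —
negative on the upstream/divergent side of the anchor, positive toward the
gene body — and equidistant candidates prefer the antisense strand (the
biologically expected direction; the tie is then explicit rather than
platform-dependent). Histograms use half-open 50-bp bins, so $-1$ falls in
$[-50, 0)$ and 0 in $[0, 50)$; bin totals equal the number of anchors with
a detected TSS. Differential TSS signal in ±50-bp anchor windows is
normalized by sequencing depth (factors proportional to mapped-read
totals, centered at geometric mean 1) and then passed through the same
estimator and increase rule.

## Heatmaps, clustering, and MNase coverage

Anchor-centered signal matrices have one row per anchor and one bin per
`bin_size` bp across $[-\mathrm{flank}, +\mathrm{flank})$; point signal is
summed per bin, per-base coverage averaged. In the gene-oriented frame the
axis is mirrored for minus-strand genes so that negative coordinates are
always the divergent side. TSS difference heatmaps fix 5-bp bins; RNA
change heatmaps default to 10-bp bins over ±500 bp (the heatmaps show
spatial structure, so clustering operates on binned profiles rather than a
single window statistic). Clustering input is the antisense- or
sense-strand matrix as selected by the caller, and rows are not
standardized by default (raw change signal is clustered; a z-score flag
exists).

k-means uses `stats::kmeans` (Lloyd) with at least 10 random restarts
under a fixed seed, keeping the best within-cluster sum of squares;
restarts under a seeded RNG give the determinism and solution quality that
matter here, without a bespoke k-means++ initializer. Labels are
relabeled so cluster 1 has the highest mean signal, making cluster ids
comparable across runs. The degenerate case $k$ = number of rows returns
the trivial zero-inertia partition.

MNase occupancy replaces a full nucleosome-positioning model with
midpoint extension: each 120–200-bp fragment contributes a fixed 40-bp
occupancy interval centered on its midpoint, per-base coverage is smoothed
with a 20-bp moving average, and the track is scaled to a fixed
fragment-count equivalent (10^6). A metagene then averages the binned
matrix column-wise per cluster. This reproduces NDR shape at promoters —
the quantity of interest — but is not a nucleosome caller.

## The synthetic-data generator

`sim_config()` defines a toy genome of promoter units tiled on alternating
strands: a coding gene, an anchor 200 bp upstream of its TSS, and a
divergent noncoding unit on the opposite strand whose TSS sits 35 bp
upstream of the anchor — echoing the observation that repression of
divergent initiation acts within a few tens of bp of the motif. Defaults
are chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `coding_rate` | 100 | expected RNA fragments per gene per sample |
| `divergent_baseline` | 50 | expected fragments per divergent unit, reference |
| `depletion_fold` | 4 | rate multiplier at affected sites, depleted condition |
| `fraction_affected` | 0.4 | fraction of sites carrying the fold |
| `n_replicates` | 3 | replicates per condition |
| `library_scales` | 1.0 / 0.8 / 1.25 | per-replicate library-size multipliers |
| `frag_len_*` | N(250, 50) on [100, 500] | fragment-length model, bp |
| `tss_jitter_sd` | 2 bp | spread of read 5′ ends around a planted TSS |
| `ndr_depth`, `ndr_sd` | 0.9, 60 bp | Gaussian MNase depletion at anchors |

Counts are Poisson (a gamma-Poisson overdispersion knob exists for
stress-testing the estimator); fragment starts are uniform within the
unit; reads carry exact-match CIGARs, MAPQ 60, `NH:i:1`, placeholder
bases and qualities — the in-scope filters never inspect base calls, so no
sequencing-error model is simulated. The TSS jitter default of 2 bp
produces the sharp, unimodal initiation clusters seen at real cryptic
promoters and makes the cluster mode a well-defined estimand; wider
clusters can be simulated explicitly. All generators are pure functions of
(config, condition, sample index): the per-stream seed is derived
arithmetically from the master seed, so identical configs give
byte-identical SAM output.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: background (intergenic and readthrough)
transcription, so the spatial decay of increased fractions with window
size has no synthetic counterpart; splicing and multi-mapping; sequence
composition and mappability; batch structure beyond a scalar library
size; and negative-binomial biological variance unless the
overdispersion knob is turned on.

## Problem sizes and verification

The shipped analysis drivers (`analysis/01`–`05`) and the acceptance
script run the full design at 200 anchors, two conditions × three
replicates (~60–150 k fragments per RNA sample, ~25–50 k TSS reads, 60 k
MNase pairs), sizes at which every planted quantity is recovered
comfortably: site-level increased fraction 40%, mean $|\log_2\mathrm{FC} -
2|$ ≈ 0.05 on affected antisense windows, nearest-TSS modes within ±2 bp
of −35 at 100% antisense orientation, and the NDR metagene minimum in the
anchor bin. The test suite additionally checks every counting path
against brute-force oracles, the size-factor formula against a
hand-computable example and against `DESeq2::estimateSizeFactorsForMatrix`
(at odd gene counts, where the ratio-scale and log-scale medians
coincide), and cluster/mode recovery against planted archetypes.

## Known limitations

* The fold-change estimator is unmoderated; at very low counts it is
  noisier than a shrinkage estimator, which is why the increase rule uses
  a 2-fold threshold rather than a significance test.
* Gene-level counting is not isoform-aware; size factors inherit that
  simplification.
* TSS cluster calling is threshold-based; promoters with signal entirely
  below `min_signal` yield no cluster and are reported as undetected
  rather than imputed.
* The MNase model is occupancy-shaped smoothing, not nucleosome calling;
  cluster-level metagenes are meaningful, single-dyad positions are not.
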