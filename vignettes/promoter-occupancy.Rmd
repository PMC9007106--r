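---
title: "Methods: promoter occupancy of broad histone-mark peaks and companion statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter occupancy of broad histone-mark peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Repressive chromatin marks such as H3K27me2/3 are deposited over broad
domains, and a common way to summarize their regulatory impact is to ask,
gene by gene, *what fraction of the promoter is buried under the mark* in
one condition but not another. In the myogenesis setting this package
targets, C2C12 myoblasts stimulated with the circulating protein Klotho
acquire H3K27me2/3 peaks over the promoters of canonical Wnt-pathway genes
(Wnt4, Wnt9a, Wnt10a, several Frizzled receptors and Wnt antagonists)
that carry no such peaks in the vehicle-treated condition — an epigenetic
signature of Wnt-pathway silencing. `promoccupy` reimplements that
quantification and the surrounding bench statistics as tested, reusable
functions.

## Coordinate conventions

Everything internal is **0-based half-open** (`[start, end)`, the BED
convention). Two input dialects are converted at the boundary:

* printed loci (`"chr4:137277489-137299726"`) and the gene-annotation TSV
  are **1-based closed** (the Ensembl table convention): `parse_locus()`
  and `read_gene_table()` subtract one from the start;
* BED / broadPeak / bedGraph files are already 0-based half-open and are
  never shifted.

This single pair of rules reproduces all fourteen published integer
percentages in the bundled fixture, which is the package's golden test.
Chromosome names are compared as exact strings. Unicode hyphen variants
(U+2010, en dash) are accepted in printed loci because published tables
use them.

## The promoter-occupancy statistic

For a gene with transcription start site (TSS) at 0-based position $t$,
the promoter window spans 3000 bp upstream to 300 bp downstream of the
TSS along the gene's own orientation (3300 bp total):

* plus strand: $[t - 3000,\; t + 300)$
* minus strand ($t$ = last base of the gene): $[t - 299,\; t + 3001)$

the same convention `GenomicRanges::promoters()` uses. The occupancy of
the window $W$ by a peak set $P$ is

$$\mathrm{percent} = 100 \cdot \frac{\left|\,\bigcup P \cap W\,\right|}{|W|},$$

with the peaks merged before intersection so overlapping or abutting
peaks are never double-counted (`merge_intervals()` also fuses abutting
intervals; union length is unaffected). The integer percent is rounded
**half-up** (`floor(x + 0.5)`), which is the rounding that matches
published tables; the raw value is always reported alongside.

A *treatment-specific* peak is a treatment peak with **zero** base pairs
of overlap with any control peak. This is the strictest reading of
"found after treatment but not in control"; because the underlying
differential criterion could also be fractional,
`treatment_specific_peaks()` exposes `max_control_overlap_frac` (default
0) to relax it. `occupancy_report()` then keeps genes with treatment
overlap > 0 bp and control overlap = 0 bp, in input gene order — the
published table's schema.

Two numerical details worth noting. Windows that would run off the
chromosome start are clamped at 0 with a warning (the window shortens;
the denominator is the realized window length). And genes shorter than
the 300 bp downstream span still get a full window: the definition is
TSS-relative, not gene-bounded.

The bundled 14-gene fixture carries strand assignments derived from the
published occupancy fractions (they are the unique assignment that
reproduces every printed percent, and agree with the mm10 Ensembl
annotation of these genes). Peak coordinates printed in the source table
are treated as 1-based closed like the gene loci; the alternative 0-based
reading changes each overlap by at most 1 bp and rounds to identical
integers for every row, so the choice is immaterial at the printed
precision.

## Read-density matrices

`density_matrix()` reproduces the reference-point ("peak center") matrix
of the usual ChIP-seq heatmap tooling directly from a bedGraph step
function. Each peak contributes one row centered at
`floor((start+end)/2)`; bin $i$ of width $b$ covers
$[c - f + (i-1)b,\; c - f + ib)$ and holds the *exact* mean depth — the
integral of the step function over the bin divided by $b$ — rather than a
sampled approximation. Defaults are $f = 1000$ bp (the ±1 kb window of
the study design) and $b = 50$ bp, the conventional bin of the tool the
field uses; the bin size is not stated in the source study, so it is an
explicit, configurable default. All-zero rows are dropped by default
(`skip_zeros`), mirroring standard practice, and the drop count is
reported. Row order — descending row mean, ties by region id — is a
deterministic stand-in for the unstated heatmap ordering.

Mass conservation (`sum(row) * bin_size` equals the integral of depth
over the profiled window) holds exactly for rational inputs and is
tested against a per-base oracle on random step functions.

## Over-representation analysis

`enrich()` scores each gene set by the upper-tail hypergeometric
probability of observing at least $x$ annotated genes in a query of $n$
drawn from a universe of $N$ containing $K$ annotated:

$$p = \sum_{k=x}^{\min(n,K)} \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}}.$$

The sum is accumulated in log space via `lchoose()` so it is stable for
genome-scale universes (~20k genes). `ease_p()` implements the
EASE-score variant of DAVID's modified Fisher's exact test — the hit
count penalized by one — which dominates the raw p-value and sends
single-hit terms to 1. The universe is an explicit argument (typically
all genes in the annotation), never inferred from the GMT: which universe
a published analysis used is rarely recoverable, so it is left in the
user's hands. Raw p-values are the headline (−log10 p is what
enrichment figures plot); Benjamini–Hochberg adjustment is optional.

A calibration note: hypergeometric p-values are discrete, so the
attainable test size at a nominal 0.05 threshold depends strongly on
$(n, K, N)$ and is usually well below 0.05. The type-I calibration test
in the suite therefore uses a collection designed analytically up front —
universe of 2000 genes, disjoint sets of sizes
{65, 75, 183, 252, 287, 299}, queries of 150 genes — for which the
attainable size is 0.0494–0.0500, making "fraction of null terms at
p ≤ 0.05 ≈ 0.05" a meaningful check rather than an impossible one.

## qPCR normalization

Following the study's protocol, the per-sample normalization factor is
the **geometric mean of the reference-gene Ct values**
(`exp(mean(log ct))`; defaults emulate the three empirically stable
reference genes Srp14, Hprt1, Rnps1). The relative quantity of target
$g$ in sample $s$ is

$$\mathrm{raw}_{s,g} = B^{\,\mathrm{NF}_s - \mathrm{Ct}_{s,g}},$$

with amplification base $B = 2$ (100% efficiency) by default; a
standard-curve base $10^{-1/\text{slope}}$ can be supplied. Each gene is
then scaled so its maximum across samples is exactly 1 ("highest
relative expression set to 1"); exact ties all scale to 1 and are
flagged. Group summaries report mean ± SEM.

One subtlety: using the geometric mean of Ct values as a Ct *offset* is
only approximately invariant to sample-wide Ct shifts when the reference
Cts differ from one another (the geometric mean is not shift-equivariant;
with a single reference gene, or equal reference Cts, the invariance is
exact — and that is the regime in which the suite tests it). Between-group
fold-change recovery is unaffected, because reference-stable designs give
every sample the same factor up to noise. For the noisy parameter-recovery
tests, the planted fold is estimated as the difference of group means of
log2 relative quantity — a ratio of geometric means — because that
estimator is linear in Gaussian Ct noise and hence unbiased for the
planted log2 fold.

## Morphometry

`csa_stats()` summarizes fiber cross-sectional areas (µm²) with n−1
dispersion and a binned frequency distribution (default bin 200 µm²;
source figures bin their distributions but do not state the width).
`classify_sizes()` sets thresholds at the **control** group's mean ± k·SD
(default k = 3, lower bound clamped at 0) and partitions the **test**
sample into small / within / large, boundary values counting as within;
the three fractions sum to 1 and the partition is invariant under
rescaling both samples. `count_ratio()` covers cells-per-100-fibers,
myonuclei-per-fiber and co-label proportions. `group_compare()` is
deliberately thin plumbing over standard machinery: Student's t (or
Wilcoxon rank-sum — the source's "non-parametric Student's t-test" is a
contradiction in terms, so both are explicit options) for two groups, and
one-way ANOVA with Dunnett's many-to-one comparisons (first group =
control) or Tukey's all-pairs post hoc otherwise, flagged at p < .05.

## What the synthetic generators emulate — and what they do not

`sim_spec()` fixes the study conditions: 14 genes on a ~3 Mb chromosome
planted with the published occupancy fractions (treatment-only),
background peaks at least one window-length away from every promoter and
shared between conditions, 5× read-density enrichment over unit
background inside peaks, a two-group qPCR design with n = 5 per group,
three noise-free-baseline reference genes and Ct noise SD 0.2 cycles,
and lognormal fiber areas (meanlog log 600 µm², sdlog 0.45, n = 500 per
group — the study's per-section sampling floor) with a 30% smaller
treated-group mean, matching the reported early-postnatal effect
direction. Planted overlaps are realized as one contiguous peak fully
inside the window covering exactly `round(fraction × 3300)` bp, so the
intended percent is exact by construction; splitting into abutting
sub-peaks is covered by the union-semantics property tests instead.
Every generator is a pure function of the spec: the seed is threaded
through `withr::with_seed` sub-streams and never leaks into the caller's
RNG.

What passing these tests shows is that the *computation* is right:
coordinate conventions, union semantics, strand handling, normalization
algebra, estimator calibration. What it cannot show is fidelity to real
data: the generators produce rectangular peaks, piecewise-constant
coverage without read noise or mappability structure, reference genes
that are stable by fiat, and fiber areas from a single lognormal. The
study's biological effect sizes (fiber CSA differences between
genotypes, the >680-fold myogenin induction upon differentiation) are
properties of the animals and cells, not of this code, and are out of
scope.

## Problem sizes used by the test suite

The suite runs at the sizes the guarantees are stated for: the complete
hypergeometric enumeration sweep for universes up to 12; 1000 random
gene/peak configurations against the per-base overlap oracle on a 100 kb
toy chromosome; 500 random step functions for the density oracle; 1000
null-query enrichment simulations; 200 noisy qPCR replicates; 10⁴-fiber
normal samples for the 3-SD classification check (expected outside
fraction 2Φ(−3) ≈ 0.0027); and 100 random end-to-end simulations with
exact recovery of every planted percent. The full suite completes in
about a minute on one CPU.

## Known limitations

* Peak files are consumed, never called: no MACS2 reimplementation, no
  significance model for differential binding (the underlying design has
  no replicates).
* bedGraph is the only coverage format (no bigWig binary I/O); GTF
  full-grammar parsing is out of scope — the annotation TSV is the
  contract.
* The enrichment stage tests over-representation only; no GO-DAG
  propagation or term database is bundled, so published term lists
  (database-version dependent) are not reproduced.
* Primer-efficiency estimation, melt-curve QC and the reference-gene
  suitability screen are upstream of the Ct table and out of scope.
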