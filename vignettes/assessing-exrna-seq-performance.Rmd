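---
title: "Assessing biofluid total RNA-seq performance with spike-in controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing biofluid total RNA-seq performance with spike-in controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exrnaperf)
```

## The problem

RNA sequencing of biofluids (plasma, urine, conditioned medium) and of the
extracellular vesicles (EVs) they carry operates at the edge of what library
preparation can handle: picogram inputs, wildly different RNA content between
fluids, and a large population of barely detected genes. Before such data can
support biological claims, the measurement process itself has to be
characterised: how true are measured fold changes, how much RNA does each
fluid actually contain, how precise are replicates, and where should the
detection threshold sit.

`exrnaperf` implements that characterisation as a reusable statistics layer.
It starts from gene-by-sample count tables (the output of any quantifier) in
which two synthetic spike-in panels — ERCC (92 RNAs, added at RNA isolation
elution) and Sequin (78 RNAs, added at lysis) — are quantified alongside the
endogenous genes. Everything upstream of the count table (trimming,
deduplication, alignment, pseudo-alignment, read tagging) is out of scope;
read-category and chromosome-origin tallies are consumed as pre-tagged
tables.

## Models and statistics

### Titration trueness

In the titration experiment, five aliquots of one RNA pool receive both spike
panels in opposing 5-point geometric dilution series (Sequin 1/15000 …
1/60000, ERCC 1/100000 … 1/25000; a factor ~1.414 per step, 4-fold across the
extremes). Spike concentration is proportional to the dilution factor $d$, so
for samples $a, b$ the designed log2 fold change of each spike is

$$E = \log_2(d_a / d_b),$$

while the observed value is $O = \log_2(k_a / k_b)$ from counts after both
libraries are subsampled to equal depth. Trueness is summarised three ways,
all on the pooled per-spike table:

* ordinary least squares of $O$ on $E$ *with* intercept; the slope (ideal: 1)
  and the adjusted $R^2$ (with the usual $n-2$ correction) are reported.
  The conventional summary reports only "slope" and "adjusted R²"; fitting
  with an intercept is this package's documented choice so that a constant
  offset does not masquerade as a slope defect.
* the deviation $\Delta = O - E$ per spike, flagged when the mean of the two
  counts falls below `trueness_min_count` (default 10 counts — small fold
  changes are unreliable below that level);
* `fraction_within`: the share of spikes with $|\Delta| \le \tau$, pooled and
  stratified by $|E|$, for thresholds $\tau$ (default 0.5 and 1 log2 units).

Spikes with a zero count in either sample are excluded rather than
pseudocounted — a pseudocount would fabricate a fold change exactly where the
data say nothing — and are returned in a separate zero-count table so nothing
disappears silently.

Which sample pairs populate the analysis is genuinely open (the original
figures do not say). `trueness()` therefore exposes four pairing modes:
`"reference"` (all samples against the mid-dilution sample; the default,
because it uses every sample once and centres the $|E|$ range), `"adjacent"`,
`"extreme"` and `"all"`, plus explicit pair lists.

### Relative RNA concentration

Spike reads and endogenous reads compete for a fixed sequencing budget, so
with a constant spike amount the ratio

$$R = \frac{\sum \text{endogenous counts}}{\sum \text{spike counts}}$$

rises with endogenous RNA content. Correcting for the spike amount actually
added (represented by its dilution factor $A$; one common stock is assumed)
and the original biofluid volume $V$ (microlitres, converted to ml) gives a
relative concentration per millilitre:

$$\rho = R \cdot A / V_{\text{ml}},$$

comparable across samples and summarised as fold differences. The endogenous
sum deliberately includes mitochondrial and rRNA counts — no exclusion beyond
the spikes themselves is applied — and the ERCC panel alone is the default
denominator (it is the panel added to the eluate); Sequin can be selected
where it was spiked. $R$ is invariant to sequencing depth in expectation,
which the test suite verifies by subsampling.

### Replicate precision: the ALC

For two technical replicates, genes with at least `detection_cutoff` counts
in *both* replicates (the pairwise rule makes "reproducibly detected"
operational) contribute an absolute log2 ratio $|\log_2(k_a/k_b)|$. The
empirical cumulative distribution of these ratios is summarised by the area
left of the curve (ALC): integrating the quantile function over probability,
which for a step CDF is exactly the arithmetic mean of the ratios. Lower ALC
means tighter replication; $2^{\text{ALC}}$ converts it to a linear fold
change. The common reading of the ALC as "the fold change that half of the
genes stay under" is, strictly, the median; since mean and median of these
distributions sit close together but are not the same number, both
`alc` and `median_ratio` are reported and neither is silently substituted for
the other. The Pearson correlation of log2 counts over retained genes is
included as the familiar scatter-plot companion statistic.

### The count cutoff from single positives

A gene observed in exactly one of two technical replicates (a *single
positive*) is noise by construction. For each candidate cutoff $c$,
`single_positive_analysis()` computes the fraction of single positives whose
nonzero count is below $c$ — the share that requiring $\ge c$ counts would
remove — and chooses the smallest $c$ reaching `removal_target` (default
0.95). The fraction of *double positives* that the same rule would discard is
reported as the cost side of the trade-off. With no single positives at all
the report is flagged and the smallest candidate returned, rather than
erroring, so pipelines keep running on unusually clean data.

### Subsampling

Libraries are compared after drawing exactly `subsample_depth` reads per
sample *without replacement* (multivariate hypergeometric across features,
implemented as sequential conditional `rhyper` draws). This matches
read-level subsampling semantics — sampling reads that exist — rather than
binomial thinning, guarantees exact column totals, and is deterministic given
the seed recorded in the run manifest.

### Composition and overlap

`composition()` reports fraction families per sample: read-mapping categories
(from a pre-tagged tally table), chromosome origin (nuclear / mitochondrial /
rRNA), region class, and the biotype breakdown computed over *exonic
endogenous* counts only. Families whose total is zero are reported absent
rather than as 0/0. `top_n_consumption()` gives the read share of the $n$
most abundant genes (ties broken by feature id for determinism);
`percentile_coverage()` rescales a per-base coverage vector onto 100
equal-width gene-body bins normalised to mean 1. `overlap()` counts shared
and unique detected genes between two samples with the Jaccard index
$J = s/(s+u_a+u_b)$ and tabulates the counts of the unique genes, which in EV
versus parent-fluid comparisons are expected to concentrate at low abundance.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `detection_cutoff` | 4 | counts | gene called present; the single-positive scan justifies it |
| `subsample_depth` | 1e6 | reads | equal footing before any comparison |
| `trueness_min_count` | 10 | counts | low-count flag on spike fold changes |
| `deviation_threshold` | 0.5 | log2 | headline trueness threshold (factor 1.41) |
| `removal_target` | 0.95 | fraction | single positives the cutoff must remove |
| `random_seed` | 1 | — | seeds every stochastic step, recorded in the manifest |

## What the synthetic generator does and does not emulate

The generator exists so that every statistic has a testable input with known
truth; it is a first-class module, not a fixture.

* `make_spike_panels()` produces log-spaced stock concentrations over
  `dynamic_range_log2` (default 10) log2 units. Real panel sheets span a
  wider range; 2^10 keeps essentially all members above the zero-count floor
  at the simulated depths, which is the regime the trueness statistics are
  about. Real sheets can be loaded from TSV instead.
* `make_titration()` scales expected spike counts as stock × dilution with
  the two panels opposed, fills the rest of the library with log-normal
  endogenous genes, and draws counts as Poisson, negative binomial, or
  deterministically (`noise = "none"`). In the deterministic mode, per-spike
  base counts are rounded half-to-even at the most-dilute sample and
  multiplied by the relative dilution, so every sample pair whose designed
  ratio is an integer (1:2:4 across samples 1, 3, 5 of the default series)
  reproduces its expected fold change *exactly*; pairs involving the
  irrational ~1.41 steps carry only integer-rounding error. This is the
  package's determinism choice for count integrality.
* `make_replicates()` plants a biofluid profile: gene abundances are
  log-normal, rescaled so the read mass of every biotype × chromosome ×
  region cell matches the planted weights exactly in expectation; replicate
  counts are negative binomial with the dispersion of the chosen replicate
  level (RNA-isolation replicates, default 0.08, are more dispersed than
  library-prep replicates, default 0.02 — the ordering is the substantive
  claim, the magnitudes are free parameters); single-positive noise genes are
  injected at rate 0.10 of the gene count with counts uniform on {1, 2, 3},
  present in exactly one replicate. The planted concentration default (0.01
  units/ml at 200 µl input and 1/25000 ERCC dilution, i.e. an
  endogenous:spike ratio of 50 and a ~2% spike read share) places spike
  coverage inside the endogenous abundance range, which is what the titration
  design aims for.
* Presets: `"ePRP"` (mitochondria-heavy, mito weight 0.77), `"ePFP"` (mito
  0.26), `"urine"` (12000 genes, nuclear-dominated).

Not emulated: read-level artefacts (PCR duplication, fragment-length and
strandedness effects, mapping ambiguity), batch and donor effects,
between-biotype abundance structure, and the heavy dominance of a few genes
seen in platelet-rich plasma (the log-normal tail is milder). Tests passing
on synthetic data therefore demonstrate that the *statistics* are computed
correctly and recover planted truth under the stated noise models — not that
any particular real biofluid will reach a given slope, ALC or cutoff.

## Numerical and degenerate-input choices

* Counts are validated as non-negative integers; rounding fractional
  upstream estimates is the caller's responsibility and is deliberately not
  done silently.
* Zero-count spikes: excluded from fold changes, reported separately.
* Zero spike totals in a sample abort concentration analysis (failed spike
  recovery is a wet-lab signal, not a number to propagate).
* `fraction_within` on an empty table, `alc()` on an empty vector and
  regression on fewer than 3 points or constant expectations are errors, not
  NaNs.
* All-zero coverage vectors return a flagged all-zero profile; all-zero
  fraction families are reported absent.
* Ties in `top_n_consumption` break by feature id.
* Reports round-trip: integers exactly, reals to at least 12 significant
  digits.
* The run manifest records the seed, the configuration, input fingerprints
  and the package version, but no wall-clock timestamp: output bundles are
  byte-identical across reruns with identical inputs, which we consider the
  more valuable property for a QC tool.

## Problem sizes

The shipped end-to-end demonstration (and `make_assessment_dataset()`
default) uses a 5-sample titration plus three biofluid replicate pairs at
300,000 expected reads per library, subsampled to 250,000 — small enough to
run in seconds, large enough that every per-library statistic operates in
its asymptotic regime. Parameter-recovery checks (the planted 17-fold
concentration difference, composition weights) use 1,000,000 reads, the depth
the analysis defaults assume.

## Known limitations

* Concentration estimates assume one spike stock across compared samples;
  different stocks would need an explicit molar bridge, which is out of
  scope.
* The endogenous:spike ratio inherits any spike-recovery failure; the
  package can only refuse to compute, not correct it.
* Trueness regression pools per-spike fold changes across the selected
  pairs; pairs sharing a sample are not independent, so the adjusted $R^2$
  is a descriptive, not inferential, quantity.
* Gene-body coverage operates on externally computed per-base vectors; no
  transcript-model handling is attempted.
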