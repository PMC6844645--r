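---
title: "Methods: TF-anchored nucleosome positioning, bookmarking and reactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-anchored nucleosome positioning, bookmarking and reactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Transcription factors (TFs) such as CTCF organize chromatin locally: a
nucleosome-depleted region (NDR) sits over the binding motif, flanked by
nucleosome-ordered arrays (NOAs) — regularly spaced nucleosomes whose
phasing decays with distance from the motif. Replication and mitosis
disrupt this architecture, and the degree to which a TF re-imposes it
(immediately after the replication fork passes, or on condensed mitotic
chromatin) is a quantitative question with three measurable faces:

1. **Where are the nucleosomes?** Fragment-midpoint profiles around
   oriented motifs, corrected for enzymatic sequence bias, summarized by
   ECDF-median positions and smoothed metaplot maxima.
2. **Is the TF still bound in mitosis?** A count model comparing ChIP to
   input in both cell-cycle phases, classifying each peak as lost (L) or
   bookmarked (BI/BS/BM).
3. **Does binding matter for reactivation?** Spike-corrected nascent
   expression (or promoter accessibility) trajectories, clustered, and
   tested for proximity enrichment of peaks.

`nucbook` implements all three layers plus a synthetic-data generator
with planted ground truth, so every stage is testable end to end without
external sequencing data.

# Fragments and cut-bias correction

Fragments live in BED conventions: 0-based half-open `[start, end)`,
length `end - start`, last covered base `end - 1`, and midpoint
`floor((start + end - 1) / 2)` (the left of the two central bases for
even lengths — the convention must be fixed somewhere, and this one keeps
midpoints integral). Filters keep uniquely aligned pairs with edit
distance strictly below 4, collapse duplicates on (position, strand,
UMI barcode), and size-select by the V-plot-derived windows: 140–200 bp
for nucleosomes (120–200 bp for pulse/chase libraries with shifted size
distributions), < 100 bp for TF footprints. Accessibility cut sites are
the two fragment ends shifted inward by 4 bp.

Micrococcal nuclease cuts sequence-preferentially. The bias model
measures, for each fragment end, the 6-mer centered on the end coordinate
— two 3-mers, one inside and one outside the fragment — reverse-
complementing right-end 6-mers so both ends read in the cut orientation.
With `gamma` the genomic rate of a 6-mer (both strands, pseudocount 100
added to raw counts before normalization) and `rho` its rate at observed
cut sites, the observed/expected ratio of a fragment is
`rho(kL) rho(kR') / (gamma(kL) gamma(kR'))`. The applied weight defaults
to the **reciprocal** of this ratio: a fragment whose ends sit in
preferentially cut contexts is over-observed and must be down-weighted.
Multiplying by the ratio itself (available as `orientation = "ratio"`)
amplifies the bias instead — the package's tests verify that only the
reciprocal flattens an occupancy-flat biased simulation. The end-PWM QC
(`end_pwm()`) checks the symmetry assumption behind using one model for
both ends: the left PWM should match the reverse complement of the right.

# Profiles

`midpoint_profile()` accumulates weighted midpoints per base pair at
strand-oriented offsets. Units are midpoints-per-billion (MPB):
`1e9 / total mapped fragments` for the standard analysis, or
`1e9 / total nucleosome-sized fragments` (`per_feature`) for libraries
whose fragment-size composition shifts between conditions. The
denominator counts weighted fragments; weighted midpoints and weighted
fragments are the same total because each fragment contributes one
midpoint. Metaplots are unweighted means across site rows. Condition
comparisons (pulse/chase to input; treated to untreated) rescale one
profile so its total signal in [-1 kb, +1 kb] matches the reference.

# Gaussian-process smoothing and the phasing statistic

Metaplot counts are overdispersed; the model stabilizes variance with
`y = log(alpha m + beta)`, `alpha = 1000`, `beta = 1`, then assumes a
Gaussian likelihood. `alpha` is exposed because the transform's
"comfort zone" depends on the scale of `m` (mean MPB per site versus raw
counts); the back-transformed posterior median is invariant to that
choice in the well-sampled regime.

`fit_gp()` is a sparse variational GP with a squared-exponential kernel:
the collapsed (inducing-point) lower bound on the log marginal
likelihood, maximized by L-BFGS-B with analytic gradients in
log-hyperparameter space. Inducing inputs sit on a fixed 10-bp grid over
the training support; at this density the bound is tight for the
lengthscales that matter here (>= 25 bp), so inducing-point optimization
is unnecessary. Initialization is `sigma_f2 = var(y)`, `lengthscale =
50` bp, `sigma_n2 = 0.1 var(y)`, with seeded multi-start (3 restarts by
default). Hyperparameters are trained on [-500, 500] bp — or on an
interval union such as [-500,-100] U [100,500] when the region around
the anchor is non-stationary (e.g. nucleosomes rolling over the motif
after TF depletion) — and predictions are made over the full window.
The training signal is centered, so predictions far from support revert
to the data mean. Two guarantees are tested continuously: the bound
never exceeds the exact dense-GP log marginal likelihood computed at the
same hyperparameters, and sparse predictions agree with the dense
posterior to well under 0.1%.

Phasing is summarized by the spectral density of the fitted kernel at
the nucleosome-plus-linker period (180 bp):
`S(s) = sigma_f2 * sqrt(2 pi l^2) * exp(-2 pi^2 s^2 l^2)`, `s = 1/180`,
reported as log10 and evaluated in log space so that long lengthscales
cannot underflow. This is the standard Fourier transform of the SE
kernel — a function that increased without bound in `s` could not be a
spectral density, so the implementation fixes the radical and the sign
of the exponent and verifies the closed form against numerical Fourier
integration to 1e-6 relative. A well-phased array fit has substantial
variance at lengthscales comparable to the linker spacing, giving a high
log10 S at p = 180; shuffled midpoints collapse `sigma_f2` (and the
statistic) by hundreds of log units.

# Nucleosome positioning and displacement

The -1/+1 nucleosome positions are ECDF medians of midpoint counts in
[-230, -70] and [70, 230] bp: the smallest position whose cumulative
fraction reaches 0.5 (with a 1e-9 tolerance so exact ties survive
floating-point rescaling of counts). Binned analysis aggregates sites in
100-site bins descending by peak height, optionally GP-smoothed across
the bin index.

Metaplot-level maxima come from the smoothed median curve: local maxima
by derivative sign change on the 1-bp grid, merged when closer than a
third of the expected spacing, then assigned to -n..+n by distance from
the anchor. One numerical guard is added to the bare derivative rule: a
maximum must rise above its flanking valleys by at least 5% of the curve
range (`min_prominence`). At desk-scale coverage the flat NDR bottom
carries sampling ripples that the sign rule would otherwise call as
(spurious, closest-to-anchor) nucleosomes; on densely averaged data the
guard is inert.

Displacements between conditions are reported with negative = toward
the motif, for either side of the anchor, and classed stable below 5 bp
and moved at or above it.

# Mitotic bookmarking

Per peak, counts follow a negative-binomial log-linear model
`~ ChipTF + ChipM + offset(log(total mapped reads))`, where `ChipTF` is
1 for every ChIP sample and `ChipM` is 1 for mitotic ChIP samples only.
This coding is the only one under which the three quoted contrasts are
simultaneously interpretable: `ChipTF` = interphase ChIP/input fold
change, `ChipTF + ChipM` = mitotic ChIP/input fold change, `ChipM` =
interphase-mitosis difference. Input samples of both phases share the
baseline. Size factors are total mapped reads, deliberately not
median-of-ratios: almost every peak is expected to differ between ChIP
and input and between phases, so expression-style size factors would
absorb signal.

Dispersion is estimated per peak by Cox-Reid adjusted profile maximum
likelihood (floored at 1e-8), with no moderation across peaks. Plain ML
at eight samples is biased low, which makes Wald tests anti-conservative
(null |z| < 2 coverage ~0.87); the Cox-Reid adjustment — the same
small-sample correction the established count-model packages use —
restores ~0.92 without borrowing information across peaks. A
`fixed_dispersion` argument fits the GLM at a known dispersion; at the
1e-8 floor this is the exact Poisson limit and reproduces the
closed-form Poisson GLM z statistics, which the tests verify.

Classification: a peak is bookmarked iff its mitotic occupancy is
significant (BH FDR < 0.05 on `ChipTF + ChipM`, no independent
filtering) **and** both mitosis replicates were called below 0.01 by the
peak caller **and** at least one mitosis replicate below 1e-10 —
a deliberately conservative AND that guards against interphase
contamination of mitotic preparations. Bookmarked peaks split on the
`ChipM` Wald test: BI when significantly higher in interphase (negative
`ChipM` coefficient), BM when higher in mitosis, BS otherwise. All
thresholds are strict inequalities.

# Reactivation dynamics

Libraries are depth-normalized to 15 million exonic + transcript reads
(spikes included in the total); spike correction then computes, per
condition, the replicate-averaged total spike count `s_C` and the factor
`sigma_C = mean_c(s_c) / s_C`, applied to transcript counts. After
correction the per-condition spike means are exactly equal — the
defining invariant. The correction's purpose is to keep genuine global
shifts (e.g. mitotic transcriptional shutdown) that depth normalization
would otherwise erase: whatever multiplies genes and spikes together
cancels, and only gene signal relative to the spikes remains.

Genes are kept when their corrected transcript count exceeds 10 in every
replicate of at least two conditions and the reference-condition mean
RPKM (counts per kb of intronic transcript model per 15 M reads) exceeds
2/15. Log2 fold changes versus the reference use condition means with a
pseudocount of 1 on the corrected scale (immaterial above ~100 counts);
the all-zero reference column is excluded from clustering.

K-means runs for k = 2..20 (Euclidean, 50 restarts per k, best inertia),
and consecutive solutions are compared by the plain Rand index —
agreeing pairs over all pairs. The selected k is the smallest k **from
which the trace stays above 0.85** for all larger k. The alternative
reading — the first single trace value above 0.85 — fails on exactly the
data the procedure targets: when an early step merely splits off a small
distal cluster, its Rand index is high even though later steps still
reshuffle genes; requiring the tail of the trace to stay high is the
reading consistent with selecting the true k on well-separated planted
clusters. Fifty restarts (rather than a handful) matter for the same
reason the selection is non-trivial: with unequal cluster sizes the
best-inertia solution is missed ~30% of the time at 10 restarts.

Peak-proximity enrichment sweeps x over [1, 1e6] bp (50 log-spaced
points by default): at each x, a one-sided Fisher exact test of
in-cluster versus all other clustered genes against TSS-within-x of the
nearest peak edge (0 when overlapping). Enrichment p-values match direct
hypergeometric summation exactly on small tables. The repli-ATAC variant
feeds promoter accessibility (cut sites of 1–100 bp fragments in the
oriented [-200, 0] window, per million library fragments) through the
same filter/log2FC/k-means/Fisher chain after floors of 0.15 in all
samples and 0.5 at steady state.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under.

* **Genome and sites.** I.i.d. sequence at a chosen GC content; motifs
  written in at non-overlapping positions at least twice the profile
  window apart, with log-normal peak heights.
* **Arrays.** Per site, fragments are a mixture: TF footprints (lengths
  U[30, 90], midpoints within ±20 bp of the motif; fraction 0.3),
  nucleosomal fragments (lengths ~N(167, 15) truncated to [100, 250])
  at planted centers `±(80 + spacing/2 + k·spacing)` with jitter SD 20 bp
  growing 50% per nucleosome index, a diffuse unphased background
  (fraction 0.15, uniform over the array span with jitter-smoothed edges,
  excluded from the NDR), and an NDR-invasion component (fraction 0.005,
  uniform inside the NDR). The mitotic condition slides the +1 nucleosome
  25 bp and the -1 nucleosome 3 bp toward the motif. The background and
  edge smoothing are not cosmetic: without them the planted profile has
  hard steps that a stationary-kernel GP rings on, producing artifactual
  maxima no real metaplot shows.
* **Cut bias.** A GC-graded preference over 6-mers; candidate fragments
  are accepted in proportion to the preference of both end k-mers
  (rejection sampling, acceptance rate logged), so realized end k-mer
  rates follow genome rate × preference.
* **Bookmarking counts.** NB counts for input/ChIP × phase × replicate
  with per-peak log-normal base rates and planted category-consistent
  log2 enrichments; category proportions default to the reported
  CTCF-class tallies (~43/36/20/1% for L/BI/BS/BM). Caller FDRs are
  emulated by a per-replicate one-sided Poisson enrichment test,
  BH-adjusted — the classification only ever consumes the FDR columns.
* **Expression.** Five trajectory clusters in log2FC space with unequal
  sizes (slow clusters smaller, as in the real heatmaps), NB counts with
  dispersion 0.02, fixed spike abundances distorted per condition by
  `spike_capture` (the technical spike loss the correction must undo),
  and TSS coordinates with peaks planted near one cluster.

**What passing tests do and do not show.** The generator plants the
structures the methods are designed to detect, under idealized
conditions: a single chromosome, i.i.d. background sequence, sites that
never overlap, no mappability gaps, no copy-number structure, honest
UMIs, and categorical ground truth. Recovery of planted parameters
demonstrates correctness of the computations and internal consistency of
the pipeline — not that real chromatin satisfies the models, nor any
genome-scale tallies, which depend on real sequencing data.

# Problem sizes and numerical choices

The shipped tests and the reproduction script run, by choice, at desk
scale: 3,000 sites × ~100 fragments/site for displacement recovery
(recovered within ±4 bp of the planted 25/3 bp), 250 sites × 100 seeds
for phasing discrimination (phased beats shuffled in 100/100 seeds),
2,000 peaks for bookmarking (balanced accuracy ~0.92; null false-call
rate far below the 5% nominal level), 1,500 genes in five clusters for
reactivation (k = 5 selected; assignment agreement ~1.0; the planted
proximal cluster tops the Fisher sweep at 100 kb). Kernel matrices get
a relative jitter of 1e-8 on the diagonal; GP hyperparameters are
box-constrained in log space (lengthscale in [2, 2000] bp); the ECDF
median uses a 1e-9 tie tolerance; Fisher tests use `fisher.test`
(checked against hypergeometric summation); BH uses `p.adjust`.

# Known limitations

* Bias correction is k-mer-only; mappability-aware correction is out of
  scope.
* Dispersion is per-peak; no shrinkage across peaks, so very shallow
  peaks have noisy dispersion and the BS/BI boundary blurs first.
* The GP assumes stationarity within the training interval; the
  interval-union mechanism is the escape hatch, not a fix, for strongly
  non-stationary anchors.
* Single-site nucleosome calling is out of scope; positioning operates
  at bin or site-set level.
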