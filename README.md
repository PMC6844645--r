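# nucbook

Quantitative analysis of transcription-factor-anchored chromatin
architecture across the cell cycle: nucleosome positioning around
binding motifs from MNase-seq-style fragment data, classification of
mitotic bookmarking from ChIP/input counts, and the link between TF
binding and gene-reactivation dynamics after mitosis and replication.

Who it is for: computational biologists working with paired-end
chromatin fragment data (MNase-seq, MNase H3 ChIP-seq, pulse/chase
nascent-chromatin MNase, ATAC-seq) around motif-centered TF binding
sites, and with ChIP/input count tables or spike-in normalized nascent
RNA-seq.

## What it computes

**Nucleosome organization.** TF binding sites show a nucleosome-depleted
region (NDR) over the motif flanked by phased nucleosome arrays.
`nucbook` builds bias-corrected fragment-midpoint profiles in
midpoints-per-billion (MPB), V-plots (midpoint offset × fragment
length), and metaplots. Enzymatic cut bias is estimated from the 6-mers
over fragment end coordinates: with γ(k) the genomic rate of 6-mer k and
ρ(k) its rate at cut sites, each fragment's observed/expected ratio is
ρ(kL)ρ(kR†)/γ(kL)γ(kR†) (kR† = reverse complement of the right-end
6-mer) and the applied weight is its reciprocal, which flattens the
bias.

**Positioning and phasing.** Metaplots are smoothed by sparse
variational Gaussian-process regression (squared-exponential kernel,
inducing inputs every 10 bp, variance-stabilizing transform
y = log(1000·m + 1)). Nucleosome positions come from ECDF medians —
the smallest position i with F(i) = Σ_{k≤i} m_k / Σ_k m_k ≥ 0.5 in the
±[70, 230] bp windows — and from maxima of the GP posterior median.
Phasing is the kernel spectral density at the nucleosome-plus-linker
period, S(s) = σ_f² √(2πl²) exp(−2π²s²l²) at s = 1/180, reported as
log10.

**Mitotic bookmarking.** Per peak, a negative-binomial GLM
`count ~ ChipTF + ChipM + offset(log(depth))` with Wald tests of the
interphase enrichment (ChipTF), mitotic enrichment (ChipTF + ChipM) and
phase difference (ChipM); per-peak Cox-Reid adjusted ML dispersion; BH
FDR without independent filtering. Peaks are bookmarked when mitotic
occupancy is significant and the mitosis peak-caller support is strong
(both replicates FDR < 0.01, one < 1e-10), then split into BI/BS/BM by
the phase-difference test; everything else is Lost (L).

**Reactivation.** Spike-corrected nascent expression: depth
normalization to 15 M reads, per-condition spike factors
σ_C = (Σ_c s̄_c / n) / s̄_C applied to transcript counts, gene filters
(count > 10 in all replicates of ≥ 2 conditions; reference RPKM > 2/15),
log2 fold-change trajectories, k-means with Rand-index model selection
(smallest k from which RI(k, k+1) stays above 0.85), and a Fisher-exact
sweep of peak proximity for x in [1, 1e6] bp.

Every input can be generated with planted ground truth
(`make_genome()`, `plant_sites()`, `simulate_fragments()`,
`simulate_peak_counts()`, `simulate_expression()`), which is how the
package tests itself.

## Worked example

Interphase-like and mitosis-like fragments over 1,000 planted motif
sites, positioned and compared:

```r
library(nucbook)

genome  <- make_genome(2e6, gc = 0.45, seed = 1)
planted <- plant_sites(genome, n_sites = 1000, min_separation = 1500, seed = 2)
fs_int  <- simulate_fragments(planted$sites, planted$genome, array_model(), seed = 3)
fs_mit  <- simulate_fragments(planted$sites, planted$genome,
                              array_model(plus_one_shift = 25, minus_one_shift = 3),
                              seed = 4)

pos_of <- function(fs) {
  pm   <- midpoint_profile(fs, planted$sites, halfwindow = 500)
  prof <- colSums(unclass(pm)); offs <- attr(pm, "offsets")
  wm <- offs >= -230 & offs <= -70; wp <- offs >= 70 & offs <= 230
  c("-1" = ecdf_median_position(prof[wm], offs[wm]),
    "+1" = ecdf_median_position(prof[wp], offs[wp]))
}
pos_of(fs_int)
#>   -1   +1
#> -170  170
displacement(pos_of(fs_mit), pos_of(fs_int))
#>   nucleosome shift  class
#> 1         -1    -4 stable
#> 2         +1   -24  moved
```

The interphase array puts the ±1 nucleosomes at ±170 bp; in the mitotic
condition the +1 nucleosome has slid 24 bp toward the motif (planted:
25 bp; negative = inward) and is classed `moved`, while the −1 shift of
4 bp sits below the 5 bp stability threshold.

```r
sm <- smooth_metaplot(metaplot(midpoint_profile(fs_int, planted$sites,
                                                halfwindow = 600)))
sm$fit
#> sparse GP fit: sigma_f2 = 2.046, lengthscale = 41.91 bp, sigma_n2 = 0.9961
#>   1001 training points, 101 inducing inputs, ELBO = -1466.400
spectral_density(sm$fit)          # log10 S at period 180 bp
#> [1] 1.867
```

A phased array yields a high spectral density at the 180 bp period;
shuffling the midpoints collapses it by orders of magnitude.

```r
truth <- make_bookmark_truth(2000, seed = 5)   # planted L/BI/BS/BM labels
pct   <- simulate_peak_counts(truth, depth = 1e7, seed = 6)
calls <- classify_bookmarking(fit_occupancy_glm(pct), pct)
table(calls$category)
#>  BI  BM  BS   L
#> 683  39 411 867
mean(calls$category != "L")        # fraction bookmarked: 56.6%
```

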