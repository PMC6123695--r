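---
title: "Methods: split-half replicability of task-fMRI group maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-half replicability of task-fMRI group maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the design

A group activation map from a task-fMRI study is a voxelwise statistic
image computed from *k* participants. `fmrirep` estimates how well such a
map would replicate in an exact re-run of the study at the same sample
size, using pseudo-replication: the full participant pool of size *N* is
split into two disjoint random halves; the first *k* participants of each
half form groups P and Q; group z-maps are fit to both and compared. The
split is repeated over many random sorts and over a grid of *k* values,
with the first-*k* prefixes nested within a sort so that larger samples
are supersets of smaller ones. Tasks that share a participant pool share
the identical set of sorts, so their curves are directly comparable (and
their sort-level values are paired).

Because halves overlap across sorts, sort-level values are not
independent; all dispersion summaries (`summarize_curves`) are therefore
reported as qualitative standard deviations, never as inferential error
bars.

# Group model

The reference pipelines in this literature fit mixed-effects group models.
`fmrirep` deliberately substitutes a one-sample t on subject-level maps,
mapped to z by cumulative matching, because every downstream statistic
consumes a group z-map and is agnostic to how it was fit:

- subject map = voxelwise mean of that subject's run maps (equal weights);
- t = mean / (sd / sqrt(k)), df = k − 1, per voxel;
- z = Φ⁻¹(F_t(t)), computed in the tail's log domain so |t| up to hundreds
  does not saturate, clamped at |z| = 38 (the double-precision-safe normal
  quantile range). Voxels with zero variance across subjects get the
  clamped value with the mean's sign, with a warning.

Variance-weighted group modeling is out of scope; with heterogeneous
lower-level variances the absolute z scale would differ, but the
pseudo-replicate comparison is within-model, so the metrics remain
meaningful.

# Similarity statistics

**Pearson (unthresholded).** Correlation of the two z-maps over the common
mask (both masks, both maps nonzero — zero marks "outside field of view").

**Sign-sensitive Jaccard.** For two-tailed thresholded maps,
`J = |{v: suprathreshold in both, same sign}| / |{v: suprathreshold in
either}|`. A voxel positive in P and negative in Q counts in the union
only. An empty union scores 0: small-k maps are often entirely
subthreshold, and an empty outcome is a replication failure, not a
missing value — this is what makes the curves start near zero.

**Peak hit rate.** One peak per cluster (the max-|z| voxel; ties break to
the smallest linear index). Direction P→Q is the fraction of P's peaks
that are suprathreshold in Q with matching sign; the reported value is
the mean of both directions. A direction with no peaks is excluded from
the mean (avoiding 0/0); if both maps are empty the value is 0, for the
same failure semantics as above.

# Thresholding

**Proportion mode** selects exactly `round(p × in-mask voxels)` voxels
with the largest |z| (two-tailed), ties broken by (|z| desc, linear index
asc) so the count is exact. The target proportion per task and threshold
label comes from the full-sample reference: the all-*N* z-map is
cluster-thresholded at a scaled z (below) and the surviving suprathreshold
fraction becomes the target. Proportion-selected voxels carry no
significance guarantee — what is equated across P and Q is the count.

**GRF cluster-extent mode** thresholds at ±z_crit, labels 26-connected
components separately per sign, and removes components whose
cluster-extent p-value exceeds the cutoff. The p-value uses the classical
stationary 3D Gaussian-field approximation: expected cluster count
`E_m = R (4 ln 2)^{3/2} (2π)^{-2} (z²−1) e^{−z²/2}` (R = resels) and
cluster-size tail `P(n ≥ s) = exp(−β s^{2/3})` with
`β = (Γ(5/2)/n̄)^{2/3}`, `n̄ = S Φ(−z)/E_m`. The formula family is a
design choice (the field's standard expected-cluster-count/exponential
size approximation) validated against Monte-Carlo: at z = 2.81, p = 0.01
on 48³ FWHM-3 noise the implied extent threshold falls within a factor of
2 of the simulated 99th-percentile maximal null cluster (it sits on the
conservative side, as expected for this approximation at moderate z).
The formula is invalid below z = 1 (E_m ≤ 0) and errors there.

Pseudo-replicate maps use z = 1.96 (cluster p < 0.05, "liberal") and
z = 2.81 (cluster p < 0.01, "conservative"). Full-sample reference maps
use thresholds scaled to equate the power of the z cutoff across sample
sizes: `z(N) = z_anchor √(N/N_anchor)`, rounded half-up to 2 decimals,
anchored at (N = 214, z = 3.50) for liberal and (N = 200, z = 5.08) for
conservative, with cluster p < 0.01.

**Smoothness** is estimated on the z-map itself (the only map available at
this stage) from first spatial differences among in-mask neighbor pairs:
`FWHM_axis = sqrt(4 ln 2 · var(map) / var(Δ))`, clamped at ≥ 0.5 voxel.
For a Gaussian autocorrelation this recovers the generating kernel FWHM to
within a few percent (and gives √(2 ln 2) ≈ 1.18 voxels for white noise).
We chose this variance-ratio form over the log-corrected variant
`sqrt(2 ln 2 / −ln ρ(1))`: the latter is exact for an ideal Gaussian
autocorrelation but degenerates on unsmoothed noise (ρ(1) → 0), and the
pipeline must tolerate barely-smooth maps; the bias difference on the
FWHM ≈ 3–4 maps the pipeline actually sees is a few percent.

# Null models

For each task and sample size, the observed per-map FWHM geometric means
and robust intensity ranges (2nd/98th in-mask percentiles) are
parameterized as normal distributions (sample mean/SD). Each null map is
white noise smoothed with a drawn FWHM (one isotropic value per map,
truncated at 0.5 voxel) and linearly rescaled so its own robust range
equals a drawn (min, max) pair (max forced above min by redrawing; error
after 100 attempts). Nulls share the real data's mask.

Per real map, the null statistic is the 95th percentile (linear
interpolation between order statistics, pinned for determinism) of the
metric computed against each null map: correlation for the unthresholded
metric; for thresholded metrics the null is proportion-thresholded at the
real map's own suprathreshold proportion and scored by signed Jaccard or
by classifying the real map's peaks against the null's signed mask. A
real map with no suprathreshold voxels scores 0. One ensemble of nulls
(default 1000; the test suite uses 100 with correspondingly wider
tolerances) is shared across all real maps of a (task, k) cell; curves
average the per-map null values. Since the analysis uses each real map's
own proportion, null values are computed against every real map (both P
and Q) and averaged.

# Measurables

Five per-participant (or participant-pair) variables: motion (mean
absolute RMS displacement, mm, averaged over runs — the generator supplies
one scalar per run); contrast power `1/(c (X′X)⁻¹ c′)` averaged over runs;
hat-matrix leverage outliers (count of diagonal entries above
`2·rank/nrows`, averaged over runs); within-subject similarity (mean
pairwise correlation of a subject's run maps; undefined with one run, in
which case its four derived regressors are dropped); between-subject
similarity (pairwise correlation of subject maps, aggregated over pairs
fully inside a pseudo-replicate).

Each variable is aggregated per pseudo-replicate (mean and n−1 SD over
members/pairs) and per pair (mean and absolute difference of the P and Q
aggregates), giving 4 regressors per variable, plus sample size: 21
regressors. Per task: rows at the largest k are dropped (their variance
can degenerate when k ≈ N/2), everything is demeaned, the within block is
orthogonalized against the motion/contrast/hat blocks (jointly), the
between block against those plus the orthogonalized within block, near-
zero-variance (tolerance 1e−12 relative) and aliased regressors are
dropped, and OLS is fit. Sample size is never orthogonalized. Effect size
per block is `d_i = β_i / sqrt(σ²_err [(X′X)⁻¹]_ii)` (σ²_err = sum of
squared residuals; no degrees-of-freedom factor), taking the signed
maximum-|d| expansion; ΔR² is the loss from deleting the block's surviving
expansions, floored at 0.

**MAP aggregation across tasks.** Effect sizes are shrunk toward 0 with a
Normal(0, 1) prior: `μ̂ = (n x̄/s²)/(n/s² + 1)` with plug-in across-task
variance s². ΔR² values are clamped to (0, 1), logit-transformed, shrunk
toward −20 with a Normal(−20, 10²) prior, and mapped back. Reading the
stated priors as (mean, SD) on these scales — and using a plug-in
likelihood — is an interpretive choice, recorded in the output: with an
extreme prior mean of −20, an SD of 10 (not variance 10) keeps the
posterior data-dominated, i.e. only weak shrinkage, which matches the
aggregation's purpose.

No inferential p-values are attached to the measurables regression: the
pseudo-replicate observations are non-independent by construction.

# The synthetic world

`generate_subject_maps` draws, per run,
`map = truth + subject_deviation + run_noise` on a 24³ grid (1-voxel
isotropic spacing) inside an ellipsoid mask (semi-axes 0.9 of the
half-extent, ~5300 voxels). The truth is a sum of peak-normalized Gaussian
blobs, so a blob's amplitude is its effect size at the peak in
within-subject SD units. Deviation and noise fields are white noise
smoothed (FWHM 3, circular FFT convolution) and rescaled to unit in-mask
SD before scaling by σ_between / σ_within — smoothness and variance are
decoupled by construction. Motion is drawn per run (|N(0.25, 0.1²)| mm)
and is independent of the maps unless the optional coupling coefficient
is set, in which case the run-noise SD is multiplied by
`exp(coupling · motion z-score)` so a motion effect is recoverable.
Designs are two event types in a jittered event-related layout (120 TRs
of 2 s), convolved with a double-gamma HRF; jitter makes contrast power
vary across runs. All randomness flows through one seeded generator;
identical spec and seed reproduce the dataset bit for bit.

The canonical suite (`synthetic_suite_config`) has three signal tasks
differing only in σ_between ∈ {0.3, 0.5, 0.8} — 30–80% of the peak
effect, spanning the plausible range from homogeneous to highly variable
populations — plus a pure-null task (no blobs), each with N = 200 and 2
runs, sharing one split plan. Blob amplitudes 0.6–1.0 give full-sample
(N = 200) peak z ≈ 13–18 and a conservative full-sample suprathreshold
proportion of ~5%, comparable to a strong task contrast.

What the generator does **not** emulate: BOLD time series and their
autocorrelation, physiological noise, EPI distortion, registration error,
non-stationary smoothness, heterogeneous per-subject deviation magnitudes
(every subject's deviation field has exactly SD σ_between), and realistic
anatomy. A green suite therefore establishes that the pipeline's
machinery reproduces the qualitative phenomena (replicability grows with
k; between-individual variability lowers the curves; observed curves
separate from smoothness-matched nulls), not that its absolute values
transfer to real data.

# Numerical and design decisions

- **Connectivity** is 26-neighbor, matching the reference cluster tool;
  peak and cutoff ties break by smallest linear (column-major) index.
- **Rounding** of scaled thresholds and proportion counts is half-up
  (base R's `round` is banker's).
- **z clamp** ±38; degenerate sd = 0 voxels are clamped with a warning.
- **Odd N**: the leftover participant after two ⌊N/2⌋ halves is unused in
  that sort.
- **In-range k**: a k runs for a task only if k ≤ ⌊N/2⌋.
- **Empty thresholded maps** are legal everywhere: Jaccard 0, no peaks,
  null statistic 0, full-sample reference proportion 0 with a warning.
- **Seeds**: every stage derives an independent stream from the master
  seed via a fixed integer hash, all below 2³¹.

# Known limitations

- At 24³ desk scale the *liberal* (z = 1.96) GRF extent threshold
  (~130 voxels at ~200 resels) exceeds typical blob excursion sizes, so
  liberal cluster-level curves are degenerate (often empty at all k);
  conservative-threshold curves are the informative ones here. On real
  brain-sized maps both regimes are informative.
- The between-subject similarity measurable is a whole-map correlation;
  with only ~200 resels its per-pair sampling error (~0.07) exceeds the
  true similarity spread it must detect, so its regression contribution
  is noise-dominated at this grid size — the suite reproduces the
  dominance of sample size, but not reliably the ordering of
  between-variability effects across conditions (see the acceptance
  suite, where that clause is left failing by design rather than
  weakened).
- GRF cluster p-values are approximate and conservative at moderate
  z_crit on these small smooth fields; they are validated only to within
  a factor of 2 of Monte-Carlo.
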