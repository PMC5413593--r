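---
title: "Ranking EEG channels by gamma-band spectral entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking EEG channels by gamma-band spectral entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaSE)
```

## The problem

Visual event-related potentials (ERPs) of alcoholic subjects show reduced
evoked gamma-band (30–55 Hz) oscillations compared with controls,
particularly over frontal and occipital cortex. Given 1-s multichannel EEG
epochs from the two groups, the questions this package addresses are:

1. **Which channels separate the groups?** Each channel of each epoch is
   summarised by one number — the normalized spectral entropy (SE) of its
   gamma-band spectrum — and channels are ranked by how strongly the two
   groups' SE distributions differ.
2. **How much of the ranked feature set is needed to classify?** The top-N
   ranked channels are reduced to d principal components and fed to a
   k-nearest-neighbour classifier under a stratified 50% holdout, producing
   an efficiency (accuracy) / sensitivity / specificity / ROC report for
   every (N, d, ranked-or-native-order) combination.

The package also contains a seeded synthetic-epoch generator with planted,
calibrated group differences, so that every stage — and the pipeline
end-to-end — is testable quantitatively without access to clinical
recordings.

## Pipeline stages and their assumptions

### Gamma extraction: zero-phase elliptic band-pass

Epochs are filtered to 30–55 Hz with an elliptic band-pass
(`filter_spec()`, `design_bandpass()`): passband ripple 0.5 dB, stopband
attenuation 40 dB, analog prototype order 6. "Sixth order" follows the
convention of standard `ellip` design routines, where the band-pass
transfer function has `2 * order = 12` poles; the alternative reading (a
12th-order prototype giving a 6-pole band-pass) cannot reach 40 dB of
attenuation within 5 Hz of the band edges and is therefore not what a
working 30–55 Hz gamma filter means. The filter is factored into
second-order sections; the design is rejected if any pole reaches the unit
circle.

Phase distortion is removed by running the filter forward and backward.
Two numerical choices matter on 256-sample epochs:

* **Edge handling.** The slowest pole has modulus 0.992, so a transient
  decays by only ≈0.1%/sample; short reflect-padding leaves edge artifacts
  larger than the stopband floor. Traces are extended by repeated odd
  (point-symmetric) reflection — `min(2 * length, 1024)` samples per side —
  and each biquad starts from its steady state for a constant input equal
  to the first padded sample.
* **Exact time-reversal symmetry.** A single forward-backward pass on
  finite data is not exactly symmetric under time reversal. The operator
  applied here is the average of the forward-backward and backward-forward
  passes, which is symmetric *by construction* (to the last bit), in the
  spirit of Gustafsson's forward-backward initialisation.

Measured on 1-s probe tones (central 128 samples): a 40 Hz tone passes at
0.910 of its input RMS (the double-pass ripple bound), a 5 Hz tone is
attenuated by 81 dB (the steady-state double-pass response at 5 Hz is
−81.4 dB).

### Normalized spectral entropy

The spectrum estimator is the single-window, untapered magnitude-squared
FFT periodogram of the full epoch. No estimator is canonical here, and this
choice has a structural advantage at the reference sampling geometry
(256 samples at 256 Hz): bins fall exactly on integer frequencies, so the
closed band [30, 55] Hz contains exactly N = 26 bin-aligned components.
With in-band probabilities $P_n(f_i) = P(f_i) / \sum_{band} P$,

$$\mathrm{SE}[f_1, f_2] = -\frac{1}{\log N[f_1,f_2]} \sum_{f_i=f_1}^{f_2}
  P_n(f_i)\, \log P_n(f_i) \in [0, 1],$$

with $0 \log 0 := 0$. Both band edges are included (closed interval);
natural logarithms are used, though the normalization makes the base
irrelevant. SE is invariant to amplitude scaling — a property the test
suite asserts and the synthetic generator exploits (see below). A 1200-epoch,
61-channel study therefore becomes a 1200 × 61 feature matrix (epochs as
rows; the transpose of the 61 × 1200 orientation sometimes quoted, chosen
to match the universal samples-by-features convention).

The pipeline computes SE on the *filtered* signal restricted to the band's
bins, matching the stated processing order. `build_feature_matrix(es, band,
filter_spec = NULL)` exposes the unfiltered variant for sensitivity
analysis: on band-limited content the two differ only through filter
ripple, since the band restriction already discards out-of-band bins.

### Channel ranking by Welch's t-test

For each channel, the alcoholic and control SE samples are compared with
the unequal-variance two-sample statistic

$$t = \frac{\bar{x}_1 - \bar{x}_2}
  {\sqrt{s_1^2 / n_1 + s_2^2 / n_2}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
Channels significant at α = 0.05 precede non-significant ones; inside each
block channels are ordered by decreasing |t|, with exact ties broken by
ascending channel index (the tie-break is unspecified in the source
methodology; index order makes reruns reproducible). Ordering by |t| rather
than by raw mean difference is the default because |t| is the quantity the
significance gate is built from; `order_by = "mean_diff"` provides the
raw-gap alternative, and the two orderings genuinely disagree when
variances differ across channels (a tested behaviour).

A one-sample Kolmogorov–Smirnov statistic against a normal with the
sample's own moments (`ks_normality()`) is provided as the descriptive
normality diagnostic. Because its parameters are estimated from the same
sample, its p-value is conservative (the Lilliefors caveat); it never gates
the pipeline.

### PCA reduction

`fit_pca()` implements the covariance route explicitly: column
mean-centering, $V = X^\top X / (N-1)$ (unbiased divisor), symmetric
eigendecomposition, eigenvalues clamped at zero against rounding,
descending order, and a deterministic sign convention (largest-magnitude
entry of each component is positive). Covariance — not correlation — is
used; SE features are already commensurate in [0, 1]. `pca_transform()`
projects any conforming matrix with the *fitted* mean and basis; held-out
data are never refitted. An SVD-based computation serves as the independent
oracle in the tests (eigenvalues to 1e−8; subspaces compared by principal
angles, since eigenvectors are only defined up to rotation inside
degenerate eigenvalue blocks).

### Classification and evaluation

`knn_classify()` is a deterministic k-nearest-neighbour vote: Euclidean
metric on the PCA scores, equal distances resolved toward the lower
training index, even votes toward the class of the single nearest
neighbour, and a positive-class score equal to the fraction of alcoholic
neighbours (so scores live on {0, 1/k, …, 1}). k is not prescribed by the
source methodology; the default is k = 3 (odd, minimising vote ties) and
every reported experiment states its k.

`holdout_evaluate()` performs one seeded, stratified 50% split and reports
confusion counts, efficiency (accuracy), sensitivity and specificity with
*alcoholic as the positive class*, plus the ROC curve (threshold sweep over
the score levels) and its trapezoid AUC, which equals the Mann–Whitney
concordance probability with ties counted half. A single holdout split is
not a testable contract, so `run_grid()` replicates over an explicit seed
list and `pivot_grid()` averages the replicates into the familiar
one-row-per-(N, d) performance table.

Two leakage-hygiene scopes exist because the source methodology is silent
about them: by default both the channel ranking and the PCA basis are
computed on the training partition only (`rank_scope = "train"`,
`pca_scope = "train"`); `"pooled"` reproduces the whole-dataset variant.
Neither is asserted to be "the" original computation.

One exact-equality convention: the selected channel subset enters PCA in
ascending channel order. PCA + k-NN are mathematically invariant to feature
order, and canonicalising makes "ranked selection of all channels" return
*bit-identical* reports to the native order, rather than reports equal only
up to eigen-solver rounding.

## The synthetic generator

`generate_epochs()` emulates the statistical structure the analysis
assumes — not ERP morphology. Each channel trace is

$$x = w \cdot \text{(unit-RMS band-limited noise, 30–55 Hz)}
    + (1-w) \cdot \text{(unit-RMS 40 Hz tone, random phase)}
    + 2 \cdot \text{(unit-RMS 1/f background, 1–29 Hz)}.$$

The mixing weight w is the *complexity dial*: w = 0 concentrates in-band
power in one bin (SE ≈ 0), w = 1 spreads it over all 26 bins
(SE ≈ 0.87). Complexity is manipulated through tone/noise mixing rather
than amplitude because SE is scale-invariant — amplitude effects would be
invisible to the feature. The out-of-band 1/f background gives the filter
real work; it is removed before features are computed.

Groups are identical except on the *planted* channels, where the alcoholic
group uses a larger w than the control group (more disorder, higher
entropy, matching the empirical direction of the group difference). The
`effect` knob is expressed directly in feature units: a pilot simulation
(100 epochs per grid point, 12-point w-grid, the exact filtering-plus-SE
pathway of the main pipeline) maps the target mean-SE gap to the required
w, and the realized gap lands within ±20% of `effect` (typically ±5%).
Effects that would require w > 1 raise a calibration error. Defaults:
61 channels, 256 Hz, 1-s epochs, `base_complexity = 0.3` (mid-range SE
≈ 0.28, leaving calibration room for effects up to ≈ 0.5, the permitted
maximum).

`planted_base_complexity` (default: `base_complexity`) sets the control
group's w on the planted channels. Lowering it makes the planted channels'
entropy *variance* small relative to the other channels, which places the
discriminative directions among the low-variance principal components —
the regime in which classification efficiency genuinely grows with the
number of retained components. With equal variances the opposite happens:
the group-mean shift itself dominates the leading component, and additional
components only add noise dimensions that dilute the Euclidean metric.
Both regimes are real phenomena of PCA-then-classifier pipelines; the test
suite exercises both, and the end-to-end evaluation uses the low-variance
regime because it reproduces the qualitative behaviour reported for the
clinical data (ranking helps at reduced N; more components help).

What the generator does **not** model: eye blinks or muscle artifact (the
reference data are artifact-cleaned before analysis, so the generator is
artifact-free by design), ERP peak morphology, and inter-channel spatial
correlation (channels are independent). Passing tests therefore demonstrate
correctness of the *algorithms* under the stated statistical structure, not
performance on real EEG; absolute SE levels are matched only qualitatively
(range, direction and size of the group gap).

## Reproducible randomness

Every randomised operation (generator, calibration pilot, holdout splits)
runs under a locally seeded RNG that is restored afterwards: the same
configuration and seed produce identical output, and package calls never
disturb the caller's random stream.

## Problem sizes used by the shipped tests and acceptance script

Chosen as the package's own verification conditions:

* Statistical oracles (Welch t vs `t.test`, PCA vs SVD, k-NN vs exhaustive
  search): 100–200 randomised instances each.
* Ranking recovery: 100 replicates of 200 epochs/group × 61 channels with
  10 planted channels at calibrated effect 0.2 (top-10 set must equal the
  planted set in ≥ 99 replicates); null calibration: 500 replicates of
  100 epochs/group × 8 channels (significant fraction inside the 99%
  binomial band around α = 0.05).
* End-to-end contrast: 300 epochs/group × 61 channels, 10 planted channels
  (all outside the first 15 native positions) at effect 0.1 with
  `planted_base_complexity = 0.12`, k = 3, 25 split seeds over the
  N ∈ {61, 25, 15} × d grids.
* The acceptance script scales the same study to 600 epochs/group (1200
  epochs total) and 5 split seeds.

## Known limitations

* The generator's independence across channels means spatial electrode
  structure (and hence electrode-map interpretation) is out of scope.
* The periodogram SE estimator is the package's documented convention; at
  sampling geometries whose bins do not align with 30/55 Hz the closed-band
  bin count changes and SE values shift slightly.
* `ks_normality()` reports the estimated-parameter KS statistic; for a
  calibrated normality *test* a Lilliefors correction would be needed.
* No multiple-testing correction is applied to the per-channel tests — the
  ranking deliberately mirrors the uncorrected p < 0.05 gate of the source
  methodology; at 61 channels ≈ 3 false positives are expected under the
  null, which affects the significance flags, not the |t| ordering.
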