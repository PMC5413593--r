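# gammaSE

Gamma-band spectral entropy analysis of two-group visual ERP recordings:
channel ranking by Welch's t-test, PCA reduction and k-NN classification.

## What this package is for

EEG studies of alcoholism report reduced evoked gamma-band (30–55 Hz)
oscillations in visual event-related potentials (ERPs), especially over
frontal and occipital cortex. Given 1-s multichannel EEG epochs from an
alcoholic and a control group, `gammaSE` implements the full analysis chain
that turns those epochs into a ranked map of discriminative channels and a
classifier-based validation of that ranking:

1. **Gamma extraction** — zero-phase (forward/reverse) sixth-order elliptic
   band-pass, 30–55 Hz, applied per channel and epoch
   (`filter_spec()`, `design_bandpass()`, `extract_gamma()`).
2. **Feature extraction** — normalized spectral entropy per channel and
   epoch over the closed band \[f1, f2\]:

   SE\[f1, f2\] = −(1 / log N) · Σ Pₙ(fᵢ) · log Pₙ(fᵢ),  Pₙ(fᵢ) = P(fᵢ) / Σ P,

   where N is the number of in-band spectral bins, so SE ∈ \[0, 1\]
   (`power_spectrum()`, `spectral_entropy()`, `build_feature_matrix()`).
3. **Channel ranking** — per-channel Welch two-sample t-test
   t = (x̄₁ − x̄₂) / √(s₁²/n₁ + s₂²/n₂) with a p < 0.05 significance gate;
   significant channels first, by decreasing |t| (`welch_t()`,
   `rank_channels()`, plus the `ks_normality()` diagnostic).
4. **Reduction** — PCA via the explicit covariance route
   V = XᵀX/(N−1) with eigendecomposition and top-d projection
   (`fit_pca()`, `pca_transform()`).
5. **Evaluation** — k-NN (default k = 3, Euclidean) under seeded stratified
   50% holdout; efficiency (accuracy), sensitivity, specificity, ROC/AUC,
   and the full ranked-vs-native-order × N × d experiment grid
   (`knn_classify()`, `holdout_evaluate()`, `roc_auc()`, `run_grid()`,
   `pivot_grid()`).

Because the clinical recordings are external, the package ships a seeded
synthetic-epoch generator (`synth_config()`, `generate_epochs()`) that
plants a *calibrated* group difference in chosen channels — the calibration
pilot expresses the effect directly in spectral-entropy units — so the
whole pipeline is quantitatively testable offline. A permissive reader for
the public alcoholism EEG trial-file layout (`read_uci_trial()`) and
plain-text persistence for epochs and feature tables are included.

## Worked example

Six hundred epochs (300 per group, 61 channels, 256 Hz), with ten
discriminative channels planted outside the first fifteen native positions:

```r
library(gammaSE)

planted <- c(20, 24, 28, 32, 36, 40, 44, 48, 52, 56)
cfg <- synth_config(n_per_group = 300, n_channels = 61,
                    planted_channels = planted, effect = 0.1,
                    base_complexity = 0.5, planted_base_complexity = 0.12,
                    seed = 4242)
es <- generate_epochs(cfg)
fm <- build_feature_matrix(es, band = c(30, 55), filter_spec = filter_spec())

rank_channels(fm)
#> <rank_result> 61 channels, 14 significant at alpha = 0.05 (ordered by |t|)
#>  rank channel name        t       df p mean_alcoholic mean_control significant
#>     1      32 ch32 134.4207 470.8501 0      0.1570662   0.05931027        TRUE
#>     2      36 ch36 131.0752 431.5080 0      0.1584838   0.05887998        TRUE
#>     3      40 ch40 129.8616 454.8342 0      0.1569468   0.05881170        TRUE
#>     4      48 ch48 129.4931 441.6448 0      0.1576662   0.05881563        TRUE
#>     5      24 ch24 126.8070 424.9520 0      0.1569665   0.05863169        TRUE
```

All ten planted channels head the ranking (the printed `t` is the group
separation of each channel's entropy; `mean_alcoholic > mean_control`
reflects the higher spectral disorder planted in the alcoholic group).
Classifying on the top 15 ranked channels:

```r
holdout_evaluate(fm, n_channels = 15, n_pcs = 15, ranked = TRUE, k = 3, seed = 1)
#> <classification_report> N=15 channels (ranked), d=15 pcs, k=3
#>   efficiency 1.0000 | sensitivity 1.0000 | specificity 1.0000 | AUC 1.0000
#>   confusion: tp=150 fp=0 tn=150 fn=0 (test n=300)
```

The ranked-vs-native-order contrast over the (N, d) grid, averaged over
five split seeds:

```r
gr <- run_grid(fm, Ns = c(25, 15),
               pcs_by_N = list(`25` = c(5, 15, 25), `15` = c(5, 15)),
               k = 3, seeds = 1:5)
pivot_grid(gr)
#>   n_channels n_pcs efficiency_pct_norank ... efficiency_pct_rank
#> 5         25     5                  83.1 ...                 100
#> 3         25    15                  89.8 ...                 100
#> 4         25    25                  93.2 ...                 100
#> 2         15     5                  50.3 ...                 100
#> 1         15    15                  51.6 ...                 100
```

Ranked selection is perfect at every (N, d); the native-order prefix of 15
channels contains no discriminative channel and stays at chance, while the
prefix of 25 (which contains two planted channels) climbs from 83% to 93%
as more principal components are retained.

A one-trial file in the public database's four-column text layout can be
read with:

```r
path <- system.file("extdata", "synthetic_trial_co2a0000001.rd", package = "gammaSE")
read_uci_trial(path)   # label inferred from the co2a... header
#> <epoch_set> 1 epochs x 4 channels x 256 samples (256 Hz, 1 s)
#>   labels: alcoholic=1, control=0
```

(That file is synthetic, generated by the package's own simulator.)

## Vignette

`vignettes/gamma-entropy-pipeline.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the synthetic
generator's calibration and its limits, and the numerical design choices
(filter edge handling, tie-breaks, leakage scopes, degenerate inputs).
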