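# uhdfinger

Decoding single-finger extension movements from ultra-high-density (uHD)
scalp EEG.

Conventional EEG montages place electrodes 60–65 mm apart; a uHD system
covers the contralateral sensorimotor cortex with 16 diamond-shaped grids
of 16 electrodes (256 channels) at 8.6 mm center-to-center pitch. This
package implements, end to end, the analysis such recordings call for,
and a synthetic uHD-EEG generator with the statistical structure the
analysis assumes, so every stage is testable without recording hardware.

For channel *c* and feature sample *n*, the band-power feature is the
log10 of band-passed, squared, segment-averaged and smoothed EEG, and the
event-related (de)synchronization is

    ERDS[n] = log p[n] − (1/|S_ref|) Σ_{k ∈ S_ref} log p[k]

in dB relative to the 0.5 s pre-cue reference window `S_ref`. Finger
identity is decoded pairwise (5 fingers → 10 problems) with a linear SVM
on the ROI channels' mu (8–12 Hz) and beta (13–25 Hz) features at each
0.25 s step of the 0–5 s task window, scored by n×k-fold stratified CV
(10×10 at full scale), with empirical p-values from label-permutation
null models (Gaussian fit to the null performances) and
Benjamini–Hochberg correction per batch of 10.

## What is in the box

| stage | functions |
| --- | --- |
| montage | `build_uhd_montage`, `four_nearest_neighbors`, `select_density_subset`, `density_targets`, `write_montage`/`read_montage` |
| synthetic data | `paradigm_spec`, `generate_paradigm`, `effect_spec`, `synthesize_recording`, `synthesize_study`, `synthetic_preset` |
| preprocessing | `resample_recording`, `notch_cascade`, `identify_bad_channels`, `apply_car`, `preprocess_study` |
| features | `band_power`, `power_shift_compensation`, `epoch_features`, `bind_epochs`, `combine_bands` |
| ERD/S | `compute_erds`, `focal_selection`, `surface_heatmap`, `time_frequency_erds` |
| decoding | `pairwise_cv`, `permutation_pvalue`, `bh_correct`, `subset_comparison`, `all_pairwise_cv` |
| redundancy | `neighbor_correlations` |
| orchestration | `pipeline_config`, `run_pipeline`, `save_results`, EDF/events I/O (`write_edf`, `read_edf`, `write_events`) |

## Worked example

Synthesize a strong-effect study (144-channel patch, 5 runs of 25 cued
extensions, −4 dB mu/beta ERD at distinct finger sources), preprocess,
extract features, and decode thumb vs little finger:

```r
library(uhdfinger)

m <- build_uhd_montage(n_grids = 16, pitch_mm = 8.6)
m
#> uHD montage: 256 electrodes, 16 grid(s), pitch 8.6 mm, 168 in ROI
median(four_nearest_neighbors(m)$distance_mm)
#> [1] 8.57

st  <- synthesize_study(synthetic_preset("strong"), seed = 1)
pre <- preprocess_study(st$runs, fs_out = NULL)
pre$report
#> bad-channel report: 0/144 channels bad (z > 6), 0/5 runs removed

mont   <- subset_montage(st$montage, pre$kept_channels, recompute_edge = FALSE)
epochs <- combine_bands(lapply(list(mu = c(8, 12), beta = c(13, 25)), \(bd)
  bind_epochs(lapply(pre$runs, \(r)
    epoch_features(power_shift_compensation(band_power(r, bd)))))))
epochs
#> epoched features: 125 trials x 288 channels x 30 samples (-0.5..6.75 s)

cv <- pairwise_cv(epochs, pair = c("thumb", "little"),
                  roi = rep(mont$roi, 2), n_iterations = 3, k_folds = 5)
cv
#> pairwise CV [thumb vs little]: peak 100.0 (0.0)% at 1.50 s (3x5-fold, 50 trials)
permutation_pvalue(epochs, cv, n_permutations = 20, seed = 2)
#> permutation test: observed 100.0%, null 63.9 (5.6)% [20 perms], p = 5.173e-11
```

The peak accuracy is the mean CV accuracy at the best 0.25 s time step
(here 1.5 s post-cue, inside the mu/beta desynchronization); the p-value
is the upper tail of a Gaussian fitted to 20 label-permutation null
performances — the injected effect is recovered decisively.

ERD/S maps and the focal-electrode rule on the beta band:

```r
beta <- compute_erds(
  bind_epochs(lapply(pre$runs, \(r)
    epoch_features(power_shift_compensation(band_power(r, c(13, 25)))))),
  finger = "middle")
beta
#> ERD/S map: 144 channels x 30 samples (dB), 25 trials, trough -4.12 dB
focal_selection(beta)
#> [1] 71 75 79
```

The trough matches the injected −4 dB depth; the 2.5th-percentile rule
selects floor(0.025 × 144) = 3 electrodes on this patch (6 on the full
256-channel montage), clustered at the middle finger's source.

Neighboring-electrode redundancy on the preprocessed data:

```r
neighbor_correlations(pre$runs[[1]], four_nearest_neighbors(mont))
#>   distance_mm  median 8.57 [8.57; 8.59]
#>   r            median 0.138 [0.114; 0.384]
#>   r_squared    median 0.019 [0.0129; 0.147]
```

`run_pipeline(pipeline_config(...))` wires all stages together and
`save_results()` writes the classification table, neighbor statistics,
focal selections, and a JSON run manifest.

## Scope

Real-data headline tables require the original recordings and are out of
scope here, as are source localization, multiclass decoding, CSP-family
methods, and real-time operation. See the methods vignette
(`vignettes/uhd-finger-decoding.Rmd`) for the model, its assumptions,
and known limitations.
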