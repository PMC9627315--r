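---
title: "Decoding single-finger movements from ultra-high-density EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-finger movements from ultra-high-density EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhdfinger)
```

## The problem

Conventional scalp EEG places electrodes 60--65 mm apart, which limits how
much spatial detail of sensorimotor activity can be resolved. Ultra-high-
density (uHD) EEG covers the sensorimotor cortex with 16 diamond-shaped
grids of 16 electrodes each --- 256 channels at 8.6 mm center-to-center
pitch. `uhdfinger` implements the full analysis chain for a cued
single-finger extension experiment on such a montage: preprocessing with
statistical bad-channel rejection, mu (8--12 Hz) and beta (13--25 Hz)
log band-power features, event-related desynchronization/synchronization
(ERD/S) topographies, time-resolved pairwise decoding of finger identity
with a linear SVM, permutation-based inference, and a redundancy analysis
of neighboring electrodes. A synthetic-data generator reproduces the
statistical structure of such recordings so that every stage is testable
without access to recording hardware.

## The montage model

The real system attaches grids to the scalp over one hemisphere. Since no
individual head geometry is distributed with this package, the montage
lives on a parametric hemispherical scalp of radius 90 mm (configurable).
Grid centers are placed by azimuthal-equidistant projection around the
patch centroid, each rigid 4x4 grid is laid out in its center's
parallel-transported tangent frame at geodesic-polar offsets, and the
whole sphere is finally rotated so that grid 0 sits at the vertex
(Cz-analog). Two properties motivated this construction:

* realized spacing: with a curved surface a flat 137 mm patch cannot be
  embedded isometrically; a naive tiling by chained perpendicular
  geodesics makes distant grids converge and collide (we measured
  electrode pairs 0.3 mm apart at the far corner of the patch). Rigid
  per-grid placement keeps every within-grid neighbor distance within a
  few hundredths of a millimetre of the nominal pitch; the median
  four-nearest-neighbor distance of the full 256-channel montage is
  8.57--8.59 mm.
* isometry of the final anchoring rotation, so "grid 0 at the vertex"
  costs nothing in spacing accuracy.

The region of interest (ROI) used for classification removes the
outermost electrode ring everywhere plus a second ring along the
anterior/posterior edges, retaining 168 of 256 electrodes (66%) --- the
study montage retains 158/256, defined only pictorially, so the exact
count is a convention here.

Reduced-density electrode subsets stand in for the 10--10 (6 positions at
~36 mm spacing) and extended 10--10 (11 positions at ~24 mm) systems.
They are fixed target-position sets in the montage frame (shipped in
`inst/extdata/`, marked synthetic); `select_density_subset()` picks the
nearest uHD electrode per target. Offsets are slightly off-symmetric so
no target is exactly equidistant between two electrodes. Because these
sparse stand-ins lie entirely on the convex hull of their own montage,
their four-nearest-neighbor graphs are built with `include_edge = TRUE`.

## The synthetic-data generator

`synthesize_recording()` is an amplitude-modulated oscillator model, not
a biophysical forward model: the analysis consumes band power only, and
this is the minimal structure that exercises every stage.

* Background: per-channel pink noise (1/f amplitude spectrum, 10 uV SD),
  a shared 60 Hz line sinusoid (5 uV), and a slow multiplicative
  band-power drift --- an Ornstein-Uhlenbeck process on the dB scale
  (SD 1 dB, 60 s correlation time) chosen specifically to exercise the
  25 s power-shift compensation.
* Sources: five finger-specific cortical sources on neighboring interior
  electrodes (two lattice steps, 17.2 mm apart where the patch allows),
  each emitting band-limited mu (20 uV SD) and beta (15 uV SD)
  oscillations mixed into channels with linear amplitude decay over a
  20 mm radius.
* Task effects: during each cued extension the source amplitude is
  scaled by `10^(ERD_dB/20)` with 0.25 s raised-cosine ramps, so band
  power changes by exactly the stated dB in expectation. Default windows
  mirror the observed dynamics: mu ERD 0.5--2.5 s, beta ERD 0.5--5 s,
  beta rebound +2 dB at 6--7 s post-cue. The post-movement mu ERS is not
  modeled. Default depths (-3 dB mu, -2.5 dB beta) are calibration
  choices --- the study does not quantify its subjects' ERD depths.
* Bad channels are replaced by white noise at 50x the pink amplitude,
  the scale of a disconnected electrode. Note that a z-score across n
  channels is bounded by (n-1)/sqrt(n), so the study's z > 6 criterion
  is only meaningful on large montages (n >= 39); on the 256-channel
  montage injected artifacts score z of about 7 and the strongest
  genuine channels about 3.

Source amplitudes are deliberately high-SNR (in-band SNR ~20 at a source
center): the mu rhythm is a prominent focal oscillation, and parameter
recovery of an injected -3 dB ERD to within +-1 dB needs the oscillator
to dominate in-band noise at the center electrode. What passing tests on
these data do *not* show: robustness to ocular/muscle artifacts, volume
conduction from a realistic head, inter-subject variability, or
electrode-skin impedance drift --- none of which the generator emulates.

## Preprocessing

Raw recordings are polyphase-resampled (600 to 200 Hz by default; an
in-package FIR resampler with reflection-padded zero-phase filtering is
used), then notch-filtered at 60 Hz and every harmonic whose +-2 Hz stop
band fits below Nyquist. All band filters are Butterworth designs with
order argument 4 (the band transform doubles the polynomial order, the
convention of the common numerical environments); they are applied
forward-only (causally), honoring the real-time orientation of the
pipeline --- only bad-channel identification and the centered moving
average are acausal.

Bad channels are identified per run on task-period data: common average
reference, 8--25 Hz band-pass, per-channel log10 mean power, z-scored
across channels. Channels above z = 6 are bad; runs with more than 10%
bad channels are dropped; surviving runs' bad sets are OR-ed (a channel
bad anywhere is bad everywhere). The step only reports --- data are not
modified until bad channels are removed and the remaining channels are
common-average referenced.

## Features, ERD/S, and classification

Band power is computed per band as: causal band-pass, squaring,
averaging in non-overlapping 0.25 s segments (feature rate 4 Hz), a
centered 0.75 s moving average with shrinking windows at the stream
edges (no data fabricated by padding), and log10. A trailing 25 s mean
(inclusive of the current sample, shorter at stream start) is subtracted
per channel to cancel slow drift. Epochs run from 0.5 s before to 7 s
after each cue, with the cue floored to the previous feature-sample
boundary so the pre-cue reference stays strictly pre-cue; at the
defaults an epoch is 30 samples.

ERD/S is the trial-averaged log band power minus its per-channel mean
over the -0.5..0 s reference window, scaled by 10 to dB. Focal
electrodes per finger are those strictly below the 2.5th nearest-rank
percentile of the window-averaged map (floor(0.025 x 256) = 6
electrodes on tie-free data; ties can only shrink the selection, and an
all-equal map selects nothing). Scalp maps spread each electrode's
activation over surface vertices with a linear kernel reaching zero at
the distance to its nearest included electrode; bad channels are
excluded by default, with a set-to-zero compatibility mode.
Time-frequency maps use an STFT with a 1 s Hamming window and 0.95 s
overlap (20 frames/s, 1 Hz bins over 8--30 Hz), epoched 1 s pre to 7 s
post, referenced to -1..0 s; display upsampling is bilinear. With that
window overlap a trial's reference window holds only about two
independent power estimates, so per-frequency null maps keep a sampling
SD near 0.5 dB even at 50 trials --- aggregate means are the meaningful
null check.

Classification follows the time-resolved pairwise scheme: at each 0.25 s
feature step in 0--5 s post-cue (20 steps; the 5 s endpoint is
excluded), the ROI channels' mu and beta features form the feature
vector of a linear SVM (unit box constraint, features standardized with
training-fold statistics, no hyperparameter search) evaluated by
stratified k-fold CV repeated n times, fold seeds equal to the iteration
index. Model performance is the mean accuracy at the best time step
(earliest on ties). High-gamma is not a default band: it is supported
as a configurable band on >= 600 Hz data but adds no value for this
paradigm.

## Permutation inference

Null models shuffle the class labels and rerun the full repeated CV.
Each null model's performance is its **own** peak accuracy over the time
grid --- the same max-over-time statistic as the observed model. An
alternative reading, evaluating null models at the observed peak step
only, makes null p-values anticonservative, because the observed
statistic is a maximum over ~20 correlated time steps while the null is
not; with the own-peak statistic, p-values on null synthetic data are
uniform (verified by Kolmogorov-Smirnov calibration in the test suite).
Both modes are available (`null_statistic`).

Two related design points came out of calibration:

* Label permutations must be exchangeable with the true assignment. The
  cue sequence is balanced within every run, while a global shuffle is
  not, so on multi-run data null models can exploit run-level band-power
  differences (drift) and the null inflates. The calibration preset is
  therefore a single run, within which the true cue order is itself a
  uniformly random permutation.
* A Gaussian is fitted to the null performances (they are approximately
  normal), so p-values below 1/n_permutations are attainable; p is the
  upper-tail probability of the observed performance. Per-subject
  batches of the 10 pairwise p-values are Benjamini-Hochberg corrected.

Density comparisons pair each decoding problem's performance on the full
ROI against the same problem on a density subset (features are reused;
the subset sees the same preprocessed data restricted to its channels)
and use a two-tailed Wilcoxon signed-rank test with median [IQR]
difference.

## Neighbor redundancy

Preprocessed (post-CAR) data are band-passed 1--30 Hz; for every unique
four-nearest-neighbor pair the Pearson r and R^2 = r^2 are reported with
nearest-rank median [25th; 75th] summaries. Bad channels are removed
before pairing. Pairs with a constant channel are dropped with a
warning. On synthetic data the median r falls monotonically from the
8.6 mm uHD graph through the ~24 mm subset to the ~36 mm subset ---
the direction the density argument predicts; sparse source-free pairs
even go slightly negative, a known side effect of common-average
referencing.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data at desk scale, as the
package's own choice of problem sizes: the statistical calibration study
uses 50 repetitions of 20 permutations with 3x5-fold CV on a 16-channel
single-run preset; decoding checks use 64--144 channel patches with 3--5
runs; parameter recovery uses 50 single-finger trials; the density
orderings use 20 seeds each. Scaling any of these up is a matter of the
corresponding arguments (`synthetic_preset("full")` reproduces the full
256-channel, 10-run geometry).

Other numerical conventions: log10 throughout with dB = 10 x log10;
nearest-rank quantiles for focal selection and IQRs; strict inequality
at the focal threshold; earliest-maximum tie-break for peak time;
permutation fold seeds derived deterministically from the permutation
index; all generator draws under a single seeded stream so identical
inputs give bit-identical recordings.

## Known limitations

* The parametric hemisphere preserves distance-dependent computations
  but is not an individual head; absolute subset spacings (e.g. the
  sparse stand-in's ~42 mm median) differ from values measured on a real
  head, so only orderings are meaningful for those.
* The generator's sources are narrow-band amplitude-modulated
  oscillators; spectral shape within a band, phase coupling, and
  artifacts are out of scope.
* Real-data headline numbers (grand-mean pairwise accuracy, per-subject
  tables) require the original recordings and are deliberately not
  reproduced here.
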