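---
title: "Methods: EFP-BOLD coupling analysis"
author: "efpcouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EFP-BOLD coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efpcouple)
```

## The problem

An EEG fingerprint (EFP) is a weight model, trained on simultaneous
EEG-fMRI, that turns a short EEG segment into one predicted BOLD value for
a deep target region (the amygdala variant is the main case; a ventral
striatum variant serves as a specificity control).  Given an EFP
time-course computed during naturalistic emotional stimulation, the
questions this package addresses are: which voxels' BOLD dynamics track
the EFP (voxel-wise GLM with group inference and FDR); whether the
coupling within a target structure is specific to salience-related
subregions (seed-coactivation ROI selection followed by a sliding-window
correlation test against a shuffled-window permutation null); and whether
EFP amplitude relates to subjective emotional reactivity across subjects.

Because the trained EFP weight tables are not public and no raw cohort is
shipped, the package pairs every analysis stage with a synthetic
EEG-fMRI-ratings generator with known ground truth, and all quantitative
claims made by the test suite and the acceptance script are
recovery/calibration properties on that generator -- not reproductions of
any real-data result.

## EFP signal computation

For each output time `t` (one per TR, 1.5 s, timestamped at the segment
end), the trailing 12-s segment of the bipolar derivation named by the
model (default Pz minus FCz) is:

1. notch-filtered for power-line interference (50 Hz, 2 Hz wide,
   zero-phase Butterworth);
2. Stockwell-transformed.  The discrete S-transform is computed in its
   frequency-domain form: the spectrum is shifted by each analysis
   frequency, multiplied by the Gaussian localizing window
   `exp(-2 pi^2 m^2 / n^2)` (sigma = 1/f in time), and
   inverse-transformed.  The f = 0 voice is excluded; analysis
   frequencies snap to the nearest DFT bin.  The implementation is tested
   against a direct time-domain Gaussian-windowed DFT oracle to 1e-6
   relative error;
3. binned to quarter-second by frequency-band cells by exact mean pooling
   (48 x 10 for a 12-s segment).  Because 0.25 s at 250 Hz is 62.5
   samples, bin boundaries are rounded sample indices, so bins alternate
   between 62 and 63 samples;
4. collapsed to one value: intercept plus the weighted sum of all cells.

Design points the upstream description leaves open, and the choices made
here:

* **Band edges.**  The 10-band reduction of the frequency axis is not
  published; the default is 10 contiguous log-spaced bands spanning
  1-40 Hz, stored inside every `EFPModel` so results are always read
  relative to a declared model.  A model file loader (`read_efp_model`)
  accepts user-supplied weight tables.
* **Demo model.**  The shipped `demo_efp_model()` is synthetic: uniform
  positive weights on the bands overlapping the generator's 4-8 Hz
  carrier, zero elsewhere.  Its output is the trailing-window mean power
  in that band -- what a trained model would recover on data whose target
  signal lives there.  It stands for no published weight set.
* **Output alignment.**  Values are emitted once per `stride_s` (default
  one TR) and timestamped at the segment end; nothing is emitted before
  one full segment.  Because the EFP integrates a trailing 12-s window,
  its effective latency relative to the underlying neural drive is about
  half a segment (~6 s).  This roughly matches the hemodynamic delay of
  the BOLD signal itself (canonical response peak ~6 s), which is why the
  default GLM regresses BOLD on the raw EFP without further convolution
  (`efp_convolve_hrf = FALSE`; the flag exists for the alternative
  convention).  Overlapping segments make consecutive EFP values strongly
  autocorrelated; all downstream inference is across subjects (GLM group
  tests) or against permutation nulls that preserve within-window
  structure, neither of which assumes serially independent EFP samples.

## Voxel-wise GLM

Per voxel, signals are detrended (linear), high-passed at 0.001 Hz and
demeaned, in that order.  The high-pass is realized as discrete-cosine
drift regression: all DCT components slower than the cutoff are
residualized out, which at 0.001 Hz and typical run lengths removes only
the slowest one or two drift shapes.  The EFP regressor is z-scored by
default so betas are comparable across models (a raw-scale option is
retained), aligned to volume times by nearest sample, with warm-up
volumes (before the first full EEG segment) dropped.  First-level fits
are ordinary least squares of each voxel on `[intercept, EFP]`.

Group inference is a two-tailed one-sample t-test of subject betas per
voxel, or a paired t-test for the contrast between two EFP models, with
Benjamini-Hochberg FDR across voxels (optionally restricted to a
sub-mask, e.g. amygdala-only correction).  Conventions: zero
across-subject variance at a voxel gives p = 1, flagged, never
significant; directional masks for the paired contrast are thresholded
at alpha/2 per direction (0.025 at the default 0.05), honoring the
two-tailed display convention.

## ROI selection by seed coactivation

The seed time-course is the mean of all voxels whose centers lie within
`radius_mm` (default 4 mm, boundary inclusive) of the seed center --
modeled on an anterior-insula salience seed.  Each target-mask voxel's
Pearson correlation with that series is computed (zero-variance voxels
become missing), and two clusters are formed over the valid
correlations:

* salience-related: `r` strictly above the 85th percentile AND strictly
  above 0.2;
* non-salience: `r` strictly below the 15th percentile AND strictly
  below 0.2.

Percentiles use linear interpolation (R type 7).  Reading "above"/"below"
as strict inequalities means exact ties at a threshold are excluded; an
all-tied input therefore yields empty clusters, which is intentional and
tested.  The ceiling for the non-salience rule is configurable
(`low_ceiling`); the default 0.2 reads "at least below 0.2" as `r < 0.2`,
the weaker of the two possible sign readings -- the stricter `r < -0.2`
is available by setting `low_ceiling = -0.2`.  Selection and testing are
meant to run on different acquisitions (the selection run versus the
movie run), which the API encourages by taking separate dataset handles.

## Sliding-window permutation test

For one subject and ROI: Pearson correlations between the EFP and each
ROI voxel are computed along a sliding window of `w` TRs (default sweep
10-50), step 1 TR, and averaged across windows, giving the real
distribution of size n (ROI voxels).  The null reassigns intact EFP
windows to BOLD window positions -- a seeded permutation without
replacement of the window start indices, never breaking samples within a
window -- and repeats the same computation 100 times, pooling
`100 x n` values.  A subject-ROI is above chance when the median of the
real distribution exceeds the 95th percentile of its null.  The x100
scaling of real-distribution frequencies seen in histogram displays is
presentation-only and never enters the decision.

Numerical conventions: zero-variance windows contribute r = 0, with a
warning, identically in the real and null branches; each permutation
draws from its own seed substream so results are reproducible and
independent of evaluation order; percentile and median are the standard
linear-interpolation definitions.

**Calibration and its limits.**  On null ROIs (white-noise EFP
independent of white-noise BOLD; 400 volumes, w = 30, 100 permutations)
the empirical above-chance rate of the nominal-5% rule is about 4-7% for
ROIs of 37-50 voxels -- the scale of the functional clusters this
analysis targets -- and this is the regime the packaged calibration
checks (200 ROIs of 40 voxels).  The rate is not invariant to ROI size:
the real per-voxel window-means spread roughly five times wider than the
permuted ones (aligned overlapping windows share samples in both series;
shuffled pairs share them in only one), so for very small ROIs
(~10-20 voxels), where the median is noisy, the decision becomes
anticonservative (we measure ~14% at 20 iid voxels, worse when voxels
are strongly inter-correlated), while for very large ROIs it becomes
conservative.  Single-subject above-chance calls on small clusters
should therefore be read as descriptive; the package's cohort-level
comparisons (coupled vs null ROI fractions) are unaffected, as both
sides share the ROI-size regime.

## Emotional reactivity

Ratings on the 1-7 scale (4 = no emotional reaction) are centered at the
printed neutral anchor 4 -- not at the subject mean -- converted to
absolute deviation, and averaged over the scene timeline (irregular
traces are step-resampled at their smallest sampling interval first, so
held ratings weigh by duration).  EFP amplitude per scene is the raw
mean of EFP values in the scene window; an absolute-mean option exists
because "mean amplitude" admits both readings.  Scene differences follow
the aversive-minus-sad convention (Snakes minus Farewell).  Cohort
outputs are paired two-tailed t-tests of both difference scores and the
cross-subject Pearson correlation between them.

## The synthetic cohort generator

The generator defines the package's study conditions:

* **Latent drive**: low-pass-filtered Gaussian noise (2nd-order
  Butterworth, default cutoff 0.1 Hz, 0.25-s sampling), demeaned, unit
  variance -- a stand-in for slow emotional fluctuation during
  naturalistic stimuli.
* **EEG** (250 Hz): constant-envelope band-limited noise in a 4-8 Hz
  carrier, amplitude-modulated by `1 + 0.5 x latent`, plus broadband
  white noise (default SD 0.5) and a quiet reference channel.  The
  envelope normalization (dividing the carrier by its analytic-signal
  magnitude) makes quarter-second band power track the latent cleanly
  (r > 0.9 noise-free), which is the property the EFP model needs.
* **BOLD** (TR 1.5 s, 2.2-mm lattice): coupled voxels are
  `beta_bold x (latent convolved with a canonical double-gamma HRF,
  unit-area, peak ~6 s, undershoot ~16 s, ratio 1/6, 32-s support)`
  plus stationary AR(1) noise (default phi 0.3, marginal SD 1);
  uncoupled voxels are pure AR(1) noise.  Default: 30% of 60 target
  voxels coupled, template `beta_bold` 0.5 with 0.1 between-subject SD
  (inter-subject coupling variability is uncharacterized upstream; this
  default is a convention, stated as such).
* **Seed region**: a 4-mm sphere of lattice voxels driven by the
  standardized BOLD-convolved latent plus a shared AR network
  fluctuation; the same fluctuation is added (amplitude
  `seed_coupling_r`, default 0.6) to the coupled target voxels, so seed
  coactivation separates coupled from uncoupled voxels the way the ROI
  selection assumes.
* **Ratings**: `4 + rating_slope x latent + noise`, saturated into
  [1, 7].  Scene latents are scaled by per-subject arousal gains (the
  aversive scene's gain is higher on average), and the same gains drive
  the EFP-level differences in the lightweight behavioral cohort, which
  is what links reactivity and EFP amplitude across subjects.

What the generator does *not* emulate: MR gradient and
ballistocardiogram artifacts, realistic EEG forward models, spatially
structured fMRI noise, motion, physiological confounds, or anatomical
variation.  Passing recovery tests therefore demonstrates that the
analysis chain is correct and calibrated under its own assumptions --
not that those assumptions hold in any real recording.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run, by the package's own
choice of scale: the three printed task timelines; oracle-equivalence
checks on signals of <= 512 samples (S-transform) and <= 120 TRs
(sliding window); null calibration on 200 ROIs x 40 voxels x 400
volumes; a 20-subject recovery cohort (450 s runs, 60 voxels,
`beta_bold` 0.5, noise SD 1) for GLM sensitivity/false-positive rate and
for coupled-vs-null ROI discrimination across windows 10-50; and 100
behavioral cohorts of 60 subjects for the reactivity chain.

## Known limitations

* The shipped demo EFP model is synthetic; applying the package to real
  recordings requires a user-supplied trained weight table.
* MR-specific EEG artifact removal is upstream of this package; raw
  scanner EEG must be cleaned before `preprocess_eeg`.
* The above-chance decision's empirical rate depends on ROI size (see
  above).
* First-level OLS ignores serial autocorrelation of BOLD noise; this is
  inconsequential for the group-level random-effects inference the
  package reports (subject betas remain unbiased and independent), but
  single-subject first-level t-values should not be interpreted as
  calibrated.
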