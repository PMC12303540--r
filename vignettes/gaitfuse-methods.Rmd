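---
title: "Methods: dual-channel gait assessment with gaitfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel gait assessment with gaitfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfuse)
```

## The measurement problem

Gait disturbance is an early and underestimated motor sign of cerebral
small vessel disease (CSVD). Two inexpensive data channels can quantify it
outside the laboratory: a smartphone accelerometer worn at the L3 waist
level during a 30-second walk, and a side-view video of a 5-metre walkway
segment processed into per-frame skeleton keypoints (OpenPose BODY_25).
`gaitfuse` implements both extraction chains, a statistical comparison
layer, and a synthetic cohort generator that produces both data streams
with known ground truth, so every stage of the pipeline can be validated
end to end without access to patient data.

## Sensor chain

A recording is an irregularly sampled tri-axial series at roughly 40 Hz.
The chain is:

1. **Resampling** to a uniform 100 Hz grid by linear interpolation
   (`resample_uniform()`). Linear, not spline: the phone's gaps are short
   and higher-order schemes would invent curvature between sparse samples.
2. **Vertical channel**: the gravity-dominant channel (largest mean
   absolute value) is taken as vertical and mean-centred
   (`vertical_component()`). At the waist, gravity makes this selection
   unambiguous; the generator's labelled vertical axis is recovered in
   every seeded trial of the test suite.
3. **RMS** of the dynamic vertical acceleration: gait intensity.
4. **Step detection** (`detect_steps()`): 4th-order Butterworth low-pass
   at 10 Hz (zero-phase), positive peaks with both height and prominence
   at least 0.3 x signal RMS, separated by at least 0.25 s. The constants
   bracket the physiological cadence band (1-3 steps/s) and are exposed in
   `run_config()`. Step frequency is the reciprocal mean interval; step
   variability is the coefficient of variation of the intervals — the
   scale-free convention, consistent with published values near 0.1
   (an SD in seconds at ~0.55 s intervals would be an order of magnitude
   smaller than the printed numbers unless divided by the mean).
5. **Unbiased autocorrelation** (`autocorr_unbiased()`): at lag k the sum
   of products over the N−k overlapping samples is divided by N−k, then by
   the lag-0 variance. The unbiased form matters because the gait peaks of
   interest sit at appreciable fractions of the record length.
6. **Regularity and symmetry** (`regularity_symmetry()`): Ad1 is the
   highest local autocorrelation maximum with lag in [0.5, 1.5] x step
   period; Ad2 the highest in [0.5, 1.5] x (2 x lag(Ad1)). Step regularity
   is Ad1. Step symmetry is min(Ad1, Ad2)/max(Ad1, Ad2) clamped to [0, 1],
   which guarantees the reported range by construction. Whether published
   "regularity" is Ad1, Ad2 or their mean is ambiguous in the field;
   `regularity_lag` in `run_config()` selects the alternative.

## Video chain

Keypoint sequences are consumed in the native OpenPose per-frame JSON
dialect. Conventions, stated once and used everywhere:

* The image y-axis points down; all geometry is computed in world
  coordinates after flipping y.
* The camera-facing side is the side whose required keypoints have the
  higher mean confidence over the clip.
* Frames are retained when every required point (camera-side limb points,
  neck, mid-hip) reaches confidence 0.3 (the OpenPose community default,
  configurable); time-series parameters use the longest contiguous
  retained run. This mirrors the exclusion of segments where the walker
  has just entered or left the screen.
* The head point is the camera-side ear, falling back to the nose when
  the ear fails the confidence threshold.
* Horizontal references use the direction of travel (sign of mid-hip
  displacement), not the image x-axis, so camera roll does not bias
  head-to-ground.

Eleven angle series are computed per retained frame: knee, ankle and elbow
interior angles, upper-arm-to-trunk, trunk-to-thigh, neck-to-trunk, body
lean, sight line, head-to-body (interior angle at the neck between
neck→ear and neck→mid-hip), head-to-ground (angle of neck→ear against the
travel direction, so a more downward-pitched head gives a smaller value),
and calf-to-vertical. Every series is wavelet-denoised *before* summary
statistics — three-level Daubechies-4 decomposition, symmetric boundary
extension, detail coefficients soft-thresholded at the universal threshold
sigma * sqrt(2 log N) with sigma = median(|finest details|)/0.6745. The
thresholded-details reconstruction is the default; an approximation-only
variant is available (`keep_details = FALSE`). Series shorter than 16
frames pass through unchanged with a warning. Dynamic joint angles are
summarised by mean and variance, postural angles by mean only.

Spatiotemporal parameters calibrate pixels to metres from the known
walkway length divided by the mid-hip displacement over the retained run.
Heel strikes are local maxima of the horizontal ankle-to-ankle separation;
step length is the mean distance between consecutive leading-ankle strike
positions; cadence is strikes over elapsed time; step speed is their
product (an exact identity in this implementation); heel height is the
mean per-cycle maximum heel clearance above the lowest observed heel
position.

### The two head angles cannot share one rigid geometry

Published head-to-body and head-to-ground means are both near 133-134
degrees in controls and both lower in CSVD. Under interior-angle
definitions these two angles are complementary around the trunk axis: a
rigid rotation of the ear about the neck that lowers one raises the other.
The generator therefore treats them with two degrees of freedom: the head
pitch offset sets head-to-ground (ground truth 135 − pitch, degrees), and
the trunk lean enters head-to-body (ground truth 135 + pitch − lean).
Group differences in both angles are reproduced jointly by calibrating
pitch and lean per group and task; this is a stated modelling convention,
not a claim about the original (unrecoverable) angle definitions.

## Group statistics

The analysis unit is the participant: repetitions are averaged within
participant and task before testing. Each (task, parameter) cell is
compared between groups with a Mann-Whitney U test written for this
package: exact two-sided p by full enumeration of the rank distribution
when the smaller sample has at most 8 observations and no ties are
present; otherwise the normal approximation with midranks, tie-corrected
variance and continuity correction. The reported statistic is
min(U, n1*n2 − U). No multiplicity adjustment gates significance,
mirroring the single-study reporting convention; a Benjamini-Hochberg
column is emitted as supplementary output. Demographics use Welch t tests
(continuous) and chi-square (sex). `headline_effects()` reports the
relative regularity deficit (control − csvd)/control and head-angle gaps
in degrees; note that on the published normal-walking means the deficit
computes to about 19.7%, so summaries always report computed values rather
than forcing agreement with any externally quoted range.

## The synthetic cohort generator

### Accelerometer model

The vertical channel is a train of biphasic Ricker-shaped impulses, one
per heel strike, on top of gravity and white noise, with an
anteroposterior harmonic and a noise-only mediolateral channel. Three
design choices matter:

* **Biphasic pulses** (width parameter 0.25 x step period). A heel strike
  is an impact followed by a rebound and integrates to roughly zero. A
  monophasic pulse train would carry a large DC pedestal; after mean
  removal that pedestal enters the autocorrelation normalisation and
  compresses the regularity scale so strongly that the joint pattern of
  healthy values (regularity near 0.8 at interval CV near 0.1) becomes
  unreachable. The zero-integral shape restores the pairwise-correlation
  scale.
* **Phase jitter, not interval random walk.** Step times are a regular
  lattice plus independent Gaussian phase noise with SD cv * T / sqrt(2),
  which makes the CV of successive intervals exactly the requested
  `timing_jitter_cv` while keeping successive intervals anti-correlated —
  walkers correct their phase against an internal rhythm. A random walk of
  intervals would penalise the stride-lag autocorrelation twice and force
  symmetry far below observed values.
* **Alternate-step attenuation** by (1 − asymmetry), weak side fixed per
  recording, implements left/right imbalance. Because symmetry is a
  min/max ratio of two correlations, it responds slowly
  (2r/(1 + r^2) with r = 1 − asymmetry), so matching printed symmetries
  near 0.85 requires asymmetry values several times larger than the
  printed deficit — a property of the statistic, not of the generator.

Sampling timestamps are irregular: Gaussian gaps around the nominal 40 Hz
with the requested gap CV.

### Keypoint walker

A planar sagittal stick figure filmed from its right side: hips translate
at cadence x step length with a small vertical bob; thigh/calf/foot and
arm segments oscillate sinusoidally over the stride; the contralateral leg
is visible at moderate confidence and phase-shifted by half a stride;
contralateral arm, ear and eye get low confidence, as in real side-view
captures. The calf is driven directly by its tilt from vertical (mean +
half-range), with the thigh derived through the knee angle, so the
calf-to-vertical mean is analytic: 180 − calf mean tilt (the half-range
must stay below the mean tilt, which the parameter validator and the
calibrated design respect). World metres map to pixels through
`image_scale` with the y flip; Gaussian pixel noise and edge dropout
(first/last frames zeroed with confidence 0) emulate detector behaviour.

What the generator does **not** emulate: out-of-plane motion, perspective
foreshortening, occlusion-induced keypoint swaps, double support and foot
rollover dynamics, and correlated (non-white) keypoint noise. Passing
tests therefore demonstrate the correctness and calibration of the
extraction chains on idealised gait, not detector robustness on real
video.

### Cohort design and calibration

`cohort_design()` holds per-group mean/SD pairs for every generator field,
additive per-task offsets (per group), demographics distributions,
repetitions and a master seed; participant-level deviations are drawn once
and shared across tasks, so repetitions differ only by generator noise.
`calibrated_design()` is the frozen default study design: 10 controls vs
19 CSVD-like walkers, three tasks, two repetitions. Posture parameters are
calibrated in closed form from the analytic ground-truth relations above.
The four impulse-train knobs per group and task (timing jitter, amplitude,
asymmetry, noise) were fitted once by damped fixed-point iteration against
the full sensor pipeline at cohort scale, and the resulting constants are
frozen in the function; they are calibration constants, not physiological
estimates, and the group SDs are chosen to produce cohort spreads of the
extracted features comparable to the published tables rather than to model
biology.

## Numerical choices and problem sizes

* Degenerate inputs fail loudly with stage identity (`[resample]`,
  `[steps]`, ...); cohort-scale extraction converts per-recording failures
  into exclusion records instead of aborting.
* The wavelet round trip is exact to floating point for any length >= 16;
  boundary handling keeps floor((n + 7)/2) coefficients per band.
* Autocorrelation windows: the search window [0.5, 1.5] x period tolerates
  a 50% error in the provisional step period; the maximum lag is
  min(3.6 x period, 0.49 x span).
* Validation runs use 30 s recordings at 40 Hz (about 1200 samples) and
  5 m clips at 60 fps (about 270 frames); recovery and monotonicity
  properties average 20 seeded replicates; calibrated group means average
  10 seeded cohorts; the null (type-I) check uses 20 replicate null
  cohorts with identical group distributions.

## Known limitations

* The head-angle conventions are internally consistent and calibrated,
  but the original definitions behind published values cannot be
  confirmed; alternative conventions would change the raw angle scale
  while leaving group contrasts intact.
* Whether published RMS is per-axis or resultant-magnitude is unknown;
  the vertical-axis convention is used and the amplitude calibration
  absorbs the scale.
* Symmetry as a min/max correlation ratio saturates near 1 and compresses
  large asymmetries; it is kept because it guarantees the printed [0, 1]
  range.
* The exact Mann-Whitney enumeration is limited to min(n) <= 8 without
  ties; beyond that the tie-corrected normal approximation is used, which
  is mildly conservative for tiny samples with heavy ties.
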