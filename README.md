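# gaitfuse

Dual-channel gait assessment for older adults: sensor gait parameters from
a waist-worn smartphone accelerometer and postural parameters from
markerless video pose estimates, with a synthetic cohort generator and the
statistics needed to compare control and CSVD-like (cerebral small vessel
disease) gait.

## Who this is for

Researchers building accessible gait biomarkers from smartphone and video
data: the package implements the full extraction pipeline for both
channels, and — because clinical recordings are rarely shareable — a
ground-truth-bearing simulator that produces both data streams at
single-recording and cohort scale, so the whole chain is testable and
reproducible end to end.

## The measures

**Sensor channel** (tri-axial accelerometer at ~40 Hz, L3 waist placement,
resampled to 100 Hz by linear interpolation; vertical = gravity-dominant
axis, mean-removed):

- *step frequency* — reciprocal mean step interval (steps/s), steps found
  as filtered peaks of vertical acceleration;
- *acceleration RMS* — root mean square of the dynamic vertical
  acceleration (m/s²), a proxy for gait intensity;
- *step variability* — coefficient of variation of step intervals;
- *step regularity* — Ad1, the unbiased autocorrelation coefficient at the
  one-step lag: `r(k) = [Σᵢ x(i)x(i+k) / (N−k)] / r(0)`, peak picked in
  lag window [0.5, 1.5] × step period;
- *step symmetry* — min(Ad1, Ad2)/max(Ad1, Ad2), where Ad2 is the
  one-stride-lag peak; 1 means left and right steps are indistinguishable.

**Video channel** (OpenPose BODY_25 keypoints, 60 fps, 5 m walkway):
confidence-filtered frames, sagittal joint angles (knee, ankle, elbow,
upper-arm–trunk, trunk–thigh: mean and variance) and postural angles
(neck–trunk, body lean, sight line, head-to-body, head-to-ground,
calf-to-vertical: mean), all series denoised with a 3-level Daubechies-4
wavelet (soft universal threshold) before summarising, plus step length,
cadence, speed and heel height from the walkway pixel-to-metre
calibration.

**Statistics**: Mann-Whitney U per (task, parameter) with exact
enumeration for small samples and tie-corrected normal approximation
otherwise; repetitions averaged within participant; Welch t / chi-square
demographics; headline effect summaries.

## Worked example

```r
library(gaitfuse)

# one synthetic recording with known ground truth
rec <- simulate_accelerometer(gait_sim_params(step_frequency = 1.8,
                                              timing_jitter_cv = 0.08,
                                              seed = 42))
extract_sensor_features(rec)
#> <gait_features> f=1.80 steps/s  rms=1.76 m/s^2  variability=0.082  regularity=0.88  symmetry=0.97

# one synthetic keypoint clip: head pitched 6 degrees down
seq <- simulate_keypoints(posture_sim_params(head_pitch_offset = 6,
                                             keypoint_noise_sd = 3, seed = 42))
extract_posture_features(seq)
#> <posture_features> head_to_body=138.5  head_to_ground=128.6  calf=159.8  step_length=0.59 m  speed=1.08 m/s
```

The recovered step frequency (1.80 steps/s) and interval CV (0.082) match
the injected values; the head-to-ground mean (128.6°) sits within noise of
the generator's analytic ground truth 135 − 6 = 129°.

At cohort scale, a calibrated 10-control vs 19-CSVD design runs through
the full chain:

```r
d <- calibrated_design(seed = 42); d$tasks <- "normal"; d$repetitions <- 1L
feat <- extract_features_table(simulate_cohort(d, channels = "sensor"))
compare_groups(feat, parameters = c("step_regularity", "rms", "step_frequency"))
#>     task       parameter control_mean control_sd csvd_mean csvd_sd  U       p
#> 1 normal step_regularity        0.779      0.133     0.569   0.141 33 0.00478
#> 2 normal             rms        1.353      0.229     1.480   0.425 72 0.30190
#> 3 normal  step_frequency        1.709      0.124     2.101   0.392 32 0.00413
```

The CSVD-like group shows the expected regularity deficit (0.57 vs 0.78,
p ≈ 0.005 in this single replicate).

The on-disk pipeline (accelerometer CSVs, OpenPose per-frame JSON
directories, metadata, features, report) is driven by `run_simulate()`,
`run_extract()`, `run_compare()` / `run_all()`, or from a shell via the
thin wrapper in `inst/cli/gaitfuse`.

## Package layout

- `R/sim-accelerometer.R`, `R/sim-keypoints.R`, `R/sim-cohort.R` — the
  synthetic generators and the calibrated cohort design;
- `R/sensor-features.R`, `R/wavelet.R` — sensor chain (resampling, step
  detection, unbiased autocorrelation) and the db4 wavelet denoiser;
- `R/video-features.R`, `R/openpose-io.R` — video chain and OpenPose JSON
  I/O;
- `R/group-stats.R` — Mann-Whitney U, comparison/demographics/headline
  tables;
- `R/pipeline.R` — configuration and the simulate/extract/compare
  commands;
- `vignettes/gaitfuse-methods.Rmd` — the model, conventions, calibration
  and limitations in full.
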