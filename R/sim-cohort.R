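# Cohort-scale simulation: per-participant parameter draws from group
# distributions, three walking tasks with additive offsets, repeated
# recordings, and a calibrated default design whose group means reproduce
# the published control / CSVD gait parameter tables.

#' Cohort design
#'
#' Describes a two-group cohort: participant counts, per-group parameter
#' distributions (mean and SD for each generator field), per-task additive
#' offsets on the means, demographics distributions, repetitions and seed.
#'
#' @param n_control,n_csvd participants per group (>= 1).
#' @param groups named list with elements `control` and `csvd`; each holds
#'   `gait` and `posture` sublists of `c(mean, sd)` pairs for
#'   [gait_sim_params()] / [posture_sim_params()] fields, plus `demo`
#'   (age/height/weight `c(mean, sd)` pairs).
#' @param task_offsets named list per group, then per task (`dual`, `fast`),
#'   of additive offsets applied to the group means (the `normal` task is
#'   the baseline).
#' @param tasks character vector of tasks, default normal/dual/fast.
#' @param repetitions recordings per participant and task, default 2.
#' @param seed integer master seed.
#' @return object of class `cohort_design`.
#' @seealso [calibrated_design()] for the table-calibrated default.
#' @export
cohort_design <- function(n_control, n_csvd, groups, task_offsets = NULL,
                          tasks = c("normal", "dual", "fast"),
                          repetitions = 2L, seed = 1L) {
  stopifnot(n_control >= 1L, n_csvd >= 1L, repetitions >= 1L)
  for (g in c("control", "csvd"))
    if (is.null(groups[[g]])) stop("design error: missing group ", g)
  d <- list(n_control = as.integer(n_control), n_csvd = as.integer(n_csvd),
            groups = groups, task_offsets = task_offsets %||% list(),
            tasks = tasks, repetitions = as.integer(repetitions),
            seed = as.integer(seed))
  structure(d, class = "cohort_design")
}

# draw one value per c(mean, sd) pair, with clamping to keep generator
# parameters valid
.draw_params <- function(spec, offsets, clamp) {
  out <- list()
  for (nm in names(spec)) {
    ms <- spec[[nm]]
    mu <- ms[1L] + (offsets[[nm]] %||% 0)
    val <- stats::rnorm(1L, mu, ms[2L])
    if (!is.null(clamp[[nm]]))
      val <- min(max(val, clamp[[nm]][1L]), clamp[[nm]][2L])
    out[[nm]] <- val
  }
  out
}

.gait_clamp <- list(step_frequency = c(0.8, 3.5), step_amplitude = c(0.2, 8),
                    timing_jitter_cv = c(0.005, 0.5),
                    amplitude_jitter_cv = c(0, 0.8), asymmetry = c(0, 0.85),
                    noise_sd = c(0.01, 3))
.posture_clamp <- list(cadence = c(0.8, 3.5), step_length = c(0.25, 1.2),
                       knee_mean = c(120, 178), knee_range = c(0, 30),
                       ankle_mean = c(80, 150), ankle_range = c(0, 30),
                       elbow_mean = c(100, 178), elbow_range = c(0, 30),
                       calf_mean = c(5, 45), calf_range = c(0, 20),
                       head_pitch_offset = c(-25, 40), trunk_lean = c(-10, 40))

#' Simulate a full two-group cohort
#'
#' Per participant x task x repetition, draws individual generator
#' parameters from the group distributions (with task offsets on the means)
#' and emits one accelerometer recording and one keypoint sequence, plus a
#' metadata row carrying the ground-truth parameters. Fully reproducible
#' from the design seed: participant-level draws and every recording use
#' seeds derived deterministically from it.
#'
#' @param design a [cohort_design()].
#' @param channels which data streams to generate: `"both"` (default),
#'   `"sensor"` or `"video"` (the other stream is skipped, for speed).
#' @return list of class `gait_cohort`: `recordings` (named list of
#'   `accel_recording`), `keypoints` (named list of `keypoint_sequence`),
#'   and `metadata` (data frame).
#' @export
simulate_cohort <- function(design, channels = c("both", "sensor", "video")) {
  channels <- match.arg(channels)
  d <- design
  recordings <- list(); keypoints <- list(); meta <- list()
  for (g in c("control", "csvd")) {
    n_g <- if (g == "control") d$n_control else d$n_csvd
    spec <- d$groups[[g]]
    for (i in seq_len(n_g)) {
      id <- sprintf("%s_%02d", ifelse(g == "control", "C", "P"), i)
      set.seed(derive_seed(d$seed, id, "participant"))
      demo <- lapply(spec$demo, function(ms) stats::rnorm(1L, ms[1L], ms[2L]))
      sex <- sample(c("male", "female"), 1L)
      bmi <- demo$weight / (demo$height / 100)^2
      # participant-level deviation from the group mean, shared across tasks
      gait_dev <- lapply(spec$gait, function(ms) stats::rnorm(1L, 0, ms[2L]))
      post_dev <- lapply(spec$posture, function(ms) stats::rnorm(1L, 0, ms[2L]))
      weak_left <- stats::runif(1L) < 0.5
      for (task in d$tasks) {
        off <- d$task_offsets[[g]][[task]] %||% list()
        gspec <- lapply(names(spec$gait), function(nm) {
          c(spec$gait[[nm]][1L] + gait_dev[[nm]], 0)
        })
        names(gspec) <- names(spec$gait)
        pspec <- lapply(names(spec$posture), function(nm) {
          c(spec$posture[[nm]][1L] + post_dev[[nm]], 0)
        })
        names(pspec) <- names(spec$posture)
        for (rep_i in seq_len(d$repetitions)) {
          key <- sprintf("%s_%s_r%d", id, task, rep_i)
          gp <- .draw_params(gspec, off$gait %||% list(), .gait_clamp)
          pp <- .draw_params(pspec, off$posture %||% list(), .posture_clamp)
          gp$seed <- derive_seed(d$seed, key, "accel")
          pp$seed <- derive_seed(d$seed, key, "video")
          gparams <- do.call(gait_sim_params, gp)
          pparams <- do.call(posture_sim_params, pp)
          if (channels != "video")
            recordings[[key]] <- simulate_accelerometer(gparams)
          if (channels != "sensor")
            keypoints[[key]] <- simulate_keypoints(pparams)
          meta[[key]] <- data.frame(
            key = key, participant = id, group = g, task = task,
            repetition = rep_i, age = demo$age, sex = sex,
            height = demo$height, weight = demo$weight, bmi = bmi,
            true_step_frequency = gp$step_frequency,
            true_timing_jitter_cv = gp$timing_jitter_cv,
            true_asymmetry = gp$asymmetry,
            true_cadence = pp$cadence, true_step_length = pp$step_length,
            true_head_pitch_offset = pp$head_pitch_offset,
            true_trunk_lean = pp$trunk_lean, true_calf_mean = pp$calf_mean,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(recordings = recordings, keypoints = keypoints,
                 metadata = do.call(rbind, meta)),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d metadata rows, %d recordings, %d keypoint sequences\n",
              nrow(x$metadata), length(x$recordings), length(x$keypoints)))
  invisible(x)
}

# shared generator settings used by the calibrated design
.calib_common_gait <- list(amplitude_jitter_cv = c(0.10, 0.03),
                           duration = c(30, 0), nominal_rate = c(40, 0),
                           rate_jitter_cv = c(0.10, 0))
.calib_common_posture <- list(knee_mean = c(165, 4), knee_range = c(10, 2),
                              ankle_mean = c(105, 4), ankle_range = c(8, 2),
                              elbow_mean = c(155, 4), elbow_range = c(8, 2),
                              calf_range = c(9, 1.5), arm_swing = c(15, 3),
                              walk_distance = c(5, 0), fps = c(60, 0),
                              image_scale = c(320, 0), image_height = c(1080, 0),
                              keypoint_noise_sd = c(3, 0),
                              dropout_fraction = c(0.10, 0.02))

#' Calibrated two-group cohort design
#'
#' The default study design: 10 controls and 19 CSVD-like walkers, three
#' tasks, two repetitions. Group generator distributions are calibrated so
#' that the full pipeline's cohort means reproduce the published group means
#' (sensor: step frequency, RMS, variability, regularity, symmetry; video:
#' calf-to-vertical, head-to-body and head-to-ground angles) for each task.
#' The head and calf settings are closed-form (the generator geometry is
#' analytic); the impulse-train settings (amplitude, asymmetry, noise) were
#' fitted once by simulation so the sensor chain lands on the target means.
#'
#' @param n_control,n_csvd group sizes, defaults 10 and 19.
#' @param repetitions recordings per participant and task, default 2.
#' @param seed master seed.
#' @return a [cohort_design()].
#' @export
calibrated_design <- function(n_control = 10L, n_csvd = 19L,
                              repetitions = 2L, seed = 20230901L) {
  groups <- list(
    control = list(
      gait = c(list(step_frequency = c(1.75, 0.19),
                    step_amplitude = c(3.31, 0.84),
                    timing_jitter_cv = c(0.089, 0.04),
                    asymmetry = c(0.463, 0.126),
                    noise_sd = c(0.194, 0.039)), .calib_common_gait),
      posture = c(list(cadence = c(1.75, 0.19), step_length = c(0.60, 0.07),
                       calf_mean = c(20.19, 2.2),
                       head_pitch_offset = c(0.89, 6.0),
                       trunk_lean = c(2.93, 4.0)), .calib_common_posture),
      demo = list(age = c(67.40, 6.79), height = c(165.10, 9.65),
                  weight = c(66.10, 11.30))),
    csvd = list(
      gait = c(list(step_frequency = c(2.00, 0.45),
                    step_amplitude = c(2.78, 0.72),
                    timing_jitter_cv = c(0.102, 0.04),
                    asymmetry = c(0.534, 0.144),
                    noise_sd = c(0.605, 0.121)), .calib_common_gait),
      posture = c(list(cadence = c(2.00, 0.40), step_length = c(0.50, 0.07),
                       calf_mean = c(18.46, 2.6),
                       head_pitch_offset = c(6.60, 7.0),
                       trunk_lean = c(13.53, 5.0)), .calib_common_posture),
      demo = list(age = c(71.79, 7.56), height = c(168.11, 7.65),
                  weight = c(65.13, 12.34)))
  )
  task_offsets <- list(
    control = list(
      dual = list(gait = list(step_frequency = -0.05, step_amplitude = -0.17,
                              timing_jitter_cv = 0.003, asymmetry = -0.004,
                              noise_sd = 0.097),
                  posture = list(cadence = -0.05, head_pitch_offset = -0.32,
                                 trunk_lean = -1.00, calf_mean = -0.16)),
      fast = list(gait = list(step_frequency = 0.15, step_amplitude = 0.78,
                              timing_jitter_cv = 0.016, asymmetry = -0.161,
                              noise_sd = -0.099),
                  posture = list(cadence = 0.15, step_length = 0.10,
                                 head_pitch_offset = -0.14,
                                 trunk_lean = -0.84, calf_mean = 0.55))),
    csvd = list(
      dual = list(gait = list(step_frequency = -0.08, step_amplitude = -0.31,
                              timing_jitter_cv = -0.006, asymmetry = 0.030,
                              noise_sd = 0.006),
                  posture = list(cadence = -0.08, head_pitch_offset = 3.38,
                                 trunk_lean = 5.07, calf_mean = -1.66)),
      fast = list(gait = list(step_frequency = 0.02, step_amplitude = 1.23,
                              timing_jitter_cv = 0.013, asymmetry = 0.079,
                              noise_sd = -0.443),
                  posture = list(cadence = 0.02, step_length = 0.08,
                                 head_pitch_offset = 1.42,
                                 trunk_lean = 1.10, calf_mean = 0.63))))
  cohort_design(n_control = n_control, n_csvd = n_csvd, groups = groups,
                task_offsets = task_offsets, repetitions = repetitions,
                seed = seed)
}
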