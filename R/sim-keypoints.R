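# Synthetic sagittal-plane OpenPose BODY_25 keypoint sequences with known
# ground-truth posture angles and spatiotemporal parameters.

# BODY_25 keypoint indices (0-based, as in the OpenPose JSON dialect)
BODY25 <- c(nose = 0L, neck = 1L, r_shoulder = 2L, r_elbow = 3L, r_wrist = 4L,
            l_shoulder = 5L, l_elbow = 6L, l_wrist = 7L, mid_hip = 8L,
            r_hip = 9L, r_knee = 10L, r_ankle = 11L, l_hip = 12L,
            l_knee = 13L, l_ankle = 14L, r_eye = 15L, l_eye = 16L,
            r_ear = 17L, l_ear = 18L, l_big_toe = 19L, l_small_toe = 20L,
            l_heel = 21L, r_big_toe = 22L, r_small_toe = 23L, r_heel = 24L)

#' Keypoint simulation parameters
#'
#' Parameter set for [simulate_keypoints()], a planar stick-figure walker
#' filmed from its right side. Hips translate at cadence x step length; leg,
#' arm and head segments oscillate sinusoidally over the gait cycle. The
#' neck-to-ear vector sits at 135 degrees from the travel direction when
#' `head_pitch_offset = 0` and is rotated forward-down by the offset, so the
#' ground-truth head-to-ground angle is `135 - head_pitch_offset` and the
#' head-to-body angle is `135 + head_pitch_offset - trunk_lean` (degrees).
#'
#' @param cadence steps per second.
#' @param step_length metres per step; walking speed = cadence x step_length.
#' @param knee_mean,knee_range knee interior angle: mean and half-range, deg.
#' @param ankle_mean,ankle_range ankle interior angle mean and half-range, deg.
#' @param elbow_mean,elbow_range elbow interior angle mean and half-range, deg.
#' @param calf_mean,calf_range forward tilt of the calf segment from the
#'   downward vertical: mean and half-range, deg; `calf_range` must stay
#'   below `calf_mean` so the calf-to-vertical angle averages
#'   `180 - calf_mean` exactly.
#' @param arm_swing upper-arm swing half-range, deg.
#' @param head_pitch_offset downward head pitch, deg (see above).
#' @param trunk_lean forward trunk lean from vertical, deg.
#' @param walk_distance metres covered by the clip (> 0).
#' @param fps frames per second.
#' @param image_scale pixels per metre.
#' @param image_height frame height in pixels (y axis points down).
#' @param keypoint_noise_sd Gaussian pixel noise added to every coordinate.
#' @param dropout_fraction fraction of frames (split between clip start and
#'   end) whose required points are zeroed with confidence 0, emulating the
#'   walker entering/leaving the field of view.
#' @param seed optional integer seed.
#' @return object of class `posture_sim_params`.
#' @export
posture_sim_params <- function(cadence = 1.8, step_length = 0.6,
                               knee_mean = 165, knee_range = 10,
                               ankle_mean = 105, ankle_range = 8,
                               elbow_mean = 155, elbow_range = 8,
                               calf_mean = 20, calf_range = 10,
                               arm_swing = 15,
                               head_pitch_offset = 0, trunk_lean = 3,
                               walk_distance = 5, fps = 60,
                               image_scale = 320, image_height = 1080,
                               keypoint_noise_sd = 0,
                               dropout_fraction = 0, seed = NULL) {
  p <- list(cadence = cadence, step_length = step_length,
            knee_mean = knee_mean, knee_range = knee_range,
            ankle_mean = ankle_mean, ankle_range = ankle_range,
            elbow_mean = elbow_mean, elbow_range = elbow_range,
            calf_mean = calf_mean, calf_range = calf_range,
            arm_swing = arm_swing,
            head_pitch_offset = head_pitch_offset, trunk_lean = trunk_lean,
            walk_distance = walk_distance, fps = fps,
            image_scale = image_scale, image_height = image_height,
            keypoint_noise_sd = keypoint_noise_sd,
            dropout_fraction = dropout_fraction, seed = seed)
  validate_posture_sim_params(p)
  structure(p, class = "posture_sim_params")
}

validate_posture_sim_params <- function(p) {
  bad <- function(msg) stop("invalid parameter: ", msg)
  if (!(p$walk_distance > 0)) bad("walk_distance must be > 0")
  if (!(p$fps > 0)) bad("fps must be > 0")
  if (!(p$image_scale > 0)) bad("image_scale must be > 0")
  if (!(p$cadence > 0)) bad("cadence must be > 0")
  if (!(p$step_length > 0)) bad("step_length must be > 0")
  if (p$dropout_fraction < 0 || p$dropout_fraction > 1)
    bad("dropout_fraction must be in [0, 1]")
  for (f in c("knee_range", "ankle_range", "elbow_range", "calf_range",
              "arm_swing"))
    if (p[[f]] < 0) bad(paste(f, "must be >= 0"))
  if (p$keypoint_noise_sd < 0) bad("keypoint_noise_sd must be >= 0")
  invisible(p)
}

# rotate a 2-vector (or n x 2 matrix) by `deg` degrees counter-clockwise
.rot2 <- function(v, deg) {
  a <- .rad(deg)
  v <- rbind(v)
  cbind(v[, 1] * cos(a) - v[, 2] * sin(a),
        v[, 1] * sin(a) + v[, 2] * cos(a))
}

#' Simulate an OpenPose BODY_25 keypoint sequence
#'
#' Samples a planar stick-figure walker at `fps` over a `walk_distance`
#' metre traverse. The camera-facing (right) side is emitted with high
#' confidence; the contralateral leg is visible at moderate confidence and
#' phase-shifted by half a stride; contralateral arm, ear and eye are given
#' low confidence, matching a side-view capture. World coordinates (metres,
#' y up) are mapped to image pixels (y down) through `image_scale` and
#' `image_height`.
#'
#' @param params a [posture_sim_params()] object.
#' @return object of class `keypoint_sequence`: `fps`, `frames` (n x 25 x 3
#'   array: x, y, confidence), `side`, `image_height`, and `truth` with the
#'   analytic angle series (head_to_ground, head_to_body, calf_to_vertical,
#'   knee, ankle, elbow in degrees), step_length, cadence, speed and the
#'   parameters.
#' @export
simulate_keypoints <- function(params) {
  p <- validate_posture_sim_params(params)
  if (!is.null(p$seed)) set.seed(p$seed)
  speed <- p$cadence * p$step_length
  duration <- p$walk_distance / speed
  n <- max(2L, floor(duration * p$fps) + 1L)
  t <- (seq_len(n) - 1L) / p$fps
  phase <- 2 * pi * (p$cadence / 2) * t    # stride phase (right leg)

  # segment lengths (metres) of the stick figure
  L <- list(trunk = 0.50, ear = 0.13, nose = 0.11, thigh = 0.42, calf = 0.45,
            toe = 0.18, upper_arm = 0.28, forearm = 0.25)

  hip_x <- 0.3 + speed * t
  hip_y <- 0.92 + 0.015 * cos(2 * pi * p$cadence * t)
  midhip <- cbind(hip_x, hip_y)
  trunk_dir <- c(sin(.rad(p$trunk_lean)), cos(.rad(p$trunk_lean)))
  neck <- midhip + rep(L$trunk, n) %o% trunk_dir

  # head: neck->ear at psi = 135 - pitch degrees from the travel direction
  psi <- 135 - p$head_pitch_offset
  ear_dir <- c(cos(.rad(psi)), sin(.rad(psi)))
  ear <- neck + rep(L$ear, n) %o% ear_dir
  nose_dir <- .rot2(ear_dir, -90)[1, ]    # facing forward of the ear axis
  nose <- ear + rep(L$nose, n) %o% nose_dir
  eye <- ear + rep(0.06, n) %o% nose_dir

  leg <- function(ph) {
    calf_tilt <- p$calf_mean + p$calf_range * sin(ph)
    knee_ang <- p$knee_mean + p$knee_range * sin(ph + pi / 2)
    thigh_tilt <- calf_tilt + (180 - knee_ang)
    hip <- midhip + cbind(0.02, -0.06)[rep(1L, n), ]
    dthigh <- cbind(sin(.rad(thigh_tilt)), -cos(.rad(thigh_tilt)))
    knee <- hip + L$thigh * dthigh
    dcalf <- cbind(sin(.rad(calf_tilt)), -cos(.rad(calf_tilt)))
    ankle <- knee + L$calf * dcalf
    ankle_ang <- p$ankle_mean + p$ankle_range * sin(ph + pi / 2)
    # ankle->toe: ankle->knee rotated clockwise (towards travel) by the
    # interior ankle angle
    up <- -dcalf
    dtoe <- cbind(up[, 1] * cos(.rad(-ankle_ang)) - up[, 2] * sin(.rad(-ankle_ang)),
                  up[, 1] * sin(.rad(-ankle_ang)) + up[, 2] * cos(.rad(-ankle_ang)))
    toe <- ankle + L$toe * dtoe
    small_toe <- ankle + 0.9 * L$toe * dtoe + cbind(0, -0.01)[rep(1L, n), ]
    heel <- ankle - 0.06 * dtoe + cbind(0, -0.03)[rep(1L, n), ]
    list(hip = hip, knee = knee, ankle = ankle, toe = toe,
         small_toe = small_toe, heel = heel,
         calf_tilt = calf_tilt, knee_ang = knee_ang, ankle_ang = ankle_ang)
  }
  arm <- function(ph) {
    swing <- p$arm_swing * sin(ph + pi)    # antiphase with ipsilateral leg
    shoulder <- neck - 0.03 * matrix(trunk_dir, n, 2, byrow = TRUE)
    dua <- cbind(sin(.rad(swing)), -cos(.rad(swing)))
    elbow <- shoulder + L$upper_arm * dua
    elbow_ang <- p$elbow_mean + p$elbow_range * sin(ph + pi)
    delta <- 180 - elbow_ang
    dfa <- cbind(dua[, 1] * cos(.rad(delta)) - dua[, 2] * sin(.rad(delta)),
                 dua[, 1] * sin(.rad(delta)) + dua[, 2] * cos(.rad(delta)))
    wrist <- elbow + L$forearm * dfa
    list(shoulder = shoulder, elbow = elbow, wrist = wrist,
         elbow_ang = elbow_ang)
  }

  right_leg <- leg(phase)
  left_leg <- leg(phase + pi)
  right_arm <- arm(phase)
  left_arm <- arm(phase + pi)

  pts <- array(0, dim = c(n, 25L, 3L))
  put <- function(name, xy, conf) {
    j <- BODY25[[name]] + 1L
    pts[, j, 1:2] <<- xy
    pts[, j, 3L] <<- conf
  }
  hi <- function() pmin(0.98, pmax(0.5, stats::rnorm(n, 0.85, 0.04)))
  mid <- function() pmin(0.7, pmax(0.31, stats::rnorm(n, 0.45, 0.04)))
  lo <- function() stats::runif(n, 0.05, 0.2)

  put("nose", nose, hi()); put("neck", neck, hi())
  put("mid_hip", midhip, hi())
  put("r_ear", ear, hi()); put("r_eye", eye, hi())
  put("l_ear", ear, lo()); put("l_eye", eye, lo())
  put("r_shoulder", right_arm$shoulder, hi())
  put("r_elbow", right_arm$elbow, hi()); put("r_wrist", right_arm$wrist, hi())
  put("l_shoulder", left_arm$shoulder, lo())
  put("l_elbow", left_arm$elbow, lo()); put("l_wrist", left_arm$wrist, lo())
  put("r_hip", right_leg$hip, hi()); put("r_knee", right_leg$knee, hi())
  put("r_ankle", right_leg$ankle, hi()); put("r_big_toe", right_leg$toe, hi())
  put("r_small_toe", right_leg$small_toe, hi()); put("r_heel", right_leg$heel, hi())
  put("l_hip", left_leg$hip, mid()); put("l_knee", left_leg$knee, mid())
  put("l_ankle", left_leg$ankle, mid()); put("l_big_toe", left_leg$toe, mid())
  put("l_small_toe", left_leg$small_toe, mid()); put("l_heel", left_leg$heel, mid())

  # world (m, y up) -> image (px, y down)
  pts[, , 1L] <- pts[, , 1L] * p$image_scale
  pts[, , 2L] <- p$image_height - pts[, , 2L] * p$image_scale
  if (p$keypoint_noise_sd > 0) {
    pts[, , 1L] <- pts[, , 1L] + stats::rnorm(n * 25L, 0, p$keypoint_noise_sd)
    pts[, , 2L] <- pts[, , 2L] + stats::rnorm(n * 25L, 0, p$keypoint_noise_sd)
  }

  # edge dropout: first/last frames lose their points entirely
  n_drop <- round(p$dropout_fraction * n)
  drop_idx <- c(seq_len(ceiling(n_drop / 2)),
                if (floor(n_drop / 2) > 0) (n - floor(n_drop / 2) + 1L):n)
  if (length(drop_idx)) pts[drop_idx, , ] <- 0

  truth_angles <- data.frame(
    time = t,
    head_to_ground = rep(psi, n),
    head_to_body = rep(135 + p$head_pitch_offset - p$trunk_lean, n),
    calf_to_vertical = 180 - abs(right_leg$calf_tilt),
    knee = right_leg$knee_ang,
    ankle = right_leg$ankle_ang,
    elbow = right_arm$elbow_ang
  )

  structure(list(
    fps = p$fps, frames = pts, side = "right", image_height = p$image_height,
    truth = list(angles = truth_angles, step_length = p$step_length,
                 cadence = p$cadence, speed = speed,
                 duration = duration, params = p)
  ), class = "keypoint_sequence")
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat(sprintf("<keypoint_sequence> %d frames at %g fps (%s side facing camera)\n",
              dim(x$frames)[1L], x$fps, x$side))
  invisible(x)
}
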