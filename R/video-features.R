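# Postural and spatiotemporal gait parameters from BODY_25 keypoint
# sequences: sagittal joint angles (denoised with a 3-level db4 wavelet
# before summarising), head/trunk posture angles, and step length, cadence,
# speed and heel height from the walkway calibration.

.side_points <- function(side) {
  s <- if (side == "right") c("r_shoulder", "r_elbow", "r_wrist", "r_hip",
                              "r_knee", "r_ankle", "r_big_toe", "r_heel",
                              "r_ear")
       else c("l_shoulder", "l_elbow", "l_wrist", "l_hip", "l_knee",
              "l_ankle", "l_big_toe", "l_heel", "l_ear")
  BODY25[c(s, "neck", "mid_hip")]
}

# camera-facing side: the one whose required keypoints are more confidently
# detected over the whole clip
.select_side <- function(seq) {
  conf <- seq$frames[, , 3L, drop = FALSE]
  msc <- function(side) mean(conf[, .side_points(side) + 1L, 1L])
  if (msc("right") >= msc("left")) "right" else "left"
}

#' Filter frames on keypoint confidence
#'
#' Retains frames in which every required point reaches the confidence
#' threshold, mirroring the exclusion of segments where the walker has just
#' entered or left the screen. Time-series parameters are computed on the
#' longest contiguous retained run.
#'
#' @param seq a `keypoint_sequence`.
#' @param required_points 0-based BODY_25 indices that must be confident;
#'   default: camera-side limb points plus neck and mid-hip.
#' @param conf_threshold minimum confidence, default 0.3.
#' @return the input sequence restricted to the longest retained run, with
#'   attributes `retained_fraction`, `frame_indices` (original indices) and
#'   `side`.
#' @export
filter_frames <- function(seq, required_points = NULL, conf_threshold = 0.3) {
  side <- if (!is.na(seq$side %||% NA_character_)) seq$side else .select_side(seq)
  if (is.null(required_points)) required_points <- .side_points(side)
  stopifnot(all(required_points %in% 0:24))
  conf <- seq$frames[, required_points + 1L, 3L, drop = FALSE][, , 1L]
  ok <- apply(conf >= conf_threshold, 1L, all)
  frac <- mean(ok)
  runs <- rle(ok)
  if (!any(runs$values)) stop("insufficient frames: no frame passes the confidence filter")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  idx <- starts[best]:ends[best]
  # require at least about one gait cycle at a conservative 1.5 steps/s
  if (length(idx) < max(8, round(seq$fps / 1.5)))
    stop("insufficient frames: longest clean run shorter than one gait cycle")
  out <- seq
  out$frames <- seq$frames[idx, , , drop = FALSE]
  out$side <- side
  attr(out, "retained_fraction") <- frac
  attr(out, "frame_indices") <- idx
  attr(out, "side") <- side
  out
}

# point trajectory in world coordinates (pixels, y up)
.world_xy <- function(seq, name, side = NULL) {
  nm <- if (!is.null(side) && grepl("^[rl]_", name)) name else name
  j <- BODY25[[nm]] + 1L
  cbind(seq$frames[, j, 1L], seq$image_height - seq$frames[, j, 2L])
}

.travel_sign <- function(seq) {
  mh <- .world_xy(seq, "mid_hip")
  s <- sign(mh[nrow(mh), 1L] - mh[1L, 1L])
  if (s == 0) 1 else s
}

#' Posture angle time series from a keypoint sequence
#'
#' Computes, per retained frame and on the camera-facing side: the dynamic
#' joint angles (knee, ankle, elbow, upper-arm-to-trunk, trunk-to-thigh) and
#' the postural angles (neck-to-trunk, body lean, sight line, head-to-body,
#' head-to-ground, calf-to-vertical). Head-to-ground is the angle of the
#' neck-to-ear vector measured from the horizontal direction of travel, so a
#' more downward-pitched head gives a smaller value; using the travel
#' direction rather than the image x-axis makes it insensitive to camera
#' roll. All series are wavelet-denoised before any statistics.
#'
#' @param seq a `keypoint_sequence` (filtered internally if not already).
#' @param conf_threshold confidence threshold for [filter_frames()].
#' @param denoise logical; apply [wavelet_denoise()] to every series.
#' @param keep_details passed to [wavelet_denoise()].
#' @return list of class `angle_series_set`: named numeric series (degrees)
#'   plus `retained_fraction`, `side`, `fps` and `n_frames`.
#' @export
posture_angle_series <- function(seq, conf_threshold = 0.3, denoise = TRUE,
                                 keep_details = TRUE) {
  fseq <- if (is.null(attr(seq, "frame_indices")))
    filter_frames(seq, conf_threshold = conf_threshold) else seq
  side <- attr(fseq, "side") %||% fseq$side
  pre <- if (side == "right") "r_" else "l_"
  P <- function(nm) .world_xy(fseq, paste0(pre, nm))
  neck <- .world_xy(fseq, "neck"); midhip <- .world_xy(fseq, "mid_hip")
  nose <- .world_xy(fseq, "nose")
  hip <- P("hip"); knee <- P("knee"); ankle <- P("ankle")
  toe <- P("big_toe"); shoulder <- P("shoulder"); elbow <- P("elbow")
  wrist <- P("wrist"); ear <- P("ear")
  trav <- .travel_sign(fseq)

  # head point: camera-side ear, falling back to nose if the ear is not
  # reliably detected
  ear_conf <- fseq$frames[, BODY25[[paste0(pre, "ear")]] + 1L, 3L]
  head_pt <- if (mean(ear_conf >= conf_threshold) >= 0.5) ear else nose

  e <- ear - neck
  head_to_ground <- .deg(atan2(e[, 2L], e[, 1L] * trav))

  series <- list(
    knee = joint_angle(hip, knee, ankle),
    ankle = joint_angle(knee, ankle, toe),
    elbow = joint_angle(shoulder, elbow, wrist),
    upper_arm_trunk = joint_angle(elbow, shoulder, midhip),
    trunk_thigh = joint_angle(neck, midhip, knee),
    neck_trunk = joint_angle(head_pt, neck, midhip),
    body_lean = segment_reference_angle(midhip, neck, "vertical"),
    sight_line = segment_reference_angle(ear, nose, "horizontal",
                                         travel_sign = trav),
    head_to_body = joint_angle(ear, neck, midhip),
    head_to_ground = head_to_ground,
    calf_to_vertical = segment_reference_angle(knee, ankle, "vertical")
  )
  if (denoise)
    series <- lapply(series, function(s)
      suppressWarnings(wavelet_denoise(s, keep_details = keep_details)))
  structure(c(series,
              list(retained_fraction = attr(fseq, "retained_fraction") %||% 1,
                   side = side, fps = fseq$fps,
                   n_frames = nrow(neck))),
            class = "angle_series_set")
}

#' Spatiotemporal gait parameters from a keypoint sequence
#'
#' Pixel-to-metre scale is obtained from the known walkway length covered by
#' the retained run (mid-hip horizontal displacement); heel strikes are the
#' local maxima of the horizontal ankle-to-ankle separation; step length is
#' the mean distance between consecutive (alternating) leading-ankle
#' positions at the strikes; cadence is strikes over elapsed time; speed is
#' their product; heel height is the mean per-cycle maximum heel clearance
#' above the ground line (the lowest camera-side heel position).
#'
#' @param seq a `keypoint_sequence` (filtered internally if needed).
#' @param walkway_length metres covered by the retained run, default 5.
#' @param conf_threshold confidence threshold for filtering.
#' @return list with `heel_height` (m), `step_length` (m), `step_speed`
#'   (m/s), `cadence` (steps/s), and `scale` (m per pixel).
#' @export
spatiotemporal_params <- function(seq, walkway_length = 5,
                                  conf_threshold = 0.3) {
  if (walkway_length <= 0) stop("invalid parameter: walkway_length must be > 0")
  fseq <- if (is.null(attr(seq, "frame_indices")))
    filter_frames(seq, conf_threshold = conf_threshold) else seq
  side <- attr(fseq, "side") %||% fseq$side
  pre <- if (side == "right") "r_" else "l_"
  other <- if (side == "right") "l_" else "r_"
  a1 <- .world_xy(fseq, paste0(pre, "ankle"))
  a2 <- .world_xy(fseq, paste0(other, "ankle"))
  mh <- .world_xy(fseq, "mid_hip")
  heel <- .world_xy(fseq, paste0(pre, "heel"))
  n <- nrow(mh); fps <- fseq$fps
  disp <- abs(mh[n, 1L] - mh[1L, 1L])
  if (disp < 1e-9) stop("degenerate input: no horizontal hip displacement")
  scale <- walkway_length / disp                       # metres per pixel
  trav <- .travel_sign(fseq)

  sep <- abs(a1[, 1L] - a2[, 1L])
  strikes <- find_peaks(sep, min_dist = max(1L, round(0.25 * fps)),
                        min_prominence = 0.3 * stats::sd(sep))
  if (length(strikes) < 2L)
    stop("insufficient steps: fewer than 2 heel strikes detected")
  lead_x <- pmax(a1[strikes, 1L] * trav, a2[strikes, 1L] * trav)
  step_px <- diff(lead_x)
  step_px <- step_px[step_px > 0]
  if (!length(step_px)) stop("insufficient steps: no forward progression between strikes")
  step_length <- mean(step_px) * scale
  cadence <- (length(strikes) - 1L) / ((strikes[length(strikes)] - strikes[1L]) / fps)
  ground <- min(heel[, 2L])                            # y up: ground is the minimum
  clearance <- heel[, 2L] - ground
  cyc <- findInterval(seq_len(n), strikes)
  heel_height <- mean(tapply(clearance, cyc, max)) * scale
  list(heel_height = heel_height, step_length = step_length,
       step_speed = step_length * cadence, cadence = cadence, scale = scale)
}

#' Posture features for one keypoint sequence
#'
#' Full video chain: confidence filtering, angle series extraction, wavelet
#' denoising, then mean and variance for the five dynamic joint angles, mean
#' for the six postural angles, plus the spatiotemporal parameters and QC
#' fields.
#'
#' @param seq a `keypoint_sequence`.
#' @param walkway_length metres covered by the clip, default 5.
#' @param conf_threshold keypoint confidence threshold, default 0.3.
#' @param keep_details passed to [wavelet_denoise()].
#' @return list of class `posture_features`: `<angle>_mean` and `<angle>_var`
#'   (degrees, degrees^2) for knee/ankle/elbow/upper_arm_trunk/trunk_thigh,
#'   `<angle>_mean` for neck_trunk/body_lean/sight_line/head_to_body/
#'   head_to_ground/calf_to_vertical, `heel_height`, `step_length`,
#'   `step_speed`, `cadence_video`, `retained_frame_fraction`, `side`.
#' @examples
#' seq <- simulate_keypoints(posture_sim_params(seed = 1))
#' pf <- extract_posture_features(seq)
#' pf$head_to_ground_mean
#' @export
extract_posture_features <- function(seq, walkway_length = 5,
                                     conf_threshold = 0.3,
                                     keep_details = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  fseq <- stage("filter", filter_frames(seq, conf_threshold = conf_threshold))
  ang <- stage("angles", posture_angle_series(fseq, conf_threshold = conf_threshold,
                                              keep_details = keep_details))
  st <- stage("spatiotemporal",
              spatiotemporal_params(fseq, walkway_length = walkway_length,
                                    conf_threshold = conf_threshold))
  dynamic <- c("knee", "ankle", "elbow", "upper_arm_trunk", "trunk_thigh")
  postural <- c("neck_trunk", "body_lean", "sight_line", "head_to_body",
                "head_to_ground", "calf_to_vertical")
  out <- list()
  for (nm in dynamic) {
    out[[paste0(nm, "_mean")]] <- mean(ang[[nm]])
    out[[paste0(nm, "_var")]] <- stats::var(ang[[nm]])
  }
  for (nm in postural) out[[paste0(nm, "_mean")]] <- mean(ang[[nm]])
  out$heel_height <- st$heel_height
  out$step_length <- st$step_length
  out$step_speed <- st$step_speed
  out$cadence_video <- st$cadence
  out$retained_frame_fraction <- ang$retained_fraction
  out$side <- ang$side
  structure(out, class = "posture_features")
}

#' @export
print.posture_features <- function(x, ...) {
  cat(sprintf(paste0("<posture_features> head_to_body=%.1f  head_to_ground=%.1f  ",
                     "calf=%.1f  step_length=%.2f m  speed=%.2f m/s\n"),
              x$head_to_body_mean, x$head_to_ground_mean,
              x$calf_to_vertical_mean, x$step_length, x$step_speed))
  invisible(x)
}
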