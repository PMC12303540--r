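# Reading and writing the OpenPose per-frame JSON dialect and the
# accelerometer CSV format.

#' Write a keypoint sequence as OpenPose per-frame JSON files
#'
#' One file per frame, named `<prefix>_<frame>_keypoints.json` with a
#' zero-padded 12-digit frame index, each containing
#' `{"people":[{"pose_keypoints_2d":[x0,y0,c0,...,x24,y24,c24]}]}` — the
#' native OpenPose output layout, so real OpenPose runs drop in unchanged.
#'
#' @param seq a `keypoint_sequence`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix, default `"frame"`.
#' @return invisibly, the vector of file paths written.
#' @export
write_openpose_json <- function(seq, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(seq$frames)[1L]
  paths <- character(n)
  for (i in seq_len(n)) {
    flat <- as.numeric(t(seq$frames[i, , ]))
    obj <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = flat)))
    paths[i] <- file.path(dir, sprintf("%s_%012d_keypoints.json", prefix, i - 1L))
    jsonlite::write_json(obj, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Parse OpenPose BODY_25 JSON frame files into a keypoint sequence
#'
#' Files are ordered by filename. A frame with an empty `people` array
#' becomes an all-zero-confidence frame; when several people are present the
#' one with the largest keypoint bounding box is kept.
#'
#' @param frame_files character vector of JSON file paths (or a directory,
#'   in which case all `*_keypoints.json` files in it are used).
#' @param fps frames per second of the source video (default 60).
#' @param image_height frame height in pixels (default 1080).
#' @return object of class `keypoint_sequence`.
#' @export
parse_openpose_json <- function(frame_files, fps = 60, image_height = 1080) {
  if (length(frame_files) == 1L && dir.exists(frame_files))
    frame_files <- list.files(frame_files, pattern = "_keypoints\\.json$",
                              full.names = TRUE)
  frame_files <- sort(frame_files)
  if (!length(frame_files)) stop("format error: no keypoint files found")
  n <- length(frame_files)
  pts <- array(0, dim = c(n, 25L, 3L))
  for (i in seq_len(n)) {
    obj <- tryCatch(jsonlite::read_json(frame_files[i], simplifyVector = TRUE),
                    error = function(e)
                      stop("format error in ", frame_files[i], ": ",
                           conditionMessage(e), call. = FALSE))
    people <- obj$people
    if (is.null(people) || (is.data.frame(people) && nrow(people) == 0L) ||
        (is.list(people) && length(people) == 0L)) next
    kp_list <- if (is.data.frame(people)) people$pose_keypoints_2d else
      lapply(people, `[[`, "pose_keypoints_2d")
    kp_list <- lapply(kp_list, as.numeric)
    bad <- vapply(kp_list, function(k) length(k) != 75L, logical(1))
    if (any(bad))
      stop("format error in ", frame_files[i],
           ": expected 25 keypoint triplets (75 values)")
    if (length(kp_list) > 1L) {
      area <- vapply(kp_list, function(k) {
        m <- matrix(k, ncol = 3L, byrow = TRUE)
        m <- m[m[, 3L] > 0, , drop = FALSE]
        if (!nrow(m)) return(0)
        diff(range(m[, 1L])) * diff(range(m[, 2L]))
      }, numeric(1))
      kp <- kp_list[[which.max(area)]]
    } else kp <- kp_list[[1L]]
    pts[i, , ] <- matrix(kp, ncol = 3L, byrow = TRUE)
  }
  structure(list(fps = fps, frames = pts, side = NA_character_,
                 image_height = image_height, truth = NULL),
            class = "keypoint_sequence")
}

#' Write an accelerometer recording to CSV
#'
#' Columns `t_s, ax, ay, az` (SI units) after `#`-prefixed header comments
#' recording provenance.
#'
#' @param rec an `accel_recording`.
#' @param path output file.
#' @param comment optional named character vector written as `# key: value`
#'   header lines.
#' @return invisibly, `path`.
#' @export
write_accelerometer_csv <- function(rec, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment))
    writeLines(sprintf("# %s: %s", names(comment), comment), con)
  df <- data.frame(t_s = rec$time, ax = rec$acc[, 1L],
                   ay = rec$acc[, 2L], az = rec$acc[, 3L])
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an accelerometer CSV
#'
#' @param path CSV with columns `t_s, ax, ay, az`; `#` comment lines are
#'   skipped.
#' @return object of class `accel_recording` (without ground truth).
#' @export
read_accelerometer_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("format error: expected columns t_s, ax, ay, az in ", path)
  if (nrow(df) < 2L) stop("degenerate input: fewer than 2 samples in ", path)
  if (any(diff(df$t_s) <= 0))
    stop("format error: timestamps not strictly increasing in ", path)
  structure(list(time = df$t_s,
                 acc = cbind(ax = df$ax, ay = df$ay, az = df$az),
                 axis_labels = c("x", "y", "z"),
                 placement = "L3 waist", truth = NULL),
            class = "accel_recording")
}
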