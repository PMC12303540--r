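# Orchestration: in-memory cohort feature extraction and the on-disk
# simulate / extract / compare pipeline with manifest, exclusion accounting
# and deterministic outputs.

#' Run configuration
#'
#' Bundles the extraction constants and paths used by the pipeline commands.
#' Defaults mirror the measurement protocol: 100 Hz resampling grid, 5 m
#' walkway, 0.3 keypoint confidence threshold.
#'
#' @param resample_rate accelerometer resampling rate, Hz.
#' @param conf_threshold keypoint confidence threshold.
#' @param walkway_length walkway length in metres.
#' @param regularity_lag autocorrelation peak defining regularity
#'   (`"step"`, `"stride"` or `"mean"`).
#' @param keep_details wavelet denoising keeps thresholded detail bands
#'   (`TRUE`) or reconstructs from the approximation only.
#' @param cutoff_hz,min_separation,prominence_frac step-detector constants.
#' @param seed integer seed for pipeline randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(resample_rate = 100, conf_threshold = 0.3,
                       walkway_length = 5, regularity_lag = "step",
                       keep_details = TRUE, cutoff_hz = 10,
                       min_separation = 0.25, prominence_frac = 0.3,
                       seed = 1L) {
  stopifnot(resample_rate > 0, walkway_length > 0, conf_threshold >= 0,
            cutoff_hz > 0, min_separation > 0, prominence_frac >= 0)
  structure(list(resample_rate = resample_rate,
                 conf_threshold = conf_threshold,
                 walkway_length = walkway_length,
                 regularity_lag = regularity_lag,
                 keep_details = keep_details, cutoff_hz = cutoff_hz,
                 min_separation = min_separation,
                 prominence_frac = prominence_frac,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Extract the feature table of a simulated cohort
#'
#' Runs the sensor and/or video chains over every recording of an in-memory
#' cohort. Per-recording failures are collected, not fatal: the affected
#' cells stay `NA` and the exclusions are attached as an attribute with
#' stage identity.
#'
#' @param cohort a `gait_cohort` from [simulate_cohort()].
#' @param config a [run_config()].
#' @return data frame: metadata columns plus sensor features
#'   (`step_frequency`, `rms`, `step_variability`, `step_regularity`,
#'   `step_symmetry`) and posture features; attribute `exclusions` is a data
#'   frame (key, channel, reason).
#' @export
extract_features_table <- function(cohort, config = run_config()) {
  meta <- cohort$metadata
  excl <- list()
  sensor_cols <- c("step_frequency", "rms", "step_variability",
                   "step_regularity", "step_symmetry")
  res <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    key <- meta$key[i]
    row <- list()
    rec <- cohort$recordings[[key]]
    if (!is.null(rec)) {
      gf <- tryCatch(extract_sensor_features(
        rec, resample_rate = config$resample_rate,
        regularity_lag = config$regularity_lag,
        cutoff_hz = config$cutoff_hz,
        min_separation = config$min_separation,
        prominence_frac = config$prominence_frac),
        error = function(e) e)
      if (inherits(gf, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          key = key, channel = "sensor", reason = conditionMessage(gf))
        row[sensor_cols] <- NA_real_
      } else row[sensor_cols] <- gf[sensor_cols]
    }
    kp <- cohort$keypoints[[key]]
    if (!is.null(kp)) {
      pf <- tryCatch(extract_posture_features(
        kp, walkway_length = config$walkway_length,
        conf_threshold = config$conf_threshold,
        keep_details = config$keep_details),
        error = function(e) e)
      if (inherits(pf, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          key = key, channel = "video", reason = conditionMessage(pf))
      } else {
        pf$side <- NULL
        row[names(pf)] <- pf
      }
    }
    res[[i]] <- row
  }
  all_cols <- unique(unlist(lapply(res, names)))
  feat <- as.data.frame(lapply(all_cols, function(cn) {
    vapply(res, function(r) if (is.null(r[[cn]])) NA_real_ else as.numeric(r[[cn]]),
           numeric(1))
  }), col.names = all_cols)
  out <- cbind(meta, feat)
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(key = character(), channel = character(), reason = character())
  out
}

.write_header_csv <- function(df, path, seed, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# gaitfuse %s", as.character(utils::packageVersion("gaitfuse"))),
               sprintf("# seed: %s", seed), extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Materialise a simulated cohort on disk
#'
#' Writes one accelerometer CSV and one OpenPose JSON frame directory per
#' recording, a metadata CSV, and a manifest JSON with the seed, the design
#' hash and per-recording paths.
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory.
#' @param seed overrides the design seed if not `NULL`.
#' @param channels passed to [simulate_cohort()].
#' @return invisibly, the manifest as a list.
#' @export
run_simulate <- function(design, out_dir, seed = NULL,
                         channels = "both") {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L) stop("I/O error: ", out_dir, " not writable")
  cohort <- simulate_cohort(design, channels = channels)
  meta <- cohort$metadata
  accel_paths <- character(0); video_dirs <- character(0)
  for (key in meta$key) {
    if (!is.null(cohort$recordings[[key]])) {
      p <- file.path(out_dir, "accel", paste0(key, ".csv"))
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      write_accelerometer_csv(cohort$recordings[[key]], p,
                              comment = c(key = key, seed = design$seed))
      accel_paths[key] <- p
    }
    if (!is.null(cohort$keypoints[[key]])) {
      d <- file.path(out_dir, "keypoints", key)
      write_openpose_json(cohort$keypoints[[key]], d)
      video_dirs[key] <- d
    }
  }
  .write_header_csv(meta, file.path(out_dir, "metadata.csv"), design$seed)
  design_json <- file.path(out_dir, "design.json")
  jsonlite::write_json(unclass(design), design_json, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    seed = design$seed,
    design_hash = unname(tools::md5sum(design_json)),
    n_recordings = length(accel_paths),
    n_keypoint_sequences = length(video_dirs),
    accel = as.list(accel_paths), video = as.list(video_dirs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Extract features from an on-disk dataset
#'
#' Reads the metadata CSV, accelerometer CSVs and keypoint directories under
#' `in_dir`, extracts sensor and posture features, and writes the features
#' CSV plus `exclusions.csv` (counts by stage and reason; failures never
#' abort the run).
#'
#' @param in_dir dataset directory produced by [run_simulate()].
#' @param out_csv path of the features CSV.
#' @param config a [run_config()].
#' @return invisibly, the features data frame.
#' @export
run_extract <- function(in_dir, out_csv, config = run_config()) {
  meta_path <- file.path(in_dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("design error: no metadata.csv in ", in_dir)
  meta <- utils::read.csv(meta_path, comment.char = "#")
  if (!nrow(meta)) stop("design error: empty dataset")
  cohort <- list(recordings = list(), keypoints = list(), metadata = meta)
  excl <- list()
  for (key in meta$key) {
    ap <- file.path(in_dir, "accel", paste0(key, ".csv"))
    if (file.exists(ap)) {
      r <- tryCatch(read_accelerometer_csv(ap), error = function(e) e)
      if (inherits(r, "error"))
        excl[[length(excl) + 1L]] <- data.frame(key = key, channel = "sensor",
                                                reason = conditionMessage(r))
      else cohort$recordings[[key]] <- r
    }
    vd <- file.path(in_dir, "keypoints", key)
    if (dir.exists(vd)) {
      s <- tryCatch(parse_openpose_json(vd), error = function(e) e)
      if (inherits(s, "error"))
        excl[[length(excl) + 1L]] <- data.frame(key = key, channel = "video",
                                                reason = conditionMessage(s))
      else cohort$keypoints[[key]] <- s
    }
  }
  class(cohort) <- "gait_cohort"
  feat <- extract_features_table(cohort, config)
  all_excl <- rbind(do.call(rbind, excl), attr(feat, "exclusions"))
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  .write_header_csv(feat, out_csv, config$seed)
  if (!is.null(all_excl) && nrow(all_excl))
    utils::write.csv(all_excl, file.path(dirname(out_csv), "exclusions.csv"),
                     row.names = FALSE)
  message(sprintf("extracted %d rows; %d exclusions", nrow(feat),
                  if (is.null(all_excl)) 0L else nrow(all_excl)))
  invisible(feat)
}

#' Compare groups from a features CSV
#'
#' Emits the comparison table, the demographics table and the headline
#' effect summary as CSVs plus a human-readable `report.txt`.
#'
#' @param features_csv features CSV from [run_extract()], or a features data
#'   frame.
#' @param out_dir report directory.
#' @param config a [run_config()].
#' @return invisibly, a list with `comparison`, `demographics`, `headline`.
#' @export
run_compare <- function(features_csv, out_dir, config = run_config()) {
  feat <- if (is.data.frame(features_csv)) features_csv else
    utils::read.csv(features_csv, comment.char = "#")
  need <- c("participant", "group", "task")
  missing_cols <- setdiff(need, names(feat))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  comparison <- compare_groups(feat)
  demo <- demographics_table(feat)
  headline <- tryCatch(headline_effects(comparison), error = function(e) NULL)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_header_csv(comparison, file.path(out_dir, "comparison.csv"), config$seed)
  .write_header_csv(demo, file.path(out_dir, "demographics.csv"), config$seed)
  if (!is.null(headline))
    .write_header_csv(headline, file.path(out_dir, "headline_effects.csv"),
                      config$seed)
  rpt <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(rpt))
  writeLines("Group comparison (Mann-Whitney U, repetitions averaged per participant)", rpt)
  for (task in unique(comparison$task)) {
    writeLines(sprintf("\n== task: %s ==", task), rpt)
    sub <- comparison[comparison$task == task, ]
    writeLines(sprintf("  %-24s control %6.2f (%.2f)  csvd %6.2f (%.2f)  U=%5.1f  p=%.4f",
                       sub$parameter, sub$control_mean, sub$control_sd,
                       sub$csvd_mean, sub$csvd_sd, sub$U, sub$p), rpt)
  }
  invisible(list(comparison = comparison, demographics = demo,
                 headline = headline))
}

#' Simulate, extract and compare in one call
#'
#' @param design a [cohort_design()]; default [calibrated_design()].
#' @param out_dir working directory for dataset, features and report.
#' @param config a [run_config()].
#' @param seed overrides the design seed.
#' @return invisibly, the [run_compare()] result.
#' @export
run_all <- function(design = calibrated_design(), out_dir,
                    config = run_config(), seed = NULL) {
  run_simulate(design, file.path(out_dir, "dataset"), seed = seed)
  feat <- run_extract(file.path(out_dir, "dataset"),
                      file.path(out_dir, "features.csv"), config)
  run_compare(feat, file.path(out_dir, "report"), config)
}
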