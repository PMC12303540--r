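# Sensor gait parameters from a waist accelerometer recording:
# step frequency, acceleration RMS, step variability (CV of step intervals),
# and autocorrelation-based step regularity and symmetry.

#' Resample an irregular recording onto a uniform grid
#'
#' Linear interpolation of each channel onto a uniform grid running from the
#' first to the last timestamp at `target_rate`; no extrapolation beyond the
#' recorded span. Linear interpolation is chosen deliberately: the phone's
#' irregular gaps are short, and higher-order schemes would invent curvature
#' between sparse samples.
#'
#' @param rec an `accel_recording` (see [simulate_accelerometer()]), or any
#'   list with `time` and `acc` (vector or matrix).
#' @param target_rate grid rate in Hz (default 100).
#' @return list of class `uniform_signal`: `rate`, `origin` (grid start in
#'   seconds), and `samples` (matrix, one column per channel).
#' @export
resample_uniform <- function(rec, target_rate = 100) {
  if (target_rate <= 0) stop("invalid parameter: target_rate must be > 0")
  t <- rec$time
  if (length(t) < 2L) stop("degenerate input: need at least 2 samples")
  if (any(diff(t) <= 0)) stop("format error: timestamps must be strictly increasing")
  acc <- rec$acc
  if (is.null(dim(acc))) acc <- matrix(acc, ncol = 1L)
  span <- t[length(t)] - t[1L]
  grid <- t[1L] + seq(0, floor(span * target_rate)) / target_rate
  samples <- apply(acc, 2L, function(ch) stats::approx(t, ch, xout = grid)$y)
  structure(list(rate = target_rate, origin = t[1L],
                 samples = matrix(samples, ncol = ncol(acc),
                                  dimnames = list(NULL, colnames(acc)))),
            class = "uniform_signal")
}

#' Extract the zero-mean vertical acceleration channel
#'
#' Selects the gravity-dominant channel (largest mean absolute value) as
#' vertical — for waist placement gravity guarantees this — and removes its
#' mean, leaving the dynamic vertical acceleration.
#'
#' @param sig a 3-channel `uniform_signal` from [resample_uniform()].
#' @return single-channel `uniform_signal` with attribute `axis` (selected
#'   column index).
#' @export
vertical_component <- function(sig) {
  x <- sig$samples
  scores <- apply(x, 2L, function(ch) mean(abs(ch)))
  if (all(scores < 1e-12)) stop("degenerate input: all channels are zero")
  axis <- which.max(scores)
  v <- x[, axis] - mean(x[, axis])
  out <- structure(list(rate = sig$rate, origin = sig$origin,
                        samples = matrix(v, ncol = 1L)),
                   class = "uniform_signal")
  attr(out, "axis") <- axis
  out
}

#' Root mean square of the dynamic vertical acceleration
#'
#' @param sig single-channel zero-mean `uniform_signal`.
#' @return RMS in m/s^2.
#' @export
acceleration_rms <- function(sig) {
  v <- as.numeric(sig$samples)
  if (!length(v)) stop("degenerate input: empty signal")
  sqrt(mean(v^2))
}

#' Detect step events in the vertical acceleration
#'
#' Low-pass filters the signal (4th-order Butterworth, 10 Hz cutoff, zero
#' phase) and returns the times of positive peaks with prominence at least
#' `prominence_frac` times the signal RMS, separated by at least
#' `min_separation` seconds. The constants bracket the physiological cadence
#' band (1-3 steps/s).
#'
#' @param sig single-channel zero-mean `uniform_signal`.
#' @param cutoff_hz low-pass cutoff, default 10.
#' @param min_separation refractory period in seconds, default 0.25.
#' @param prominence_frac prominence floor as a fraction of RMS, default 0.3.
#' @return numeric vector of event times (seconds), ordered.
#' @export
detect_steps <- function(sig, cutoff_hz = 10, min_separation = 0.25,
                         prominence_frac = 0.3) {
  v <- as.numeric(sig$samples)
  rate <- sig$rate
  bf <- signal::butter(4, min(0.99, cutoff_hz / (rate / 2)), type = "low")
  smooth <- as.numeric(signal::filtfilt(bf, v))
  prom <- prominence_frac * sqrt(mean(smooth^2))
  idx <- find_peaks(smooth, min_dist = max(1L, round(min_separation * rate)),
                    min_prominence = prom)
  # positive means a genuine upward excursion: the same floor applies to the
  # peak height, which rejects small bumps whose prominence comes from deep
  # neighbouring valleys rather than from the peak itself
  idx <- idx[smooth[idx] >= prom]
  if (length(idx) < 3L) stop("insufficient steps: fewer than 3 events detected")
  sig$origin + (idx - 1L) / rate
}

#' Step frequency and variability from event times
#'
#' Step frequency is the reciprocal mean step interval; step variability is
#' the coefficient of variation of the intervals (sample SD / mean), the
#' scale-free convention consistent with printed values around 0.1.
#'
#' @param events ordered step event times in seconds (>= 3).
#' @return list with `step_frequency` (Hz) and `step_variability` (unitless).
#' @export
temporal_features <- function(events) {
  if (length(events) < 3L) stop("insufficient steps: need >= 3 events")
  iv <- diff(events)
  if (any(iv <= 0)) stop("inconsistent events: non-positive interval")
  list(step_frequency = 1 / mean(iv),
       step_variability = stats::sd(iv) / mean(iv))
}

#' Unbiased normalized autocorrelation
#'
#' At lag k the autocovariance is the sum of products over the N - k
#' overlapping samples divided by (N - k), then normalized by the lag-0
#' variance, so the coefficient does not shrink with lag (the estimator of
#' choice for gait regularity from trunk acceleration).
#'
#' @param sig single-channel zero-mean `uniform_signal`.
#' @param max_lag maximum lag in seconds; must be below half the signal span.
#' @return list of class `gait_acf`: `lag` (seconds) and `coef` (r(0) = 1).
#' @export
autocorr_unbiased <- function(sig, max_lag) {
  v <- as.numeric(sig$samples)
  n <- length(v)
  if (max_lag >= (n - 1) / sig$rate / 2)
    stop("invalid parameter: max_lag must be below half the signal span")
  c0 <- sum(v * v) / n
  if (c0 < 1e-24) stop("degenerate input: zero-variance signal")
  kmax <- floor(max_lag * sig$rate)
  coef <- vapply(0:kmax, function(k) {
    m <- n - k
    (sum(v[seq_len(m)] * v[(k + 1):n]) / m) / c0
  }, numeric(1))
  structure(list(lag = (0:kmax) / sig$rate, coef = coef), class = "gait_acf")
}

#' Step regularity and symmetry from the autocorrelation
#'
#' The one-step coefficient Ad1 is the highest local autocorrelation maximum
#' with lag in \[0.5, 1.5\] x step period; the one-stride coefficient Ad2 is
#' the highest local maximum in \[0.5, 1.5\] x (2 x lag(Ad1)). Step
#' regularity is Ad1; step symmetry is min(Ad1, Ad2) / max(Ad1, Ad2),
#' clamped to \[0, 1\] when both coefficients are positive and 0 otherwise,
#' which guarantees the reported \[0, 1\] range.
#'
#' @param acf_obj a `gait_acf` from [autocorr_unbiased()].
#' @param step_period expected step period in seconds (e.g. from
#'   [temporal_features()]).
#' @param regularity_lag which autocorrelation peak defines regularity:
#'   `"step"` (Ad1, default), `"stride"` (Ad2) or `"mean"` of the two.
#' @return list with `step_regularity`, `step_symmetry`, and QC fields
#'   `ad1`, `ad2`, `lag_step`, `lag_stride` (seconds).
#' @export
regularity_symmetry <- function(acf_obj, step_period,
                                regularity_lag = c("step", "stride", "mean")) {
  regularity_lag <- match.arg(regularity_lag)
  pick <- function(lo, hi) {
    win <- which(acf_obj$lag >= lo & acf_obj$lag <= hi)
    if (length(win) < 3L) return(NULL)
    loc <- find_peaks(acf_obj$coef[win], min_dist = 1L, min_prominence = 0)
    if (!length(loc)) return(NULL)
    best <- win[loc[which.max(acf_obj$coef[win][loc])]]
    list(value = acf_obj$coef[best], lag = acf_obj$lag[best])
  }
  p1 <- pick(0.5 * step_period, 1.5 * step_period)
  if (is.null(p1)) stop("no periodicity: no local maximum in the one-step lag window")
  p2 <- pick(0.5 * 2 * p1$lag, 1.5 * 2 * p1$lag)
  if (is.null(p2)) stop("no periodicity: no local maximum in the one-stride lag window")
  ad1 <- p1$value; ad2 <- p2$value
  sym <- if (ad1 > 0 && ad2 > 0) min(1, min(ad1, ad2) / max(ad1, ad2)) else 0
  reg <- switch(regularity_lag, step = ad1, stride = ad2, mean = (ad1 + ad2) / 2)
  list(step_regularity = reg, step_symmetry = sym,
       ad1 = ad1, ad2 = ad2, lag_step = p1$lag, lag_stride = p2$lag)
}

#' Sensor gait parameters for one recording
#'
#' Full sensor chain: resample to a uniform grid (100 Hz), select and
#' mean-remove the vertical channel, then compute RMS, detect steps for
#' frequency and variability, and derive regularity and symmetry from the
#' unbiased autocorrelation.
#'
#' @param rec an `accel_recording`.
#' @param resample_rate uniform grid rate, Hz (default 100).
#' @param regularity_lag passed to [regularity_symmetry()].
#' @param cutoff_hz,min_separation,prominence_frac passed to [detect_steps()].
#' @return list of class `gait_features` with `step_frequency`, `rms`,
#'   `step_variability`, `step_regularity`, `step_symmetry`, and a `qc`
#'   record (step count, selected axis, Ad1/Ad2 and their lags).
#' @examples
#' rec <- simulate_accelerometer(gait_sim_params(seed = 1))
#' f <- extract_sensor_features(rec)
#' f$step_frequency
#' @export
extract_sensor_features <- function(rec, resample_rate = 100,
                                    regularity_lag = "step",
                                    cutoff_hz = 10, min_separation = 0.25,
                                    prominence_frac = 0.3) {
  span <- rec$time[length(rec$time)] - rec$time[1L]
  if (span < 10) stop("degenerate input: recording shorter than 10 s")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  uni <- stage("resample", resample_uniform(rec, resample_rate))
  vert <- stage("vertical", vertical_component(uni))
  rms <- stage("rms", acceleration_rms(vert))
  events <- stage("steps", detect_steps(vert, cutoff_hz = cutoff_hz,
                                        min_separation = min_separation,
                                        prominence_frac = prominence_frac))
  tf <- stage("temporal", temporal_features(events))
  period <- 1 / tf$step_frequency
  max_lag <- min(3.6 * period, 0.49 * span)
  acf_obj <- stage("autocorr", autocorr_unbiased(vert, max_lag))
  rs <- stage("regularity", regularity_symmetry(acf_obj, period,
                                                regularity_lag = regularity_lag))
  structure(list(
    step_frequency = tf$step_frequency,
    rms = rms,
    step_variability = tf$step_variability,
    step_regularity = rs$step_regularity,
    step_symmetry = rs$step_symmetry,
    qc = list(n_steps = length(events), axis = attr(vert, "axis"),
              ad1 = rs$ad1, ad2 = rs$ad2,
              lag_step = rs$lag_step, lag_stride = rs$lag_stride)
  ), class = "gait_features")
}

#' @export
print.gait_features <- function(x, ...) {
  cat(sprintf(paste0("<gait_features> f=%.2f steps/s  rms=%.2f m/s^2  ",
                     "variability=%.3f  regularity=%.2f  symmetry=%.2f\n"),
              x$step_frequency, x$rms, x$step_variability,
              x$step_regularity, x$step_symmetry))
  invisible(x)
}
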