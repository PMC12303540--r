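# Daubechies-4 discrete wavelet transform and soft-threshold denoising.
#
# The decomposition uses symmetric (half-sample) boundary extension, so each
# band keeps floor((n + L - 1)/2) coefficients (L = 8 taps); this slight
# redundancy is what makes the reconstruction exact at the boundaries.

# db4 analysis filters (8 taps, orthonormal; sum(lo) = sqrt(2)).
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)

.conv_full <- function(x, f) {
  n <- length(x)
  out <- numeric(n + length(f) - 1L)
  for (j in seq_along(f)) {
    idx <- j:(j + n - 1L)
    out[idx] <- out[idx] + f[j] * x
  }
  out
}

.dwt_step <- function(x) {
  L <- 8L
  n <- length(x)
  xe <- c(rev(x[seq_len(L - 1L)]), x, rev(x[(n - L + 2L):n]))
  va <- .conv_full(xe, .db4_dec_lo)[L:length(xe)]
  vd <- .conv_full(xe, .db4_dec_hi)[L:length(xe)]
  keep <- seq(2L, length(va), by = 2L)
  list(a = va[keep], d = vd[keep])
}

.idwt_step <- function(a, d, n_out) {
  L <- 8L
  upsample <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, length(u), by = 2L)] <- cf
    u
  }
  s <- .conv_full(upsample(a), rev(.db4_dec_lo)) +
       .conv_full(upsample(d), rev(.db4_dec_hi))
  s[(L - 2L) + seq_len(n_out)]
}

#' Multi-level db4 wavelet decomposition
#'
#' Decomposes a numeric series into one approximation band and `levels`
#' detail bands with the 8-tap Daubechies-4 filter and symmetric boundary
#' extension.
#'
#' @param x numeric vector, length at least 16.
#' @param levels number of decomposition levels (default 3).
#' @return list with `approx` (coarsest approximation), `details` (list of
#'   detail coefficient vectors, finest first) and `lengths` (per-level input
#'   lengths, needed for exact reconstruction).
#' @seealso [wavelet_reconstruct()], [wavelet_denoise()]
#' @export
wavelet_decompose <- function(x, levels = 3L) {
  if (!is.numeric(x) || length(x) < 16L)
    stop("wavelet_decompose: need a numeric series of length >= 16")
  if (anyNA(x)) stop("wavelet_decompose: series contains NA")
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- as.numeric(x)
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(a)
    st <- .dwt_step(a)
    details[[lev]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, lengths = lengths)
}

#' Reconstruct a series from a db4 decomposition
#'
#' Inverse of [wavelet_decompose()]; with untouched coefficients the round
#' trip is exact to floating-point precision.
#'
#' @param dec decomposition as returned by [wavelet_decompose()].
#' @return numeric vector with the original length.
#' @export
wavelet_reconstruct <- function(dec) {
  a <- dec$approx
  for (lev in rev(seq_along(dec$details))) {
    a <- .idwt_step(a, dec$details[[lev]], dec$lengths[lev])
  }
  a
}

#' Wavelet denoising of an angle or acceleration time series
#'
#' Three-level Daubechies-4 decomposition; the detail coefficients are
#' soft-thresholded with the universal threshold sigma * sqrt(2 log N), where
#' sigma is the robust noise estimate MAD(finest details) / 0.6745, and the
#' series is reconstructed to its original length. Series shorter than 16
#' samples (too short to support three db4 levels) are returned unchanged
#' with a warning.
#'
#' @param x numeric series (e.g. a joint-angle trajectory in degrees).
#' @param levels decomposition depth, default 3.
#' @param keep_details if `FALSE`, detail bands are dropped entirely
#'   (approximation-only reconstruction) instead of thresholded.
#' @return denoised numeric series, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1/60)
#' noisy <- sin(2 * pi * t) + rnorm(length(t), sd = 0.2)
#' smooth <- wavelet_denoise(noisy)
#' @export
wavelet_denoise <- function(x, levels = 3L, keep_details = TRUE) {
  if (length(x) < 16L) {
    warning("series too short for 3-level db4 denoising; returned unchanged")
    return(x)
  }
  dec <- wavelet_decompose(x, levels = levels)
  if (keep_details) {
    sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
    soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
    dec$details <- lapply(dec$details, soft)
  } else {
    dec$details <- lapply(dec$details, function(d) numeric(length(d)))
  }
  wavelet_reconstruct(dec)
}
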