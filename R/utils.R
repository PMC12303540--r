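# Shared geometry and signal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' Interior angle at a joint
#'
#' Angle at vertex `b` between the rays b->a and b->c, in degrees, always in
#' \[0, 180\]. Invariant to translation, uniform scaling and in-plane rotation
#' of all three points.
#'
#' @param a,b,c numeric length-2 vectors (x, y), or n x 2 matrices for a
#'   vectorised call over frames.
#' @return angle(s) in degrees in \[0, 180\].
#' @examples
#' joint_angle(c(0, 0), c(1, 0), c(2, 0))  # collinear: 180
#' joint_angle(c(0, 0), c(0, 1), c(1, 1))  # right angle: 90
#' @export
joint_angle <- function(a, b, c) {
  a <- rbind(a); b <- rbind(b); c <- rbind(c)
  u <- a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
  v <- c - b[rep_len(seq_len(nrow(b)), nrow(c)), , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-12) || any(nv < 1e-12))
    stop("joint_angle: coincident points give a degenerate geometry")
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  out <- .deg(acos(cosang))
  if (length(out) == 1L) out[[1L]] else out
}

#' Angle of a segment against a reference direction
#'
#' Angle in degrees, in \[0, 180\], between the directed segment p->q and a
#' reference direction: `"vertical"` is up in world coordinates (callers must
#' flip the image y-axis first) and `"horizontal"` is the direction of
#' travel, supplied through `travel_sign` as +1 (towards +x) or -1.
#'
#' @param p,q numeric length-2 vectors or n x 2 matrices (world coordinates,
#'   y up).
#' @param reference `"vertical"` or `"horizontal"`.
#' @param travel_sign +1 or -1; only used for the horizontal reference.
#' @return angle(s) in degrees in \[0, 180\].
#' @export
segment_reference_angle <- function(p, q, reference = c("vertical", "horizontal"),
                                    travel_sign = 1) {
  reference <- match.arg(reference)
  p <- rbind(p); q <- rbind(q)
  v <- q - p
  nv <- sqrt(rowSums(v^2))
  if (any(nv < 1e-12))
    stop("segment_reference_angle: coincident points")
  ref <- if (reference == "vertical") c(0, 1) else c(sign(travel_sign), 0)
  cosang <- pmin(1, pmax(-1, (v[, 1] * ref[1] + v[, 2] * ref[2]) / nv))
  out <- .deg(acos(cosang))
  if (length(out) == 1L) out[[1L]] else out
}

# Local maxima with a prominence floor and a refractory distance.
# Prominence of a peak: height above the higher of the two deepest valleys
# separating it from taller terrain (or the series ends).
find_peaks <- function(x, min_dist = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1L) x[1:(i - 1L)] else h
    higher_l <- which(left > h)
    lmin <- min(left[if (length(higher_l)) (max(higher_l) + 1L):(i - 1L) else seq_along(left)])
    right <- if (i < n) x[(i + 1L):n] else h
    higher_r <- which(right > h)
    rmin <- min(right[if (length(higher_r)) seq_len(min(higher_r) - 1L) else seq_along(right)])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce minimum separation, favouring taller peaks
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  }
  sort(sel)
}

# Deterministic child seed derived from a base seed and a label; kept well
# below 2^31.
derive_seed <- function(seed, ...) {
  lbl <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lbl)) h <- (h * 31 + ch) %% 2147480009
  as.integer(h)
}
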