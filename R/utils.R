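#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish geometry/validation errors
# from segmentation failures (which carry qc_flags and trigger the manual
# override path).
abort_cornoct <- function(message, class, ...) {
  stop(structure(
    class = c(class, "cornoct_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    abort_cornoct(sprintf("`%s` must be a single finite number", name),
                  "cornoct_validation_error")
  }
  if (positive && x <= 0) {
    abort_cornoct(sprintf("`%s` must be > 0", name),
                  "cornoct_validation_error")
  }
  invisible(x)
}

# Centered moving average with edge truncation (window shrinks at borders,
# so the filter stays symmetric and location-preserving in the interior).
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- floor(width / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smooth a depth x lateral raster with separable uniform kernels.
smooth_raster <- function(pixels, axial_width = 3L, lateral_width = 5L) {
  out <- pixels
  if (axial_width > 1L) {
    out <- apply(out, 2L, moving_average, width = axial_width)
  }
  if (lateral_width > 1L) {
    out <- t(apply(out, 1L, moving_average, width = lateral_width))
  }
  out
}

# Indices of strict local maxima of a vector (plateaus take the first index).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  # treat exact plateaus as rising through
  d[d == 0] <- .Machine$double.eps
  which(diff(sign(d)) < 0) + 1L
}

# Topographic prominence of each peak: height above the highest of the two
# key saddles separating the peak from higher ground (or from the signal
# border). O(n * n_peaks), fine for single profiles.
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    right <- if (p < length(y)) y[(p + 1L):length(y)] else numeric(0)
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    sad_l <- if (length(higher_l)) min(left[(max(higher_l)):(p - 1L)]) else
      if (length(left)) min(left) else h
    sad_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else
      if (length(right)) min(right) else h
    h - max(sad_l, sad_r)
  }, numeric(1))
}

# Sub-pixel peak localization: parabola through (p-1, p, p+1).
# Returns the (1-based) fractional index of the vertex.
parabolic_refine <- function(y, p) {
  if (p <= 1L || p >= length(y)) return(as.numeric(p))
  y0 <- y[p - 1L]; y1 <- y[p]; y2 <- y[p + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0) return(as.numeric(p))   # not a concave vertex
  p + 0.5 * (y0 - y2) / denom
}

# Sample SD with n-1 denominator (explicit so the repeatability formulas
# read exactly as defined).
sample_sd <- function(x) stats::sd(x)
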