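# Shared fixtures: a reduced raster with the instrument's native pixel
# pitches (so all physical-unit logic is identical) but fewer pixels, to
# keep unit tests fast. 512 columns still fit the 128-column exclusion
# plus the two 0.5-mm flanking regions.
small_geom <- function(depth_px = 700L, width_px = 512L) {
  optical_geometry(
    depth_px = depth_px, width_px = width_px,
    depth_extent_mm = 2.01 * depth_px / 1365,
    width_extent_mm = 8.41 * width_px / 2048)
}

post_truth <- function(...) {
  args <- utils::modifyList(
    list(epi_um = 54, bowman_um = 18, flap_um = 106, total_um = 443,
         apex_depth_um = 120), list(...))
  do.call(cornea_truth, args)
}

pre_truth <- function(...) {
  args <- utils::modifyList(
    list(epi_um = 53.1, bowman_um = 17, total_um = 525.8,
         apex_depth_um = 120), list(...))
  do.call(cornea_truth, args)
}

# Independent sub-pixel peak oracle: brute-force argmax plus the closed
# form parabola vertex through the three samples around it. Written out
# here so tests do not depend on the package's own refinement code path.
oracle_peak <- function(y) {
  p <- which.max(y)
  if (p <= 1L || p >= length(y)) return(as.numeric(p))
  a <- y[p - 1L]; b <- y[p]; c2 <- y[p + 1L]
  p + 0.5 * (a - c2) / (a - 2 * b + c2)
}

# Brute-force ridge position of interface `k` in a noiseless raster:
# restrict the column to a window around the true depth, then oracle_peak.
oracle_ridge <- function(pixels, truth_depth, halfwin = 8L) {
  vapply(seq_along(truth_depth), function(j) {
    d <- truth_depth[j]
    if (is.na(d)) return(NA_real_)
    rows <- max(1L, floor(d) - halfwin):min(nrow(pixels), ceiling(d) + halfwin)
    rows[1L] - 1L + oracle_peak(pixels[rows, j])
  }, numeric(1))
}

# A bare axial profile of Gaussian peaks at given sub-pixel depths.
gaussian_profile <- function(depths, amps, n, sigma = 1.5) {
  z <- seq_len(n)
  y <- rowSums(vapply(seq_along(depths), function(i) {
    amps[i] * exp(-((z - depths[i])^2) / (2 * sigma^2))
  }, numeric(n)))
  structure(list(depth = z, reflectivity = y, ref_row = round(depths[1]),
                 offsets = integer(0), provenance = "synthetic"),
            class = "axial_profile")
}

# Truth-only cohort thicknesses as a ready cohort_record. Rare ordering
# resamples are expected in Monte-Carlo loops and not of interest there.
truth_cohort <- function(design) {
  tr <- suppressWarnings(generate_cohort(design, render = FALSE)$truth)
  class(tr) <- c("cohort_record", "data.frame")
  tr
}
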