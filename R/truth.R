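#' Ground-truth description of a simulated cornea
#'
#' Holds the geometric layer structure from which a synthetic B-scan is
#' rendered: anterior curvature, apex position, sublayer thicknesses
#' (geometric um), an optional sinusoidal microdistortion of the Bowman's
#' layer boundaries (the fine wrinkling seen after flap repositioning), and
#' per-interface peak reflectivities.
#'
#' Thicknesses are geometric; the renderer converts them to optical path
#' using the geometry's group index. `flap_um` is the depth of the flap
#' interface below the anterior surface (i.e. the flap thickness); set it to
#' `NA` for a pre-operative cornea, which then has four interfaces instead
#' of five.
#'
#' @param epi_um,bowman_um epithelium and Bowman's layer thicknesses, um.
#' @param total_um total corneal thickness (anterior surface to
#'   endothelium-aqueous interface), um.
#' @param flap_um flap interface depth below the surface, um, or `NA`
#'   (pre-operative).
#' @param anterior_radius_mm anterior surface curvature radius, mm
#'   (`Inf` = flat).
#' @param apex_depth_um optical depth of the corneal apex below the image
#'   top, um.
#' @param apex_offset_px lateral shift of the apex from the image centre,
#'   px (positive = rightward).
#' @param microdistortion_amp_um,microdistortion_period_um amplitude and
#'   lateral period of the sinusoidal perturbation applied to the
#'   epithelium-Bowman's, Bowman's-stroma and flap boundaries; amplitude 0
#'   disables it.
#' @param interface_reflectivities named numeric vector of peak amplitudes
#'   for `air_epi`, `epi_bowman`, `bowman_stroma`, `flap`, `endo_aqueous`.
#'
#' @return An object of class `cornea_truth`.
#' @examples
#' cornea_truth(epi_um = 53.1, bowman_um = 17.0, total_um = 525.8)
#' @export
cornea_truth <- function(epi_um = 53.1, bowman_um = 17.0, total_um = 525.8,
                         flap_um = NA_real_,
                         anterior_radius_mm = 7.8, apex_depth_um = 200,
                         apex_offset_px = 0,
                         microdistortion_amp_um = 0,
                         microdistortion_period_um = 400,
                         interface_reflectivities = c(
                           air_epi = 1.0, epi_bowman = 0.50,
                           bowman_stroma = 0.55, flap = 0.45,
                           endo_aqueous = 0.70)) {
  stopifnot_scalar(epi_um, "epi_um", positive = TRUE)
  stopifnot_scalar(bowman_um, "bowman_um", positive = TRUE)
  stopifnot_scalar(total_um, "total_um", positive = TRUE)
  stopifnot_scalar(apex_depth_um, "apex_depth_um")
  stopifnot_scalar(apex_offset_px, "apex_offset_px")
  stopifnot_scalar(microdistortion_amp_um, "microdistortion_amp_um")
  stopifnot_scalar(microdistortion_period_um, "microdistortion_period_um",
                   positive = TRUE)
  if (microdistortion_amp_um < 0) {
    abort_cornoct("microdistortion amplitude must be >= 0",
                  "cornoct_validation_error")
  }
  if (!is_scalar_number(anterior_radius_mm) && !identical(anterior_radius_mm, Inf)) {
    abort_cornoct("`anterior_radius_mm` must be a positive number or Inf",
                  "cornoct_validation_error")
  }
  if (anterior_radius_mm <= 0) {
    abort_cornoct("`anterior_radius_mm` must be > 0", "cornoct_validation_error")
  }
  has_flap <- !is.na(flap_um)
  if (has_flap) {
    stopifnot_scalar(flap_um, "flap_um", positive = TRUE)
    if (!(epi_um + bowman_um < flap_um && flap_um < total_um)) {
      abort_cornoct(
        "layer ordering violated: need epi + bowman < flap depth < total",
        "cornoct_validation_error")
    }
  } else if (epi_um + bowman_um >= total_um) {
    abort_cornoct("epi + bowman must be < total thickness",
                  "cornoct_validation_error")
  }
  required <- c("air_epi", "epi_bowman", "bowman_stroma", "flap", "endo_aqueous")
  if (!all(required %in% names(interface_reflectivities))) {
    abort_cornoct("interface_reflectivities must name all five interfaces",
                  "cornoct_validation_error")
  }
  structure(
    list(epi_um = epi_um, bowman_um = bowman_um, total_um = total_um,
         flap_um = flap_um,
         anterior_radius_mm = anterior_radius_mm,
         apex_depth_um = apex_depth_um, apex_offset_px = apex_offset_px,
         microdistortion_amp_um = microdistortion_amp_um,
         microdistortion_period_um = microdistortion_period_um,
         interface_reflectivities = interface_reflectivities),
    class = "cornea_truth"
  )
}

# Names of the interfaces present for a given truth, in depth order.
truth_interfaces <- function(truth) {
  if (is.na(truth$flap_um)) {
    c("air_epi", "epi_bowman", "bowman_stroma", "endo_aqueous")
  } else {
    c("air_epi", "epi_bowman", "bowman_stroma", "flap", "endo_aqueous")
  }
}

#' Per-column interface depths implied by a cornea truth
#'
#' Evaluates the exact sub-pixel row coordinate of every interface at every
#' lateral column, after anterior curvature and microdistortion. Depths are
#' 1-based optical-path pixel coordinates; columns whose anterior sag falls
#' outside the lateral footprint of the curvature radius are `NA`.
#'
#' @param truth a [cornea_truth()] object.
#' @param geometry an [optical_geometry()] object.
#' @return A numeric matrix with one row per interface (named) and
#'   `geometry$width_px` columns.
#' @export
truth_interface_depths <- function(truth, geometry) {
  w <- geometry$width_px
  cols <- seq_len(w)
  centre <- (w + 1) / 2 + truth$apex_offset_px
  x_um <- (cols - centre) * lateral_pitch_um(geometry)
  if (is.finite(truth$anterior_radius_mm)) {
    r_um <- truth$anterior_radius_mm * 1000
    sag_um <- ifelse(abs(x_um) < r_um, r_um - sqrt(r_um^2 - x_um^2), NA_real_)
  } else {
    sag_um <- rep(0, w)
  }
  pitch <- axial_pitch_um(geometry)
  # above the cornea is air (n = 1): the anterior sag maps 1:1 into
  # optical-path pixels
  z_ant <- 1 + (truth$apex_depth_um + sag_um) / pitch

  wiggle <- if (truth$microdistortion_amp_um > 0) {
    geom_um_to_px(truth$microdistortion_amp_um, geometry) *
      sin(2 * pi * (cols - centre) * lateral_pitch_um(geometry) /
            truth$microdistortion_period_um)
  } else 0

  ifc <- truth_interfaces(truth)
  depths <- matrix(NA_real_, nrow = length(ifc), ncol = w,
                   dimnames = list(ifc, NULL))
  depths["air_epi", ] <- z_ant
  depths["epi_bowman", ] <- z_ant + geom_um_to_px(truth$epi_um, geometry) + wiggle
  depths["bowman_stroma", ] <- z_ant +
    geom_um_to_px(truth$epi_um + truth$bowman_um, geometry) + wiggle
  if ("flap" %in% ifc) {
    depths["flap", ] <- z_ant + geom_um_to_px(truth$flap_um, geometry) + wiggle
  }
  depths["endo_aqueous", ] <- z_ant + geom_um_to_px(truth$total_um, geometry)
  depths
}

#' @export
print.cornea_truth <- function(x, ...) {
  cat(sprintf(
    "<cornea_truth> epi %.1f um, Bowman %.1f um, flap %s, total %.1f um, R %.1f mm\n",
    x$epi_um, x$bowman_um,
    if (is.na(x$flap_um)) "absent (pre-op)" else sprintf("%.1f um", x$flap_um),
    x$total_um, x$anterior_radius_mm))
  invisible(x)
}
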