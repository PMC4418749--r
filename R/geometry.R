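#' Optical geometry of a UHR-OCT B-scan
#'
#' Describes the raster of an ultra-high-resolution anterior-segment OCT
#' instrument: the depth axis stores *optical path length* (geometric
#' distance times the tissue group index), and geometric thicknesses are
#' recovered by dividing optical distances by `group_index`.
#'
#' The defaults reproduce a spectral-domain instrument with 1365 depth
#' pixels covering 2.01 mm, 2048 lateral pixels covering 8.41 mm, an axial
#' point-spread FWHM of 3 um in tissue, and the corneal group index 1.376.
#'
#' @param depth_px,width_px integer raster dimensions (depth x lateral).
#' @param depth_extent_mm,width_extent_mm physical spans of the two axes, mm.
#' @param axial_psf_fwhm_um axial point-spread-function FWHM, um (optical).
#' @param group_index dimensionless refractive (group) index used to convert
#'   optical path to geometric thickness.
#'
#' @return An object of class `optical_geometry`.
#' @examples
#' g <- optical_geometry()
#' axial_pitch_um(g)    # ~1.4725 um (optical) per pixel
#' lateral_pitch_um(g)  # ~4.106 um per pixel
#' @export
optical_geometry <- function(depth_px = 1365L, width_px = 2048L,
                             depth_extent_mm = 2.01, width_extent_mm = 8.41,
                             axial_psf_fwhm_um = 3.0, group_index = 1.376) {
  depth_px <- as.integer(depth_px)
  width_px <- as.integer(width_px)
  if (depth_px <= 0L || width_px <= 0L) {
    abort_cornoct("raster dimensions must be positive", "cornoct_geometry_error")
  }
  stopifnot_scalar(depth_extent_mm, "depth_extent_mm", positive = TRUE)
  stopifnot_scalar(width_extent_mm, "width_extent_mm", positive = TRUE)
  stopifnot_scalar(axial_psf_fwhm_um, "axial_psf_fwhm_um", positive = TRUE)
  stopifnot_scalar(group_index, "group_index", positive = TRUE)
  structure(
    list(depth_px = depth_px, width_px = width_px,
         depth_extent_mm = depth_extent_mm, width_extent_mm = width_extent_mm,
         axial_psf_fwhm_um = axial_psf_fwhm_um, group_index = group_index),
    class = "optical_geometry"
  )
}

#' @rdname optical_geometry
#' @param geometry an `optical_geometry` object.
#' @export
axial_pitch_um <- function(geometry) {
  geometry$depth_extent_mm * 1000 / geometry$depth_px
}

#' @rdname optical_geometry
#' @export
lateral_pitch_um <- function(geometry) {
  geometry$width_extent_mm * 1000 / geometry$width_px
}

# geometric um -> optical px and back
geom_um_to_px <- function(um, geometry) {
  um * geometry$group_index / axial_pitch_um(geometry)
}
px_to_geom_um <- function(px, geometry) {
  px * axial_pitch_um(geometry) / geometry$group_index
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat(sprintf(
    "<optical_geometry> %d x %d px (%.2f x %.2f mm), axial PSF %.1f um, n = %.3f\n",
    x$depth_px, x$width_px, x$depth_extent_mm, x$width_extent_mm,
    x$axial_psf_fwhm_um, x$group_index))
  invisible(x)
}
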