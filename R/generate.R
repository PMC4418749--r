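#' Render a synthetic UHR-OCT B-scan from a cornea truth
#'
#' Each interface becomes a curved ridge whose axial cross-section is a
#' Gaussian with the geometry's PSF FWHM; a weak bulk backscatter fills the
#' stroma; optional artifacts emulate the instrument's central specular
#' reflex (a saturated vertical band at the apex) and horizontal artifact
#' lines; speckle is modelled as multiplicative exponential noise on the
#' noiseless image plus a small additive Gaussian background.
#'
#' The spatial extent of the analysis — the central exclusion window plus
#' the two 0.5-mm flanking regions — must fit inside the raster; interfaces
#' that leave the raster in the lateral periphery (inevitable for a curved
#' cornea over a wide scan) are clipped, as in real instrument images, and
#' the returned truth still records their unclipped depths.
#'
#' @param truth a [cornea_truth()].
#' @param geometry an [optical_geometry()].
#' @param noise_level dimensionless in `[0, 1]`: 0 = noiseless, 1 = fully
#'   developed speckle.
#' @param artifact_flags character subset of `c("reflex", "hbands")`.
#' @param seed integer; set for a reproducible raster (`NULL` leaves the RNG
#'   state alone).
#' @param meta named list of acquisition metadata (subject, group, visit,
#'   scan_rep, ...) stored with the image.
#'
#' @return A list with elements `image` (a `bscan_image`: `pixels`,
#'   `geometry`, `meta`) and `truth` (the input `cornea_truth` with an added
#'   `interface_depths_px` matrix of exact per-column depths).
#' @examples
#' g <- optical_geometry(depth_px = 700, width_px = 512,
#'                       depth_extent_mm = 2.01 * 700 / 1365,
#'                       width_extent_mm = 8.41 * 512 / 2048)
#' b <- generate_bscan(cornea_truth(), g, noise_level = 0, seed = 1)
#' dim(b$image$pixels)
#' @export
generate_bscan <- function(truth, geometry = optical_geometry(),
                           noise_level = 1.0,
                           artifact_flags = character(0),
                           seed = NULL, meta = list()) {
  if (!inherits(truth, "cornea_truth")) {
    abort_cornoct("`truth` must be a cornea_truth", "cornoct_validation_error")
  }
  if (!inherits(geometry, "optical_geometry")) {
    abort_cornoct("`geometry` must be an optical_geometry",
                  "cornoct_validation_error")
  }
  stopifnot_scalar(noise_level, "noise_level")
  if (noise_level < 0 || noise_level > 1) {
    abort_cornoct("`noise_level` must lie in [0, 1]", "cornoct_validation_error")
  }
  bad <- setdiff(artifact_flags, c("reflex", "hbands"))
  if (length(bad)) {
    abort_cornoct(paste0("unknown artifact flags: ", paste(bad, collapse = ", ")),
                  "cornoct_validation_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  d_px <- geometry$depth_px
  w_px <- geometry$width_px
  depths <- truth_interface_depths(truth, geometry)

  # the central analysis span (exclusion + two 0.5-mm flanks) must fit
  span_half <- 64L + region_width_cols(geometry)
  centre <- round((w_px + 1) / 2 + truth$apex_offset_px)
  span_cols <- max(1L, centre - span_half):min(w_px, centre + span_half - 1L)
  span_depths <- depths[, span_cols, drop = FALSE]
  if (anyNA(span_depths) ||
      max(span_depths) > d_px - 2 || min(span_depths) < 2) {
    abort_cornoct(
      "interfaces fall outside the raster within the central analysis span",
      "cornoct_geometry_error")
  }

  refl <- truth$interface_reflectivities
  sigma_px <- (geometry$axial_psf_fwhm_um / axial_pitch_um(geometry)) / 2.3548
  half_win <- max(3L, ceiling(6 * sigma_px))

  img <- matrix(0, nrow = d_px, ncol = w_px)
  for (ifc in rownames(depths)) {
    d <- depths[ifc, ]
    ok_cols <- which(!is.na(d))
    if (!length(ok_cols)) next
    base <- floor(d[ok_cols])
    amp <- refl[[ifc]]
    for (k in (-half_win):half_win) {
      rows <- base + k
      keep <- rows >= 1L & rows <= d_px
      if (!any(keep)) next
      idx <- cbind(rows[keep], ok_cols[keep])
      img[idx] <- img[idx] +
        amp * exp(-((rows[keep] - d[ok_cols][keep])^2) / (2 * sigma_px^2))
    }
  }

  # bulk stromal backscatter between anterior surface and endothelium
  z <- matrix(seq_len(d_px), nrow = d_px, ncol = w_px)
  za <- matrix(depths["air_epi", ], nrow = d_px, ncol = w_px, byrow = TRUE)
  ze <- matrix(depths["endo_aqueous", ], nrow = d_px, ncol = w_px, byrow = TRUE)
  inside <- !is.na(za) & !is.na(ze) & z > za & z < ze
  img[inside] <- img[inside] + 0.04 * max(refl)

  if ("reflex" %in% artifact_flags) {
    # saturated vertical band centred on the apex, Gaussian lateral taper
    rc <- centre
    cols <- max(1L, rc - 20L):min(w_px, rc + 20L)
    taper <- exp(-((cols - rc)^2) / (2 * 6^2))
    z_top <- 1L
    z_bot <- min(d_px, ceiling(max(depths["endo_aqueous", cols], na.rm = TRUE)) + 30L)
    img[z_top:z_bot, cols] <- img[z_top:z_bot, cols] +
      3 * max(refl) * matrix(taper, nrow = z_bot - z_top + 1L,
                             ncol = length(cols), byrow = TRUE)
  }
  if ("hbands" %in% artifact_flags) {
    n_bands <- 3L
    band_rows <- sort(sample.int(d_px - 1L, n_bands))
    for (r in band_rows) {
      img[r:(r + 1L), ] <- img[r:(r + 1L), ] + 0.35 * max(refl)
    }
  }

  if (noise_level > 0) {
    n <- length(img)
    speckle <- (1 - noise_level) + noise_level * stats::rexp(n)
    img <- img * speckle +
      abs(stats::rnorm(n, 0, 0.01 * max(refl) * noise_level))
  }
  img[img < 0] <- 0

  meta <- utils::modifyList(
    list(subject = NA_character_, group = NA_character_,
         visit = NA_character_, scan_rep = NA_integer_, seed = seed),
    meta)
  truth$interface_depths_px <- depths
  list(
    image = structure(list(pixels = img, geometry = geometry, meta = meta),
                      class = "bscan_image"),
    truth = truth
  )
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("<bscan_image> %d x %d px, subject %s, visit %s, scan %s\n",
              nrow(x$pixels), ncol(x$pixels),
              x$meta$subject, x$meta$visit, x$meta$scan_rep))
  invisible(x)
}

#' Write / read a B-scan as 16-bit grayscale TIFF (or PNG) plus JSON sidecar
#'
#' Intensities are normalised by the image maximum before quantisation; the
#' scale, the acquisition metadata, the truth thicknesses and the exact
#' per-column interface depths are stored in the JSON sidecar so the image
#' round-trips with its ground truth.
#'
#' @param bscan the list returned by [generate_bscan()] (`image` + `truth`),
#'   or a bare `bscan_image` (then no truth is written).
#' @param image_path output path ending in `.tif`/`.tiff` or `.png`.
#' @param truth_path output path for the JSON sidecar (`NULL` to skip).
#' @return `image_path`, invisibly.
#' @export
write_bscan <- function(bscan, image_path, truth_path = NULL) {
  image <- if (inherits(bscan, "bscan_image")) bscan else bscan$image
  truth <- if (inherits(bscan, "bscan_image")) NULL else bscan$truth
  px <- image$pixels
  scale <- max(px, 1e-12)
  norm <- pmin(px / scale, 1)
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, image_path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(norm, image_path)
  } else {
    abort_cornoct("image_path must end in .tif/.tiff/.png",
                  "cornoct_validation_error")
  }
  if (!is.null(truth_path)) {
    side <- list(
      scale = scale,
      geometry = unclass(image$geometry),
      meta = image$meta
    )
    if (!is.null(truth)) {
      side$truth_um <- list(
        epi_um = truth$epi_um, bowman_um = truth$bowman_um,
        flap_um = truth$flap_um, total_um = truth$total_um)
      side$interface_depths_px <- apply(truth$interface_depths_px, 1L,
                                        identity, simplify = FALSE)
    }
    jsonlite::write_json(side, truth_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(image_path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(image_path, truth_path = NULL) {
  ext <- tolower(tools::file_ext(image_path))
  norm <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(image_path)
  } else if (ext == "png") {
    png::readPNG(image_path)
  } else {
    abort_cornoct("image_path must end in .tif/.tiff/.png",
                  "cornoct_validation_error")
  }
  scale <- 1
  geometry <- NULL
  meta <- list()
  truth_um <- NULL
  depths <- NULL
  if (!is.null(truth_path)) {
    side <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    scale <- side$scale
    g <- side$geometry
    geometry <- optical_geometry(g$depth_px, g$width_px, g$depth_extent_mm,
                                 g$width_extent_mm, g$axial_psf_fwhm_um,
                                 g$group_index)
    meta <- side$meta
    truth_um <- side$truth_um
    if (!is.null(side$interface_depths_px)) {
      depths <- do.call(rbind, side$interface_depths_px)
    }
  }
  if (is.null(geometry)) {
    geometry <- optical_geometry(depth_px = nrow(norm), width_px = ncol(norm))
  }
  structure(
    list(pixels = norm * scale, geometry = geometry, meta = meta,
         truth_um = truth_um, interface_depths_px = depths),
    class = "bscan_image")
}
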