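#' Segmentation tuning parameters
#'
#' @param axial_smooth,lateral_smooth uniform denoising window widths (px)
#'   applied to the raster before profile building.
#' @param profile_smooth window width (px) applied to the averaged axial
#'   profile before peak detection.
#' @param prominence_factor peak prominence floor, in multiples of the
#'   robust noise SD of the profile tail.
#' @param windows_um plausibility windows (geometric um) constraining the
#'   peak-ordered interface assignment: `epithelium` and `bowman` are
#'   measured from the previous interface, `flap` and `total` from the
#'   anterior surface.
#' @param artifact_margin_px axial margin (px) around the corneal band kept
#'   out of the row-baseline estimate.
#' @param reflex_energy_factor a specular reflex is declared when the
#'   maximal column energy exceeds this multiple of the median column
#'   energy.
#' @return A named list of parameters.
#' @export
segmentation_params <- function(axial_smooth = 3L, lateral_smooth = 5L,
                                profile_smooth = 3L, prominence_factor = 3,
                                windows_um = list(
                                  epithelium = c(35, 75),
                                  bowman = c(8, 30),
                                  flap = c(70, 140),
                                  total = c(350, 700)),
                                artifact_margin_px = 10L,
                                reflex_energy_factor = 3) {
  list(axial_smooth = axial_smooth, lateral_smooth = lateral_smooth,
       profile_smooth = profile_smooth, prominence_factor = prominence_factor,
       windows_um = windows_um, artifact_margin_px = artifact_margin_px,
       reflex_energy_factor = reflex_energy_factor)
}

# Number of columns in one 0.5-mm flanking analysis region.
region_width_cols <- function(geometry) {
  as.integer(round(500 / lateral_pitch_um(geometry)))
}

# Midmost index among the tied minima of the (smoothed) anterior depth
# trace; the apex tie-break for flat corneas.
apex_from_anterior <- function(anterior) {
  if (all(is.na(anterior))) {
    abort_cornoct("no detectable anterior surface", "cornoct_detection_error")
  }
  sm <- moving_average(ifelse(is.na(anterior), max(anterior, na.rm = TRUE),
                              anterior), 31L)
  tied <- which(sm <= min(sm) + 1e-9)
  tied[ceiling(length(tied) / 2)]
}

# Sub-pixel anterior (air-epithelium) surface depth per column, NA where no
# surface is detectable. Works on a laterally smoothed copy so speckle does
# not trigger false first peaks.
find_anterior <- function(pixels, axial_smooth = 3L, lateral_smooth = 11L) {
  sm <- smooth_raster(pixels, axial_smooth, lateral_smooth)
  apply(sm, 2L, function(col) {
    cmax <- max(col)
    if (cmax <= 0) return(NA_real_)
    peaks <- local_maxima(col)
    peaks <- peaks[col[peaks] >= 0.35 * cmax]
    if (!length(peaks)) return(NA_real_)
    parabolic_refine(col, peaks[1L])
  })
}

#' Locate the corneal apex of a B-scan
#'
#' The apex is the lateral position where the air-epithelium interface is
#' shallowest. It centres the specular-reflex exclusion window when no
#' reflex is detected. Ties (a flat cornea) resolve to the midmost tied
#' column.
#'
#' @param image a `bscan_image`.
#' @param params a [segmentation_params()] list.
#' @return Integer lateral column index.
#' @export
locate_apex <- function(image, params = segmentation_params()) {
  apex_from_anterior(find_anterior(image$pixels, params$axial_smooth))
}

#' Preprocess a B-scan: denoise, remove artifacts, exclude the reflex
#'
#' Applies uniform denoising, attenuates horizontal artifact lines by
#' subtracting a per-row robust baseline estimated over columns where the
#' row lies outside the corneal band, locates the central specular reflex
#' as the column of maximal energy (falling back to the apex when no reflex
#' is present), excludes the central 128 columns around it, and records the
#' two 0.5-mm flanking analysis regions.
#'
#' @param image a `bscan_image`.
#' @param params a [segmentation_params()] list.
#' @return An object of class `preprocessed_image` with elements `pixels`,
#'   `excluded_columns`, `analysis_regions` (list of two column-index
#'   vectors), `reflex_col`, `apex_col`, `anterior`, `geometry`, `meta`.
#' @export
preprocess <- function(image, params = segmentation_params()) {
  g <- image$geometry
  regw <- region_width_cols(g)
  if (g$width_px < 128L + 2L * regw) {
    abort_cornoct(
      "image narrower than the exclusion window plus two 0.5-mm regions",
      "cornoct_geometry_error")
  }
  raw <- image$pixels
  # first pass: crude anterior trace; horizontal artifact lines in air can
  # still masquerade as the surface here, so it is only used to delimit
  # the corneal band for the row-baseline estimate
  anterior <- find_anterior(raw, params$axial_smooth)
  if (all(is.na(anterior))) {
    abort_cornoct("no detectable anterior surface", "cornoct_detection_error")
  }

  # specular reflex: column of maximal (smoothed) energy, if prominent
  energy <- moving_average(colSums(raw), 5L)
  reflex_col <- NA_integer_
  if (max(energy) > params$reflex_energy_factor * stats::median(energy)) {
    reflex_col <- which.max(energy)
  }

  sm <- smooth_raster(raw, params$axial_smooth, params$lateral_smooth)

  # horizontal artifact suppression: per-row median over columns where the
  # row is in air above the anterior surface or below the plausible
  # posterior band (row-robust baseline)
  d_px <- g$depth_px
  margin <- params$artifact_margin_px
  post_off <- geom_um_to_px(max(params$windows_um$total), g) + margin
  a_ok <- !is.na(anterior)
  a_fill <- anterior
  for (r in seq_len(d_px)) {
    outside <- a_ok & (r < a_fill - margin | r > a_fill + post_off)
    if (sum(outside) >= 50L) {
      b <- stats::median(sm[r, outside])
      if (b > 0) sm[r, ] <- pmax(sm[r, ] - b, 0)
    }
  }

  # second pass on the cleaned raster: the anterior trace used for
  # alignment and apex localisation is free of artifact-line false peaks
  anterior <- find_anterior(sm, params$axial_smooth)
  if (all(is.na(anterior))) {
    abort_cornoct("no detectable anterior surface", "cornoct_detection_error")
  }
  apex_col <- apex_from_anterior(anterior)
  centre <- if (is.na(reflex_col)) apex_col else reflex_col

  # 128-column exclusion, left-biased about the centre column
  lo <- centre - 64L
  hi <- centre + 63L
  if (lo - regw < 1L || hi + regw > g$width_px) {
    abort_cornoct(
      "exclusion window and flanking regions do not fit inside the raster",
      "cornoct_geometry_error")
  }
  excluded <- lo:hi
  regions <- list(left = (lo - regw):(lo - 1L), right = (hi + 1L):(hi + regw))

  structure(
    list(pixels = sm, excluded_columns = excluded,
         analysis_regions = regions, reflex_col = reflex_col,
         apex_col = apex_col, anterior = anterior,
         geometry = g, meta = image$meta),
    class = "preprocessed_image")
}

#' Build flattened longitudinal reflectivity profiles
#'
#' For each 0.5-mm flanking region the A-scans are depth-aligned to the
#' local air-epithelium ridge (integer shifts) and averaged into one axial
#' profile, so the interface peaks stay as sharp as the single-A-scan PSF
#' while speckle averages out.
#'
#' @param pre a `preprocessed_image`.
#' @return A list of two `axial_profile` objects (`depth`, `reflectivity`,
#'   `ref_row`, `offsets`, `provenance`).
#' @export
build_profiles <- function(pre) {
  g <- pre$geometry
  lapply(names(pre$analysis_regions), function(side) {
    cols <- pre$analysis_regions[[side]]
    a <- pre$anterior[cols]
    ok <- !is.na(a)
    if (sum(ok) < length(cols) / 2) {
      abort_cornoct(
        sprintf("anterior surface undetectable in the %s analysis region", side),
        "cornoct_detection_error")
    }
    cols <- cols[ok]; a <- a[ok]
    ref <- round(stats::median(a))
    offsets <- as.integer(round(a - ref))
    d_px <- g$depth_px
    aligned <- matrix(NA_real_, nrow = d_px, ncol = length(cols))
    for (j in seq_along(cols)) {
      src <- seq_len(d_px) + offsets[j]
      keep <- src >= 1L & src <= d_px
      aligned[keep, j] <- pre$pixels[src[keep], cols[j]]
    }
    structure(
      list(depth = seq_len(d_px),
           reflectivity = rowMeans(aligned, na.rm = TRUE),
           ref_row = ref, offsets = offsets,
           provenance = sprintf("%s region, %d A-scans averaged",
                                side, length(cols))),
      class = "axial_profile")
  })
}

# Default anatomical plausibility windows, converted to optical-path px.
windows_px <- function(windows_um, geometry) {
  lapply(windows_um, geom_um_to_px, geometry = geometry)
}

#' Detect corneal interfaces on an axial reflectivity profile
#'
#' Local maxima above a prominence floor are assigned in depth order as
#' air-epithelium, epithelium-Bowman's, Bowman's-stroma, flap (post-op
#' only) and endothelium-aqueous, each constrained to an anatomical
#' plausibility window; peak positions are refined to sub-pixel precision
#' by a parabolic fit through the peak and its two neighbours.
#'
#' @param profile an `axial_profile`.
#' @param post_op logical; expect a flap interface.
#' @param geometry the image's [optical_geometry()].
#' @param params a [segmentation_params()] list.
#' @return An `interface_set`: sub-pixel depths `air_epi_px`,
#'   `epi_bowman_px`, `bowman_stroma_px`, `flap_px` (NA pre-op),
#'   `endo_aqueous_px`, plus `qc_flags` and per-interface `provenance`.
#' @export
detect_interfaces <- function(profile, post_op, geometry,
                              params = segmentation_params()) {
  y <- profile$reflectivity
  y[!is.finite(y)] <- 0
  ys <- moving_average(y, params$profile_smooth)
  peaks <- local_maxima(ys)
  if (!length(peaks)) {
    abort_cornoct("no reflectivity peaks found", "cornoct_segmentation_error",
                  qc_flags = "no_peaks")
  }
  win <- windows_px(params$windows_um, geometry)

  # anterior surface: the strongest peak
  ant_idx <- peaks[which.max(ys[peaks])]

  # robust noise scale from the profile tail beyond any plausible cornea
  tail_start <- ceiling(ant_idx + max(win$total)) + 40L
  sigma <- if (length(ys) - tail_start >= 40L) {
    stats::mad(ys[tail_start:length(ys)])
  } else {
    stats::mad(diff(ys)) / sqrt(2)
  }
  thr <- params$prominence_factor * max(sigma, 1e-12)
  prom <- peak_prominence(ys, peaks)
  keep <- prom >= thr | peaks == ant_idx
  peaks <- peaks[keep]; prom <- prom[keep]

  # Depth-ordered assignment within the window: the shallowest candidate
  # whose prominence is within reach of the strongest candidate (relative
  # floor rejects residual speckle bumps riding on the stromal backscatter).
  pick <- function(lo, hi, used) {
    cand <- which(peaks > lo & peaks < hi & !(peaks %in% used))
    if (!length(cand)) return(NA_integer_)
    strong <- cand[prom[cand] >= 0.3 * max(prom[cand])]
    min(peaks[strong])
  }

  air <- ant_idx
  used <- air
  epi <- pick(air + win$epithelium[1], air + win$epithelium[2], used)
  used <- c(used, epi)
  bow <- if (!is.na(epi)) {
    pick(epi + win$bowman[1], epi + win$bowman[2], used)
  } else NA_integer_
  used <- c(used, bow)
  flap <- NA_integer_
  if (post_op) {
    flap_lo <- max(air + win$flap[1],
                   if (!is.na(bow)) bow + geom_um_to_px(8, geometry) else -Inf)
    flap <- pick(flap_lo, air + win$flap[2], used)
    used <- c(used, flap)
  }
  endo <- pick(air + win$total[1], air + win$total[2], used)

  required <- c(air_epi = air, epi_bowman = epi, bowman_stroma = bow,
                endo_aqueous = endo)
  if (post_op) required <- c(required, flap = flap)
  missing <- names(required)[is.na(required)]
  if (length(missing)) {
    abort_cornoct(
      paste0("could not assign interfaces: ", paste(missing, collapse = ", ")),
      "cornoct_segmentation_error",
      qc_flags = paste0("missing_", missing))
  }

  refine <- function(p) if (is.na(p)) NA_real_ else parabolic_refine(ys, p)
  interface_set(
    air_epi_px = refine(air),
    epi_bowman_px = refine(epi),
    bowman_stroma_px = refine(bow),
    flap_px = if (post_op) refine(flap) else NA_real_,
    endo_aqueous_px = refine(endo),
    qc_flags = character(0),
    provenance = stats::setNames(rep("auto", 5),
                                 c("air_epi", "epi_bowman", "bowman_stroma",
                                   "flap", "endo_aqueous")))
}

#' Construct an interface set
#'
#' @param air_epi_px,epi_bowman_px,bowman_stroma_px,flap_px,endo_aqueous_px
#'   sub-pixel interface depths (optical-path px); `flap_px` may be `NA`
#'   (pre-operative).
#' @param qc_flags character vector of detection-confidence notes.
#' @param provenance named character vector, `"auto"` or `"manual"` per
#'   interface.
#' @return An object of class `interface_set`.
#' @export
interface_set <- function(air_epi_px, epi_bowman_px, bowman_stroma_px,
                          flap_px = NA_real_, endo_aqueous_px,
                          qc_flags = character(0),
                          provenance = NULL) {
  depths <- c(air_epi = air_epi_px, epi_bowman = epi_bowman_px,
              bowman_stroma = bowman_stroma_px, flap = flap_px,
              endo_aqueous = endo_aqueous_px)
  present <- depths[!is.na(depths)]
  if (any(diff(present) <= 0)) {
    abort_cornoct("interface depths must be strictly increasing",
                  "cornoct_validation_error")
  }
  if (is.null(provenance)) {
    provenance <- stats::setNames(rep("auto", 5), names(depths))
  }
  structure(
    list(air_epi_px = unname(air_epi_px),
         epi_bowman_px = unname(epi_bowman_px),
         bowman_stroma_px = unname(bowman_stroma_px),
         flap_px = unname(flap_px),
         endo_aqueous_px = unname(endo_aqueous_px),
         qc_flags = qc_flags, provenance = provenance),
    class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf(
    "<interface_set> air-epi %.2f, epi-Bowman %.2f, Bowman-stroma %.2f, flap %s, endo %.2f px\n",
    x$air_epi_px, x$epi_bowman_px, x$bowman_stroma_px,
    if (is.na(x$flap_px)) "--" else sprintf("%.2f", x$flap_px),
    x$endo_aqueous_px))
  invisible(x)
}

#' Replace automatically detected interfaces with manual depths
#'
#' Mirrors the manual-segmentation fallback used when detected peak
#' locations do not match the visible sublayer boundaries.
#'
#' @param iset an [interface_set()].
#' @param override named numeric vector of replacement depths (px); names
#'   among `air_epi`, `epi_bowman`, `bowman_stroma`, `flap`,
#'   `endo_aqueous`. Empty override returns `iset` unchanged.
#' @return The updated `interface_set`, with overridden interfaces marked
#'   `"manual"` in `provenance`.
#' @export
apply_manual_override <- function(iset, override) {
  if (length(override) == 0) return(iset)
  valid <- c("air_epi", "epi_bowman", "bowman_stroma", "flap", "endo_aqueous")
  if (is.null(names(override)) || !all(names(override) %in% valid)) {
    abort_cornoct("override must be named by interface",
                  "cornoct_validation_error")
  }
  ov <- unlist(override)
  if (any(diff(ov[order(match(names(ov), valid))]) <= 0) && length(ov) > 1) {
    abort_cornoct("override depths must be strictly increasing",
                  "cornoct_validation_error")
  }
  depths <- c(air_epi = iset$air_epi_px, epi_bowman = iset$epi_bowman_px,
              bowman_stroma = iset$bowman_stroma_px, flap = iset$flap_px,
              endo_aqueous = iset$endo_aqueous_px)
  depths[names(ov)] <- ov
  prov <- iset$provenance
  prov[names(ov)] <- "manual"
  interface_set(depths[["air_epi"]], depths[["epi_bowman"]],
                depths[["bowman_stroma"]], depths[["flap"]],
                depths[["endo_aqueous"]],
                qc_flags = iset$qc_flags, provenance = prov)
}

#' Segment one B-scan into its corneal interfaces
#'
#' Runs the full central-cornea segmentation: preprocessing (denoise,
#' artifact removal, reflex exclusion), flattened profile averaging over
#' the two 0.5-mm flanking regions, ordered peak detection on each
#' region's profile, and averaging of the two regional interface sets into
#' one central measurement per scan.
#'
#' @param image a `bscan_image`.
#' @param post_op logical; defaults to `image$meta$visit != "PRE"` when the
#'   metadata carries a visit label.
#' @param params a [segmentation_params()] list.
#' @return An [interface_set()] (depths averaged over the two regions).
#' @export
segment_bscan <- function(image, post_op = NULL,
                          params = segmentation_params()) {
  if (is.null(post_op)) {
    v <- image$meta$visit
    if (is.null(v) || is.na(v)) {
      abort_cornoct(
        "`post_op` must be given when image metadata has no visit label",
        "cornoct_validation_error")
    }
    post_op <- !identical(v, "PRE")
  }
  pre <- preprocess(image, params)
  profiles <- build_profiles(pre)
  isets <- lapply(profiles, detect_interfaces, post_op = post_op,
                  geometry = image$geometry, params = params)
  mean2 <- function(field) mean(vapply(isets, `[[`, numeric(1), field))
  interface_set(
    air_epi_px = mean2("air_epi_px"),
    epi_bowman_px = mean2("epi_bowman_px"),
    bowman_stroma_px = mean2("bowman_stroma_px"),
    flap_px = if (post_op) mean2("flap_px") else NA_real_,
    endo_aqueous_px = mean2("endo_aqueous_px"),
    qc_flags = unique(unlist(lapply(isets, `[[`, "qc_flags"))),
    provenance = isets[[1]]$provenance)
}
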