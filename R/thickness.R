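#' Convert interface depths to geometric sublayer thicknesses
#'
#' Interface separations along the depth axis are optical path lengths;
#' dividing by the geometry's group index (1.376 for corneal tissue by
#' default) yields geometric thickness in um. Epithelium is the
#' air-epithelium to epithelium-Bowman's separation, Bowman's layer the
#' next separation, flap and total cornea are measured from the anterior
#' surface.
#'
#' @param iset an [interface_set()].
#' @param geometry an [optical_geometry()].
#' @param meta optional named list of scan metadata carried through.
#' @return An object of class `sublayer_thickness`: `epithelium_um`,
#'   `bowman_um`, `flap_um` (NA pre-op), `total_um`, `meta`.
#' @examples
#' g <- optical_geometry()
#' iset <- interface_set(100, 100 + 137.6 / axial_pitch_um(g), 200,
#'                       endo_aqueous_px = 600)
#' interfaces_to_thickness(iset, g)$epithelium_um  # exactly 100 um
#' @export
interfaces_to_thickness <- function(iset, geometry, meta = list()) {
  if (!inherits(iset, "interface_set")) {
    abort_cornoct("`iset` must be an interface_set", "cornoct_validation_error")
  }
  need <- c("air_epi_px", "epi_bowman_px", "bowman_stroma_px",
            "endo_aqueous_px")
  vals <- unlist(iset[need])
  if (anyNA(vals)) {
    abort_cornoct("interface set is missing required interfaces",
                  "cornoct_conversion_error")
  }
  to_um <- function(dpx) px_to_geom_um(dpx, geometry)
  structure(
    list(
      epithelium_um = to_um(iset$epi_bowman_px - iset$air_epi_px),
      bowman_um = to_um(iset$bowman_stroma_px - iset$epi_bowman_px),
      flap_um = if (is.na(iset$flap_px)) NA_real_ else
        to_um(iset$flap_px - iset$air_epi_px),
      total_um = to_um(iset$endo_aqueous_px - iset$air_epi_px),
      meta = meta),
    class = "sublayer_thickness")
}

#' Average the two scan repetitions of one visit
#'
#' The per-visit thickness of each sublayer is the arithmetic mean of the
#' two repeated measurements.
#'
#' @param s1,s2 `sublayer_thickness` objects from the same subject and
#'   visit, with the same layers present.
#' @return A `sublayer_thickness` with element-wise mean values.
#' @export
average_scans <- function(s1, s2) {
  if (!inherits(s1, "sublayer_thickness") ||
      !inherits(s2, "sublayer_thickness")) {
    abort_cornoct("inputs must be sublayer_thickness objects",
                  "cornoct_validation_error")
  }
  if (is.na(s1$flap_um) != is.na(s2$flap_um)) {
    abort_cornoct("scans disagree on flap availability",
                  "cornoct_validation_error")
  }
  structure(
    list(epithelium_um = (s1$epithelium_um + s2$epithelium_um) / 2,
         bowman_um = (s1$bowman_um + s2$bowman_um) / 2,
         flap_um = (s1$flap_um + s2$flap_um) / 2,
         total_um = (s1$total_um + s2$total_um) / 2,
         meta = s1$meta),
    class = "sublayer_thickness")
}

#' @export
print.sublayer_thickness <- function(x, ...) {
  cat(sprintf(
    "<sublayer_thickness> epi %.2f, Bowman %.2f, flap %s, total %.2f um\n",
    x$epithelium_um, x$bowman_um,
    if (is.na(x$flap_um)) "--" else sprintf("%.2f", x$flap_um),
    x$total_um))
  invisible(x)
}

#' Assemble per-scan segmentation results into a long cohort table
#'
#' Joins per-scan thickness results to the manifest and returns the
#' long-format cohort record (one row per subject x visit x scan x layer)
#' together with a QC report of failed scans. Failed scans are excluded
#' from the table; repeatability analyses later drop their visit pairs.
#'
#' @param results named list of `sublayer_thickness` (or a segmentation
#'   failure condition / `NULL` for failed scans); names are
#'   `"<subject>_<visit>_s<rep>"` keys matching the manifest rows.
#' @param manifest the manifest data.frame from [generate_cohort()] (or an
#'   equivalent table with subject_id, group, visit, scan_rep columns).
#' @return A list: `cohort` (data.frame: subject_id, group, visit,
#'   scan_rep, layer, thickness_um) of class `cohort_record`, and `qc`
#'   (list with `n_scans`, `n_failed`, `failed_keys`).
#' @export
assemble_cohort <- function(results, manifest) {
  keys <- sprintf("%s_%s_s%d", manifest$subject_id, manifest$visit,
                  manifest$scan_rep)
  miss <- setdiff(keys, names(results))
  if (length(miss)) {
    abort_cornoct(
      paste0("manifest rows without a result or logged failure: ",
             paste(utils::head(miss, 5), collapse = ", ")),
      "cornoct_validation_error")
  }
  rows <- list()
  failed <- character(0)
  for (i in seq_along(keys)) {
    k <- keys[i]
    res <- results[[k]]
    if (!inherits(res, "sublayer_thickness")) {
      failed <- c(failed, k)
      next
    }
    layers <- c(epithelium = res$epithelium_um, bowman = res$bowman_um,
                flap = res$flap_um, total = res$total_um)
    layers <- layers[!is.na(layers)]
    rows[[k]] <- data.frame(
      subject_id = manifest$subject_id[i], group = manifest$group[i],
      visit = manifest$visit[i], scan_rep = manifest$scan_rep[i],
      layer = names(layers), thickness_um = unname(layers),
      stringsAsFactors = FALSE)
  }
  cohort <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(subject_id = character(0), group = character(0),
               visit = character(0), scan_rep = integer(0),
               layer = character(0), thickness_um = numeric(0))
  }
  dup <- duplicated(cohort[c("subject_id", "visit", "scan_rep", "layer")])
  if (any(dup)) {
    abort_cornoct("duplicate (subject, visit, scan, layer) rows",
                  "cornoct_validation_error")
  }
  class(cohort) <- c("cohort_record", "data.frame")
  list(cohort = cohort,
       qc = list(n_scans = length(keys), n_failed = length(failed),
                 failed_keys = failed))
}

# Per-subject visit means (two scans averaged); drops incomplete scan pairs.
# Returns wide-by-nothing long data.frame subject_id, group, visit, layer,
# thickness_um.
average_cohort_scans <- function(cohort) {
  agg <- stats::aggregate(
    thickness_um ~ subject_id + group + visit + layer, data = cohort,
    FUN = mean)
  n <- stats::aggregate(
    thickness_um ~ subject_id + group + visit + layer, data = cohort,
    FUN = length)
  agg[n$thickness_um == 2L, , drop = FALSE]
}
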