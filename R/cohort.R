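#' Cohort design for synthetic longitudinal corneal imaging
#'
#' Describes one surgical group imaged at five visits (`PRE`, `1D`, `1W`,
#' `2W`, `1M`) with two scan repetitions per visit. Each subject's true
#' sublayer thickness at a visit is
#' `mean[layer, visit] + sd_between[layer] * u_s + sd_visit[layer] * e_sv`,
#' with `u_s` a per-subject standard-normal intercept and `e_sv` an
#' independent per-visit fluctuation; each scan repetition then adds
#' independent repeatability noise with SD `pair_diff_sd[layer] / sqrt(2)`,
#' so the difference of the two scans of a visit has SD
#' `pair_diff_sd[layer]`.
#'
#' @param group group label (e.g. `"Moria"` or `"FEMTO"`).
#' @param n_subjects number of subjects.
#' @param mean_um numeric matrix, layers (`epithelium`, `bowman`, `flap`,
#'   `total`) x visits (`PRE`, `1D`, `1W`, `2W`, `1M`), geometric um;
#'   `flap` is `NA` at `PRE`.
#' @param sd_between_um,sd_visit_um per-layer SDs (um) of the
#'   between-subject intercept and the within-subject per-visit fluctuation.
#' @param pair_diff_sd_um per-layer SD (um) of the difference between the
#'   two scan repetitions of one visit (the repeatability target).
#' @param seed master seed for cohort generation.
#' @return An object of class `cohort_design`.
#' @seealso [default_cohort_design()] for designs matching the published
#'   microkeratome and femtosecond-laser groups.
#' @export
cohort_design <- function(group, n_subjects, mean_um,
                          sd_between_um, sd_visit_um, pair_diff_sd_um,
                          seed = 1L) {
  visits <- c("PRE", "1D", "1W", "2W", "1M")
  layers <- c("epithelium", "bowman", "flap", "total")
  if (!is.matrix(mean_um) || !identical(rownames(mean_um), layers) ||
      !identical(colnames(mean_um), visits)) {
    abort_cornoct("`mean_um` must be a 4 x 5 matrix with layer rows and visit columns",
                  "cornoct_validation_error")
  }
  if (!is.na(mean_um["flap", "PRE"])) {
    abort_cornoct("flap mean must be NA pre-operatively",
                  "cornoct_validation_error")
  }
  for (v in list(sd_between_um, sd_visit_um, pair_diff_sd_um)) {
    if (!all(names(v) == layers) || any(v < 0)) {
      abort_cornoct("SD vectors must be named by the four layers and be >= 0",
                    "cornoct_validation_error")
    }
  }
  if (n_subjects < 1) {
    abort_cornoct("`n_subjects` must be >= 1", "cornoct_validation_error")
  }
  structure(
    list(group = group, n_subjects = as.integer(n_subjects),
         visits = visits, layers = layers, mean_um = mean_um,
         sd_between_um = sd_between_um, sd_visit_um = sd_visit_um,
         pair_diff_sd_um = pair_diff_sd_um, seed = as.integer(seed)),
    class = "cohort_design")
}

#' Default cohort designs for the two flap-creation groups
#'
#' Parameterised from the published group summaries: per-visit thickness
#' means and cross-sectional SDs, consecutive-visit change SDs, and
#' week-1 test-retest difference SDs. The within-subject visit SD is
#' derived from the change SDs (`Var(change) = 2 sd_visit^2 +
#' pair_diff_sd^2 / 2` for visit means of two averaged scans) and the
#' between-subject SD from the cross-sectional SDs by variance subtraction.
#'
#' @param group `"Moria"` (microkeratome, n = 20) or `"FEMTO"`
#'   (femtosecond laser, n = 21).
#' @param n_subjects optional override of the group sample size.
#' @param seed master seed.
#' @return A [cohort_design()].
#' @export
default_cohort_design <- function(group = c("Moria", "FEMTO"),
                                  n_subjects = NULL, seed = 1L) {
  group <- match.arg(group)
  visits <- c("PRE", "1D", "1W", "2W", "1M")
  layers <- c("epithelium", "bowman", "flap", "total")
  if (group == "Moria") {
    n <- 20L
    mean_um <- rbind(
      epithelium = c(53.1, 56.0, 54.4, 55.7, 56.9),
      bowman     = c(17.0, 18.5, 18.0, 18.1, 18.4),
      flap       = c(NA,   95.8, 95.5, 96.5, 98.2),
      total      = c(525.8, 439.5, 431.6, 432.0, 434.2))
    obs_sd <- rbind(
      epithelium = c(3.7, 3.2, 3.6, 3.7, 4.1),
      bowman     = c(1.6, 1.4, 1.5, 1.1, 1.3),
      flap       = c(NA,  7.6, 7.8, 7.9, 8.2),
      total      = c(25.0, 24.0, 23.6, 23.1, 23.0))
    # consecutive-visit change SDs, post-surgical intervals only for total
    change_sd <- c(epithelium = 2.6, bowman = 1.2, flap = 2.4, total = 3.7)
    pair_diff_sd <- c(epithelium = 1.22, bowman = 0.61, flap = 1.80,
                      total = 4.29)
  } else {
    n <- 21L
    mean_um <- rbind(
      epithelium = c(51.9, 54.5, 53.2, 53.2, 55.2),
      bowman     = c(15.7, 17.4, 17.2, 17.1, 17.8),
      flap       = c(NA,  105.6, 106.3, 105.7, 107.5),
      total      = c(521.7, 453.1, 443.7, 441.7, 445.0))
    obs_sd <- rbind(
      epithelium = c(3.2, 2.8, 3.1, 3.1, 4.0),
      bowman     = c(1.8, 1.5, 1.2, 1.7, 1.7),
      flap       = c(NA,  8.2, 8.6, 7.6, 8.5),
      total      = c(27.2, 36.8, 37.8, 37.4, 36.0))
    change_sd <- c(epithelium = 2.7, bowman = 1.35, flap = 3.2, total = 8.5)
    pair_diff_sd <- c(epithelium = 1.02, bowman = 0.48, flap = 2.00,
                      total = 4.71)
  }
  dimnames(mean_um) <- list(layers, visits)
  dimnames(obs_sd) <- list(layers, visits)
  sd_visit <- sqrt(pmax(change_sd^2 - pair_diff_sd^2 / 2, 0) / 2)
  med_obs <- apply(obs_sd, 1L, stats::median, na.rm = TRUE)
  sd_between <- sqrt(pmax(med_obs^2 - sd_visit^2 - pair_diff_sd^2 / 2,
                          (0.3 * med_obs)^2))
  names(sd_visit) <- names(sd_between) <- layers
  cohort_design(group = group,
                n_subjects = if (is.null(n_subjects)) n else n_subjects,
                mean_um = mean_um,
                sd_between_um = sd_between, sd_visit_um = sd_visit,
                pair_diff_sd_um = pair_diff_sd, seed = seed)
}

#' Generate a synthetic cohort of corneal scans
#'
#' Draws per-subject true sublayer trajectories from a [cohort_design()],
#' adds independent per-scan repeatability noise, and returns the manifest
#' plus the per-scan ground-truth thickness table. With `render = TRUE`
#' every scan is also rendered to a full B-scan raster (and written to
#' `outdir` as TIFF + JSON sidecar when `outdir` is given).
#'
#' Sampled thickness sets violating positivity or the anatomical ordering
#' (epithelium + Bowman's < flap depth < total) are redrawn with a warning,
#' up to 100 retries per scan.
#'
#' @param design a [cohort_design()].
#' @param render logical; render pixel rasters for every scan.
#' @param outdir directory for rendered images (`NULL` keeps them in
#'   memory).
#' @param geometry raster geometry used when rendering.
#' @param noise_level,artifact_flags passed to [generate_bscan()].
#' @return A list: `manifest` (data.frame: subject_id, group, visit,
#'   scan_rep, image_path, truth_path), `truth` (long data.frame:
#'   subject_id, group, visit, scan_rep, layer, thickness_um), and, when
#'   rendering in memory, `images` (named list of [generate_bscan()]
#'   results).
#' @export
generate_cohort <- function(design, render = FALSE, outdir = NULL,
                            geometry = optical_geometry(),
                            noise_level = 1.0,
                            artifact_flags = c("reflex", "hbands")) {
  if (!inherits(design, "cohort_design")) {
    abort_cornoct("`design` must be a cohort_design", "cornoct_validation_error")
  }
  set.seed(design$seed)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  visits <- design$visits
  layers <- design$layers
  manifest <- list()
  truth_rows <- list()
  images <- list()

  comp_sd <- decompose_component_sds(design)
  n_resampled <- 0L
  comp_means <- vapply(visits, function(v) visit_component_means(design, v),
                       numeric(4))
  min_mean <- apply(comp_means, 1L, min)
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("%s%02d", substr(design$group, 1, 1), s)
    # subject anatomy intercepts, truncated so every component stays
    # realisable (> 1 um) at every visit of this subject's trajectory
    u <- stats::rnorm(4L)
    names(u) <- c("epi", "bowman", "gap_flap", "gap_rest")
    for (ci in seq_len(4L)) {
      tries <- 0L
      while (min_mean[ci] + comp_sd$between[ci] * u[ci] <= 1 &&
             tries < 100L) {
        u[ci] <- stats::rnorm(1L)
        tries <- tries + 1L
      }
      n_resampled <- n_resampled + tries
    }
    for (v in visits) {
      visit <- draw_visit_scans(design, comp_sd, u, v)
      n_resampled <- n_resampled + visit$n_resampled
      for (rep_i in 1:2) {
        thick <- visit$scans[[rep_i]]
        img_path <- truth_path <- NA_character_
        key <- sprintf("%s_%s_s%d", sid, v, rep_i)
        if (render) {
          scan_seed <- sample.int(2147483646L, 1L)
          tr <- cornea_truth(
            epi_um = thick[["epithelium"]], bowman_um = thick[["bowman"]],
            total_um = thick[["total"]],
            flap_um = if (v == "PRE") NA_real_ else thick[["flap"]])
          b <- generate_bscan(tr, geometry, noise_level = noise_level,
                              artifact_flags = artifact_flags,
                              seed = scan_seed,
                              meta = list(subject = sid, group = design$group,
                                          visit = v, scan_rep = rep_i))
          if (!is.null(outdir)) {
            img_path <- file.path(outdir, paste0(key, ".tif"))
            truth_path <- file.path(outdir, paste0(key, ".json"))
            write_bscan(b, img_path, truth_path)
          } else {
            images[[key]] <- b
          }
        }
        manifest[[key]] <- data.frame(
          subject_id = sid, group = design$group, visit = v,
          scan_rep = rep_i, image_path = img_path, truth_path = truth_path,
          stringsAsFactors = FALSE)
        present <- if (v == "PRE") setdiff(layers, "flap") else layers
        truth_rows[[key]] <- data.frame(
          subject_id = sid, group = design$group, visit = v,
          scan_rep = rep_i, layer = present,
          thickness_um = unname(thick[present]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_resampled > 0L) {
    warning(sprintf(
      "resampled %d draw(s) to satisfy thickness positivity/ordering",
      n_resampled), call. = FALSE)
  }
  out <- list(
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
  if (render && is.null(outdir)) out$images <- images
  out
}

thickness_ok <- function(thick, post_op) {
  ok <- all(thick[c("epithelium", "bowman", "total")] > 0) &&
    thick[["epithelium"]] + thick[["bowman"]] < thick[["total"]]
  if (ok && post_op) {
    ok <- !is.na(thick[["flap"]]) && thick[["flap"]] > 0 &&
      thick[["epithelium"]] + thick[["bowman"]] < thick[["flap"]] &&
      thick[["flap"]] < thick[["total"]]
  }
  isTRUE(ok)
}

# Subject anatomy is drawn as positive building blocks -- epithelium,
# Bowman's layer, the stromal part of the flap (flap depth minus
# epithelium and Bowman's) and the residual stroma below the flap plane --
# so the anatomical ordering epi + bowman < flap < total holds by
# construction. The component SDs are derived from the designed per-layer
# SDs by variance subtraction (floored at 20% of the layer SD so a
# component never degenerates), which reproduces the designed marginal
# layer SDs while keeping subjects anatomically coherent.
decompose_component_sds <- function(design) {
  dec <- function(sds) {
    e <- sds[["epithelium"]]; b <- sds[["bowman"]]
    f <- sds[["flap"]]; t <- sds[["total"]]
    c(epi = e, bowman = b,
      gap_flap = sqrt(max(f^2 - e^2 - b^2, (0.2 * f)^2)),
      gap_rest = sqrt(max(t^2 - f^2, (0.2 * t)^2)))
  }
  list(between = dec(design$sd_between_um), visit = dec(design$sd_visit_um))
}

# Component means for one visit. The flap plane exists anatomically even
# pre-operatively; its pre-op component mean is taken from the first
# post-op visit, and the residual stroma absorbs the difference (the
# ablation then appears as post-op shrinkage of the residual component).
visit_component_means <- function(design, v) {
  m <- design$mean_um
  vf <- if (v == "PRE") "1D" else v
  epi <- m["epithelium", v]; bow <- m["bowman", v]
  gap_flap <- m["flap", vf] - m["epithelium", vf] - m["bowman", vf]
  c(epi = epi, bowman = bow, gap_flap = gap_flap,
    gap_rest = m["total", v] - epi - bow - gap_flap)
}

# One visit's two scans: component-level visit truth (subject intercept +
# visit fluctuation) plus independent per-layer repeatability noise per
# scan. Non-positive components or scan draws violating the measured
# ordering are redrawn (capped); the resample count is reported so the
# caller can warn once.
draw_visit_scans <- function(design, comp_sd, u, v, max_retries = 100L) {
  post_op <- v != "PRE"
  scan_sd <- design$pair_diff_sd_um / sqrt(2)
  layers <- design$layers
  comp_mean <- visit_component_means(design, v)
  for (i in seq_len(max_retries)) {
    comp <- comp_mean + comp_sd$between * u +
      comp_sd$visit * stats::rnorm(4L)
    if (any(comp <= 0.5)) next
    mu_v <- c(epithelium = comp[["epi"]], bowman = comp[["bowman"]],
              flap = if (post_op)
                comp[["epi"]] + comp[["bowman"]] + comp[["gap_flap"]]
              else NA_real_,
              total = sum(comp))
    scans <- vector("list", 2L)
    ok <- TRUE
    scan_redraws <- 0L
    for (rep_i in 1:2) {
      got <- FALSE
      for (j in 1:10) {
        thick <- mu_v + scan_sd * stats::rnorm(length(layers))
        names(thick) <- layers
        if (thickness_ok(thick, post_op)) {
          scans[[rep_i]] <- thick
          scan_redraws <- scan_redraws + j - 1L
          got <- TRUE
          break
        }
      }
      if (!got) { ok <- FALSE; break }
    }
    if (ok) return(list(scans = scans, n_resampled = i - 1L + scan_redraws))
  }
  abort_cornoct("could not sample valid thicknesses within retry cap",
                "cornoct_validation_error")
}
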