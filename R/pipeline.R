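#' Pipeline configuration
#'
#' Assembles and validates the configuration for a full
#' simulate - segment - thickness - statistics run. Unknown fields are
#' rejected so configs stay forward-compatible and typos surface early.
#'
#' @param n_per_group subjects per group in the simulated cohorts.
#' @param groups character subset of `c("Moria", "FEMTO")`.
#' @param geometry an [optical_geometry()] (defaults to the instrument's
#'   native raster).
#' @param noise_level,artifact_flags passed to [generate_bscan()].
#' @param repeatability_visit visit at which the agreement table is
#'   computed.
#' @param icc_type,ci_method statistics options (see
#'   [intraclass_correlation()], [group_difference_ci()]).
#' @param seed master seed for the run.
#' @param fault_keys character vector of scan keys
#'   (`"<subject>_<visit>_s<rep>"`) whose images are blanked before
#'   segmentation; a fault-injection hook for exercising the QC path.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 6L,
                            groups = c("Moria", "FEMTO"),
                            geometry = optical_geometry(),
                            noise_level = 1.0,
                            artifact_flags = c("reflex", "hbands"),
                            repeatability_visit = "1W",
                            icc_type = "agreement",
                            ci_method = "pooled",
                            seed = 1L,
                            fault_keys = character(0)) {
  groups <- match.arg(groups, several.ok = TRUE)
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         geometry = geometry, noise_level = noise_level,
         artifact_flags = artifact_flags,
         repeatability_visit = repeatability_visit,
         icc_type = icc_type, ci_method = ci_method,
         seed = as.integer(seed), fault_keys = fault_keys),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys must be arguments of
#'   [pipeline_config()] (`geometry` may be a mapping of
#'   [optical_geometry()] arguments). Unknown keys raise a config error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort_cornoct(paste0("unknown config keys: ", paste(extra, collapse = ", ")),
                  "cornoct_config_error")
  }
  if (!is.null(raw$geometry)) {
    gextra <- setdiff(names(raw$geometry), names(formals(optical_geometry)))
    if (length(gextra)) {
      abort_cornoct(paste0("unknown geometry keys: ",
                           paste(gextra, collapse = ", ")),
                    "cornoct_config_error")
    }
    raw$geometry <- do.call(optical_geometry, raw$geometry)
  }
  do.call(pipeline_config, raw)
}

# Stable hash of a config (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_result_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cornoct run %s seed %d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full simulation-to-statistics pipeline
#'
#' Simulates one cohort per configured group, renders and writes every
#' B-scan (TIFF + JSON truth sidecar), segments each scan, converts
#' interfaces to thicknesses, assembles the long cohort table, and writes
#' the repeatability table, the per-visit summary table, the
#' consecutive-visit change table, the between-group difference table, a
#' QC report and a run log. Failed segmentations are listed in the QC
#' report and excluded from statistics. Identical config + seed produces
#' byte-identical result CSVs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `status` (0 ok, 1 data error), the
#'   result tables, the QC report and the config hash.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort_cornoct("`config` must be a pipeline_config", "cornoct_config_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(outdir, "images")
  hash <- config_hash(config)
  log_path <- file.path(outdir, "run.log")
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  unlink(log_path)
  say("cornoct pipeline: seed %d, config %s", config$seed, hash)

  manifests <- list()
  results <- list()
  interface_rows <- list()
  for (gi in seq_along(config$groups)) {
    grp <- config$groups[[gi]]
    design <- default_cohort_design(grp, n_subjects = config$n_per_group,
                                    seed = config$seed + gi)
    say("simulating %s cohort (n = %d)", grp, design$n_subjects)
    sim <- generate_cohort(design, render = TRUE, outdir = img_dir,
                           geometry = config$geometry,
                           noise_level = config$noise_level,
                           artifact_flags = config$artifact_flags)
    manifests[[grp]] <- sim$manifest
    say("segmenting %d scans", nrow(sim$manifest))
    for (i in seq_len(nrow(sim$manifest))) {
      row <- sim$manifest[i, ]
      key <- sprintf("%s_%s_s%d", row$subject_id, row$visit, row$scan_rep)
      img <- read_bscan(row$image_path, row$truth_path)
      if (key %in% config$fault_keys) img$pixels[] <- 0
      res <- tryCatch({
        iset <- segment_bscan(img, post_op = row$visit != "PRE")
        interface_rows[[key]] <- data.frame(
          key = key, air_epi_px = iset$air_epi_px,
          epi_bowman_px = iset$epi_bowman_px,
          bowman_stroma_px = iset$bowman_stroma_px,
          flap_px = iset$flap_px, endo_aqueous_px = iset$endo_aqueous_px,
          provenance = paste(unique(iset$provenance), collapse = "+"),
          stringsAsFactors = FALSE)
        interfaces_to_thickness(iset, img$geometry,
                                meta = as.list(row[c("subject_id", "group",
                                                     "visit", "scan_rep")]))
      }, cornoct_error = function(e) {
        say("segmentation failed for %s: %s", key, conditionMessage(e))
        e
      })
      results[[key]] <- res
    }
  }
  manifest <- do.call(rbind, c(manifests, list(make.row.names = FALSE)))
  asm <- assemble_cohort(results, manifest)
  cohort <- asm$cohort
  qc <- asm$qc
  qc$config_hash <- hash
  qc$seed <- config$seed
  jsonlite::write_json(qc, file.path(outdir, "qc.json"), auto_unbox = TRUE)

  status <- 0L
  if (qc$n_failed > 0) say("%d of %d scans failed QC", qc$n_failed, qc$n_scans)
  if (!nrow(cohort)) {
    say("no usable scans; halting after QC report")
    return(invisible(list(status = 1L, qc = qc, config_hash = hash)))
  }

  write_result_csv(do.call(rbind, c(interface_rows,
                                    list(make.row.names = FALSE))),
                   file.path(outdir, "interfaces.csv"), hash, config$seed)
  write_result_csv(cohort, file.path(outdir, "cohort.csv"), hash, config$seed)

  agree <- tryCatch(
    agreement_table(cohort, visit = config$repeatability_visit,
                    icc_type = config$icc_type),
    cornoct_error = function(e) { say("agreement table: %s",
                                      conditionMessage(e)); NULL })
  if (!is.null(agree)) {
    write_result_csv(agree, file.path(outdir, "agreement.csv"),
                     hash, config$seed)
  }

  summary_tab <- visit_summary_table(cohort)
  write_result_csv(summary_tab, file.path(outdir, "visit_summary.csv"),
                   hash, config$seed)

  change_rows <- list()
  for (grp in unique(cohort$group)) {
    for (l in intersect(c("epithelium", "bowman", "flap", "total"),
                        unique(cohort$layer[cohort$group == grp]))) {
      ch <- tryCatch(visit_changes(cohort, grp, l),
                     cornoct_error = function(e) NULL)
      if (!is.null(ch)) change_rows[[paste(grp, l)]] <- ch
    }
  }
  changes <- if (length(change_rows)) {
    do.call(rbind, c(change_rows, list(make.row.names = FALSE)))
  } else NULL
  if (!is.null(changes)) {
    write_result_csv(changes, file.path(outdir, "visit_changes.csv"),
                     hash, config$seed)
  }

  gdiff <- NULL
  if (length(unique(cohort$group)) == 2L) {
    avg <- average_cohort_scans(cohort)
    gs <- sort(unique(avg$group))
    gd_rows <- list()
    for (l in unique(avg$layer)) {
      for (v in unique(avg$visit[avg$layer == l])) {
        a <- avg$thickness_um[avg$group == gs[1] & avg$layer == l &
                                avg$visit == v]
        b <- avg$thickness_um[avg$group == gs[2] & avg$layer == l &
                                avg$visit == v]
        if (length(a) < 2 || length(b) < 2) next
        gd <- group_difference_ci(length(a), mean(a), sample_sd(a),
                                  length(b), mean(b), sample_sd(b),
                                  method = config$ci_method)
        gd_rows[[paste(l, v)]] <- cbind(
          data.frame(layer = l, visit = v,
                     group1 = gs[1], group2 = gs[2]), gd)
      }
    }
    if (length(gd_rows)) {
      gdiff <- do.call(rbind, c(gd_rows, list(make.row.names = FALSE)))
      write_result_csv(gdiff, file.path(outdir, "group_differences.csv"),
                       hash, config$seed)
    }
  }
  say("pipeline complete: status %d", status)
  invisible(list(status = status, cohort = cohort, agreement = agree,
                 visit_summary = summary_tab, changes = changes,
                 group_differences = gdiff, qc = qc, config_hash = hash))
}
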