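test_that("default geometry matches the instrument raster", {
  g <- optical_geometry()
  expect_identical(c(g$depth_px, g$width_px), c(1365L, 2048L))
  expect_equal(c(g$depth_extent_mm, g$width_extent_mm), c(2.01, 8.41))
  expect_equal(g$axial_psf_fwhm_um, 3.0)
  expect_equal(g$group_index, 1.376)
  expect_equal(axial_pitch_um(g), 2010 / 1365)
  expect_equal(lateral_pitch_um(g), 8410 / 2048)
})

test_that("noiseless flat-cornea ridges sit at the truth depths (brute-force oracle)", {
  g <- small_geom()
  b <- generate_bscan(pre_truth(anterior_radius_mm = Inf), g,
                      noise_level = 0, seed = 1)
  d <- b$truth$interface_depths_px
  cols <- seq(10L, g$width_px - 10L, by = 25L)
  for (ifc in rownames(d)) {
    ridge <- oracle_ridge(b$image$pixels[, cols, drop = FALSE], d[ifc, cols])
    expect_lt(max(abs(ridge - d[ifc, cols])), 0.5)
  }
})

test_that("per-column truth depths are strictly increasing with depth", {
  g <- small_geom()
  for (tr in list(pre_truth(), post_truth(),
                  post_truth(microdistortion_amp_um = 1.5))) {
    d <- truth_interface_depths(tr, g)
    ok <- colSums(is.na(d)) == 0
    expect_true(all(apply(d[, ok, drop = FALSE], 2L, function(x)
      all(diff(x) > 0))))
  }
})

test_that("identical seed and inputs give bit-identical rasters", {
  g <- small_geom()
  b1 <- generate_bscan(post_truth(), g, noise_level = 1,
                       artifact_flags = c("reflex", "hbands"), seed = 99)
  b2 <- generate_bscan(post_truth(), g, noise_level = 1,
                       artifact_flags = c("reflex", "hbands"), seed = 99)
  expect_identical(b1$image$pixels, b2$image$pixels)
  b3 <- generate_bscan(post_truth(), g, noise_level = 1, seed = 100)
  expect_false(identical(b1$image$pixels, b3$image$pixels))
})

test_that("zero microdistortion leaves the Bowman boundary flat across columns", {
  g <- small_geom()
  tr <- pre_truth(anterior_radius_mm = Inf)
  d <- truth_interface_depths(tr, g)
  expect_equal(diff(range(d["epi_bowman", ])), 0)
  tr2 <- pre_truth(anterior_radius_mm = Inf, microdistortion_amp_um = 2)
  d2 <- truth_interface_depths(tr2, g)
  expect_gt(diff(range(d2["epi_bowman", ])), 1)
  # anterior surface and endothelium stay smooth
  expect_equal(diff(range(d2["air_epi", ])), 0)
  expect_equal(diff(range(d2["endo_aqueous", ])), 0)
})

test_that("rasters are finite, non-negative, and correctly shaped", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 1,
                      artifact_flags = c("reflex", "hbands"), seed = 3)
  expect_identical(dim(b$image$pixels), c(g$depth_px, g$width_px))
  expect_true(all(is.finite(b$image$pixels)))
  expect_true(all(b$image$pixels >= 0))
})

test_that("interfaces outside the raster are rejected with a geometry error", {
  g <- small_geom(depth_px = 300L)
  expect_error(generate_bscan(pre_truth(total_um = 600), g, noise_level = 0),
               class = "cornoct_geometry_error")
})

test_that("truth validation enforces layer ordering and positivity", {
  expect_error(cornea_truth(epi_um = -1), class = "cornoct_validation_error")
  expect_error(cornea_truth(epi_um = 54, bowman_um = 18, flap_um = 60,
                            total_um = 443),
               class = "cornoct_validation_error")
  expect_error(cornea_truth(epi_um = 300, bowman_um = 300, total_um = 500),
               class = "cornoct_validation_error")
  expect_error(cornea_truth(microdistortion_amp_um = -1),
               class = "cornoct_validation_error")
})

test_that("B-scans round-trip through TIFF/PNG plus JSON sidecar", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 1, seed = 11,
                      meta = list(subject = "M01", visit = "1W", scan_rep = 1L))
  # TIFF is written at 16 bits, PNG at 8
  tols <- c(tif = 1e-4, png = 1 / 128)
  for (ext in names(tols)) {
    tol <- tols[[ext]]
    ip <- tempfile(fileext = paste0(".", ext))
    tp <- tempfile(fileext = ".json")
    write_bscan(b, ip, tp)
    rt <- read_bscan(ip, tp)
    expect_identical(dim(rt$pixels), dim(b$image$pixels))
    expect_lt(max(abs(rt$pixels - b$image$pixels)) / max(b$image$pixels),
              tol)
    expect_equal(rt$meta$visit, "1W")
    expect_equal(rt$truth_um$epi_um, 54)
    expect_equal(unname(rt$interface_depths_px["flap", 10]),
                 unname(b$truth$interface_depths_px["flap", 10]))
    unlink(c(ip, tp))
  }
})

test_that("a one-subject cohort yields exactly 10 manifest rows", {
  design <- default_cohort_design("Moria", n_subjects = 1, seed = 5)
  out <- generate_cohort(design, render = FALSE)
  expect_identical(nrow(out$manifest), 10L)
  expect_setequal(unique(out$manifest$visit), c("PRE", "1D", "1W", "2W", "1M"))
  # pre-op rows carry no flap layer
  expect_false("flap" %in% out$truth$layer[out$truth$visit == "PRE"])
  expect_true("flap" %in% out$truth$layer[out$truth$visit == "1D"])
})

test_that("zero repeatability SD makes both scans of a visit identical", {
  design <- default_cohort_design("Moria", n_subjects = 4, seed = 2)
  design$pair_diff_sd_um[] <- 0
  tr <- generate_cohort(design, render = FALSE)$truth
  w <- reshape(tr, idvar = c("subject_id", "visit", "layer"),
               timevar = "scan_rep", direction = "wide",
               drop = "group")
  expect_equal(w$thickness_um.1, w$thickness_um.2)
})

test_that("cohort generation is deterministic in the design seed", {
  design <- default_cohort_design("FEMTO", n_subjects = 3, seed = 42)
  t1 <- generate_cohort(design, render = FALSE)$truth
  t2 <- generate_cohort(design, render = FALSE)$truth
  expect_identical(t1, t2)
})

test_that("implausible sampled thicknesses are resampled with a warning", {
  design <- default_cohort_design("Moria", n_subjects = 2, seed = 7)
  design$pair_diff_sd_um[] <- c(60, 30, 60, 80)  # huge scan noise
  expect_warning(generate_cohort(design, render = FALSE),
                 "resampled")
})

test_that("simulated scan-pair flap difference SD recovers the design value", {
  # Monte-Carlo oracle: over replicate cohorts of n = 20, the empirical SD
  # of week-1 flap scan differences must match the designed 1.80 um pair
  # SD within 3 Monte-Carlo standard errors.
  n_rep <- 200
  sds <- vapply(seq_len(n_rep), function(r) {
    design <- default_cohort_design("Moria", seed = 1000 + r)
    tr <- suppressWarnings(generate_cohort(design, render = FALSE)$truth)
    fl <- tr[tr$visit == "1W" & tr$layer == "flap", ]
    w <- reshape(fl[c("subject_id", "scan_rep", "thickness_um")],
                 idvar = "subject_id", timevar = "scan_rep",
                 direction = "wide")
    sd(w$thickness_um.2 - w$thickness_um.1)
  }, numeric(1))
  mc_se <- sd(sds) / sqrt(n_rep)
  # sample SD is biased by the c4(n) factor; compare to its expectation
  c4 <- sqrt(2 / 19) * gamma(10) / gamma(19 / 2)
  expect_lt(abs(mean(sds) - 1.80 * c4), 3 * mc_se)
})
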