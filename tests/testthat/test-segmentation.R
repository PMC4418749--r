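test_that("the exclusion window removes exactly 128 columns and the regions flank it", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 1,
                      artifact_flags = c("reflex", "hbands"), seed = 21)
  pre <- preprocess(b$image)
  expect_length(pre$excluded_columns, 128L)
  regw <- round(500 / lateral_pitch_um(g))
  expect_length(pre$analysis_regions$left, regw)
  expect_length(pre$analysis_regions$right, regw)
  # exclusion correctness: no excluded column enters any analysis region
  expect_length(intersect(pre$excluded_columns,
                          unlist(pre$analysis_regions)), 0L)
  expect_true(all(pre$analysis_regions$left < min(pre$excluded_columns)))
  expect_true(all(pre$analysis_regions$right > max(pre$excluded_columns)))
})

test_that("the exclusion window is centred on the injected specular reflex", {
  g <- small_geom()
  # apex (and reflex) shifted off-centre by 40 columns
  b <- generate_bscan(post_truth(apex_offset_px = 40), g, noise_level = 1,
                      artifact_flags = "reflex", seed = 22)
  pre <- preprocess(b$image)
  apex_true <- round((g$width_px + 1) / 2) + 40
  expect_lt(abs(pre$reflex_col - apex_true), 3)
  expect_equal(pre$excluded_columns,
               (pre$reflex_col - 64L):(pre$reflex_col + 63L))
})

test_that("preprocessing a clean noiseless image preserves ridge maxima", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1)
  pre <- preprocess(b$image)
  d <- b$truth$interface_depths_px
  cols <- unlist(pre$analysis_regions)[seq(1, 240, by = 20)]
  for (ifc in c("air_epi", "flap", "endo_aqueous")) {
    before <- oracle_ridge(b$image$pixels[, cols, drop = FALSE], d[ifc, cols])
    after <- oracle_ridge(pre$pixels[, cols, drop = FALSE], d[ifc, cols])
    expect_lt(max(abs(after - before)), 0.5)
  }
})

test_that("horizontal artifact bands are attenuated in air", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 0, seed = 31)
  # deterministic artifact line in the air region above the cornea
  band_rows <- 30:31
  img <- b$image
  img$pixels[band_rows, ] <- img$pixels[band_rows, ] + 0.35
  pre <- preprocess(img)
  cols <- unlist(pre$analysis_regions)
  expect_lt(max(pre$pixels[band_rows, cols]),
            0.1 * max(img$pixels[band_rows, cols]))
  # and the band does not divert the anterior-surface trace
  d <- b$truth$interface_depths_px
  expect_lt(max(abs(pre$anterior[cols] - d["air_epi", cols])), 1.5)
})

test_that("an image too narrow for exclusion plus regions raises a geometry error", {
  g <- small_geom(width_px = 300L)
  b <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1)
  expect_error(preprocess(b$image), class = "cornoct_geometry_error")
})

test_that("locate_apex finds the shallowest anterior column", {
  g <- small_geom()
  # flat cornea: all columns tie, midmost index wins
  bf <- generate_bscan(pre_truth(anterior_radius_mm = Inf), g,
                       noise_level = 0, seed = 1)
  expect_equal(locate_apex(bf$image), g$width_px / 2)
  # curved, apex centred
  bc <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1)
  expect_lt(abs(locate_apex(bc$image) - (g$width_px + 1) / 2), 2.5)
  # curved, apex shifted right by 100 columns
  bs <- generate_bscan(post_truth(apex_offset_px = 100), g,
                       noise_level = 0, seed = 1)
  expect_lt(abs(locate_apex(bs$image) - locate_apex(bc$image) - 100), 2.5)
  # blank image: no anterior surface
  blank <- bc$image
  blank$pixels[] <- 0
  expect_error(locate_apex(blank), class = "cornoct_detection_error")
})

test_that("flattened averaging keeps profiles as sharp as a single A-scan", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1)
  pre <- preprocess(b$image)
  profs <- build_profiles(pre)
  expect_length(profs, 2L)

  fwhm <- function(y) {
    p <- which.max(y)
    half <- y[p] / 2
    lo <- max(which(y[1:p] < half))
    hi <- p - 1 + min(which(y[p:length(y)] < half))
    # linear interpolation at the half-maximum crossings
    x1 <- lo + (half - y[lo]) / (y[lo + 1] - y[lo])
    x2 <- hi - 1 + (half - y[hi - 1]) / (y[hi] - y[hi - 1])
    x2 - x1
  }
  # reference: one A-scan of the same preprocessed image (same denoising),
  # so the only width difference left is the alignment itself
  cols <- pre$analysis_regions$left
  single_fwhm <- fwhm(pre$pixels[, cols[60]])
  for (p in profs) {
    y <- p$reflectivity
    y[!is.finite(y)] <- 0
    expect_lt(abs(fwhm(y) - single_fwhm) / single_fwhm, 0.10)
  }

  # without flattening (plain column average over a curved cornea) the
  # anterior peak smears far beyond the single-A-scan width
  unflattened <- rowMeans(pre$pixels[, cols])
  expect_gt(fwhm(unflattened), 3 * single_fwhm)
})

test_that("noiseless flat cornea: averaged profile equals a single A-scan", {
  g <- small_geom()
  b <- generate_bscan(pre_truth(anterior_radius_mm = Inf), g,
                      noise_level = 0, seed = 1)
  pre <- preprocess(b$image)
  profs <- build_profiles(pre)
  one_col <- pre$pixels[, pre$analysis_regions$left[1]]
  expect_equal(profs[[1]]$reflectivity, one_col, tolerance = 1e-8)
})

test_that("five synthetic Gaussian peaks are recovered at sub-pixel accuracy", {
  g <- small_geom()
  px_per_um <- g$group_index / axial_pitch_um(g)
  depths <- 100.3 + c(0, 54, 72, 106, 443) * px_per_um
  prof <- gaussian_profile(depths, c(1, 0.5, 0.55, 0.45, 0.7),
                           n = g$depth_px)
  iset <- detect_interfaces(prof, post_op = TRUE, geometry = g)
  got <- c(iset$air_epi_px, iset$epi_bowman_px, iset$bowman_stroma_px,
           iset$flap_px, iset$endo_aqueous_px)
  # oracle: brute-force argmax + analytic parabola in a window per peak
  oracle <- vapply(depths, function(d) {
    rows <- (floor(d) - 8):(ceiling(d) + 8)
    rows[1] - 1 + oracle_peak(prof$reflectivity[rows])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 0.2)
  expect_lt(max(abs(got - depths)), 0.2)
})

test_that("pre-operative profiles yield four interfaces and no flap", {
  g <- small_geom()
  px_per_um <- g$group_index / axial_pitch_um(g)
  depths <- 100 + c(0, 53.1, 70.1, 525.8) * px_per_um
  prof <- gaussian_profile(depths, c(1, 0.5, 0.55, 0.7), n = g$depth_px)
  iset <- detect_interfaces(prof, post_op = FALSE, geometry = g)
  expect_true(is.na(iset$flap_px))
  expect_lt(abs(iset$bowman_stroma_px - depths[3]), 0.3)
})

test_that("a corneal-less profile raises a segmentation failure", {
  g <- small_geom()
  prof <- structure(list(depth = seq_len(g$depth_px),
                         reflectivity = exp(-seq_len(g$depth_px) / 150),
                         ref_row = 1, offsets = integer(0),
                         provenance = "synthetic"),
                    class = "axial_profile")
  expect_error(detect_interfaces(prof, post_op = FALSE, geometry = g),
               class = "cornoct_segmentation_error")
  # peaks present but nothing at corneal separations
  prof2 <- gaussian_profile(c(100, 400), c(1, 0.5), n = g$depth_px)
  err <- tryCatch(detect_interfaces(prof2, post_op = FALSE, geometry = g),
                  cornoct_segmentation_error = function(e) e)
  expect_s3_class(err, "cornoct_segmentation_error")
  expect_true(length(err$qc_flags) > 0)
})

test_that("manual overrides replace flagged interfaces and keep monotonicity", {
  iset <- interface_set(100, 150, 167, 199, 514)
  expect_identical(apply_manual_override(iset, numeric(0)), iset)
  ov <- c(air_epi = 101, epi_bowman = 151, bowman_stroma = 168,
          flap = 200, endo_aqueous = 515)
  full <- apply_manual_override(iset, ov)
  expect_equal(full$flap_px, 200)
  expect_true(all(full$provenance == "manual"))
  # override only the flap, between existing neighbours
  part <- apply_manual_override(iset, c(flap = 210))
  expect_equal(part$flap_px, 210)
  expect_equal(part$epi_bowman_px, 150)
  expect_equal(unname(part$provenance["flap"]), "manual")
  expect_equal(unname(part$provenance["air_epi"]), "auto")
  # non-monotonic override rejected
  expect_error(apply_manual_override(iset, c(flap = 160)),
               class = "cornoct_validation_error")
  expect_error(interface_set(100, 90, 167, endo_aqueous_px = 514),
               class = "cornoct_validation_error")
})

test_that("end-to-end segmentation matches truth on noiseless and noisy scans", {
  g <- small_geom()
  # noiseless: sub-pixel agreement with the generator truth
  b0 <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1,
                       meta = list(visit = "1W"))
  th0 <- interfaces_to_thickness(segment_bscan(b0$image), g)
  expect_lt(abs(th0$epithelium_um - 54), 0.5)
  expect_lt(abs(th0$bowman_um - 18), 0.5)
  expect_lt(abs(th0$flap_um - 106), 0.5)
  expect_lt(abs(th0$total_um - 443), 0.5)
  # full speckle plus both artifacts
  b1 <- generate_bscan(post_truth(), g, noise_level = 1,
                       artifact_flags = c("reflex", "hbands"), seed = 2,
                       meta = list(visit = "1W"))
  th1 <- interfaces_to_thickness(segment_bscan(b1$image), g)
  expect_lt(abs(th1$epithelium_um - 54), 3)
  expect_lt(abs(th1$bowman_um - 18), 3)
  expect_lt(abs(th1$flap_um - 106), 3)
  expect_lt(abs(th1$total_um - 443), 3)
})

test_that("segmentation needs an explicit post_op flag without visit metadata", {
  g <- small_geom()
  b <- generate_bscan(post_truth(), g, noise_level = 0, seed = 1)
  expect_error(segment_bscan(b$image), class = "cornoct_validation_error")
  iset <- segment_bscan(b$image, post_op = TRUE)
  expect_false(is.na(iset$flap_px))
})
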