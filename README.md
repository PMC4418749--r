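# cornoct

Corneal sublayer segmentation and repeatability statistics for
ultra-high-resolution anterior-segment OCT.

## The problem

After thin-flap refractive surgery (sub-Bowman's keratomileusis, SBK),
clinicians track micrometre-scale changes in the central corneal
sublayers — the epithelium (~50 µm), Bowman's layer (~8–20 µm), the
surgical flap (~90–110 µm) and the total cornea (~440–530 µm). UHR-OCT
resolves these layers at ~3 µm axial resolution, but turning a B-scan
into thickness numbers requires an automated segmentation of the axial
reflectivity peaks, and the clinical claims rest on test–retest
repeatability and longitudinal statistics.

`cornoct` provides that full pipeline for R users:

* **`synthetic` module** — a seeded B-scan and cohort generator with
  exact ground truth (curved layered cornea, specular reflex, horizontal
  artifact lines, speckle), so every stage is testable without any image
  deposit: `optical_geometry()`, `cornea_truth()`, `generate_bscan()`,
  `cohort_design()`, `generate_cohort()`, TIFF/PNG + JSON I/O.
* **segmentation** — `preprocess()` (denoise, row-baseline artifact
  removal, 128-column specular-reflex exclusion), `locate_apex()`,
  `build_profiles()` (flattened averaging over two 0.5-mm flanking
  regions), `detect_interfaces()` (depth-ordered peak assignment within
  anatomical windows, sub-pixel parabolic refinement),
  `apply_manual_override()`, and the `segment_bscan()` driver.
* **thickness** — `interfaces_to_thickness()` (optical path / 1.376 →
  geometric µm), `average_scans()`, `assemble_cohort()`.
* **repeatability statistics** — for paired differences `d`:
  CoR `= 2·SD(d)`, CoR% `= CoR/overall mean × 100`, Bland–Altman
  95% LoA `= mean(d) ± 1.96·SD(d)`, and the two-way absolute-agreement
  single-measures ICC(A,1); assembled per group × layer by
  `agreement_table()`.
* **longitudinal statistics** — `visit_changes()` (repeated-measures
  ANOVA + Bonferroni post hoc paired t-tests over consecutive visits),
  `group_difference_ci()` (pooled-variance Student t interval),
  `required_sample_size()` (noncentral-t power iteration).
* **pipeline** — `run_pipeline()` orchestrates
  simulate → segment → thickness → statistics with a QC report, run log
  and deterministic CSV outputs; a thin CLI lives at
  `inst/cli/cornoct` (subcommands `simulate`, `segment`, `analyze`,
  `all`; YAML config).

## Worked example

Simulate a noisy post-operative B-scan at the instrument's native
geometry (1365 × 2048 px over 2.01 × 8.41 mm), segment it, and convert to
geometric thicknesses:

```r
library(cornoct)
g <- optical_geometry()
truth <- cornea_truth(epi_um = 54, bowman_um = 18, flap_um = 106,
                      total_um = 443)
scan <- generate_bscan(truth, g, noise_level = 1,
                       artifact_flags = c("reflex", "hbands"), seed = 42,
                       meta = list(visit = "1W"))
(iset <- segment_bscan(scan$image))
#> <interface_set> air-epi 148.49, epi-Bowman 198.88, Bowman-stroma 215.65, flap 247.44, endo 562.34 px
interfaces_to_thickness(iset, g)
#> <sublayer_thickness> epi 53.93, Bowman 17.95, flap 105.90, total 442.89 um
```

Against the simulated truth (54 / 18 / 106 / 443 µm) every layer is
recovered well inside the instrument's 3 µm axial resolution.

Repeatability of a simulated femtosecond-laser cohort (n = 21, two scans
per visit) at the one-week visit:

```r
cohort <- generate_cohort(default_cohort_design("FEMTO", seed = 1),
                          render = FALSE)$truth
class(cohort) <- c("cohort_record", "data.frame")
agreement_table(cohort, visit = "1W")
#>        layer  n m1_mean m2_mean dif_sd   icc cor_um cor_pct loa_low_um loa_high_um
#> 1 epithelium 21    52.8    52.5  1.295 0.945   2.59    4.92      -2.85        2.23
#> 2     bowman 21    17.2    17.2  0.624 0.936   1.25    7.25      -1.25        1.20
#> 3       flap 21   102.9   103.0  2.161 0.979   4.32    4.20      -4.11        4.36
#> 4      total 21   442.0   440.9  4.489 0.994   8.98    2.03      -9.84        7.76
```

Each row reads like a repeatability table: the two measurements' means,
the paired-difference SD, ICC near 1 (high reliability), CoR (twice the
difference SD — the smallest change distinguishable from measurement
noise), CoR as % of the mean, and the Bland–Altman limits of agreement.

The between-group flap comparison from group summaries (one day
post-surgery, microkeratome vs femtosecond laser):

```r
group_difference_ci(20, 95.8, 7.6, 21, 105.6, 8.2)
#>   diff_mean_um ci_low_um ci_high_um  p_value df
#> 1          9.8       4.8       14.8 0.000305 39
```

i.e. microkeratome flaps are 9.8 µm thinner (95% CI 4.8–14.8 µm).

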