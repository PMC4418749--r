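#' Coefficient of repeatability
#'
#' Twice the sample SD (denominator n - 1) of the paired differences
#' between the two repeated measurements of each subject.
#'
#' @param diffs numeric vector of paired test-retest differences, um.
#' @return CoR in um.
#' @examples
#' coefficient_of_repeatability(c(-2, 0, 2))  # sd = 2 -> CoR = 4
#' @export
coefficient_of_repeatability <- function(diffs) {
  if (length(diffs) < 2L) {
    abort_cornoct("need at least 2 paired differences",
                  "cornoct_insufficient_data_error")
  }
  2 * sample_sd(diffs)
}

#' CoR as a percentage of the overall mean
#'
#' @param cor_um coefficient of repeatability, um.
#' @param overall_mean_um mean of all first and second measurements, um.
#' @return CoR%, dimensionless percentage.
#' @export
cor_percent <- function(cor_um, overall_mean_um) {
  if (!is_scalar_number(overall_mean_um) || overall_mean_um <= 0) {
    abort_cornoct("overall mean must be > 0", "cornoct_domain_error")
  }
  cor_um / overall_mean_um * 100
}

#' Bland-Altman 95% limits of agreement
#'
#' Mean difference plus/minus 1.96 times the SD of the differences (the
#' multiplier is fixed at 1.96, not a t quantile).
#'
#' @param diffs numeric vector of paired differences, um.
#' @return Named numeric vector `c(loa_low, loa_high)`.
#' @export
limits_of_agreement <- function(diffs) {
  if (length(diffs) < 2L) {
    abort_cornoct("need at least 2 paired differences",
                  "cornoct_insufficient_data_error")
  }
  m <- mean(diffs)
  s <- sample_sd(diffs)
  c(loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Intraclass correlation coefficient, two-way absolute agreement, single
#' measures
#'
#' ICC(A,1) from the two-way mean squares of the subjects x measurements
#' table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects, `k = 2` measurements; absolute agreement penalises a
#' systematic offset between the two measurements. The `"consistency"`
#' variant (no column term) is available for comparison.
#'
#' @param m1,m2 paired measurement vectors, one value per subject.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC, a dimensionless value in (-Inf, 1].
#' @export
intraclass_correlation <- function(m1, m2, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(m1) != length(m2)) {
    abort_cornoct("m1 and m2 must be paired", "cornoct_validation_error")
  }
  n <- length(m1)
  if (n < 3L) {
    abort_cornoct("need at least 3 subjects", "cornoct_insufficient_data_error")
  }
  k <- 2
  x <- cbind(m1, m2)
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - gm)^2)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= 0) {
    abort_cornoct("zero total variance: ICC undefined", "cornoct_domain_error")
  }
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Intrasession repeatability table for one visit
#'
#' For every group x layer with complete scan pairs at `visit`, computes
#' the repeatability row: mean +/- SD of each measurement, paired
#' difference (second minus first) mean +/- SD, ICC, CoR, CoR% and the
#' Bland-Altman 95% limits of agreement. Subjects missing either scan of
#' the visit are dropped pairwise.
#'
#' @param cohort a `cohort_record` long table (subject_id, group, visit,
#'   scan_rep, layer, thickness_um).
#' @param visit visit label at which repeatability is assessed (default
#'   `"1W"`, one week after surgery).
#' @param icc_type passed to [intraclass_correlation()].
#' @return A data.frame of class `agreement_result` with one row per
#'   group x layer.
#' @export
agreement_table <- function(cohort, visit = "1W",
                            icc_type = "agreement") {
  sub <- cohort[cohort$visit == visit, , drop = FALSE]
  if (!nrow(sub)) {
    abort_cornoct(sprintf("no data at visit %s", visit),
                  "cornoct_insufficient_data_error")
  }
  layer_order <- c("epithelium", "bowman", "flap", "total")
  out <- list()
  for (g in unique(sub$group)) {
    for (l in intersect(layer_order, unique(sub$layer[sub$group == g]))) {
      d <- sub[sub$group == g & sub$layer == l, , drop = FALSE]
      w <- stats::reshape(d[c("subject_id", "scan_rep", "thickness_um")],
                          idvar = "subject_id", timevar = "scan_rep",
                          direction = "wide")
      w <- w[stats::complete.cases(w), , drop = FALSE]
      if (nrow(w) < 3L) next
      m1 <- w$thickness_um.1
      m2 <- w$thickness_um.2
      diffs <- m2 - m1
      cor_um <- coefficient_of_repeatability(diffs)
      loa <- limits_of_agreement(diffs)
      out[[paste(g, l)]] <- data.frame(
        group = g, layer = l, n = nrow(w),
        m1_mean = mean(m1), m1_sd = sample_sd(m1),
        m2_mean = mean(m2), m2_sd = sample_sd(m2),
        dif_mean = mean(diffs), dif_sd = sample_sd(diffs),
        icc = intraclass_correlation(m1, m2, icc_type),
        cor_um = cor_um,
        cor_pct = cor_percent(cor_um, mean(c(m1, m2))),
        loa_low_um = loa[["loa_low"]], loa_high_um = loa[["loa_high"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    abort_cornoct(
      sprintf("fewer than 3 complete scan pairs at visit %s", visit),
      "cornoct_insufficient_data_error")
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("agreement_result", "data.frame")
  res
}
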