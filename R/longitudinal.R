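#' Between-visit thickness changes with repeated-measures ANOVA and
#' Bonferroni post hoc tests
#'
#' Per consecutive-visit interval (`1D-PRE`, `1W-1D`, `2W-1W`, `1M-2W`;
#' the first is absent for the flap, which does not exist pre-operatively)
#' the paired change mean +/- SD is reported. An omnibus one-way
#' repeated-measures ANOVA across the visits tests for any change over
#' time; the post hoc consecutive-visit paired t-tests are Bonferroni
#' corrected over the number of intervals, with significance at
#' `alpha = 0.05`.
#'
#' Scan repetitions are averaged per visit before analysis; only subjects
#' with complete visit trajectories enter the ANOVA, and each interval's
#' paired test uses the subjects complete for that interval.
#'
#' @param cohort a `cohort_record` long table.
#' @param group group label to analyse.
#' @param layer layer to analyse (`epithelium`, `bowman`, `flap`, `total`).
#' @param alpha significance level.
#' @return A data.frame of class `change_result` with one row per
#'   interval: `change_mean`, `change_sd`, `n`, `p_value` (Bonferroni
#'   corrected), `significant`; the omnibus ANOVA p-value is attached as
#'   attribute `"anova_p"`.
#' @export
visit_changes <- function(cohort, group, layer, alpha = 0.05) {
  d <- cohort[cohort$group == group & cohort$layer == layer, , drop = FALSE]
  if (!nrow(d)) {
    abort_cornoct("no data for requested group/layer",
                  "cornoct_insufficient_data_error")
  }
  avg <- average_cohort_scans(d)
  visits <- intersect(c("PRE", "1D", "1W", "2W", "1M"), unique(avg$visit))
  if (length(visits) < 2L) {
    abort_cornoct("need at least two visits", "cornoct_insufficient_data_error")
  }

  # omnibus repeated-measures ANOVA on complete trajectories
  wide <- stats::reshape(avg[c("subject_id", "visit", "thickness_um")],
                         idvar = "subject_id", timevar = "visit",
                         direction = "wide")
  complete <- wide[stats::complete.cases(wide), , drop = FALSE]
  anova_p <- NA_real_
  if (length(visits) >= 3L && nrow(complete) >= 3L) {
    long <- data.frame(
      subject_id = factor(rep(complete$subject_id, length(visits))),
      visit = factor(rep(visits, each = nrow(complete)), levels = visits),
      thickness_um = unlist(complete[paste0("thickness_um.", visits)],
                            use.names = FALSE))
    fit <- stats::aov(thickness_um ~ visit + Error(subject_id),
                      data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    anova_p <- tab[["Pr(>F)"]][1]
  }

  intervals <- cbind(visits[-length(visits)], visits[-1])
  n_int <- nrow(intervals)
  rows <- list()
  for (i in seq_len(n_int)) {
    v1 <- intervals[i, 1]; v2 <- intervals[i, 2]
    a <- avg[avg$visit == v1, c("subject_id", "thickness_um")]
    b <- avg[avg$visit == v2, c("subject_id", "thickness_um")]
    m <- merge(a, b, by = "subject_id")
    if (nrow(m) < 3L) {
      abort_cornoct(
        sprintf("fewer than 3 complete pairs for interval %s-%s", v2, v1),
        "cornoct_insufficient_data_error")
    }
    ch <- m$thickness_um.y - m$thickness_um.x
    p_raw <- stats::t.test(ch)$p.value
    p_adj <- min(1, p_raw * n_int)
    rows[[i]] <- data.frame(
      group = group, layer = layer,
      interval = paste0(v2, "-", v1),
      change_mean = mean(ch), change_sd = sample_sd(ch), n = nrow(m),
      p_value = p_adj, significant = p_adj < alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "anova_p") <- anova_p
  class(res) <- c("change_result", "data.frame")
  res
}

#' Per-visit group summary table
#'
#' Mean +/- SD of scan-averaged thicknesses per group x layer x visit,
#' flagged for significant change from the preceding visit (from
#' [visit_changes()]).
#'
#' @param cohort a `cohort_record` long table.
#' @param alpha significance level for the change flag.
#' @return A data.frame with columns group, layer, visit, n, mean_um,
#'   sd_um, sig_vs_previous.
#' @export
visit_summary_table <- function(cohort, alpha = 0.05) {
  avg <- average_cohort_scans(cohort)
  visits <- intersect(c("PRE", "1D", "1W", "2W", "1M"), unique(avg$visit))
  rows <- list()
  for (g in unique(avg$group)) {
    for (l in intersect(c("epithelium", "bowman", "flap", "total"),
                        unique(avg$layer[avg$group == g]))) {
      ch <- tryCatch(visit_changes(cohort, g, l, alpha),
                     cornoct_error = function(e) NULL)
      for (v in visits) {
        d <- avg[avg$group == g & avg$layer == l & avg$visit == v, ]
        if (!nrow(d)) next
        sig <- FALSE
        if (!is.null(ch)) {
          hit <- ch$interval[ch$significant]
          sig <- any(startsWith(hit, paste0(v, "-")))
        }
        rows[[paste(g, l, v)]] <- data.frame(
          group = g, layer = l, visit = v, n = nrow(d),
          mean_um = mean(d$thickness_um), sd_um = sample_sd(d$thickness_um),
          sig_vs_previous = sig, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Two-group thickness difference with pooled-t confidence interval
#'
#' Independent-samples comparison from group summaries: the difference is
#' `mean2 - mean1`, the interval a pooled-variance Student t interval
#' (`"welch"` uses the Welch-Satterthwaite degrees of freedom instead),
#' and the two-sided p-value comes from the same t statistic.
#'
#' @param n1,mean1,sd1 first group's size, mean and SD.
#' @param n2,mean2,sd2 second group's size, mean and SD.
#' @param confidence confidence level (default 0.95).
#' @param method `"pooled"` (default) or `"welch"`.
#' @return A data.frame of class `group_diff_result`: `diff_mean_um`,
#'   `ci_low_um`, `ci_high_um`, `p_value`, `df`.
#' @examples
#' group_difference_ci(20, 95.8, 7.6, 21, 105.6, 8.2)  # diff 9.8 (4.8, 14.8)
#' @export
group_difference_ci <- function(n1, mean1, sd1, n2, mean2, sd2,
                                confidence = 0.95,
                                method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (n1 < 2 || n2 < 2 || sd1 <= 0 || sd2 <= 0 ||
      confidence <= 0 || confidence >= 1) {
    abort_cornoct("invalid group summaries or confidence level",
                  "cornoct_domain_error")
  }
  diff <- mean2 - mean1
  if (method == "pooled") {
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
    se <- sp * sqrt(1 / n1 + 1 / n2)
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df)
  tstat <- diff / se
  res <- data.frame(
    diff_mean_um = diff,
    ci_low_um = diff - tcrit * se, ci_high_um = diff + tcrit * se,
    p_value = 2 * stats::pt(-abs(tstat), df), df = df)
  class(res) <- c("group_diff_result", "data.frame")
  res
}

#' Minimum sample size by noncentral-t power iteration
#'
#' Smallest per-group (or per-sample) n whose achieved power under the
#' noncentral t distribution reaches the target, for a standardised effect
#' size d at significance level alpha.
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param alpha type-I error rate.
#' @param power target power.
#' @param test_family `"one_sample"` (one-sample or paired) or
#'   `"two_sample"` (per-group n).
#' @param tails 1 or 2.
#' @param n_max iteration cap; exceeding it raises a divergence error.
#' @return Integer n.
#' @examples
#' required_sample_size(1.0, 0.05, 0.95, "one_sample", tails = 1)
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.95,
                                 test_family = c("one_sample", "two_sample"),
                                 tails = 2, n_max = 1e6) {
  test_family <- match.arg(test_family)
  if (!is_scalar_number(effect_size_d) || effect_size_d <= 0 ||
      alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1 ||
      !tails %in% c(1, 2)) {
    abort_cornoct("invalid power-analysis inputs", "cornoct_domain_error")
  }
  n <- if (test_family == "one_sample") 2L else 2L
  repeat {
    df <- if (test_family == "one_sample") n - 1 else 2 * n - 2
    ncp <- if (test_family == "one_sample") effect_size_d * sqrt(n) else
      effect_size_d * sqrt(n / 2)
    if (df >= 1) {
      tcrit <- stats::qt(1 - alpha / tails, df)
      pw <- 1 - stats::pt(tcrit, df, ncp)
      if (tails == 2) pw <- pw + stats::pt(-tcrit, df, ncp)
      if (pw >= power) return(n)
    }
    n <- n + 1L
    if (n > n_max) {
      abort_cornoct("power target unattainable within iteration cap",
                    "cornoct_divergence_error")
    }
  }
}
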