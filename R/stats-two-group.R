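#' Welch t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed from group means, SDs and
#' sizes, with Welch-Satterthwaite degrees of freedom and a confidence
#' interval for the mean difference. The estimate is `m2 - m1`, so passing
#' the patient arm first and the control arm second reproduces the
#' convention of reporting control-minus-patient differences.
#'
#' \deqn{t = (m_2 - m_1) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param conf_level Confidence level for the difference (default 0.95).
#' @param label Result label.
#' @return A [test_result()] row (`method = "welch_t"`).
#' @export
#' @examples
#' # MMSE in the reference cohort: ADS 23.66 (4.30, n 29) vs controls
#' # 29.18 (1.13, n 17)
#' welch_t_summary(23.66, 4.30, 29, 29.18, 1.13, 17)$statistic
welch_t_summary <- function(m1, s1, n1, m2, s2, n2, conf_level = 0.95,
                            label = "welch_t") {
  if (n1 < 2 || n2 < 2) {
    hids_abort("both groups need n >= 2", "hids_sample_size_error")
  }
  if (s1 < 0 || s2 < 0) {
    hids_abort("SDs must be >= 0", "hids_parameter_error")
  }
  if (s1 == 0 && s2 == 0) {
    hids_abort("both group variances are zero; t is undefined",
               "hids_degenerate_error")
  }
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  est <- m2 - m1
  t_stat <- est / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  crit <- qt(1 - (1 - conf_level) / 2, df)
  test_result(
    label = label, estimate = est, statistic_name = "t",
    statistic = t_stat, df1 = df,
    ci_low = est - crit * se, ci_high = est + crit * se,
    ci_level = conf_level, p = p, method = "welch_t",
    n_used = n1 + n2
  )
}

#' Two-group test on raw values
#'
#' Compares two groups with either the Welch t-test (`engine =
#' "parametric"`, identical to [welch_t_summary()] applied to the group
#' summaries) or the Wilcoxon rank-sum test (`engine = "wilcoxon"`): exact
#' enumeration when both groups have n <= 10 and there are no ties,
#' otherwise the normal approximation with tie correction. The Wilcoxon
#' estimate and CI are the Hodges-Lehmann location shift (group 2 minus
#' group 1).
#'
#' @param values Numeric outcome vector.
#' @param groups Factor or character vector with exactly two levels aligned
#'   to `values`; the first level (alphabetical for characters) is group 1.
#' @param engine `"parametric"` or `"wilcoxon"`.
#' @param conf_level Confidence level.
#' @param label Result label.
#' @return A [test_result()] row.
#' @export
#' @examples
#' two_group_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
#'                engine = "wilcoxon")$p  # exact: 0.1
two_group_test <- function(values, groups,
                           engine = c("parametric", "wilcoxon"),
                           conf_level = 0.95, label = "two_group") {
  engine <- match.arg(engine)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) != 2) {
    hids_abort("exactly two non-empty groups are required",
               "hids_grouping_error")
  }
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    hids_abort("both groups need at least 2 non-missing values",
               "hids_grouping_error")
  }
  n_used <- length(g1) + length(g2)
  if (engine == "parametric") {
    res <- welch_t_summary(mean(g1), sd(g1), length(g1),
                           mean(g2), sd(g2), length(g2),
                           conf_level = conf_level, label = label)
    res$n_used <- as.integer(n_used)
    return(res)
  }
  ties <- anyDuplicated(values) > 0
  exact <- length(g1) <= 10 && length(g2) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(g2, g1, exact = exact, correct = !exact,
                conf.int = TRUE, conf.level = conf_level)
  )
  test_result(
    label = label, estimate = unname(wt$estimate), statistic_name = "W",
    statistic = unname(wt$statistic),
    ci_low = wt$conf.int[1], ci_high = wt$conf.int[2],
    ci_level = conf_level, p = wt$p.value, method = "wilcoxon",
    n_used = n_used
  )
}
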