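#' Partial correlation with covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed (with intercept) on the covariates. The p-value comes from
#' \eqn{t = r\sqrt{(n - k - 2)/(1 - r^2)}} with `n - k - 2` degrees of
#' freedom (k covariates). The default CI is the Fisher z interval with
#' standard error \eqn{1/\sqrt{n - k - 3}}; a seeded percentile bootstrap
#' over subjects is available as an alternative, since analytic intervals
#' can understate the uncertainty in small samples.
#'
#' With no covariates the result reduces exactly to the plain Pearson
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates aligned to
#'   `x` and `y` (columns may be factors).
#' @param ci_method `"fisher_z"` (default) or `"bootstrap"`.
#' @param conf_level CI level.
#' @param n_boot Bootstrap resamples (bootstrap CI only).
#' @param seed Seed for the bootstrap (required when `ci_method =
#'   "bootstrap"`).
#' @param label Result label.
#' @return A [test_result()] row (`method = "partial_r"`).
#' @export
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- -z + rnorm(50)
#' partial_correlation(x, y, data.frame(z = z))$estimate
partial_correlation <- function(x, y, covariates = NULL,
                                ci_method = c("fisher_z", "bootstrap"),
                                conf_level = 0.95, n_boot = 2000,
                                seed = NULL, label = "partial_r") {
  ci_method <- match.arg(ci_method)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_along(x))
  }
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  keep <- !is.na(x) & !is.na(y) &
    (if (k) complete.cases(covariates) else TRUE)
  x <- x[keep]
  y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  if (n < k + 4) {
    hids_abort("partial correlation needs n >= number of covariates + 4",
               "hids_sample_size_error")
  }
  part_r <- function(x, y, covs) {
    if (ncol(covs)) {
      mm <- model.matrix(~ ., data = covs)
      rx <- lm.fit(mm, x)$residuals
      ry <- lm.fit(mm, y)$residuals
    } else {
      rx <- x - mean(x)
      ry <- y - mean(y)
    }
    if (sd(rx) == 0 || sd(ry) == 0) {
      hids_abort("zero residual variance; partial correlation undefined",
                 "hids_degenerate_error")
    }
    cor(rx, ry)
  }
  r <- part_r(x, y, covariates)
  df <- n - k - 2
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df)

  if (ci_method == "fisher_z") {
    if (n - k - 3 <= 0) {
      ci <- c(NA_real_, NA_real_)
    } else {
      z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
      hw <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - k - 3)
      ci <- tanh(c(z - hw, z + hw))
    }
  } else {
    if (is.null(seed)) {
      hids_abort("the bootstrap CI requires a seed", "hids_parameter_error")
    }
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, replace = TRUE)
        tryCatch(part_r(x[idx], y[idx], covariates[idx, , drop = FALSE]),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2), na.rm = TRUE))
  }
  test_result(
    label = label, estimate = r, statistic_name = "r", statistic = t_stat,
    df1 = df, ci_low = ci[1], ci_high = ci[2], ci_level = conf_level,
    p = p, method = "partial_r", n_used = n
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control: sorted p-values are scaled by
#' `m / rank`, made monotone non-increasing from the largest down, capped at
#' 1 and returned in the input order. Output is elementwise >= input; the
#' single-value family is the identity. (BH is not idempotent, so adjusted
#' values should not be re-adjusted.) Delegates to [stats::p.adjust()] after
#' validating the domain.
#'
#' @param pvalues Numeric vector in \[0, 1\] (`NA` allowed, kept `NA`).
#' @return Adjusted p-values, same order and length.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.049, 0.05))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) {
    hids_abort("p-values must be numeric", "hids_domain_error")
  }
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) {
    hids_abort("p-values must lie in [0, 1]", "hids_domain_error")
  }
  p.adjust(pvalues, method = "BH")
}
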