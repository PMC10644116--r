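#' Residualize volumes on intracranial volume
#'
#' For every volume column (the ten subfield volumes and the two
#' whole-hippocampus volumes) fits ordinary least squares
#' `volume ~ intercept + ICV` on the chosen fit scope and replaces the
#' column by the residuals for *all* subjects: a controls-only fit still
#' adjusts patients using the control-fitted line. Residuals are not
#' re-centered (pure residual method), so adjusted values can be negative.
#'
#' @param dataset Subject tibble (canonical schema).
#' @param fit_scope `"all"` (default) fits the ICV regression on every
#'   subject; `"controls_only"` fits on controls and applies the line to
#'   everyone. The choice matters when disease alters the ICV-volume
#'   coupling; both are exposed because the right scope is study-specific.
#' @return The dataset with volume columns replaced by residuals (mm^3
#'   residual units) and an `icv_fit` attribute: a tibble of per-column
#'   slope, intercept and scope.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(seed = 7))
#' adj <- icv_adjust(cohort)
#' attr(adj, "icv_fit")[1:2, ]
icv_adjust <- function(dataset, fit_scope = c("all", "controls_only")) {
  fit_scope <- match.arg(fit_scope)
  in_scope <- if (fit_scope == "all") rep(TRUE, nrow(dataset)) else
    dataset$group == "control"
  icv <- dataset$icv_mm3
  scope_icv <- icv[in_scope]
  if (sum(in_scope) < 3) {
    hids_abort("ICV adjustment needs at least 3 subjects in the fit scope",
               "hids_sample_size_error")
  }
  if (var(scope_icv) == 0) {
    hids_abort("ICV has zero variance within the fit scope; design is degenerate",
               "hids_degenerate_design_error")
  }
  fits <- list()
  out <- dataset
  for (col in all_volume_columns()) {
    v <- dataset[[col]]
    fit <- lm(v[in_scope] ~ scope_icv)
    b <- coef(fit)
    out[[col]] <- v - (b[[1]] + b[[2]] * icv)
    fits[[col]] <- tibble::tibble(column = col, intercept = b[[1]],
                                  slope = b[[2]], fit_scope = fit_scope)
  }
  attr(out, "icv_fit") <- dplyr::bind_rows(fits)
  out
}

#' Composite cognitive domain score
#'
#' Arithmetic mean of the available (non-missing) test-level z-scores that
#' make up one cognitive domain for one participant. If every test is
#' missing, the composite is missing (`NA`), never zero.
#'
#' @param test_z Numeric vector of demographically normed test z-scores for
#'   one subject and domain; `NA` marks an unadministered test.
#' @return The composite z-score with attribute `n_available` (tests
#'   averaged); `NA` with `n_available = 0` when no test is available.
#' @export
#' @examples
#' composite_domain_score(c(0.5, NA, -0.5, 1.0))
composite_domain_score <- function(test_z) {
  if (!is.numeric(test_z)) {
    hids_abort("test z-scores must be numeric", "hids_parameter_error")
  }
  present <- test_z[!is.na(test_z)]
  score <- if (length(present)) mean(present) else NA_real_
  attr(score, "n_available") <- length(present)
  score
}

#' Normalize values to the control group
#'
#' Control-referenced z-scores:
#' \eqn{z_i = (x_i - \bar{x}_{ctl}) / s_{ctl}} with the sample SD
#' (denominator n-1) of the control values.
#'
#' @param values Numeric vector to standardize (any subjects).
#' @param control_values Numeric vector of control-group values (>= 2
#'   non-missing, SD > 0).
#' @return Numeric vector of z-scores, same length as `values`.
#' @export
#' @examples
#' normalize_to_controls(1 + sqrt(2), c(0, 2))
normalize_to_controls <- function(values, control_values) {
  ctl <- control_values[!is.na(control_values)]
  if (length(ctl) < 2) {
    hids_abort("need at least 2 control values", "hids_sample_size_error")
  }
  s <- sd(ctl)
  if (s == 0) {
    hids_abort("control SD is zero; cannot standardize",
               "hids_degenerate_scale_error")
  }
  (values - mean(ctl)) / s
}
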