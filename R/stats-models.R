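#' Shapiro-Wilk residual normality check
#'
#' Gate used to route each model to a parametric or nonparametric engine:
#' residuals are called normal when the Shapiro-Wilk p-value is at least
#' `alpha`. Degenerate residual vectors (zero variance) are reported
#' non-normal with an undefined W.
#'
#' @param residuals Numeric vector, 3 <= n <= 5000.
#' @param alpha Gate level (default 0.05).
#' @return List: `W`, `p`, `is_normal`, `degenerate`.
#' @export
residual_normality <- function(residuals, alpha = 0.05) {
  residuals <- residuals[!is.na(residuals)]
  n <- length(residuals)
  if (n < 3 || n > 5000) {
    hids_abort("Shapiro-Wilk requires 3 <= n <= 5000",
               "hids_sample_size_error")
  }
  if (var(residuals) == 0) {
    return(list(W = NA_real_, p = NA_real_, is_normal = FALSE,
                degenerate = TRUE))
  }
  sw <- shapiro.test(residuals)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= alpha, degenerate = FALSE)
}

#' Sequential covariate selection over the age/sex/education ladder
#'
#' Starting from the base model `outcome ~ primary`, candidate covariates
#' are offered strictly in the fixed ladder order (age, then sex, then
#' education). Each step is kept only if the nested-model F-test against the
#' current accepted model is significant at `alpha`; the ladder stops at the
#' first non-significant step, so the selected covariates are always a
#' prefix of the ladder. A covariate that is constant (or otherwise makes
#' the design rank deficient) is skipped with a warning rather than aborting
#' the ladder. The accepted model's residuals are then gated with
#' [residual_normality()] to choose the inference engine: `parametric` when
#' normal, otherwise `wilcoxon` for covariate-free group models and
#' `permutation` when covariates are present.
#'
#' @param data Data frame containing all columns.
#' @param outcome Outcome column name.
#' @param primary Primary predictor column name (group factor or a
#'   continuous score such as HiDs).
#' @param candidates Covariate ladder, in order.
#' @param alpha Significance level for each nested F-test.
#' @return A `hids_model_spec` list: `outcome`, `primary`, `covariates`,
#'   `residuals_normal`, `shapiro_w`, `shapiro_p`, `engine`, `n_used`, and
#'   the accepted `model` (an `lm` fit).
#' @export
covariate_selection <- function(data, outcome, primary,
                                candidates = c("age", "sex", "education"),
                                alpha = 0.05) {
  used_cols <- c(outcome, primary, intersect(candidates, names(data)))
  cc <- complete.cases(data[, used_cols])
  d <- as.data.frame(data[cc, used_cols])
  if (is.character(d[[primary]])) d[[primary]] <- factor(d[[primary]])
  n <- nrow(d)
  max_pars <- 2 + length(candidates)
  if (n <= max_pars + 2) {
    hids_abort("too few complete cases for the covariate ladder",
               "hids_sample_size_error")
  }
  current <- lm(reformulate(primary, outcome), data = d)
  covs <- character()
  for (cand in candidates) {
    if (!cand %in% names(d)) next
    x <- d[[cand]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning(sprintf("covariate `%s` is constant; skipped", cand),
              call. = FALSE)
      next
    }
    candidate_fit <- lm(reformulate(c(primary, covs, cand), outcome),
                        data = d)
    if (candidate_fit$rank <= current$rank) {
      warning(sprintf("covariate `%s` is collinear with the current model; skipped",
                      cand), call. = FALSE)
      next
    }
    cmp <- anova(current, candidate_fit)
    p_step <- cmp$`Pr(>F)`[2]
    if (is.na(p_step) || p_step >= alpha) break
    current <- candidate_fit
    covs <- c(covs, cand)
  }
  gate <- residual_normality(residuals(current))
  engine <- if (isTRUE(gate$is_normal)) "parametric"
  else if (length(covs) == 0) "wilcoxon"
  else "permutation"
  structure(
    list(outcome = outcome, primary = primary, covariates = covs,
         residuals_normal = isTRUE(gate$is_normal),
         shapiro_w = gate$W, shapiro_p = gate$p,
         engine = engine, n_used = n, model = current),
    class = "hids_model_spec"
  )
}

#' ANCOVA group test
#'
#' Ordinary least squares `outcome ~ group + covariates`. Reports the
#' partial F for the group term (1 numerator df, obtained by comparing the
#' covariate-only model against the full model), the group coefficient (the
#' second group level minus the first) with its 95% CI, and the F-test
#' p-value. With no covariates the F statistic equals the squared
#' pooled-variance t statistic exactly.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param group Group column name (coerced to a factor; make `control` the
#'   first level to report patient-minus-control effects).
#' @param covariates Character vector of covariate column names.
#' @param conf_level CI level.
#' @param label Result label.
#' @return A [test_result()] row (`method = "ancova"`).
#' @export
group_ancova <- function(data, outcome, group, covariates = character(),
                         conf_level = 0.95, label = outcome) {
  used <- c(outcome, group, covariates)
  d <- as.data.frame(data[complete.cases(data[, used]), used])
  if (is.character(d[[group]])) d[[group]] <- factor(d[[group]])
  full <- lm(reformulate(c(group, covariates), outcome), data = d)
  if (full$rank < length(covariates) + nlevels(d[[group]])) {
    hids_abort("singular design in ANCOVA", "hids_design_error")
  }
  reduced <- lm(
    if (length(covariates)) reformulate(covariates, outcome)
    else reformulate("1", outcome),
    data = d
  )
  cmp <- anova(reduced, full)
  f_stat <- cmp$F[2]
  df1 <- cmp$Df[2]
  df2 <- cmp$Res.Df[2]
  p <- cmp$`Pr(>F)`[2]
  coef_name <- grep(paste0("^", group), names(coef(full)), value = TRUE)[1]
  est <- coef(full)[[coef_name]]
  ci <- confint(full, coef_name, level = conf_level)
  test_result(
    label = label, estimate = est, statistic_name = "F", statistic = f_stat,
    df1 = df1, df2 = df2, ci_low = ci[1], ci_high = ci[2],
    ci_level = conf_level, p = p, method = "ancova", n_used = nrow(d)
  )
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    block <- cbind(k, matrix(rest[sub], nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Permutation test for a linear-model coefficient
#'
#' Fits `formula` by OLS and compares the t statistic of one coefficient
#' against its distribution under random permutation of the outcome vector
#' (simple permutation scheme). The Monte Carlo p-value is
#' \eqn{(1 + \#\{|t_b| \ge |t_{obs}|\}) / (B + 1)} and is deterministic
#' given `seed`. With `exact = TRUE` (n <= 8) all n! permutations are
#' enumerated and the p-value is the exact tail proportion.
#'
#' @param formula Model formula; the outcome is permuted, the design held
#'   fixed.
#' @param data Data frame.
#' @param coef Name of the coefficient of interest as it appears in the
#'   fitted model (e.g. `"groupADS"`).
#' @param B Number of permutations (>= 99; default 5000).
#' @param seed Integer seed, required for the Monte Carlo path.
#' @param exact Enumerate all permutations instead of sampling.
#' @param conf_level CI level for the (parametric) coefficient CI, reported
#'   descriptively alongside the permutation p.
#' @param label Result label.
#' @return A [test_result()] row (`method = "permutation_lm"`); `statistic`
#'   is the observed t, `p` the permutation p-value.
#' @export
permutation_lm <- function(formula, data, coef, B = 5000, seed = NULL,
                           exact = FALSE, conf_level = 0.95,
                           label = "permutation_lm") {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  n <- nrow(X)
  k <- ncol(X)
  if (qr(X)$rank < k) {
    hids_abort("design matrix is rank deficient", "hids_design_error")
  }
  if (!coef %in% colnames(X)) {
    hids_abort(sprintf("coefficient `%s` is not in the design (have: %s)",
                       coef, paste(colnames(X), collapse = ", ")),
               "hids_parameter_error")
  }
  if (!exact) {
    if (B < 99) {
      hids_abort("B must be at least 99 for a stable permutation p-value",
                 "hids_parameter_error")
    }
    if (is.null(seed)) {
      hids_abort("a seed is required for Monte Carlo permutation",
                 "hids_parameter_error")
    }
  } else if (n > 8) {
    hids_abort("exact enumeration is limited to n <= 8", "hids_parameter_error")
  }

  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)           # k x n projector to coefficients
  j <- match(coef, colnames(X))
  t_of <- function(Y) {          # Y: n x B matrix of outcomes
    betas <- H %*% Y
    fit <- X %*% betas
    rss <- colSums((Y - fit)^2)
    se <- sqrt(rss / (n - k) * XtXinv[j, j])
    betas[j, ] / se
  }
  t_obs <- t_of(matrix(y, ncol = 1))[1]

  if (exact) {
    perms <- all_permutations(n)
    Yp <- matrix(y[t(perms)], nrow = n)
    t_perm <- t_of(Yp)
    p <- mean(abs(t_perm) >= abs(t_obs) - 1e-12)
    B_used <- nrow(perms)
  } else {
    t_perm <- withr::with_seed(as.integer(seed), {
      Yp <- vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n))
      t_of(Yp)
    })
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (B + 1)
    B_used <- B
  }
  fit_lm <- lm(formula, data)
  ci <- confint(fit_lm, coef, level = conf_level)
  res <- test_result(
    label = label, estimate = coef(fit_lm)[[coef]], statistic_name = "t",
    statistic = t_obs, df1 = n - k, ci_low = ci[1], ci_high = ci[2],
    ci_level = conf_level, p = p, method = "permutation_lm", n_used = n
  )
  attr(res, "B") <- B_used
  res
}

#' Moderation (interaction) test
#'
#' OLS of `y ~ x * moderator + covariates` with `x` and any continuous
#' moderator mean-centered before the product term is formed. Reports the
#' interaction coefficient with CI and p.
#'
#' @param data Data frame.
#' @param y,x,moderator Column names; the moderator may be binary (factor or
#'   two-level character) or continuous.
#' @param covariates Additional covariate column names.
#' @param conf_level CI level.
#' @param label Result label.
#' @return A [test_result()] row (`method = "moderation"`); `estimate` is
#'   the interaction beta.
#' @export
moderation_test <- function(data, y, x, moderator, covariates = character(),
                            conf_level = 0.95,
                            label = paste0(y, "~", x, "x", moderator)) {
  used <- c(y, x, moderator, covariates)
  d <- as.data.frame(data[complete.cases(data[, used]), used])
  d[[x]] <- d[[x]] - mean(d[[x]])
  m <- d[[moderator]]
  if (is.character(m) || is.factor(m)) {
    m <- factor(m)
    if (nlevels(m) < 2) {
      hids_abort("moderator has fewer than two observed levels",
                 "hids_design_error")
    }
    d[[moderator]] <- m
  } else {
    d[[moderator]] <- m - mean(m)
  }
  form <- reformulate(c(paste(x, "*", moderator), covariates), y)
  fit <- lm(form, data = d)
  if (any(is.na(coef(fit)))) {
    hids_abort("singular design in moderation model", "hids_design_error")
  }
  int_name <- grep(":", names(coef(fit)), value = TRUE)[1]
  est <- coef(fit)[[int_name]]
  se <- sqrt(diag(vcov(fit)))[[int_name]]
  df <- fit$df.residual
  t_stat <- est / se
  p <- 2 * pt(-abs(t_stat), df)
  ci <- confint(fit, int_name, level = conf_level)
  test_result(
    label = label, estimate = est, statistic_name = "beta",
    statistic = t_stat, df1 = df, ci_low = ci[1], ci_high = ci[2],
    ci_level = conf_level, p = p, method = "moderation", n_used = nrow(d)
  )
}
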