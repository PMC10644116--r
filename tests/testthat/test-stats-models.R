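test_that("residual_normality gates on Shapiro-Wilk at alpha = 0.05", {
  withr::with_seed(2, {
    g <- residual_normality(rnorm(100))
    expect_true(g$is_normal)
    expect_equal(g$W, unname(shapiro.test(withr::with_seed(2, rnorm(100)))$statistic))
    bad <- residual_normality(rexp(100))
    expect_false(bad$is_normal)
  })
  deg <- residual_normality(rep(1, 20))
  expect_false(deg$is_normal)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$W))
  expect_error(residual_normality(c(1, 2)), class = "hids_sample_size_error")
})

test_that("Shapiro gate has nominal size and good power at n = 100", {
  withr::with_seed(31, {
    null_rej <- mean(vapply(1:500, function(i) {
      !residual_normality(rnorm(100))$is_normal
    }, logical(1)))
    exp_rej <- mean(vapply(1:200, function(i) {
      !residual_normality(rexp(100))$is_normal
    }, logical(1)))
  })
  expect_gt(null_rej, 0.02)
  expect_lt(null_rej, 0.08)
  expect_gt(exp_rej, 0.95)
})

test_that("covariate ladder keeps the base model under the null and finds real covariates", {
  sim_select <- function(seed, age_beta) {
    withr::with_seed(seed, {
      d <- data.frame(
        group = factor(rep(c("control", "ADS"), each = 100), levels = c("control", "ADS")),
        age = rnorm(200, 70, 6),
        sex = sample(c("f", "m"), 200, TRUE),
        education = rnorm(200, 15, 3)
      )
      d$y <- age_beta * d$age + rnorm(200, sd = if (age_beta > 0) 0.1 else 1)
      covariate_selection(d, "y", "group")$covariates
    })
  }
  base_kept <- vapply(1:300, function(s) {
    length(sim_select(s, 0)) == 0
  }, logical(1))
  expect_gte(mean(base_kept), 0.90)

  age_found <- vapply(1:100, function(s) {
    "age" %in% sim_select(1000 + s, 2)
  }, logical(1))
  expect_gte(mean(age_found), 0.99)
})

test_that("selected covariates are a ladder prefix; constant covariates are skipped", {
  withr::with_seed(9, {
    d <- data.frame(
      group = factor(rep(c("control", "ADS"), each = 60), levels = c("control", "ADS")),
      age = rnorm(120, 70, 6),
      sex = "f", # constant: rank-deficient candidate
      education = rnorm(120, 15, 3)
    )
    d$y <- 0.5 * d$age + 0.8 * d$education + rnorm(120, sd = 0.5)
    expect_warning(spec <- covariate_selection(d, "y", "group"), "constant")
    expect_true(all(spec$covariates %in% c("age", "education")))
    expect_equal(spec$covariates[1], "age")
    expect_s3_class(spec$model, "lm")
    expect_true(spec$engine %in% c("parametric", "wilcoxon", "permutation"))
  })
  # empty candidate list -> base model trivially
  withr::with_seed(10, {
    d <- data.frame(group = factor(rep(c("a", "b"), each = 20)),
                    y = rnorm(40))
    spec <- covariate_selection(d, "y", "group", candidates = character())
    expect_equal(spec$covariates, character())
  })
})

test_that("ANCOVA F without covariates equals the squared pooled t exactly", {
  withr::with_seed(12, {
    d <- data.frame(group = factor(rep(c("control", "ADS"), c(17, 29)), levels = c("control", "ADS")),
                    y = rnorm(46, sd = 2))
    r <- group_ancova(d, "y", "group")
    tt <- t.test(y ~ group, data = d, var.equal = TRUE)
    expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(r$df1, 1)
    expect_equal(r$df2, 44)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    # estimate is ADS minus control (second level minus first)
    expect_equal(r$estimate,
                 mean(d$y[d$group == "ADS"]) - mean(d$y[d$group == "control"]),
                 tolerance = 1e-12)
  })
})

test_that("ANCOVA recovers a known group effect with a real covariate", {
  withr::with_seed(13, {
    d <- data.frame(group = factor(rep(c("control", "ADS"), each = 100), levels = c("control", "ADS")),
                    age = rnorm(200, 70, 6))
    d$y <- 10 * (d$group == "ADS") + d$age + rnorm(200)
    r <- group_ancova(d, "y", "group", "age")
    expect_lt(abs(r$estimate - 10), 0.5)
    expect_lt(r$ci_high - r$ci_low, 1)
    expect_lt(r$p, 1e-10)
    expect_error(group_ancova(within(d, age2 <- age), "y", "group",
                              c("age", "age2")),
                 class = "hids_design_error")
  })
})

test_that("permutation_lm is seed-deterministic and validates B", {
  withr::with_seed(14, {
    d <- data.frame(x = rnorm(30))
    d$y <- 0.8 * d$x + rnorm(30)
  })
  r1 <- permutation_lm(y ~ x, d, "x", B = 499, seed = 5)
  r2 <- permutation_lm(y ~ x, d, "x", B = 499, seed = 5)
  expect_identical(r1$p, r2$p)
  r3 <- permutation_lm(y ~ x, d, "x", B = 499, seed = 6)
  expect_true(abs(r3$p - r1$p) < 0.05) # same inference, different draw
  expect_error(permutation_lm(y ~ x, d, "x", B = 50, seed = 1),
               class = "hids_parameter_error")
  expect_error(permutation_lm(y ~ x, d, "x", B = 499),
               class = "hids_parameter_error")
  expect_error(permutation_lm(y ~ x, d, "nope", B = 499, seed = 1),
               class = "hids_parameter_error")
})

test_that("exhaustive permutation reaches the exact attainable minimum", {
  d <- data.frame(g = rep(c(0, 1), each = 4),
                  y = c(1, 2, 3, 4, 10, 11, 12, 13))
  r <- permutation_lm(y ~ g, d, "g", exact = TRUE)
  # perfectly separated 4/4 split: 2 of the C(8,4)=70 assignments tie |t|
  expect_equal(r$p, 2 / 70, tolerance = 1e-12)
  expect_equal(attr(r, "B"), factorial(8))
})

test_that("permutation p agrees with the parametric p under Gaussian errors", {
  withr::with_seed(15, {
    d <- data.frame(x = rnorm(100))
    d$y <- 0.25 * d$x + rnorm(100)
  })
  fit <- lm(y ~ x, d)
  p_param <- summary(fit)$coefficients["x", 4]
  r <- permutation_lm(y ~ x, d, "x", B = 10000, seed = 99)
  expect_lt(abs(r$p - p_param), 0.02)
})

test_that("moderation_test recovers constructed interactions and errors on degenerate moderators", {
  withr::with_seed(16, {
    d <- data.frame(x = rnorm(50), m = rnorm(50))
    d$y <- d$x * d$m # pure interaction, no noise (perfect-fit warning expected)
    r <- suppressWarnings(moderation_test(d, "y", "x", "m"))
    expect_equal(r$estimate, 1, tolerance = 1e-8)
    expect_lt(r$p, 1e-20)
  })
  d2 <- data.frame(x = rnorm(30), m = rep("AD", 30), y = rnorm(30))
  expect_error(moderation_test(d2, "y", "x", "m"),
               class = "hids_design_error")
})

test_that("bh_adjust reproduces hand step-up values and its invariants", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.049, 0.05)), c(0.015, 0.05, 0.05))
  withr::with_seed(17, {
    for (i in 1:25) {
      p <- runif(sample(1:12, 1))^sample(1:3, 1)
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      # monotone: sorting by p never decreases the adjusted values
      expect_true(all(diff(adj[order(p)]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "hids_domain_error")
  expect_error(bh_adjust("a"), class = "hids_domain_error")
})

test_that("partial_correlation reduces to Pearson and matches the closed form", {
  withr::with_seed(18, {
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    plain <- partial_correlation(x, y)
    expect_equal(plain$estimate, cor(x, y), tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(plain$p, ct$p.value, tolerance = 1e-10)
    expect_equal(partial_correlation(x, x + 0 * y)$estimate, 1,
                 tolerance = 1e-12)
    for (i in 1:50) {
      z <- rnorm(50)
      x2 <- 0.4 * z + rnorm(50)
      y2 <- -0.3 * z + rnorm(50)
      r <- partial_correlation(x2, y2, data.frame(z = z))
      expect_equal(r$estimate, oracle_partial_r_1cov(x2, y2, z),
                   tolerance = 1e-10)
    }
  })
})

test_that("partial_correlation CIs behave and the bootstrap is seeded", {
  withr::with_seed(19, {
    z <- rnorm(60)
    x <- z + rnorm(60)
    y <- -z - 0.8 * x + rnorm(60)
    covs <- data.frame(z = z)
    fz <- partial_correlation(x, y, covs)
    expect_true(fz$ci_low < fz$estimate && fz$estimate < fz$ci_high)
    b1 <- partial_correlation(x, y, covs, ci_method = "bootstrap",
                              n_boot = 500, seed = 3)
    b2 <- partial_correlation(x, y, covs, ci_method = "bootstrap",
                              n_boot = 500, seed = 3)
    expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
    expect_error(partial_correlation(x, y, covs, ci_method = "bootstrap"),
                 class = "hids_parameter_error")
  })
  expect_error(partial_correlation(rep(1, 20), rnorm(20)),
               class = "hids_degenerate_error")
  expect_error(partial_correlation(rnorm(4), rnorm(4), data.frame(z = rnorm(4))),
               class = "hids_sample_size_error")
})
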