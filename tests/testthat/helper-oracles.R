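# Independent oracles, deliberately naive implementations.

# brute-force double-loop Euclidean cross-distance
oracle_distance_matrix <- function(patients, controls) {
  out <- matrix(0, nrow(patients), ncol = nrow(controls))
  for (i in seq_len(nrow(patients))) {
    for (j in seq_len(nrow(controls))) {
      out[i, j] <- sqrt(sum((patients[i, ] - controls[j, ])^2))
    }
  }
  dimnames(out) <- list(rownames(patients), rownames(controls))
  out
}

# hand step-up BH: sort, scale by m/i, enforce monotonicity from the top, cap
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    scaled[i] <- min(scaled[i], scaled[i + 1])
  }
  adj <- pmin(scaled, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# single-covariate partial correlation, closed form
oracle_partial_r_1cov <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# random profile matrix with canonical labels
random_profiles <- function(n, labels, prefix = "s") {
  m <- matrix(rnorm(n * length(labels), sd = 50), n,
              dimnames = list(paste0(prefix, seq_len(n)), labels))
  m
}

whole_labels <- function() {
  as.vector(vapply(hids_subfields(),
                   function(sf) paste(sf, c("L", "R"), sep = "_"),
                   character(2)))
}

# small, fast cohort for structural tests
small_params <- function(seed = 1, ...) {
  cohort_params(n_ads = 12, n_controls = 8, seed = seed, ...)
}

# zero-effect (null) parameters: no atrophy, no cognitive coupling
null_params <- function(seed = 1, n_ads = 20, n_controls = 20) {
  cohort_params(
    n_ads = n_ads, n_controls = n_controls,
    atrophy_effect = setNames(numeric(5), hids_subfields()),
    cognition_loadings = setNames(numeric(7), cognitive_domains()),
    thickness_mean = c(ads = 2.5, control = 2.5),
    age_mean = c(ads = 71, control = 71),
    age_sd = c(ads = 5, control = 5),
    education_mean = c(ads = 16, control = 16),
    education_sd = c(ads = 2.8, control = 2.8),
    sex_prop_f = c(ads = 0.5, control = 0.5),
    seed = seed
  )
}
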