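#' Generate a synthetic case-control cohort
#'
#' Draws one cohort from the generative model described in
#' [cohort_params()]. Controls have latent severity 0; each ADS participant
#' receives a half-normal severity \eqn{s_i} that simultaneously shrinks the
#' atrophied subfield volumes and lowers the cognitive scores, so atrophy
#' and cognitive impairment share a single cause. Volumes are coupled to
#' intracranial volume through the configured elasticity, cortical thickness
#' and amyloid SUVr are drawn independently of severity, and SUVr is emitted
#' for ADS participants only.
#'
#' Generation is deterministic given `(params, seed)`. The returned tibble
#' carries a `provenance` attribute recording the parameters and seed so
#' that cohorts generated with the same seed but different parameters remain
#' distinguishable.
#'
#' @param params A `hids_cohort_params` object from [cohort_params()].
#' @param seed Optional integer overriding `params$seed`.
#' @return A tibble in the canonical subject-table schema (see
#'   [subject_table_columns()]), one row per subject, with an additional
#'   hidden column `latent_severity` (the generating severity, for
#'   validation studies) and a `provenance` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(seed = 42))
#' table(cohort$group)
generate_cohort <- function(params, seed = NULL) {
  if (!inherits(params, "hids_cohort_params")) {
    hids_abort("`params` must be created by cohort_params()",
               "hids_parameter_error")
  }
  validate_cohort_params(params)
  if (!is.null(seed)) params$seed <- as.integer(seed)

  n_ads <- params$n_ads
  n_ctl <- params$n_controls
  n <- n_ads + n_ctl
  grp <- c(rep("ADS", n_ads), rep("control", n_ctl))
  arm <- ifelse(grp == "ADS", "ads", "control")

  cohort <- withr::with_seed(params$seed, {
    subgroup <- rep(NA_character_, n)
    amci_idx <- sample.int(n_ads, params$n_amci)
    subgroup[seq_len(n_ads)] <- "AD"
    subgroup[amci_idx] <- "aMCI"

    age <- rnorm(n, params$age_mean[arm], params$age_sd[arm])
    sex <- ifelse(runif(n) < params$sex_prop_f[arm], "f", "m")
    education <- pmax(6, round(rnorm(n, params$education_mean[arm],
                                     params$education_sd[arm])))
    icv <- rnorm(n, params$icv_mean, params$icv_sd)

    severity <- c(abs(rnorm(n_ads, 0, params$severity_sd)), rep(0, n_ctl))
    u <- rnorm(n, 0, params$subject_scale_sd)
    icv_dev <- params$icv_slope * (icv - params$icv_mean) / params$icv_mean

    ce <- params$covariate_effects
    age_c <- age - mean(params$age_mean)
    # bilateral-total demographic offsets are split by subfield share and
    # hemisphere so the configured slope applies to the whole-hippocampus sum
    demo_total <- ce$age_volume * age_c + ce$sex_volume * (sex == "m")
    share <- params$subfield_means / sum(params$subfield_means)

    vols <- list()
    for (sf in hids_subfields()) {
      mult <- pmax(1 - params$atrophy_effect[[sf]] * severity,
                   params$atrophy_floor)
      for (h in hids_hemispheres()) {
        e <- rnorm(n, 0, params$subfield_cv)
        v <- params$subfield_means[[sf]] * mult * (1 + u + icv_dev + e) +
          demo_total * share[[sf]] / 2
        vols[[volume_column(sf, h)]] <- pmax(v, 0.1)
      }
    }
    vol_tbl <- as_tibble(vols)
    whole_l <- rowSums(vol_tbl[, volume_column(hids_subfields(), "L")])
    whole_r <- rowSums(vol_tbl[, volume_column(hids_subfields(), "R")])

    cog <- list()
    demo_cog <- ce$age_cognition * age_c +
      ce$education_cognition * (education - mean(params$education_mean))
    for (dom in cognitive_domains()) {
      raw <- params$cognition_intercepts[[dom]] -
        params$cognition_loadings[[dom]] * severity +
        rnorm(n, 0, params$cognition_noise_sd[[dom]]) + demo_cog
      if (dom %in% c("mmse", "moca")) raw <- pmin(pmax(round(raw), 0), 30)
      cog[[dom]] <- raw
    }

    thickness <- pmax(0.5, rnorm(n, params$thickness_mean[arm],
                                 params$thickness_sd[arm]))
    suvr <- ifelse(grp == "ADS",
                   rnorm(n, params$suvr_mean, params$suvr_sd), NA_real_)

    out <- tibble::tibble(
      id = sprintf("S%03d", seq_len(n)),
      group = grp,
      subgroup = subgroup,
      age = round(age, 1),
      sex = sex,
      education = as.numeric(education),
      icv_mm3 = icv
    )
    out <- dplyr::bind_cols(out, vol_tbl)
    out$whole_hipp_l_mm3 <- whole_l
    out$whole_hipp_r_mm3 <- whole_r
    out$cortical_thickness_mm <- thickness
    out$amyloid_suvr <- suvr
    for (dom in cognitive_domains()) out[[dom]] <- cog[[dom]]
    out$latent_severity <- severity

    if (params$missing_rate > 0 && length(params$missing_fields)) {
      for (col in params$missing_fields) {
        drop <- runif(n) < params$missing_rate
        out[[col]][drop] <- NA_real_
      }
    }
    out
  })

  attr(cohort, "provenance") <- list(
    source = "synthetic",
    seed = params$seed,
    params = params,
    generated_by = "hidscore::generate_cohort"
  )
  cohort
}
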