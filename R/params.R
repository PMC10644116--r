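#' Reference cohort summary statistics
#'
#' Group-level summary statistics (mean, SD, n per arm) of the reference
#' amyloid-stratified case-control cohort that the default simulator
#' parameters reproduce: 29 participants on the Alzheimer's disease spectrum
#' (ADS; 12 aMCI, 17 probable AD) and 17 amyloid-negative controls. The
#' `est` column carries the published Welch t statistic for each group
#' comparison, where available, so it can be recomputed from the summaries
#' with [welch_t_summary()].
#'
#' Whole-hippocampus values are the bilateral subfield totals after
#' intracranial-volume adjustment; cognitive composites are z-scores against
#' demographically matched norms.
#'
#' @return A tibble with one row per measure: `measure`, `ads_mean`,
#'   `ads_sd`, `ads_n`, `control_mean`, `control_sd`, `control_n`, `est`.
#' @export
#' @examples
#' s <- reference_group_summaries()
#' m <- s[s$measure == "mmse", ]
#' welch_t_summary(m$ads_mean, m$ads_sd, m$ads_n,
#'                 m$control_mean, m$control_sd, m$control_n)
reference_group_summaries <- function() {
  tibble::tribble(
    ~measure,            ~ads_mean, ~ads_sd, ~ads_n, ~control_mean, ~control_sd, ~control_n, ~est,
    "age",                   70.00,    6.12,     29,         73.00,        3.71,         17, 1.83,
    "education",             15.10,    2.69,     29,         16.24,        2.86,         17, 1.32,
    "mmse",                  23.66,    4.30,     29,         29.18,        1.13,         17, 6.55,
    "imm_recall",            -2.12,    0.82,     29,          0.56,        0.73,         17, NA,
    "del_recall",            -2.25,    0.76,     29,          0.26,        0.55,         17, NA,
    "moca",                  18.83,    5.10,     29,         27.50,        1.73,         17, 8.09,
    "verbal_fluency",        -1.13,    0.99,     29,          0.23,        0.80,         17, 4.67,
    "processing_speed",      -1.01,    1.32,     29,          0.77,        0.82,         17, 5.65,
    "attention_exec",        -0.94,    0.99,     29,          0.55,        0.57,         17, 6.48,
    "whole_hippocampus",    922.00,  395.00,     29,       1455.00,      257.00,         17, 5.53,
    "cortical_thickness",     2.40,    0.39,     29,          2.55,        0.44,         17, 4.07
  )
}

# Fixed per-hemisphere allocation of the whole-hippocampus mean across
# subfields. The reference cohort publishes no subfield-level means, so these
# shares are engineering constants (CA1 largest, CA2 smallest, consistent
# with the typical subfield size ordering), not published values.
subfield_allocation <- function() {
  c(CA1 = 0.40, CA2 = 0.03, CA3 = 0.07, DG = 0.30, SUB = 0.20)
}

#' Construct simulator parameters for a synthetic case-control cohort
#'
#' The defaults encode the reference cohort of
#' [reference_group_summaries()]: 29 ADS vs 17 control participants, a
#' bilateral whole-hippocampus total of 1455 (SD 257) mm^3 in controls and
#' 922 (SD 395) mm^3 in ADS, atrophy restricted to CA1, DG and SUB, and
#' cognitive scores coupled to a single half-normal latent severity so that
#' group means match the reference values.
#'
#' The generative model for a raw volume of subject i, subfield f,
#' hemisphere h is
#' \deqn{v_{ifh} = m_f \max(1 - a_f s_i, \mathrm{floor})
#'       (1 + u_i + \beta \delta_i + e_{ifh})}
#' where \eqn{m_f} is the control per-hemisphere mean, \eqn{a_f} the
#' fractional atrophy effect, \eqn{s_i \ge 0} the latent severity (0 for
#' controls, half-normal for ADS), \eqn{u_i} a per-subject scale factor,
#' \eqn{\delta_i} the relative ICV deviation with elasticity \eqn{\beta}
#' (`icv_slope`) and \eqn{e_{ifh}} per-cell noise. Cognitive scores are
#' `intercept - loading * s + noise`; MMSE/MoCA are rounded and clamped to
#' \[0, 30\].
#'
#' @param n_ads,n_controls Group sizes (each at least 2).
#' @param icv_mean,icv_sd Intracranial volume distribution, mm^3.
#' @param whole_mean_control Target control mean of the bilateral subfield
#'   total, mm^3.
#' @param subfield_props Named shares (CA1, CA2, CA3, DG, SUB) allocating the
#'   per-hemisphere whole-hippocampus mean across subfields; must sum to 1.
#' @param atrophy_effect Named fractional volume reduction per unit severity
#'   for each subfield, values in \[0, 1). `NULL` solves the CA1/DG/SUB
#'   fraction from the reference whole-hippocampus group gap.
#' @param severity_sd Scale of the half-normal latent severity in ADS.
#' @param atrophy_floor Lower bound on the atrophy multiplier, keeping raw
#'   volumes positive.
#' @param subject_scale_sd SD of the per-subject common scale factor.
#' @param subfield_cv Relative SD of the per-cell volume noise.
#' @param icv_slope Dimensionless ICV elasticity of volumes (allometric
#'   coupling): a 1% larger ICV scales every volume by `icv_slope` percent.
#' @param cognition_loadings Named weight per cognitive domain on the latent
#'   severity (score units per severity unit). `NULL` solves each loading
#'   from the reference group mean gap.
#' @param cognition_noise_sd Named per-domain residual SD; defaults to the
#'   reference control-arm SDs.
#' @param covariate_effects List of slopes used to inject demographic
#'   confounding: `age_volume` (mm^3 of bilateral total per year of age),
#'   `sex_volume` (mm^3 offset for males), `age_cognition` and
#'   `education_cognition` (score units per year, applied to every domain).
#'   All default to 0: composites are demographically normed upstream and
#'   the reference groups are matched.
#' @param thickness_mean,thickness_sd Named (`ads`, `control`) global
#'   cortical thickness parameters, mm. Thickness is independent of latent
#'   severity by design.
#' @param suvr_mean,suvr_sd Amyloid SUVr distribution, emitted for ADS only
#'   and independent of severity by default.
#' @param age_mean,age_sd,education_mean,education_sd Named (`ads`,
#'   `control`) demographic distributions.
#' @param sex_prop_f Named (`ads`, `control`) probability of female sex.
#' @param n_amci Number of ADS participants labelled aMCI (the rest are AD);
#'   labels are assigned independently of severity.
#' @param missing_rate Missing-at-random dropout probability applied to
#'   `missing_fields`.
#' @param missing_fields Columns subject to dropout (cognition and SUVr
#'   columns only).
#' @param seed Integer seed; generation is deterministic given
#'   `(params, seed)`.
#' @return A `hids_cohort_params` list, validated.
#' @seealso [generate_cohort()], [default_params_from_table1()]
#' @export
cohort_params <- function(n_ads = 29L,
                          n_controls = 17L,
                          icv_mean = 1.5e6,
                          icv_sd = 1.5e5,
                          whole_mean_control = 1455,
                          subfield_props = subfield_allocation(),
                          atrophy_effect = NULL,
                          severity_sd = 1,
                          atrophy_floor = 0.02,
                          subject_scale_sd = 0.151,
                          subfield_cv = 0.20,
                          icv_slope = 0.5,
                          cognition_loadings = NULL,
                          cognition_noise_sd = NULL,
                          covariate_effects = list(age_volume = 0,
                                                   sex_volume = 0,
                                                   age_cognition = 0,
                                                   education_cognition = 0),
                          thickness_mean = c(ads = 2.40, control = 2.55),
                          thickness_sd = c(ads = 0.39, control = 0.44),
                          suvr_mean = 1.40,
                          suvr_sd = 0.20,
                          age_mean = c(ads = 70, control = 73),
                          age_sd = c(ads = 6.12, control = 3.71),
                          education_mean = c(ads = 15.10, control = 16.24),
                          education_sd = c(ads = 2.69, control = 2.86),
                          sex_prop_f = c(ads = 14 / 29, control = 6 / 17),
                          n_amci = NULL,
                          missing_rate = 0,
                          missing_fields = character(),
                          seed = 1L) {
  ref <- reference_group_summaries()
  e_s <- severity_sd * sqrt(2 / pi)  # mean of a half-normal

  subfield_means <- (whole_mean_control / 2) * subfield_props

  if (is.null(atrophy_effect)) {
    whole <- ref[ref$measure == "whole_hippocampus", ]
    gap <- whole$control_mean - whole$ads_mean
    affected <- c("CA1", "DG", "SUB")
    a <- gap / (e_s * 2 * sum(subfield_means[affected]))
    atrophy_effect <- setNames(numeric(5), hids_subfields())
    atrophy_effect[affected] <- a
  }

  cog <- ref[ref$measure %in% cognitive_domains(), ]
  intercepts <- setNames(cog$control_mean, cog$measure)
  if (is.null(cognition_loadings)) {
    cognition_loadings <- setNames(
      (cog$control_mean - cog$ads_mean) / e_s, cog$measure
    )
  }
  if (is.null(cognition_noise_sd)) {
    cognition_noise_sd <- setNames(cog$control_sd, cog$measure)
  }
  if (is.null(n_amci)) {
    n_amci <- max(0L, min(n_ads, round(n_ads * 12 / 29)))
  }

  params <- structure(
    list(
      n_ads = as.integer(n_ads),
      n_controls = as.integer(n_controls),
      icv_mean = icv_mean, icv_sd = icv_sd,
      subfield_means = subfield_means,
      atrophy_effect = atrophy_effect,
      severity_sd = severity_sd,
      atrophy_floor = atrophy_floor,
      subject_scale_sd = subject_scale_sd,
      subfield_cv = subfield_cv,
      icv_slope = icv_slope,
      cognition_intercepts = intercepts,
      cognition_loadings = cognition_loadings,
      cognition_noise_sd = cognition_noise_sd,
      covariate_effects = covariate_effects,
      thickness_mean = thickness_mean, thickness_sd = thickness_sd,
      suvr_mean = suvr_mean, suvr_sd = suvr_sd,
      age_mean = age_mean, age_sd = age_sd,
      education_mean = education_mean, education_sd = education_sd,
      sex_prop_f = sex_prop_f,
      n_amci = as.integer(n_amci),
      missing_rate = missing_rate,
      missing_fields = missing_fields,
      seed = as.integer(seed)
    ),
    class = "hids_cohort_params"
  )
  validate_cohort_params(params)
  params
}

#' Default simulator parameters for the reference cohort
#'
#' Convenience wrapper returning [cohort_params()] with all defaults: group
#' sizes 29/17, control whole-hippocampus 1455 (SD 257) mm^3, ADS target
#' 922 mm^3, atrophy confined to CA1, DG and SUB, and cognitive loadings
#' matched to the reference group mean gaps.
#'
#' @return A `hids_cohort_params` object.
#' @export
#' @examples
#' p <- default_params_from_table1()
#' p$n_ads
#' p$atrophy_effect
default_params_from_table1 <- function() cohort_params()

validate_cohort_params <- function(params) {
  fail <- function(field, why) {
    hids_abort(sprintf("invalid cohort parameter `%s`: %s", field, why),
               "hids_parameter_error")
  }
  if (!is.numeric(params$n_ads) || params$n_ads < 2) {
    fail("n_ads", "must be at least 2 (distances to controls need >= 2 patients' worth of data)")
  }
  if (!is.numeric(params$n_controls) || params$n_controls < 2) {
    fail("n_controls", "must be at least 2")
  }
  sds <- c(icv_sd = params$icv_sd, subject_scale_sd = params$subject_scale_sd,
           subfield_cv = params$subfield_cv, severity_sd = params$severity_sd,
           suvr_sd = params$suvr_sd)
  for (nm in names(sds)) {
    if (!is.finite(sds[[nm]]) || sds[[nm]] < 0) fail(nm, "SDs must be >= 0")
  }
  if (!all(is.finite(params$subfield_means)) || any(params$subfield_means <= 0)) {
    fail("subfield_means", "control subfield means must all be > 0")
  }
  if (!setequal(names(params$atrophy_effect), hids_subfields())) {
    fail("atrophy_effect", "must be named by the five subfields")
  }
  if (any(params$atrophy_effect < 0 | params$atrophy_effect >= 1)) {
    fail("atrophy_effect", "fractional reductions must lie in [0, 1)")
  }
  if (params$missing_rate < 0 || params$missing_rate >= 1) {
    fail("missing_rate", "must lie in [0, 1)")
  }
  allowed_missing <- c(cognitive_domains(), "amyloid_suvr")
  if (length(params$missing_fields) &&
      !all(params$missing_fields %in% allowed_missing)) {
    fail("missing_fields", "dropout is supported for cognition and SUVr columns only")
  }
  if (params$n_amci < 0 || params$n_amci > params$n_ads) {
    fail("n_amci", "must lie between 0 and n_ads")
  }
  invisible(params)
}

#' Read simulator parameters from a flat YAML file
#'
#' The file is a flat key-value document whose keys mirror the arguments of
#' [cohort_params()]; absent keys keep their defaults. Named vector
#' arguments (e.g. `atrophy_effect`) are given as YAML mappings.
#'
#' @param path Path to a YAML file.
#' @return A validated `hids_cohort_params` object.
#' @export
cohort_params_from_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    hids_abort("reading YAML parameter files requires the 'yaml' package",
               "hids_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    hids_abort(sprintf("unknown parameter key(s): %s",
                       paste(unknown, collapse = ", ")),
               "hids_parameter_error")
  }
  vecs <- c("subfield_props", "atrophy_effect", "cognition_loadings",
            "cognition_noise_sd", "thickness_mean", "thickness_sd",
            "age_mean", "age_sd", "education_mean", "education_sd",
            "sex_prop_f")
  for (nm in intersect(names(raw), vecs)) raw[[nm]] <- unlist(raw[[nm]])
  do.call(cohort_params, raw)
}
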