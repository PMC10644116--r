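#' Build subfield profile vectors
#'
#' Assembles one ordered profile vector per subject from ICV-adjusted
#' bilateral subfield volumes. The label order is canonical and enforced:
#' subfields in the order CA1, CA2, CA3, DG, SUB (restricted to the
#' requested set), left hemisphere before right. Subjects missing any
#' requested value are excluded (no imputation) and reported.
#'
#' @param adjusted Tibble from [icv_adjust()] (or any subject table with the
#'   canonical volume columns).
#' @param subfields Subset of [hids_subfields()] to include; the
#'   whole-profile default yields length-10 vectors, a single subfield a
#'   length-2 (L, R) vector.
#' @return Numeric matrix, one row per retained subject (rownames = subject
#'   id), columns labelled `"CA1_L"`, `"CA1_R"`, ... Attribute `excluded` is
#'   a tibble (`id`, `reason`) of dropped subjects.
#' @export
build_profiles <- function(adjusted, subfields = hids_subfields()) {
  if (length(subfields) == 0) {
    hids_abort("at least one subfield is required", "hids_parameter_error")
  }
  subfields <- match.arg(subfields, hids_subfields(), several.ok = TRUE)
  subfields <- hids_subfields()[hids_subfields() %in% subfields]
  cols <- volume_columns(subfields)
  labels <- as.vector(vapply(
    subfields, function(sf) paste(sf, hids_hemispheres(), sep = "_"),
    character(2)
  ))
  mat <- as.matrix(adjusted[, cols])
  colnames(mat) <- labels
  rownames(mat) <- adjusted$id
  keep <- complete.cases(mat)
  excluded <- tibble::tibble(
    id = adjusted$id[!keep],
    reason = vapply(which(!keep), function(i) {
      paste("missing", paste(labels[is.na(mat[i, ])], collapse = ", "))
    }, character(1))
  )
  if (nrow(excluded)) {
    message(sprintf("build_profiles: excluded %d subject(s) with missing volumes: %s",
                    nrow(excluded), paste(excluded$id, collapse = ", ")))
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Patient-to-control Euclidean distance matrix
#'
#' Computes the N x M matrix of Euclidean distances between every patient
#' profile (rows) and every control profile (columns),
#' \eqn{d_{nm} = \sqrt{\sum_k (x_{nk} - y_{mk})^2}}. Profiles must share an
#' identical label order; a mismatch is an error, never a silent reorder.
#'
#' @param patients,controls Profile matrices from [build_profiles()] with
#'   identical column labels.
#' @return N x M numeric matrix with patient ids as rownames and control ids
#'   as colnames; all entries >= 0 (mm^3 units).
#' @export
#' @examples
#' p <- matrix(c(0, 0), 1, dimnames = list("pat", c("CA1_L", "CA1_R")))
#' c1 <- matrix(c(3, 4), 1, dimnames = list("ctl", c("CA1_L", "CA1_R")))
#' distance_matrix(p, c1)  # 3-4-5 triangle: 5
distance_matrix <- function(patients, controls) {
  if (!is.matrix(patients)) patients <- as.matrix(patients)
  if (!is.matrix(controls)) controls <- as.matrix(controls)
  if (nrow(patients) < 1 || nrow(controls) < 1) {
    hids_abort("need at least one patient and one control profile",
               "hids_parameter_error")
  }
  if (is.null(colnames(patients)) || is.null(colnames(controls)) ||
      !identical(colnames(patients), colnames(controls))) {
    hids_abort("profile label order differs between patients and controls; refusing to reorder",
               "hids_alignment_error")
  }
  # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y, clamped against roundoff
  sq <- outer(rowSums(patients^2), rowSums(controls^2), `+`) -
    2 * patients %*% t(controls)
  dm <- sqrt(pmax(sq, 0))
  dimnames(dm) <- list(rownames(patients), rownames(controls))
  dm
}

#' Degeneration scores from a distance matrix
#'
#' The hippocampal degeneration score (HiDs) of a patient is the arithmetic
#' mean of their Euclidean distances to all M control profiles: the row
#' means of the patient-by-control distance matrix.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param scope Label recorded with the scores: `"whole_profile"` or a
#'   subfield code.
#' @return Tibble `id`, `scope`, `hids` (mm^3 units, >= 0).
#' @export
hids_from_matrix <- function(dm, scope = "whole_profile") {
  if (ncol(dm) < 1) {
    hids_abort("distance matrix needs at least one control column",
               "hids_parameter_error")
  }
  tibble::tibble(
    id = rownames(dm),
    scope = scope,
    hids = unname(rowMeans(dm))
  )
}

#' Compute degeneration scores for a subfield set
#'
#' Composition of [build_profiles()], [distance_matrix()] and
#' [hids_from_matrix()]: profiles are built on the requested subfields, ADS
#' subjects take the patient role and controls the reference role, and each
#' patient's HiDs is the mean distance to all controls. Patients are never
#' compared to themselves.
#'
#' @param adjusted ICV-adjusted subject tibble (must contain `group`).
#' @param subfields Subfield subset; the default whole profile uses all five.
#' @param scope Scope label; defaults to `"whole_profile"` for the full set
#'   or the subfield code for a singleton.
#' @param scale Optional per-feature standardization (z-scaling columns to
#'   the control mean/SD) before the distance. OFF by default: the score is
#'   defined on ICV-adjusted volumes in their native units, so larger
#'   subfields carry more weight by construction.
#' @return Tibble `id`, `scope`, `hids` for the ADS subjects, with the
#'   distance matrix in attribute `distance_matrix`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(seed = 1))
#' adj <- icv_adjust(cohort)
#' head(compute_hids(adj))
compute_hids <- function(adjusted, subfields = hids_subfields(),
                         scope = NULL, scale = FALSE) {
  if (is.null(scope)) {
    scope <- if (length(subfields) == length(hids_subfields()))
      "whole_profile" else paste(subfields, collapse = "+")
  }
  profiles <- build_profiles(adjusted, subfields)
  grp <- setNames(adjusted$group, adjusted$id)[rownames(profiles)]
  pat <- profiles[grp == "ADS", , drop = FALSE]
  ctl <- profiles[grp == "control", , drop = FALSE]
  if (scale) {
    mu <- colMeans(ctl)
    s <- apply(ctl, 2, sd)
    if (any(s == 0)) {
      hids_abort("control SD is zero for a profile feature; cannot z-scale",
                 "hids_degenerate_scale_error")
    }
    pat <- sweep(sweep(pat, 2, mu), 2, s, `/`)
    ctl <- sweep(sweep(ctl, 2, mu), 2, s, `/`)
  }
  dm <- distance_matrix(pat, ctl)
  out <- hids_from_matrix(dm, scope = scope)
  attr(out, "distance_matrix") <- dm
  out
}

#' Per-subfield degeneration scores
#'
#' Recomputes HiDs from a single subfield's bilateral (L, R) values, the
#' per-subfield variant of the whole-profile score.
#'
#' @param adjusted ICV-adjusted subject tibble.
#' @param subfield One subfield code.
#' @inheritParams compute_hids
#' @return Tibble `id`, `scope` (= subfield), `hids`.
#' @export
subfield_hids <- function(adjusted, subfield, scale = FALSE) {
  subfield <- match.arg(subfield, hids_subfields())
  compute_hids(adjusted, subfields = subfield, scope = subfield,
               scale = scale)
}

#' Leave-one-out control degeneration scores
#'
#' Places each control in the patient role against the remaining controls,
#' giving a null reference distribution for the degeneration score. Used by
#' calibration checks; not part of the patient-facing analysis.
#'
#' @param adjusted ICV-adjusted subject tibble.
#' @param subfields Subfield subset.
#' @return Tibble `id`, `scope`, `hids`, one row per control.
#' @export
control_pseudo_hids <- function(adjusted, subfields = hids_subfields()) {
  profiles <- build_profiles(adjusted, subfields)
  grp <- setNames(adjusted$group, adjusted$id)[rownames(profiles)]
  ctl <- profiles[grp == "control", , drop = FALSE]
  if (nrow(ctl) < 2) {
    hids_abort("leave-one-out control scores need at least 2 controls",
               "hids_sample_size_error")
  }
  scope <- if (length(subfields) == length(hids_subfields()))
    "whole_profile" else paste(subfields, collapse = "+")
  rows <- lapply(seq_len(nrow(ctl)), function(i) {
    dm <- distance_matrix(ctl[i, , drop = FALSE], ctl[-i, , drop = FALSE])
    tibble::tibble(id = rownames(ctl)[i], scope = scope,
                   hids = unname(rowMeans(dm)))
  })
  dplyr::bind_rows(rows)
}
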