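#' Canonical subject-table columns
#'
#' The wide one-row-per-subject schema used throughout: identifiers and
#' demographics, intracranial volume, ten bilateral subfield volumes, the
#' two whole-hippocampus volumes, global cortical thickness, amyloid SUVr
#' (ADS only, may be absent) and seven cognitive scores. Decimal point,
#' UTF-8, RFC 4180 CSV.
#'
#' @return Character vector of required column names, in canonical order.
#' @export
subject_table_columns <- function() {
  c("id", "group", "subgroup", "age", "sex", "education", "icv_mm3",
    volume_columns(), "whole_hipp_l_mm3", "whole_hipp_r_mm3",
    "cortical_thickness_mm", "amyloid_suvr", cognitive_domains())
}

all_volume_columns <- function() {
  c(volume_columns(), "whole_hipp_l_mm3", "whole_hipp_r_mm3")
}

#' Read and validate a subject table
#'
#' Reads a wide CSV/TSV subject table, optionally renaming foreign headers
#' through `col_map`, checks the schema and enforces the record invariants:
#' positive raw volumes and ICV, MMSE/MoCA within \[0, 30\], recognised
#' group/sex codes, and subgroup present exactly for ADS rows. Rows that
#' violate an invariant are dropped with a row-addressed diagnostic
#' (returned in the `diagnostics` attribute and raised as a warning); the
#' reader never imputes, so absent optional cells stay `NA`.
#'
#' @param path File to read.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's actual headers, e.g. `c(icv_mm3 = "ICV")`.
#' @return A validated tibble of subject records with attribute
#'   `diagnostics` (a tibble: `row`, `id`, `field`, `problem`).
#' @export
read_subject_table <- function(path, dialect = c("csv", "tsv"),
                               col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    hids_abort(sprintf("file not found: %s", path), "hids_io_error")
  }
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  tbl <- suppressWarnings(
    reader(path, show_col_types = FALSE, progress = FALSE,
           na = c("", "NA"), col_types = readr::cols(.default = readr::col_guess()))
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(tbl)) {
        names(tbl)[names(tbl) == col_map[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(subject_table_columns(), names(tbl))
  # amyloid_suvr may be wholly absent (e.g. a controls-only table)
  missing_cols <- setdiff(missing_cols, "amyloid_suvr")
  if (length(missing_cols)) {
    hids_abort(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "hids_schema_error")
  }
  if (!"amyloid_suvr" %in% names(tbl)) tbl$amyloid_suvr <- NA_real_

  numeric_cols <- c("age", "education", "icv_mm3", all_volume_columns(),
                    "cortical_thickness_mm", "amyloid_suvr",
                    cognitive_domains())
  for (col in numeric_cols) {
    if (!is.numeric(tbl[[col]])) {
      parsed <- suppressWarnings(as.numeric(tbl[[col]]))
      bad <- which(!is.na(tbl[[col]]) & is.na(parsed))
      if (length(bad)) {
        hids_abort(sprintf("non-numeric value in column `%s`, row(s) %s",
                           col, paste(head(bad, 5), collapse = ", ")),
                   "hids_parse_error")
      }
      tbl[[col]] <- parsed
    }
  }
  tbl$id <- as.character(tbl$id)
  if (anyDuplicated(tbl$id)) {
    hids_abort(sprintf("duplicate subject id(s): %s",
                       paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", ")),
               "hids_integrity_error")
  }
  validate_dataset(tbl[, subject_table_columns()])
}

# row-level invariant checks; drops offending rows with diagnostics
validate_dataset <- function(tbl) {
  diags <- list()
  note <- function(rows, field, problem) {
    if (length(rows)) {
      diags[[length(diags) + 1]] <<- tibble::tibble(
        row = rows, id = tbl$id[rows], field = field, problem = problem
      )
    }
  }
  note(which(!tbl$group %in% c("ADS", "control")), "group",
       "unrecognized group label")
  note(which(tbl$group == "ADS" & !tbl$subgroup %in% c("aMCI", "AD")),
       "subgroup", "ADS rows require subgroup aMCI or AD")
  note(which(tbl$group == "control" & !is.na(tbl$subgroup)), "subgroup",
       "control rows must have no subgroup")
  note(which(!is.na(tbl$sex) & !tbl$sex %in% c("f", "m")), "sex",
       "sex must be 'f' or 'm'")
  note(which(!is.na(tbl$icv_mm3) & tbl$icv_mm3 <= 0), "icv_mm3",
       "range: ICV must be > 0")
  for (col in all_volume_columns()) {
    note(which(!is.na(tbl[[col]]) & tbl[[col]] <= 0), col,
         "range: raw volumes must be > 0")
  }
  for (col in c("mmse", "moca")) {
    note(which(!is.na(tbl[[col]]) & (tbl[[col]] < 0 | tbl[[col]] > 30)),
         col, "range: score must lie in [0, 30]")
  }
  diags <- if (length(diags)) dplyr::bind_rows(diags) else
    tibble::tibble(row = integer(), id = character(),
                   field = character(), problem = character())
  bad_rows <- sort(unique(diags$row))
  if (length(bad_rows)) {
    warning(sprintf(
      "rejected %d row(s) violating record invariants: %s",
      length(bad_rows),
      paste(sprintf("row %d [%s: %s]", diags$row, diags$field, diags$problem),
            collapse = "; ")
    ), call. = FALSE)
    tbl <- tbl[-bad_rows, ]
  }
  attr(tbl, "diagnostics") <- diags
  tbl
}

#' Write a subject table
#'
#' Writes the canonical wide CSV; absent values become empty cells.
#'
#' @param dataset Subject tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- intersect(subject_table_columns(), names(dataset))
  readr::write_csv(dataset[, cols], path, na = "")
  invisible(path)
}

# -- TestResult ---------------------------------------------------------------

#' Construct a test-result row
#'
#' The common currency for every fitted comparison: estimate, statistic,
#' degrees of freedom, confidence interval, p and (after family-wise
#' adjustment) BH-adjusted p, plus a method tag so result tables are
#' self-describing.
#'
#' @param label Human-readable model label.
#' @param estimate Effect estimate in outcome units (mean difference, group
#'   coefficient, correlation, interaction beta ...).
#' @param statistic_name One of `"t"`, `"F"`, `"W"`, `"r"`, `"beta"`.
#' @param statistic Test statistic value.
#' @param df1,df2 Degrees of freedom (scalar statistics use `df1`).
#' @param ci_low,ci_high Confidence bounds for `estimate`.
#' @param ci_level Confidence level, e.g. `0.95`.
#' @param p Two-sided p-value.
#' @param p_adj BH-adjusted p, `NA` until adjusted.
#' @param method One of `"welch_t"`, `"pooled_t"`, `"wilcoxon"`, `"ancova"`,
#'   `"permutation_lm"`, `"partial_r"`, `"moderation"`.
#' @param n_used Number of complete-case observations used.
#' @return One-row tibble.
#' @export
test_result <- function(label, estimate, statistic_name, statistic,
                        df1 = NA_real_, df2 = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_level = 0.95, p, p_adj = NA_real_, method,
                        n_used) {
  statistic_name <- match.arg(statistic_name, c("t", "F", "W", "r", "beta"))
  method <- match.arg(method, c("welch_t", "pooled_t", "wilcoxon", "ancova",
                                "permutation_lm", "partial_r", "moderation"))
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  tibble::tibble(
    label = label, estimate = estimate, statistic_name = statistic_name,
    statistic = statistic, df1 = df1, df2 = df2,
    ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
    p = p, p_adj = p_adj, method = method, n_used = as.integer(n_used)
  )
}

results_columns <- function() {
  c("label", "estimate", "statistic_name", "statistic", "df1", "df2",
    "ci_low", "ci_high", "ci_level", "p", "p_adj", "method", "n_used")
}

#' Write a results table
#'
#' One row per test result, fixed column order (`label`, `estimate`,
#' `statistic_name`, `statistic`, `df1`, `df2`, `ci_low`, `ci_high`,
#' `ci_level`, `p`, `p_adj`, `method`, `n_used`, then any extra columns such
#' as `family`). Floats are serialized at 6 significant digits; absent
#' values become empty cells, never the string "NaN".
#'
#' @param path Output CSV path.
#' @param results Tibble of [test_result()] rows (extra columns allowed).
#' @return `path`, invisibly.
#' @export
write_results <- function(path, results) {
  if (is.null(results) || nrow(results) == 0) {
    hids_abort("results must be non-empty", "hids_parameter_error")
  }
  extra <- setdiff(names(results), results_columns())
  out <- results[, c(results_columns(), extra)]
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 6)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path CSV path.
#' @return Tibble of results.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}
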