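#' Univariate data checks for biomarker and inflammation columns
#'
#' The pre-adjustment checks: per-column counts of missing, zero and
#' below-detection values, the range, and the lowest decile (10th
#' percentile, linear-interpolation "type 7" definition). When `group` is
#' given, the internal lowest deciles of AGP and CRP are compared with the
#' external reference deciles and the 20% rule decides which reference the
#' adjustment should use (see [choose_reference()]). Heuristic unit warnings
#' fire when the AGP median falls outside 0.1-5 g/L or the CRP median
#' outside 0.01-200 mg/L; unit errors cannot be detected mechanically, so
#' these warn but never fail.
#'
#' @param data A data frame with one row per participant.
#' @param columns Character vector of column names to summarise; default all
#'   numeric columns.
#' @param lod Named list or vector mapping column names to lower limits of
#'   detection; columns without an entry get `n_below_lod = NA`.
#' @param group Optional `"PSC"` or `"WRA"`; enables the reference decision.
#' @param agp_col,crp_col Names of the inflammation marker columns (units
#'   g/L and mg/L), used for the reference decision and unit heuristics.
#' @return A list of class `"qc_summary"`: `$columns` (per-column tibble),
#'   `$reference` (per-marker decision tibble or `NULL`), `$warnings`
#'   (character vector of unit warnings, also raised as R warnings).
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 200, seed = 1))
#' qc_summary(svy, group = "PSC")
qc_summary <- function(data, columns = NULL, lod = list(), group = NULL,
                       agp_col = "agp", crp_col = "crp") {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) rlang::abort("Cannot summarise an empty table.")
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(columns) == 0L) rlang::abort("No numeric columns to summarise.")
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("Columns not found: ", paste(missing_cols, collapse = ", ")))
  }

  summarise_col <- function(col) {
    x <- data[[col]]
    ok <- x[!is.na(x)]
    if (length(ok) == 0L) {
      rlang::abort(paste0("Column '", col, "' has no nonmissing values."))
    }
    col_lod <- if (col %in% names(lod)) as.numeric(lod[[col]]) else NA_real_
    tibble::tibble(
      column = col,
      n = length(x),
      n_missing = sum(is.na(x)),
      n_zero = sum(ok == 0),
      n_below_lod = if (is.na(col_lod)) NA_integer_ else sum(ok < col_lod),
      lod = col_lod,
      min = min(ok),
      max = max(ok),
      median = stats::median(ok),
      lowest_decile = unname(stats::quantile(ok, 0.10, type = 7))
    )
  }
  cols <- purrr::map_dfr(columns, summarise_col)

  warnings <- character()
  warn_unit <- function(col, lo, hi, unit) {
    if (col %in% cols$column) {
      med <- cols$median[cols$column == col]
      if (med < lo || med > hi) {
        msg <- sprintf(
          "Median %s = %.3g lies outside the plausible range [%g, %g] %s; check units.",
          col, med, lo, hi, unit)
        warnings <<- c(warnings, msg)
        rlang::warn(msg)
      }
    }
  }
  warn_unit(agp_col, 0.1, 5, "g/L")
  warn_unit(crp_col, 0.01, 200, "mg/L")

  reference <- NULL
  if (!is.null(group)) {
    grp <- normalize_group(group)
    ext <- external_reference(grp)
    decide <- function(col, ext_ref, marker) {
      if (!col %in% cols$column) return(NULL)
      internal <- cols$lowest_decile[cols$column == col]
      dplyr::mutate(choose_reference(internal, ext_ref), marker = marker,
                    .before = 1)
    }
    reference <- dplyr::bind_rows(
      decide(agp_col, ext$agp_ref, "AGP"),
      decide(crp_col, ext$crp_ref, "CRP")
    )
  }

  structure(list(columns = cols, reference = reference, warnings = warnings),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("Pre-adjustment data checks\n")
  print(x$columns, ...)
  if (!is.null(x$reference)) {
    cat("\nReference decile decision (20% rule):\n")
    print(x$reference, ...)
  }
  if (length(x$warnings) > 0) {
    cat("\nWarnings:\n")
    cat(paste0("  - ", x$warnings, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Single random imputation of values below the limit of detection
#'
#' Values censored by the assay's lower limit of detection are commonly
#' recorded as 0 or as the LoD itself; a log transform of either is wrong or
#' undefined. Each censored value is replaced by one uniform draw strictly
#' inside (0, lod). Single random imputation is the recommended default for
#' CRP below the LoD; users with their own multiply-imputed values can
#' supply them instead and skip this step.
#'
#' @param values Numeric vector (concentrations).
#' @param lod Positive lower limit of detection, in the units of `values`.
#' @param censored Optional logical vector flagging which entries are
#'   censored. Default: entries strictly below `lod` (which captures values
#'   recorded as 0). Set `at_lod = TRUE` to also treat values recorded
#'   exactly at the LoD as censored.
#' @param at_lod Also flag values equal to `lod` (default `FALSE`).
#' @param seed Optional integer; fixes the draw for reproducibility without
#'   disturbing the caller's RNG stream.
#' @return `values` with censored entries replaced; `NA`s untouched.
#' @export
#' @examples
#' impute_below_lod(c(0, 0.5, 2, NA), lod = 0.05, seed = 42)
impute_below_lod <- function(values, lod, censored = NULL, at_lod = FALSE,
                             seed = NULL) {
  if (!is.numeric(lod) || length(lod) != 1L || is.na(lod) || lod <= 0) {
    rlang::abort("lod must be a single positive number.")
  }
  if (is.null(censored)) {
    censored <- !is.na(values) & (values < lod | (at_lod & values == lod))
  }
  stopifnot(is.logical(censored), length(censored) == length(values))
  censored <- censored & !is.na(values)
  n_cens <- sum(censored)
  if (n_cens == 0L) return(values)
  draw <- function() {
    repeat {
      u <- stats::runif(n_cens, min = 0, max = lod)
      if (all(u > 0 & u < lod)) return(u)  # guard the open-interval contract
    }
  }
  values[censored] <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  values
}

#' Choose between external and internal reference deciles (20% rule)
#'
#' If the internal lowest decile of an inflammation marker differs from the
#' external reference decile by more than 20% (relative to the external
#' value, the fixed benchmark), the internal decile is used for the
#' adjustment; otherwise the external reference is kept. The decision is
#' made per marker, independently.
#'
#' @param internal_decile Positive internal 10th percentile of the marker.
#' @param external_ref Positive external reference decile.
#' @param tolerance Relative-difference threshold, default 0.20.
#' @return A one-row tibble: `value` (the reference to use), `source`
#'   (`"external"` or `"internal"`), `internal_decile`, `external_ref`,
#'   `relative_difference`.
#' @export
#' @examples
#' choose_reference(0.60, 0.59)  # within 20%: external kept
#' choose_reference(0.80, 0.59)  # 35.6% off: internal used
choose_reference <- function(internal_decile, external_ref, tolerance = 0.20) {
  stopifnot(length(internal_decile) == 1L, length(external_ref) == 1L)
  if (is.na(internal_decile) || internal_decile <= 0) {
    rlang::abort("internal_decile must be a positive number.")
  }
  if (is.na(external_ref) || external_ref <= 0) {
    rlang::abort("external_ref must be a positive number.")
  }
  rel <- abs(internal_decile - external_ref) / external_ref
  use_internal <- rel > tolerance
  tibble::tibble(
    value = if (use_internal) internal_decile else external_ref,
    source = if (use_internal) "internal" else "external",
    internal_decile = internal_decile,
    external_ref = external_ref,
    relative_difference = rel
  )
}

#' Screen the biomarker-inflammation relation before adjusting
#'
#' Regression correction is only defensible when the expected relation is
#' present in the data at hand: positive for the iron markers (ferritin,
#' sTfR, which rise as acute-phase reactants), negative for retinol, RBP and
#' zinc (depressed by inflammation). For each inflammation marker in the
#' biomarker's rule, this fits a simple log-log regression and a Spearman
#' rank correlation. The verdict is `"do_not_adjust"` when the fitted slope
#' contradicts the expected sign for every marker in the rule; otherwise
#' `"adjust"`.
#'
#' @param data Data frame holding the columns below.
#' @param biomarker Biomarker name (see [normalize_biomarker()]).
#' @param group `"PSC"` or `"WRA"`.
#' @param biomarker_col,agp_col,crp_col Column names; an inflammation column
#'   may be absent or `NULL` if that marker was not assayed.
#' @param min_pairs Minimum complete pairs required per marker (default 30).
#' @return A list of class `"relation_screen"`: `$markers` tibble (one row
#'   per marker: `spearman_r`, `spearman_p`, `ols_slope_loglog`,
#'   `sign_consistent`, `n_pairs`), `$verdict`, `$expected_sign`,
#'   `$biomarker`.
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 400, seed = 7))
#' screen_relation(svy, "ferritin", "PSC")
screen_relation <- function(data, biomarker, group,
                            biomarker_col = NULL, agp_col = "agp",
                            crp_col = "crp", min_pairs = 30) {
  rule <- lookup_rule(biomarker, group)
  markers_used <- rule$markers_used[[1]]
  if (length(markers_used) == 0L) {
    rlang::abort(paste0("'", rule$biomarker, "' is not adjusted for inflammation in ",
                        rule$group, "; nothing to screen."))
  }
  biomarker_col <- biomarker_col %||% rule$biomarker
  mb <- pull_column(data, biomarker_col)
  marker_cols <- list(AGP = agp_col, CRP = crp_col)

  screen_one <- function(marker) {
    col <- marker_cols[[marker]]
    if (is.null(col) || !col %in% names(data)) return(NULL)
    x <- pull_column(data, col)
    ok <- !is.na(mb) & !is.na(x)
    if (sum(ok) < min_pairs) {
      rlang::abort(sprintf(
        "Only %d complete %s pairs; at least %d required for screening.",
        sum(ok), marker, min_pairs))
    }
    mbo <- mb[ok]; xo <- x[ok]
    if (stats::sd(mbo) == 0 || stats::sd(xo) == 0) {
      rlang::abort(paste0("Constant column encountered while screening ", marker,
                          "; the relation is undefined."))
    }
    if (any(mbo <= 0) || any(xo <= 0)) {
      rlang::abort("Nonpositive values encountered; impute below-LoD values before screening.")
    }
    ct <- stats::cor.test(mbo, xo, method = "spearman", exact = FALSE)
    slope <- unname(stats::coef(stats::lm(log(mbo) ~ log(xo)))[2])
    consistent <- switch(rule$expected_sign,
                         positive = slope > 0,
                         negative = slope < 0,
                         none = NA)
    tibble::tibble(marker = marker, n_pairs = sum(ok),
                   spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
                   ols_slope_loglog = slope, sign_consistent = consistent)
  }
  markers <- purrr::map_dfr(markers_used, screen_one)
  if (nrow(markers) == 0L) {
    rlang::abort(paste0("None of the inflammation markers required for '",
                        rule$biomarker, "' (", paste(markers_used, collapse = ", "),
                        ") are present in the data."))
  }
  verdict <- if (all(!markers$sign_consistent)) "do_not_adjust" else "adjust"
  structure(list(biomarker = rule$biomarker, group = rule$group,
                 expected_sign = rule$expected_sign, markers = markers,
                 verdict = verdict),
            class = "relation_screen")
}

#' @export
print.relation_screen <- function(x, ...) {
  cat(sprintf("Relation screen for %s (%s), expected sign: %s\n",
              x$biomarker, x$group, x$expected_sign))
  print(x$markers, ...)
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Does serum zinc need inflammation adjustment?
#'
#' Serum zinc is adjusted only in preschool-age children, and only when the
#' Spearman correlation between zinc and at least one available inflammation
#' marker is negative (r < -0.1) and marginally significant (P < 0.1,
#' two-sided). In women of reproductive age zinc is never adjusted.
#' Spearman correlation is rank-based, so the decision is invariant to
#' monotone transforms; raw concentrations are used.
#'
#' @inheritParams screen_relation
#' @param zinc_col Column holding serum zinc.
#' @return A logical scalar with attribute `"detail"`: a tibble of per-marker
#'   r, P, and whether each fired the rule.
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 400, seed = 3))
#' zinc_needs_adjustment(svy, "PSC")
zinc_needs_adjustment <- function(data, group, zinc_col = "zinc",
                                  agp_col = "agp", crp_col = "crp",
                                  min_pairs = 30) {
  grp <- normalize_group(group)
  if (grp == "WRA") {
    return(structure(FALSE, detail = tibble::tibble(
      marker = character(), spearman_r = numeric(), spearman_p = numeric(),
      fires = logical())))
  }
  zinc <- pull_column(data, zinc_col)
  marker_cols <- list(AGP = agp_col, CRP = crp_col)
  test_one <- function(marker) {
    col <- marker_cols[[marker]]
    if (is.null(col) || !col %in% names(data)) return(NULL)
    x <- pull_column(data, col)
    ok <- !is.na(zinc) & !is.na(x)
    if (sum(ok) < min_pairs) {
      rlang::abort(sprintf(
        "Only %d complete zinc-%s pairs; at least %d required.",
        sum(ok), marker, min_pairs))
    }
    ct <- stats::cor.test(zinc[ok], x[ok], method = "spearman", exact = FALSE)
    tibble::tibble(marker = marker, spearman_r = unname(ct$estimate),
                   spearman_p = ct$p.value,
                   fires = unname(ct$estimate) < -0.1 & ct$p.value < 0.1)
  }
  detail <- purrr::map_dfr(c("AGP", "CRP"), test_one)
  if (nrow(detail) == 0L) {
    rlang::abort("Neither AGP nor CRP is present; the zinc rule cannot be evaluated.")
  }
  structure(any(detail$fires), detail = detail)
}

pull_column <- function(data, col) {
  if (!col %in% names(data)) {
    rlang::abort(paste0("Column '", col, "' not found in the data."))
  }
  x <- data[[col]]
  if (!is.numeric(x)) rlang::abort(paste0("Column '", col, "' must be numeric."))
  x
}
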