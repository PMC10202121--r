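#' Construct an adjustment model from known coefficients
#'
#' Mostly useful for testing and for auditing a correction with externally
#' supplied coefficients; [fit_adjustment_model()] is the usual entry point.
#'
#' @param beta1 Slope of ln(biomarker) on ln(AGP), or `NULL` if AGP is not
#'   in the model.
#' @param beta2 Slope on ln(CRP), or `NULL`.
#' @param intercept Model intercept (log scale).
#' @param covariate_coefficients Named numeric vector of coefficients for
#'   optional binary covariates (they shape the fit; they are never
#'   subtracted in the correction).
#' @param n_used Number of complete cases behind the coefficients.
#' @return An object of class `"adjustment_model"`.
#' @export
adjustment_model <- function(beta1 = NULL, beta2 = NULL, intercept = NA_real_,
                             covariate_coefficients = NULL, n_used = NA_integer_) {
  if (is.null(beta1) && is.null(beta2)) {
    rlang::abort("At least one of beta1 (AGP) and beta2 (CRP) must be supplied.")
  }
  structure(
    list(beta1 = beta1, beta2 = beta2, intercept = intercept,
         covariate_coefficients = covariate_coefficients,
         markers_in_model = c(if (!is.null(beta1)) "AGP",
                              if (!is.null(beta2)) "CRP"),
         n_used = n_used, fit = NULL),
    class = "adjustment_model")
}

#' Fit the unweighted log-log adjustment regression
#'
#' One joint ordinary-least-squares fit of ln(biomarker) on ln(AGP) and
#' ln(CRP) together (never marker-by-marker), on complete cases, unweighted
#' even when the survey carries sampling weights. Optional binary covariates
#' (e.g. malaria status) enter the fit as main effects. The regression uses
#' the raw log markers; the reference-decile truncation applies only at
#' correction time ([apply_adjustment()]).
#'
#' @param data Data frame of participant records.
#' @param biomarker_col Column with the (strictly positive) biomarker.
#' @param agp_col,crp_col Inflammation marker columns; pass `NULL` to leave
#'   a marker out of the model (e.g. sTfR uses AGP only, or CRP was not
#'   assayed).
#' @param covariate_cols Character vector of covariate columns.
#' @param min_n Minimum complete cases required (default 30).
#' @return An `"adjustment_model"`: coefficients `beta1`/`beta2`,
#'   `intercept`, `covariate_coefficients`, `markers_in_model`, `n_used`,
#'   and the underlying `lm` fit in `$fit`.
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 500, seed = 1))
#' fit_adjustment_model(svy, "ferritin")
fit_adjustment_model <- function(data, biomarker_col, agp_col = "agp",
                                 crp_col = "crp", covariate_cols = NULL,
                                 min_n = 30) {
  data <- tibble::as_tibble(data)
  mb <- pull_column(data, biomarker_col)
  use_agp <- !is.null(agp_col)
  use_crp <- !is.null(crp_col)
  if (!use_agp && !use_crp) {
    rlang::abort("At least one inflammation marker column is required.")
  }
  agp <- if (use_agp) pull_column(data, agp_col) else NULL
  crp <- if (use_crp) pull_column(data, crp_col) else NULL

  df <- tibble::tibble(ln_mb = check_log(mb, biomarker_col))
  if (use_agp) df$ln_agp <- check_log(agp, agp_col)
  if (use_crp) df$ln_crp <- check_log(crp, crp_col)
  for (cv in covariate_cols) df[[cv]] <- pull_column(data, cv)

  complete <- stats::complete.cases(df)
  df <- df[complete, ]
  if (nrow(df) < min_n) {
    rlang::abort(sprintf("Only %d complete cases; at least %d required to fit.",
                         nrow(df), min_n))
  }
  rhs <- c(if (use_agp) "ln_agp", if (use_crp) "ln_crp", covariate_cols)
  form <- stats::reformulate(rhs, response = "ln_mb")
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    rlang::abort("Rank-deficient fit (a marker or covariate is constant or collinear).")
  }
  model <- adjustment_model(
    beta1 = if (use_agp) unname(cf[["ln_agp"]]),
    beta2 = if (use_crp) unname(cf[["ln_crp"]]),
    intercept = unname(cf[["(Intercept)"]]),
    covariate_coefficients = if (length(covariate_cols) > 0)
      cf[covariate_cols],
    n_used = nrow(df))
  model$fit <- fit
  model
}

check_log <- function(x, name) {
  if (any(x <= 0, na.rm = TRUE)) {
    rlang::abort(paste0(
      "Column '", name, "' contains nonpositive values; the log transform is ",
      "undefined. Impute below-LoD values first (impute_below_lod())."))
  }
  log(x)
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Log-log inflammation adjustment model (OLS, unweighted)\n")
  cat("  markers:", paste(x$markers_in_model, collapse = " + "),
      " n =", x$n_used, "\n")
  if (!is.null(x$beta1)) cat(sprintf("  beta1 [ln(AGP)]: %.4f\n", x$beta1))
  if (!is.null(x$beta2)) cat(sprintf("  beta2 [ln(CRP)]: %.4f\n", x$beta2))
  if (!is.null(x$covariate_coefficients)) {
    cat("  covariates:",
        paste(sprintf("%s = %.4f", names(x$covariate_coefficients),
                      x$covariate_coefficients), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_adjustment_model
#' @param x An `"adjustment_model"`.
#' @param ... Unused.
#' @method tidy adjustment_model
#' @export
tidy.adjustment_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    cf <- summary(x$fit)$coefficients
    ci <- stats::confint(x$fit)
    out <- tibble::tibble(
      term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
      statistic = cf[, 3], p.value = cf[, 4],
      conf.low = ci[, 1], conf.high = ci[, 2])
  } else {
    out <- tibble::tibble(
      term = c("(Intercept)",
               if (!is.null(x$beta1)) "ln_agp",
               if (!is.null(x$beta2)) "ln_crp",
               names(x$covariate_coefficients)),
      estimate = c(x$intercept, x$beta1, x$beta2,
                   unname(x$covariate_coefficients)),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_)
  }
  out
}

#' @rdname fit_adjustment_model
#' @method glance adjustment_model
#' @export
glance.adjustment_model <- function(x, ...) {
  tibble::tibble(
    beta1 = x$beta1 %||% NA_real_,
    beta2 = x$beta2 %||% NA_real_,
    intercept = x$intercept,
    n_used = x$n_used,
    markers = paste(x$markers_in_model, collapse = "+"),
    r.squared = if (!is.null(x$fit)) summary(x$fit)$r.squared else NA_real_)
}

#' Reference-truncated log difference
#'
#' The excess of a log inflammation value over the log reference decile,
#' floored at zero: `max(ln_value - ln_ref, 0)`. Observations at or below
#' the reference decile yield 0 and therefore receive no correction. A PSC
#' child with AGP 2.1 g/L against the external reference 0.59 g/L has
#' `ln(2.1) - ln(0.59) = 1.27`; one with AGP 0.3 g/L has 0.
#'
#' @param ln_value Numeric vector of log marker values; `NA`s propagate.
#' @param ln_ref Finite log reference value (scalar or vector).
#' @return Nonnegative log differences, same length as `ln_value`.
#' @export
#' @examples
#' reference_difference(log(c(2.1, 0.3, 0.59)), log(0.59))
reference_difference <- function(ln_value, ln_ref) {
  if (any(!is.finite(ln_ref))) rlang::abort("ln_ref must be finite.")
  pmax(ln_value - ln_ref, 0)
}

#' Apply the regression correction to a table
#'
#' Per row, the corrected log biomarker is the unadjusted log value minus
#' `beta1` times the AGP log-excess minus `beta2` times the CRP log-excess
#' (each excess truncated at the reference decile, [reference_difference()]),
#' then exponentiated back to the original units. Rows missing any marker in
#' the model get a missing adjusted value rather than a partial correction.
#' Rows whose total correction is exactly zero return the unadjusted value
#' exactly (no log/exp round trip).
#'
#' @param data Data frame of participant records.
#' @param model An `"adjustment_model"`.
#' @param refs Reference deciles as returned by [external_reference()],
#'   [reference_values()] or [choose_reference()]-based resolution; must
#'   cover every marker in the model.
#' @param biomarker_col Column to adjust (strictly positive where nonmissing).
#' @param agp_col,crp_col Inflammation marker columns.
#' @param output_format `"simple"` appends `<biomarker>_adj` and the per-row
#'   `adjusted` flag; `"full"` also appends the per-row log differences and
#'   carries the model and log reference values as attributes
#'   (`"adjustment_model"`, `"reference_values"`, `"ln_refs"`).
#' @return The input tibble with adjustment columns appended.
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 200, seed = 2))
#' m <- fit_adjustment_model(svy, "ferritin")
#' apply_adjustment(svy, m, external_reference("PSC"), "ferritin")
apply_adjustment <- function(data, model, refs, biomarker_col,
                             agp_col = "agp", crp_col = "crp",
                             output_format = c("simple", "full")) {
  output_format <- match.arg(output_format)
  stopifnot(inherits(model, "adjustment_model"))
  data <- tibble::as_tibble(data)
  mb <- pull_column(data, biomarker_col)
  ln_mb <- check_log(mb, biomarker_col)

  use_agp <- "AGP" %in% model$markers_in_model
  use_crp <- "CRP" %in% model$markers_in_model
  if (use_agp && (!"agp_ref" %in% names(refs) || is.na(refs$agp_ref))) {
    rlang::abort("The model uses AGP but no AGP reference value was supplied.")
  }
  if (use_crp && (!"crp_ref" %in% names(refs) || is.na(refs$crp_ref))) {
    rlang::abort("The model uses CRP but no CRP reference value was supplied.")
  }

  ln_agp_diff <- ln_crp_diff <- rep(NA_real_, nrow(data))
  correction <- rep(0, nrow(data))
  if (use_agp) {
    agp <- pull_column(data, agp_col)
    ln_agp_diff <- reference_difference(check_log(agp, agp_col), log(refs$agp_ref))
    correction <- correction + model$beta1 * ln_agp_diff
  }
  if (use_crp) {
    crp <- pull_column(data, crp_col)
    ln_crp_diff <- reference_difference(check_log(crp, crp_col), log(refs$crp_ref))
    correction <- correction + model$beta2 * ln_crp_diff
  }

  mb_adj <- ifelse(!is.na(correction) & correction == 0,
                   mb, exp(ln_mb - correction))
  out <- data
  out[[paste0(biomarker_col, "_adj")]] <- mb_adj
  out$adjusted <- !is.na(mb_adj)
  if (output_format == "full") {
    out$ln_agp_diff <- ln_agp_diff
    out$ln_crp_diff <- ln_crp_diff
    attr(out, "adjustment_model") <- model
    attr(out, "reference_values") <- refs
    attr(out, "ln_refs") <- c(
      ln_agp_ref = if (use_agp) log(refs$agp_ref) else NA_real_,
      ln_crp_ref = if (use_crp) log(refs$crp_ref) else NA_real_)
  }
  out
}

#' Adjust one biomarker end to end
#'
#' The full pipeline for a single biomarker: look up the adjustment rule for
#' the population group; for serum zinc in preschool-age children run the
#' Spearman screen first; screen the sign of the biomarker-inflammation
#' relation; resolve the reference deciles (external unless the internal
#' decile differs by more than 20%); fit the unweighted log-log regression;
#' and apply the truncated correction. Biomarkers whose rule uses no
#' inflammation marker (folate, B-12, zinc in WRA) are returned unchanged
#' and flagged unadjusted, as are biomarkers that fail a screen.
#'
#' If only one of the rule's inflammation markers is present in the data,
#' that marker alone is used (the recommended single-marker fallback).
#'
#' @param data Data frame of participant records.
#' @param biomarker Biomarker name (case-insensitive, synonyms accepted).
#' @param group `"PSC"`, `"WRA"`, or `"MANUAL"`. `"MANUAL"` applies the
#'   unconditional adjustment rules with user-supplied `refs` (required).
#' @param biomarker_col Column holding the biomarker; defaults to the
#'   canonical biomarker name.
#' @param agp_col,crp_col Inflammation marker columns; `NULL` or absent
#'   columns are treated as unavailable.
#' @param refs Optional reference deciles ([reference_values()]); overrides
#'   the automatic external/internal resolution.
#' @param covariate_cols Optional binary covariates (e.g. malaria) included
#'   in the regression fit; they never enter the correction itself.
#' @param screen Run the sign screen and block on contradiction (default
#'   `TRUE`).
#' @param min_n Minimum complete cases for fitting and screening.
#' @param output_format `"simple"` or `"full"` (see [apply_adjustment()]).
#' @return An object of class `"brinda_adjustment"`: `$data` (input tibble
#'   plus adjustment columns), `$adjusted` (was any correction applied),
#'   `$reason` (why not, if not), `$model`, `$refs`, `$rule`, `$screen`,
#'   `$zinc_screen`. Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 500, seed = 11))
#' res <- adjust_biomarker(svy, "ferritin", "PSC")
#' glance(res)
adjust_biomarker <- function(data, biomarker, group, biomarker_col = NULL,
                             agp_col = "agp", crp_col = "crp", refs = NULL,
                             covariate_cols = NULL, screen = TRUE, min_n = 30,
                             output_format = c("simple", "full")) {
  output_format <- match.arg(output_format)
  grp <- normalize_group(group, allow_manual = TRUE)
  # MANUAL mode: user-defined population; the unconditional rule pattern
  # (identical in PSC and WRA for every biomarker except zinc) with the
  # conservative PSC zinc screen, and user references are mandatory
  rule <- lookup_rule(biomarker, if (grp == "MANUAL") "PSC" else grp)
  rule$group <- grp
  data <- tibble::as_tibble(data)
  biomarker_col <- biomarker_col %||% find_column(data, rule$biomarker)

  unadjusted <- function(reason, zinc_screen = NULL, screen_result = NULL) {
    structure(list(data = data, biomarker = rule$biomarker,
                   biomarker_col = biomarker_col, group = grp, rule = rule,
                   adjusted = FALSE, reason = reason, model = NULL,
                   refs = NULL, screen = screen_result,
                   zinc_screen = zinc_screen, output_format = output_format),
              class = "brinda_adjustment")
  }

  if (length(rule$markers_used[[1]]) == 0L) {
    return(unadjusted("no_adjustment_recommended"))
  }

  zinc_screen <- NULL
  if (rule$conditional) {
    zinc_screen <- zinc_needs_adjustment(data, grp, zinc_col = biomarker_col,
                                         agp_col = agp_col, crp_col = crp_col,
                                         min_pairs = min_n)
    if (!isTRUE(as.logical(zinc_screen))) {
      return(unadjusted("zinc_screen_negative", zinc_screen = zinc_screen))
    }
  }

  have_agp <- "AGP" %in% rule$markers_used[[1]] &&
    !is.null(agp_col) && agp_col %in% names(data)
  have_crp <- "CRP" %in% rule$markers_used[[1]] &&
    !is.null(crp_col) && crp_col %in% names(data)
  if (!have_agp && !have_crp) {
    rlang::abort(paste0(
      "'", rule$biomarker, "' requires adjustment for ",
      paste(rule$markers_used[[1]], collapse = "/"),
      " but no such column is present in the data."))
  }
  if (length(rule$markers_used[[1]]) == 2L && (!have_agp || !have_crp)) {
    rlang::inform(paste0(
      "Only ", if (have_agp) "AGP" else "CRP", " is available for '",
      rule$biomarker, "'; using the single available inflammation marker."))
  }

  screen_result <- NULL
  if (screen) {
    screen_result <- screen_relation(
      data, rule$biomarker, if (grp == "MANUAL") "PSC" else grp,
      biomarker_col = biomarker_col,
      agp_col = if (have_agp) agp_col else NULL,
      crp_col = if (have_crp) crp_col else NULL, min_pairs = min_n)
    if (screen_result$verdict == "do_not_adjust") {
      rlang::warn(paste0(
        "The ", rule$biomarker, "-inflammation relation contradicts the expected ",
        rule$expected_sign, " direction; adjustment not applied."))
      return(unadjusted("sign_contradiction", zinc_screen = zinc_screen,
                        screen_result = screen_result))
    }
  }

  if (is.null(refs)) {
    if (grp == "MANUAL") {
      rlang::abort("Group 'MANUAL' requires user reference values (refs =).")
    }
    refs <- resolve_references(data, grp,
                               agp_col = if (have_agp) agp_col else NULL,
                               crp_col = if (have_crp) crp_col else NULL)
  }

  model <- fit_adjustment_model(
    data, biomarker_col,
    agp_col = if (have_agp) agp_col else NULL,
    crp_col = if (have_crp) crp_col else NULL,
    covariate_cols = covariate_cols, min_n = min_n)
  adjusted_data <- apply_adjustment(
    data, model, refs, biomarker_col,
    agp_col = agp_col, crp_col = crp_col, output_format = output_format)

  structure(list(data = adjusted_data, biomarker = rule$biomarker,
                 biomarker_col = biomarker_col, group = grp, rule = rule,
                 adjusted = TRUE, reason = NULL, model = model, refs = refs,
                 screen = screen_result, zinc_screen = zinc_screen,
                 output_format = output_format),
            class = "brinda_adjustment")
}

find_column <- function(data, canonical) {
  hits <- names(data)[vapply(names(data), function(nm) {
    out <- tryCatch(normalize_biomarker(nm), error = function(e) NA_character_)
    identical(out, canonical)
  }, logical(1))]
  if (length(hits) == 0L) {
    rlang::abort(paste0("No column for biomarker '", canonical,
                        "' found; pass biomarker_col explicitly."))
  }
  hits[1]
}

#' Resolve reference deciles for a dataset (external vs internal)
#'
#' Computes the internal lowest decile of each available inflammation marker
#' and applies the 20% rule ([choose_reference()]) against the external
#' reference for the group, per marker independently.
#'
#' @inheritParams qc_summary
#' @return A one-row reference tibble (`agp_ref`, `crp_ref`, `source`);
#'   `source` is `"external"` when both markers keep the external value,
#'   otherwise `"internal"`.
#' @export
resolve_references <- function(data, group, agp_col = "agp", crp_col = "crp") {
  grp <- normalize_group(group)
  ext <- external_reference(grp)
  pick <- function(col, ext_ref) {
    if (is.null(col) || !col %in% names(data)) {
      return(list(value = NA_real_, source = NA_character_))
    }
    x <- pull_column(data, col)
    internal <- unname(stats::quantile(x[!is.na(x)], 0.10, type = 7))
    ch <- choose_reference(internal, ext_ref)
    list(value = ch$value, source = ch$source)
  }
  a <- pick(agp_col, ext$agp_ref)
  c_ <- pick(crp_col, ext$crp_ref)
  source <- if (any(stats::na.omit(c(a$source, c_$source)) == "internal"))
    "internal" else "external"
  tibble::tibble(group = grp, agp_ref = a$value, crp_ref = c_$value,
                 source = source, agp_source = a$source, crp_source = c_$source)
}

#' @export
print.brinda_adjustment <- function(x, ...) {
  cat(sprintf("BRINDA inflammation adjustment: %s (%s)\n", x$biomarker, x$group))
  if (!x$adjusted) {
    cat("  No adjustment applied (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("  markers: %s; n fitted = %d; reference source: %s\n",
                paste(x$model$markers_in_model, collapse = " + "),
                x$model$n_used, x$refs$source))
    if (!is.null(x$model$beta1)) cat(sprintf("  beta1 [ln(AGP)] = %.4f\n", x$model$beta1))
    if (!is.null(x$model$beta2)) cat(sprintf("  beta2 [ln(CRP)] = %.4f\n", x$model$beta2))
  }
  invisible(x)
}

#' @rdname adjust_biomarker
#' @param x A `"brinda_adjustment"`.
#' @param ... Unused.
#' @method tidy brinda_adjustment
#' @export
tidy.brinda_adjustment <- function(x, ...) {
  if (!x$adjusted) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  tidy(x$model)
}

#' @rdname adjust_biomarker
#' @method glance brinda_adjustment
#' @export
glance.brinda_adjustment <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarker,
    group = x$group,
    adjusted = x$adjusted,
    reason = x$reason %||% NA_character_,
    beta1 = if (x$adjusted) x$model$beta1 %||% NA_real_ else NA_real_,
    beta2 = if (x$adjusted) x$model$beta2 %||% NA_real_ else NA_real_,
    n_used = if (x$adjusted) x$model$n_used else NA_integer_,
    agp_ref = if (x$adjusted) x$refs$agp_ref else NA_real_,
    crp_ref = if (x$adjusted) x$refs$crp_ref else NA_real_,
    reference_source = if (x$adjusted) x$refs$source else NA_character_)
}

#' @rdname adjust_biomarker
#' @param object A `"brinda_adjustment"`.
#' @method autoplot brinda_adjustment
#' @export
autoplot.brinda_adjustment <- function(object, ...) {
  if (!object$adjusted) {
    rlang::abort("No adjustment was applied; nothing to plot.")
  }
  adj_col <- paste0(object$biomarker_col, "_adj")
  df <- tidyr::pivot_longer(
    dplyr::select(object$data, unadjusted = all_of(object$biomarker_col),
                  adjusted = all_of(adj_col)),
    cols = c("unadjusted", "adjusted"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$series)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = paste0(object$biomarker, " (original units, log scale)"),
      y = "density", colour = NULL,
      title = paste0("Inflammation adjustment of ", object$biomarker,
                     " (", object$group, ")")) +
    ggplot2::theme_minimal()
}

#' Deficiency prevalence
#'
#' Percentage of nonmissing values below (or above, for sTfR) a user-chosen
#' cut-off, with a binomial standard error. Cut-offs are survey inputs, in
#' the same units as the values. Optional survey weights are accepted for
#' prevalence only; the adjustment regression itself is always unweighted.
#'
#' @param values Numeric vector of (adjusted or unadjusted) biomarker values.
#' @param cutoff Deficiency cut-off, same units as `values`.
#' @param direction `"below"` (ferritin, retinol, RBP, zinc) or `"above"`
#'   (sTfR).
#' @param weights Optional nonnegative survey weights.
#' @return A one-row tibble: `n`, `n_deficient`, `prevalence` (percent),
#'   `se` (percent).
#' @export
#' @examples
#' prevalence(c(5, 10, 15, 30), cutoff = 12, direction = "below")
prevalence <- function(values, cutoff, direction = c("below", "above"),
                       weights = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, !is.na(cutoff))
  ok <- !is.na(values)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(values))
    if (any(weights < 0, na.rm = TRUE)) rlang::abort("weights must be nonnegative.")
    ok <- ok & !is.na(weights)
  }
  if (sum(ok) == 0L) rlang::abort("All values are missing; prevalence undefined.")
  x <- values[ok]
  deficient <- if (direction == "below") x < cutoff else x > cutoff
  if (is.null(weights)) {
    p <- mean(deficient)
    se <- sqrt(p * (1 - p) / length(x))
  } else {
    w <- weights[ok]
    if (sum(w) == 0) rlang::abort("weights sum to zero.")
    p <- sum(w * deficient) / sum(w)
    se <- sqrt(p * (1 - p) * sum(w^2)) / sum(w)
  }
  tibble::tibble(n = length(x), n_deficient = sum(deficient),
                 prevalence = 100 * p, se = 100 * se)
}

#' Compare deficiency prevalence with and without a binary covariate
#'
#' Evaluates whether including a binary covariate (typically malaria status)
#' in the adjustment regression changes the estimated deficiency
#' prevalence. The covariate alters the fitted AGP/CRP coefficients only;
#' the correction still subtracts only the inflammation terms.
#'
#' @inheritParams adjust_biomarker
#' @param covariate_col Binary covariate column; both levels must be present.
#' @param cutoff,direction Passed to [prevalence()], applied to the adjusted
#'   values.
#' @return A two-row tibble (`model = "without_covariate"`,
#'   `"with_covariate"`) with `prevalence`, `se`, `n`, `beta1`, `beta2`.
#' @export
#' @examples
#' cfg <- survey_config(n = 800, seed = 5, malaria_prevalence = 0.2)
#' svy <- generate_survey(cfg)
#' compare_with_covariate(svy, "ferritin", "PSC", "malaria",
#'                        cutoff = 12, direction = "below")
compare_with_covariate <- function(data, biomarker, group, covariate_col,
                                   cutoff, direction = c("below", "above"),
                                   ...) {
  direction <- match.arg(direction)
  cov <- pull_column(data, covariate_col)
  levels_present <- unique(stats::na.omit(cov))
  if (length(levels_present) < 2L) {
    rlang::abort(paste0("Covariate '", covariate_col,
                        "' is constant; both levels must be present."))
  }
  if (!all(levels_present %in% c(0, 1))) {
    rlang::abort(paste0("Covariate '", covariate_col, "' must be binary (0/1)."))
  }
  run_one <- function(covs, label) {
    res <- adjust_biomarker(data, biomarker, group, covariate_cols = covs, ...)
    if (!res$adjusted) {
      rlang::abort(paste0("Adjustment was not applied (", res$reason,
                          "); no prevalence comparison possible."))
    }
    adj <- res$data[[paste0(res$biomarker_col, "_adj")]]
    prev <- prevalence(adj, cutoff, direction)
    dplyr::mutate(prev, model = label, beta1 = res$model$beta1 %||% NA_real_,
                  beta2 = res$model$beta2 %||% NA_real_, .before = 1)
  }
  dplyr::bind_rows(run_one(NULL, "without_covariate"),
                   run_one(covariate_col, "with_covariate"))
}
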