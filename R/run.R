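#' Run the full adjustment pipeline on a survey table
#'
#' File-in/file-out orchestration mirroring the published macro's user
#' contract: map survey columns to canonical biomarker and inflammation
#' marker names, pick a population group (or `"MANUAL"` with user reference
#' values), and receive the input table with adjusted columns appended.
#' Data checks (unit heuristics, summary statistics, the reference-decile
#' decision) run first and warn without blocking; a biomarker whose
#' log-log relation with inflammation contradicts the expected direction is
#' left unadjusted with an explicit log line, never silently passed.
#'
#' @param input Path to a CSV file (header row; `NA` or empty cells as
#'   missing) or a data frame.
#' @param output Optional path for the output CSV (input columns plus
#'   adjusted columns). The input file is never modified.
#' @param group `"PSC"`, `"WRA"` or `"MANUAL"`.
#' @param columns Named list mapping canonical biomarker names to column
#'   names in the input, e.g. `list(ferritin = "sf", zinc = "zn_serum")`.
#'   At least one biomarker must be mapped.
#' @param agp_col,crp_col Inflammation marker columns (AGP in g/L, CRP in
#'   mg/L); at least one is required.
#' @param malaria_col Optional binary covariate column included in the
#'   regression fits.
#' @param agp_ref,crp_ref User reference deciles, required (for each mapped
#'   marker) if and only if `group = "MANUAL"`.
#' @param output_format `"simple"` appends `<column>_adj` only; `"full"`
#'   also appends per-biomarker log differences, coefficients and log
#'   reference values.
#' @param lod Named list mapping input column names to lower limits of
#'   detection; censored values (recorded as 0 or below the LoD) are
#'   single-imputed uniformly on (0, LoD) before any log transform.
#' @param seed Integer seed controlling the LoD imputation draws.
#' @param qc_report Optional path for a QC sidecar CSV (per-column summary
#'   statistics); defaults to `<output>_qc.csv` when `output` is given.
#' @param min_n Minimum complete cases per fit or screen.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list: `$data` (output tibble), `$results` (named
#'   list of [adjust_biomarker()] objects), `$qc` (the [qc_summary()]),
#'   `$log` (character vector of log lines).
#' @export
#' @examples
#' svy <- generate_survey(survey_config(n = 300, seed = 9))
#' run <- run_adjustment(svy, group = "PSC",
#'                       columns = list(ferritin = "ferritin"))
#' names(run$data)
run_adjustment <- function(input, output = NULL, group,
                           columns = list(), agp_col = NULL, crp_col = NULL,
                           malaria_col = NULL, agp_ref = NULL, crp_ref = NULL,
                           output_format = c("simple", "full"), lod = list(),
                           seed = NULL, qc_report = NULL, min_n = 30,
                           verbose = FALSE) {
  output_format <- match.arg(output_format)
  grp <- normalize_group(group, allow_manual = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) rlang::inform(msg)
  }

  if (is.character(input)) {
    if (!file.exists(input)) rlang::abort(paste0("Input file not found: ", input))
    data <- readr::read_csv(input, na = c("", "NA"), show_col_types = FALSE)
  } else {
    data <- tibble::as_tibble(input)
  }

  if (length(columns) == 0L) {
    rlang::abort("Map at least one biomarker column via `columns`.")
  }
  columns <- stats::setNames(unlist(columns),
                             vapply(names(columns), normalize_biomarker,
                                    character(1)))
  missing_cols <- setdiff(unname(columns), names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("Mapped columns not in the input: ",
                        paste(missing_cols, collapse = ", ")))
  }
  have_agp <- !is.null(agp_col) && agp_col %in% names(data)
  have_crp <- !is.null(crp_col) && crp_col %in% names(data)
  if (!is.null(agp_col) && !have_agp) {
    rlang::abort(paste0("AGP column '", agp_col, "' not in the input."))
  }
  if (!is.null(crp_col) && !have_crp) {
    rlang::abort(paste0("CRP column '", crp_col, "' not in the input."))
  }
  if (!have_agp && !have_crp) {
    rlang::abort("At least one inflammation marker column (agp_col/crp_col) is required.")
  }
  if (grp == "MANUAL") {
    if (have_agp && is.null(agp_ref)) {
      rlang::abort("Group 'MANUAL' with an AGP column requires agp_ref.")
    }
    if (have_crp && is.null(crp_ref)) {
      rlang::abort("Group 'MANUAL' with a CRP column requires crp_ref.")
    }
  }

  # Step 2: limit-of-detection repair before any log transform
  if (length(lod) > 0L) {
    for (i in seq_along(lod)) {
      col <- names(lod)[i]
      if (!col %in% names(data)) {
        rlang::abort(paste0("LoD given for unknown column '", col, "'."))
      }
      sub_seed <- if (is.null(seed)) NULL else seed + i
      before <- data[[col]]
      data[[col]] <- impute_below_lod(before, as.numeric(lod[[i]]),
                                      seed = sub_seed)
      n_imp <- sum(before != data[[col]], na.rm = TRUE)
      say("Imputed ", n_imp, " below-LoD value(s) in '", col, "' (LoD ",
          lod[[i]], ").")
    }
  }

  qc_cols <- unique(c(unname(columns), if (have_agp) agp_col,
                      if (have_crp) crp_col))
  qc <- qc_summary(data, columns = qc_cols, lod = lod,
                   group = if (grp == "MANUAL") NULL else grp,
                   agp_col = agp_col %||% "", crp_col = crp_col %||% "")

  refs <- if (grp == "MANUAL") {
    reference_values(agp_ref = if (have_agp) agp_ref else NA_real_,
                     crp_ref = if (have_crp) crp_ref else NA_real_,
                     source = "user")
  } else {
    r <- resolve_references(data, grp, agp_col = if (have_agp) agp_col,
                            crp_col = if (have_crp) crp_col)
    say("Reference deciles: AGP ", r$agp_ref, " (", r$agp_source %||% "-",
        "), CRP ", r$crp_ref, " (", r$crp_source %||% "-", ").")
    r
  }

  out <- data
  results <- list()
  for (bm in names(columns)) {
    col <- columns[[bm]]
    res <- adjust_biomarker(
      data, bm, grp, biomarker_col = col,
      agp_col = if (have_agp) agp_col, crp_col = if (have_crp) crp_col,
      refs = refs, covariate_cols = malaria_col, min_n = min_n,
      output_format = output_format)
    results[[bm]] <- res
    if (!res$adjusted) {
      say("'", bm, "' left unadjusted: ", res$reason, ".")
      next
    }
    say("Adjusted '", bm, "' using ",
        paste(res$model$markers_in_model, collapse = " + "),
        " (n = ", res$model$n_used, ").")
    adj_col <- paste0(col, "_adj")
    out[[adj_col]] <- res$data[[adj_col]]
    if (output_format == "full") {
      if ("AGP" %in% res$model$markers_in_model) {
        out[[paste0(col, "_ln_agp_diff")]] <- res$data$ln_agp_diff
        out[[paste0(col, "_beta1")]] <- res$model$beta1
        out$ln_agp_ref <- log(refs$agp_ref)
      }
      if ("CRP" %in% res$model$markers_in_model) {
        out[[paste0(col, "_ln_crp_diff")]] <- res$data$ln_crp_diff
        out[[paste0(col, "_beta2")]] <- res$model$beta2
        out$ln_crp_ref <- log(refs$crp_ref)
      }
    }
  }

  if (!is.null(output)) {
    readr::write_csv(out, output)
    say("Wrote ", output, " (", nrow(out), " rows).")
    qc_report <- qc_report %||% paste0(output, "_qc.csv")
  }
  if (!is.null(qc_report)) {
    readr::write_csv(qc$columns, qc_report)
    say("Wrote QC report ", qc_report, ".")
  }

  invisible(list(data = out, results = results, qc = qc, log = log_lines))
}
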