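#' Which inflammation markers adjust which micronutrient biomarkers
#'
#' The adjustment policy is fixed by the BRINDA publications, not estimated
#' from data: ferritin, retinol and RBP are adjusted for both AGP and CRP;
#' sTfR for AGP only; serum zinc conditionally (preschool-age children only,
#' and only when the zinc-inflammation Spearman screen fires, see
#' [zinc_needs_adjustment()]); serum folate, red-blood-cell folate and
#' vitamin B-12 are never adjusted. The table covers the two population
#' groups with published reference deciles: preschool-age children (PSC) and
#' nonpregnant women of reproductive age (WRA).
#'
#' @return A tibble with one row per biomarker x group: `biomarker`, `group`,
#'   `use_agp`, `use_crp` (logicals), `conditional` (the zinc screen applies
#'   before adjustment), and `expected_sign` of the log-log relation with
#'   inflammation (`"positive"`, `"negative"` or `"none"`).
#' @seealso [lookup_rule()], [external_reference()]
#' @export
#' @examples
#' biomarker_rules()
biomarker_rules <- function() {
  per_group <- tibble::tribble(
    ~biomarker,     ~use_agp, ~use_crp, ~conditional, ~expected_sign,
    "ferritin",     TRUE,     TRUE,     FALSE,        "positive",
    "stfr",         TRUE,     FALSE,    FALSE,        "positive",
    "retinol",      TRUE,     TRUE,     FALSE,        "negative",
    "rbp",          TRUE,     TRUE,     FALSE,        "negative",
    "zinc",         TRUE,     TRUE,     TRUE,         "negative",
    "serum_folate", FALSE,    FALSE,    FALSE,        "none",
    "rbc_folate",   FALSE,    FALSE,    FALSE,        "none",
    "b12",          FALSE,    FALSE,    FALSE,        "none"
  )
  rules <- dplyr::bind_rows(
    dplyr::mutate(per_group, group = "PSC"),
    dplyr::mutate(per_group, group = "WRA")
  )
  # zinc does not routinely need adjustment in WRA
  rules <- dplyr::mutate(
    rules,
    use_agp = .data$use_agp & !(.data$biomarker == "zinc" & .data$group == "WRA"),
    use_crp = .data$use_crp & !(.data$biomarker == "zinc" & .data$group == "WRA"),
    conditional = .data$conditional & .data$group == "PSC",
    expected_sign = ifelse(.data$biomarker == "zinc" & .data$group == "WRA",
                           "none", .data$expected_sign)
  )
  dplyr::select(rules, "biomarker", "group", "use_agp", "use_crp",
                "conditional", "expected_sign")
}

# synonym map: survey datasets vary in naming; a silent mismatch is worse
# than a strict error, so unknown names never fall through to a default
.biomarker_synonyms <- c(
  ferritin = "ferritin", serum_ferritin = "ferritin", sf = "ferritin",
  stfr = "stfr", sftr = "stfr", tfr = "stfr",
  soluble_transferrin_receptor = "stfr",
  retinol = "retinol", serum_retinol = "retinol",
  rbp = "rbp", retinol_binding_protein = "rbp",
  zinc = "zinc", serum_zinc = "zinc", zn = "zinc",
  serum_folate = "serum_folate", folate = "serum_folate",
  rbc_folate = "rbc_folate", red_blood_cell_folate = "rbc_folate",
  b12 = "b12", vitamin_b12 = "b12", vitamin_b_12 = "b12", b_12 = "b12",
  cobalamin = "b12"
)

#' Canonicalise a biomarker name
#'
#' Case-insensitive, with a small synonym map (`"sTfR"`, `"serum zinc"`,
#' `"vitamin B-12"`, ...). Unknown names are an error, never a default.
#'
#' @param biomarker A single biomarker name.
#' @return One of `"ferritin"`, `"stfr"`, `"retinol"`, `"rbp"`, `"zinc"`,
#'   `"serum_folate"`, `"rbc_folate"`, `"b12"`.
#' @export
#' @examples
#' normalize_biomarker("sTfR")
#' normalize_biomarker("Serum Zinc")
normalize_biomarker <- function(biomarker) {
  stopifnot(is.character(biomarker), length(biomarker) == 1L)
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(biomarker)))
  key <- gsub("^_|_$", "", key)
  out <- unname(.biomarker_synonyms[key])
  if (is.na(out)) {
    rlang::abort(paste0(
      "Unknown biomarker '", biomarker, "'. Known biomarkers: ",
      paste(unique(.biomarker_synonyms), collapse = ", "), "."
    ))
  }
  out
}

normalize_group <- function(group, allow_manual = FALSE) {
  stopifnot(is.character(group), length(group) == 1L)
  g <- toupper(trimws(group))
  valid <- c("PSC", "WRA", if (allow_manual) "MANUAL")
  if (!g %in% valid) {
    rlang::abort(paste0("Unknown population group '", group, "'; expected one of ",
                        paste(valid, collapse = ", "), "."))
  }
  g
}

#' Look up the adjustment rule for one biomarker and population group
#'
#' @param biomarker Biomarker name (case-insensitive; synonyms such as
#'   `"sTfR"` or `"serum zinc"` are accepted).
#' @param group `"PSC"` or `"WRA"`.
#' @return A one-row tibble with the columns of [biomarker_rules()] plus
#'   `markers_used`, a list-column holding the character vector of
#'   inflammation markers in the adjustment model (possibly empty).
#' @export
#' @examples
#' lookup_rule("sTfR", "PSC")   # AGP only
#' lookup_rule("zinc", "WRA")   # no adjustment
lookup_rule <- function(biomarker, group) {
  bm <- normalize_biomarker(biomarker)
  grp <- normalize_group(group)
  rule <- dplyr::filter(biomarker_rules(),
                        .data$biomarker == bm, .data$group == grp)
  stopifnot(nrow(rule) == 1L)
  rule$markers_used <- list(c("AGP", "CRP")[c(rule$use_agp, rule$use_crp)])
  rule
}

#' External BRINDA reference deciles for AGP and CRP
#'
#' The lowest-decile (10th percentile) values of the inflammation markers in
#' the BRINDA multi-country reference database. Observations at or below the
#' reference receive no correction; above it, the correction is proportional
#' to the log-excess over the reference.
#'
#' @param group `"PSC"` (preschool-age children) or `"WRA"` (nonpregnant
#'   women of reproductive age). `"MANUAL"` has no external constants and is
#'   an error: supply user values via [reference_values()] instead.
#' @return A one-row tibble: `group`, `agp_ref` (g/L), `crp_ref` (mg/L),
#'   `source = "external"`.
#' @export
#' @examples
#' external_reference("PSC")  # AGP 0.59 g/L, CRP 0.10 mg/L
#' external_reference("WRA")  # AGP 0.54 g/L, CRP 0.16 mg/L
external_reference <- function(group) {
  grp <- normalize_group(group, allow_manual = TRUE)
  if (grp == "MANUAL") {
    rlang::abort(paste0(
      "No external reference deciles exist for group 'MANUAL'; ",
      "supply agp_ref/crp_ref via reference_values()."
    ))
  }
  refs <- tibble::tibble(
    group = c("PSC", "WRA"),
    agp_ref = c(0.59, 0.54),
    crp_ref = c(0.10, 0.16)
  )
  dplyr::mutate(dplyr::filter(refs, .data$group == grp), source = "external")
}

#' Construct a set of reference decile values
#'
#' Used for `"MANUAL"` population groups (user-supplied references) and
#' internally when the 20% rule selects internal deciles.
#'
#' @param agp_ref,crp_ref Positive reference deciles (g/L and mg/L); either
#'   may be `NA` when the corresponding marker is absent, but not both.
#' @param source `"external"`, `"internal"` or `"user"`.
#' @param group Population group label, default `"MANUAL"`.
#' @return A one-row tibble matching [external_reference()]'s shape.
#' @export
reference_values <- function(agp_ref = NA_real_, crp_ref = NA_real_,
                             source = "user", group = "MANUAL") {
  source <- match.arg(source, c("external", "internal", "user"))
  if (is.na(agp_ref) && is.na(crp_ref)) {
    rlang::abort("At least one of agp_ref and crp_ref must be supplied.")
  }
  if (!is.na(agp_ref) && agp_ref <= 0) rlang::abort("agp_ref must be positive.")
  if (!is.na(crp_ref) && crp_ref <= 0) rlang::abort("crp_ref must be positive.")
  tibble::tibble(group = group, agp_ref = as.numeric(agp_ref),
                 crp_ref = as.numeric(crp_ref), source = source)
}

#' Write the rule and reference registry as CSV
#'
#' Exports [biomarker_rules()] and the external reference deciles so that
#' documentation, tests and downstream pipelines share one machine-readable
#' source of truth. The same two files ship in `inst/extdata/`.
#'
#' @param dir Directory to write `biomarker_rules.csv` and
#'   `reference_deciles.csv` into.
#' @return Invisibly, the paths written.
#' @export
export_registry <- function(dir = ".") {
  paths <- file.path(dir, c("biomarker_rules.csv", "reference_deciles.csv"))
  readr::write_csv(biomarker_rules(), paths[1])
  refs <- dplyr::bind_rows(external_reference("PSC"), external_reference("WRA"))
  readr::write_csv(refs, paths[2])
  invisible(paths)
}
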