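test_that("the truncated log difference reproduces the worked PSC examples", {
  ref <- external_reference("PSC")
  expect_equal(round(reference_difference(log(2.1), log(ref$agp_ref)), 2), 1.27)
  expect_identical(reference_difference(log(0.3), log(ref$agp_ref)), 0)
  expect_identical(reference_difference(log(0.59), log(0.59)), 0)
})

test_that("the truncated log difference vectorises and propagates missingness", {
  out <- reference_difference(log(c(2.1, 0.3, NA, 0.59)), log(0.59))
  expect_equal(out[1], log(2.1) - log(0.59))
  expect_identical(out[2], 0)
  expect_true(is.na(out[3]))
  expect_identical(out[4], 0)
  expect_true(all(out >= 0, na.rm = TRUE))
  expect_error(reference_difference(1, Inf), "finite")
})

test_that("the joint log-log OLS recovers generator coefficients within 3 standard errors", {
  cfg <- survey_config(
    n = 2000, seed = 41,
    biomarkers = list(ferritin = list(intercept = log(20), beta1 = -0.3,
                                      beta2 = -0.1, noise_sd = 0.3)))
  m <- fit_adjustment_model(generate_survey(cfg), "ferritin")
  est <- tidy(m)
  b1 <- est[est$term == "ln_agp", ]
  b2 <- est[est$term == "ln_crp", ]
  expect_lt(abs(b1$estimate - (-0.3)), 3 * b1$std.error)
  expect_lt(abs(b2$estimate - (-0.1)), 3 * b2$std.error)
  expect_identical(m$markers_in_model, c("AGP", "CRP"))
  expect_lte(m$n_used, cfg$n)
})

test_that("a biomarker independent of inflammation yields near-zero coefficients", {
  cfg <- survey_config(
    n = 5000, seed = 42,
    biomarkers = list(ferritin = list(intercept = log(20), beta1 = 0,
                                      beta2 = 0, noise_sd = 0.3)))
  m <- fit_adjustment_model(generate_survey(cfg), "ferritin")
  expect_lt(abs(m$beta1), 0.05)
  expect_lt(abs(m$beta2), 0.05)
})

test_that("single-marker fits drop the other coefficient entirely", {
  svy <- psc_survey(n = 300, seed = 43)
  m <- fit_adjustment_model(svy, "stfr", agp_col = "agp", crp_col = NULL)
  expect_identical(m$markers_in_model, "AGP")
  expect_null(m$beta2)
  expect_false("ln_crp" %in% tidy(m)$term)
})

test_that("unfittable data is rejected with a clear error", {
  svy <- psc_survey(n = 100, seed = 44)
  expect_error(fit_adjustment_model(svy[1:10, ], "ferritin"), "complete cases")
  svy$agp <- 1.3  # constant marker -> rank deficiency
  expect_error(fit_adjustment_model(svy, "ferritin"), "Rank-deficient")
  svy2 <- psc_survey(n = 100, seed = 45)
  svy2$ferritin[1] <- 0
  expect_error(fit_adjustment_model(svy2, "ferritin"), "nonpositive")
})

test_that("a zero-coefficient model returns every value unchanged, exactly", {
  svy <- psc_survey(n = 50, seed = 51)
  m <- adjustment_model(beta1 = 0, beta2 = 0)
  out <- apply_adjustment(svy, m, external_reference("PSC"), "ferritin")
  expect_identical(out$ferritin_adj, svy$ferritin)
})

test_that("apply_adjustment matches the hand evaluation of the correction formula", {
  # ferritin 50, beta1 0.5, beta2 0.2, AGP diff 1.0, CRP diff 0.5
  df <- tibble::tibble(ferritin = 50, agp = 0.59 * exp(1), crp = 0.10 * exp(0.5))
  m <- adjustment_model(beta1 = 0.5, beta2 = 0.2)
  out <- apply_adjustment(df, m, external_reference("PSC"), "ferritin")
  expect_equal(out$ferritin_adj, 50 * exp(-0.6), tolerance = 1e-12)
})

test_that("apply_adjustment matches the frozen five-row spreadsheet oracle", {
  df <- tibble::tibble(
    ferritin = c(50, 30, 12, 100, 8),
    agp = c(2.1, 0.3, 0.59, 1.0, 5.0),
    crp = c(5, 0.05, 0.1, 2, 10))
  m <- adjustment_model(beta1 = 0.5, beta2 = 0.2)
  out <- apply_adjustment(df, m, external_reference("PSC"), "ferritin",
                          output_format = "full")
  oracle <- c(12.11971373256193, 30, 12, 42.19101822996011, 1.09403443224911)
  expect_equal(out$ferritin_adj, oracle, tolerance = 1e-10)
  expect_equal(out$ln_agp_diff,
               c(1.26957008681175, 0, 0, 0.52763274208237, 2.13707065451647),
               tolerance = 1e-10)
  expect_equal(out$ln_crp_diff,
               c(3.91202300542815, 0, 0, 2.99573227355399, 4.60517018598809),
               tolerance = 1e-10)
})

test_that("rows missing a model marker get a missing adjusted value, not a partial correction", {
  df <- tibble::tibble(ferritin = c(50, 60), agp = c(2, 2), crp = c(5, NA))
  m <- adjustment_model(beta1 = 0.5, beta2 = 0.2)
  out <- apply_adjustment(df, m, external_reference("PSC"), "ferritin")
  expect_false(is.na(out$ferritin_adj[1]))
  expect_true(is.na(out$ferritin_adj[2]))
  expect_identical(out$adjusted, c(TRUE, FALSE))
})

test_that("a model marker without a matching reference value is an error", {
  df <- tibble::tibble(ferritin = 50, agp = 2, crp = 5)
  m <- adjustment_model(beta1 = 0.5, beta2 = 0.2)
  refs <- reference_values(agp_ref = 0.59)  # no CRP reference
  expect_error(apply_adjustment(df, m, refs, "ferritin"), "CRP reference")
})

test_that("adjustment moves values in the direction implied by the coefficient signs", {
  svy <- psc_survey(n = 300, seed = 52)
  refs <- external_reference("PSC")

  pos <- apply_adjustment(svy, adjustment_model(beta1 = 0.8, beta2 = 0.3),
                          refs, "ferritin", output_format = "full")
  expect_true(all(pos$ferritin_adj <= svy$ferritin))
  zero_diff <- pos$ln_agp_diff == 0 & pos$ln_crp_diff == 0
  expect_identical(pos$ferritin_adj == svy$ferritin, zero_diff)
  expect_true(any(zero_diff) && !all(zero_diff))

  neg <- apply_adjustment(svy, adjustment_model(beta1 = -0.2, beta2 = -0.08),
                          refs, "retinol", output_format = "full")
  expect_true(all(neg$retinol_adj >= svy$retinol))
  zd <- neg$ln_agp_diff == 0 & neg$ln_crp_diff == 0
  expect_identical(neg$retinol_adj == svy$retinol, zd)
})

test_that("adjust_biomarker leaves never-adjusted biomarkers untouched and flagged", {
  svy <- psc_survey(n = 100, seed = 53)
  svy$b12 <- withr::with_seed(53, exp(rnorm(100, log(300), 0.3)))
  res <- adjust_biomarker(svy, "b12", "WRA")
  expect_false(res$adjusted)
  expect_identical(res$reason, "no_adjustment_recommended")
  expect_identical(res$data$b12, svy$b12)
  expect_false("b12_adj" %in% names(res$data))
  expect_identical(tidy(res), tibble::tibble(
    term = character(), estimate = numeric(), std.error = numeric(),
    statistic = numeric(), p.value = numeric()))
})

test_that("sTfR is adjusted with AGP only even when CRP is present", {
  svy <- psc_survey(n = 400, seed = 54)
  res <- adjust_biomarker(svy, "sTfR", "PSC")
  expect_true(res$adjusted)
  expect_identical(res$model$markers_in_model, "AGP")
  expect_null(res$model$beta2)
  expect_true("stfr_adj" %in% names(res$data))
})

test_that("zinc in PSC is adjusted only when the Spearman screen fires", {
  fires <- psc_survey(n = 400, seed = 55)
  res <- adjust_biomarker(fires, "zinc", "PSC")
  expect_true(res$adjusted)
  expect_true(as.logical(res$zinc_screen))

  cfg_null <- survey_config(
    n = 400, seed = 56,
    biomarkers = list(zinc = list(intercept = log(75), beta1 = 0, beta2 = 0,
                                  noise_sd = 0.2)))
  res_null <- adjust_biomarker(generate_survey(cfg_null), "zinc", "PSC")
  expect_false(res_null$adjusted)
  expect_identical(res_null$reason, "zinc_screen_negative")
  expect_identical(res_null$data$zinc, generate_survey(cfg_null)$zinc)
})

test_that("a sign contradiction blocks adjustment with a warning", {
  cfg <- survey_config(
    n = 400, seed = 57,
    biomarkers = list(rbp = list(intercept = 0, beta1 = 0.4, beta2 = 0.15,
                                 noise_sd = 0.2)))
  expect_warning(res <- adjust_biomarker(generate_survey(cfg), "rbp", "PSC"),
                 "contradicts")
  expect_false(res$adjusted)
  expect_identical(res$reason, "sign_contradiction")
})

test_that("adjust_biomarker falls back to the single available inflammation marker", {
  svy <- dplyr::select(psc_survey(n = 400, seed = 58), -crp)
  expect_message(res <- adjust_biomarker(svy, "ferritin", "PSC"),
                 "single available")
  expect_true(res$adjusted)
  expect_identical(res$model$markers_in_model, "AGP")
  no_markers <- dplyr::select(psc_survey(100, 59), -agp, -crp)
  expect_error(adjust_biomarker(no_markers, "ferritin", "PSC"),
               "no such column")
})

test_that("MANUAL group applies user reference values and requires them", {
  svy <- psc_survey(n = 400, seed = 60)
  expect_error(adjust_biomarker(svy, "ferritin", "MANUAL"),
               "requires user reference")
  refs <- reference_values(agp_ref = 0.7, crp_ref = 0.3)
  res <- adjust_biomarker(svy, "ferritin", "MANUAL", refs = refs)
  expect_true(res$adjusted)
  expect_identical(res$refs$source, "user")
  # stricter references (higher deciles) correct less
  lax <- adjust_biomarker(svy, "ferritin", "MANUAL",
                          refs = reference_values(agp_ref = 2, crp_ref = 5))
  expect_true(all(lax$data$ferritin_adj >= res$data$ferritin_adj - 1e-12))
})

test_that("full output carries diffs, coefficients and log reference values", {
  svy <- psc_survey(n = 300, seed = 61)
  res <- adjust_biomarker(svy, "ferritin", "PSC", output_format = "full")
  out <- res$data
  expect_true(all(c("ferritin_adj", "ln_agp_diff", "ln_crp_diff") %in% names(out)))
  expect_s3_class(attr(out, "adjustment_model"), "adjustment_model")
  lr <- attr(out, "ln_refs")
  expect_equal(unname(lr["ln_agp_ref"]), log(res$refs$agp_ref))
  g <- glance(res)
  expect_identical(g$adjusted, TRUE)
  expect_identical(g$reference_source, res$refs$source)
})

test_that("glance and autoplot summarise an adjustment result", {
  svy <- psc_survey(n = 300, seed = 62)
  res <- adjust_biomarker(svy, "ferritin", "PSC")
  g <- glance(res)
  expect_identical(g$biomarker, "ferritin")
  expect_true(is.finite(g$beta1) && is.finite(g$beta2))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  unadj <- adjust_biomarker(svy, "zinc", "WRA", biomarker_col = "zinc")
  expect_error(autoplot(unadj), "nothing to plot")
})

test_that("prevalence counts deficient participants in either direction", {
  expect_equal(prevalence(c(1, 2, 3, 4), 2.5, "below")$prevalence, 50)
  expect_equal(prevalence(c(1, 2, 3, 4), 2.5, "above")$prevalence, 50)
  out <- prevalence(c(5, 10, NA, 30), 12, "below")
  expect_identical(out$n, 3L)
  expect_identical(out$n_deficient, 2L)
  expect_equal(out$se, 100 * sqrt((2 / 3) * (1 / 3) / 3))
  expect_error(prevalence(c(NA_real_, NA_real_), 1, "below"), "missing")
})

test_that("survey weights shift prevalence as expected", {
  vals <- c(1, 1, 10, 10)
  w <- c(3, 3, 1, 1)
  expect_equal(prevalence(vals, 5, "below", weights = w)$prevalence, 75)
  expect_error(prevalence(vals, 5, "below", weights = c(-1, 1, 1, 1)),
               "nonnegative")
})

test_that("adjusting a positively confounded biomarker cannot lower deficiency prevalence", {
  svy <- psc_survey(n = 500, seed = 63)
  res <- adjust_biomarker(svy, "ferritin", "PSC")
  expect_gt(res$model$beta1, 0)
  unadj <- prevalence(svy$ferritin, 12, "below")$prevalence
  adj <- prevalence(res$data$ferritin_adj, 12, "below")$prevalence
  expect_gte(adj, unadj)
})

test_that("the covariate comparison runs both fits and validates the covariate", {
  cfg <- survey_config(n = 600, seed = 64, malaria_prevalence = 0.3)
  svy <- generate_survey(cfg)
  out <- compare_with_covariate(svy, "ferritin", "PSC", "malaria",
                                cutoff = 12, direction = "below")
  expect_identical(out$model, c("without_covariate", "with_covariate"))
  expect_true(all(is.finite(out$prevalence)))
  # a null covariate barely moves the inflammation coefficients
  expect_lt(abs(out$beta1[1] - out$beta1[2]), 0.1)

  svy$malaria <- 0L
  expect_error(compare_with_covariate(svy, "ferritin", "PSC", "malaria",
                                      cutoff = 12), "constant")
  svy$malaria <- rep(c(1, 2), 300)
  expect_error(compare_with_covariate(svy, "ferritin", "PSC", "malaria",
                                      cutoff = 12), "binary")
})
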