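---
title: "Adjusting micronutrient biomarkers for inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting micronutrient biomarkers for inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflammadjust)
```

## The model and its assumptions

Acute-phase inflammation shifts several serum micronutrient biomarkers
away from the values that reflect true nutrient status: ferritin and
soluble transferrin receptor (sTfR) rise, while retinol, retinol binding
protein (RBP) and zinc fall. The BRINDA regression-correction approach
implemented here models the confounding on the log scale. For a biomarker
MB and inflammation markers AGP (α-1-acid glycoprotein, g/L) and CRP
(C-reactive protein, mg/L), one unweighted OLS regression is fitted
jointly on both markers:

$$\ln MB = \beta_0 + \beta_1 \ln AGP + \beta_2 \ln CRP + \varepsilon$$

and each observation is corrected only for its excess inflammation over a
reference decile $r$ (the 10th percentile of the marker in a low-burden
reference population):

$$\ln MB_{adj} = \ln MB - \beta_1 \, d_{AGP} - \beta_2 \, d_{CRP},
\qquad d_X = \max(\ln X - \ln r_X,\, 0)$$

followed by exponentiation back to the original units. The truncation at
the reference decile encodes the method's central assumption: participants
whose inflammation markers sit at or below the reference level carry no
inflammation signal to remove, so they are returned unchanged. A second
assumption is log-linearity of the biomarker–inflammation relation over
the observed range; the pre-adjustment screens below exist precisely
because that relation must be present, and in the expected direction, in
the data at hand before a regression correction is defensible.

Three deliberate properties of the implementation follow the method's
published description rather than plausible alternatives:

* the regression of step 4 uses the **raw** log markers, not the truncated
  differences — truncation enters only at correction time;
* the fit is **always unweighted**, even when the survey has sampling
  weights (weights are accepted for prevalence estimation only);
* a binary covariate such as malaria status, when requested, enters the
  **fit** as a main effect but is never subtracted in the correction — it
  reshapes $\beta_1$ and $\beta_2$, nothing else. Interaction terms are
  not included; with no stated specification for them, the main-effect
  model is the minimal and more stable choice.

## Which biomarkers, which markers

The adjustment policy is fixed knowledge, shipped as a machine-readable
table (`biomarker_rules()`, also exported to `inst/extdata/`): ferritin,
retinol and RBP use AGP and CRP jointly; sTfR uses AGP alone; serum and
red-blood-cell folate and vitamin B-12 are never adjusted. Serum zinc is
special: never adjusted in women of reproductive age, and in preschool-age
children only when the Spearman correlation between zinc and at least one
available inflammation marker is both negative (r < −0.1) and marginally
significant (P < 0.1). The significance test is two-sided, using the
large-sample t approximation; the published rule does not state sidedness,
and the two-sided choice is the more conservative screen (a one-sided test
would fire more often). When a rule calls for both markers but the survey
assayed only one, that single marker is used — the recommended fallback —
with an explicit message.

Population groups `PSC` and `WRA` carry published external reference
deciles (AGP 0.59 / CRP 0.10 and AGP 0.54 / CRP 0.16 respectively). Any
other population must run as group `MANUAL` with user-supplied reference
values; `MANUAL` applies the unconditional rule pattern (identical between
PSC and WRA for every biomarker except zinc) and retains the conservative
PSC zinc screen, since no published rule exists for other groups.

## Pre-adjustment checks and their numerical choices

`qc_summary()`, `impute_below_lod()`, `choose_reference()`,
`screen_relation()` and `zinc_needs_adjustment()` implement the
recommended data checks. The choices that the method leaves open are
resolved as follows, and each is visible in the output so it can be
audited:

* **Percentiles** use linear interpolation between order statistics
  (quantile type 7, the R default). The method specifies only "the lowest
  decile"; any reasonable definition differs by less than sampling noise
  at survey sizes, and type 7 makes results reproducible against other
  software using the same default.
* **The 20% rule** for preferring internal over external reference deciles
  is read as a relative difference with the external value as the
  denominator, because the external value is the fixed benchmark being
  compared against. The decision is made per marker, independently, and is
  scale-invariant by construction.
* **Below-LoD values** (commonly recorded as 0 or as the LoD itself) are
  repaired by single random imputation: one uniform draw strictly inside
  (0, LoD) per censored value, reproducible under a seed. Values recorded
  exactly at the LoD are kept by default (`at_lod = TRUE` treats them as
  censored); multiply-imputed values from the user's own pipeline can be
  supplied in place of this step.
* **Unit checks are heuristic**: the expected units (AGP g/L, CRP mg/L)
  cannot be verified mechanically, so the package warns — never fails —
  when the AGP median falls outside 0.1–5 g/L or the CRP median outside
  0.01–200 mg/L.
* **Sign screening** fits a simple log-log regression and a Spearman
  correlation per marker; adjustment is blocked (with a warning, not
  silently) only when every marker in the rule contradicts the expected
  direction. Zinc's Spearman screen runs on raw concentrations; rank
  correlation is invariant to monotone transforms, so the choice is
  immaterial and documented only for reproducibility.
* **Degenerate inputs** are hard errors: constant columns, nonpositive
  values at log-transform time (impute first), fewer than `min_n = 30`
  complete cases for any fit or screen. The 30-case floor is configurable;
  the method states no minimum, and 30 is the conventional smallest sample
  at which an OLS slope and its normal-theory interval are worth
  reporting.
* Rows missing any marker that is in the model receive a **missing**
  adjusted value rather than a partial one-marker correction, because
  mixing single- and two-marker corrections within one dataset silently
  changes the estimand. Rows whose total correction is exactly zero are
  returned bit-identically (no `exp(log(x))` round trip).

## The synthetic survey generator

`generate_survey()` draws ln AGP and ln CRP from a correlated bivariate
normal (default log-scale SDs 0.45 and 1.2, correlation 0.5 — lognormal
marker distributions with CRP much more dispersed than AGP, as in real
surveys), an optional Bernoulli malaria indicator, and each biomarker from
the same log-linear model the adjustment assumes, with known
coefficients. Two calibration choices make the generator internally
consistent with the method: the default log-mean of each inflammation
marker places its population 10th percentile exactly at the external
reference decile of the chosen group (so roughly 10% of participants fall
below the reference and receive no correction), and the default biomarker
coefficients follow the field-expected directions — ferritin 0.8/0.3 and
sTfR 0.25/0 (positive), retinol, RBP and zinc negative.

Because the generator *is* the model, parameter recovery and direction
properties are exact science, not luck; what passing tests on it do **not**
show is robustness to features of real surveys it deliberately omits:
cluster/stratum design effects, assay measurement error, non-lognormal
tails, mixtures of infection states, or biomarkers whose relation with
inflammation is nonlinear. Results on real data depend on the
pre-adjustment screens catching such departures.

Validation problem sizes, chosen to make Monte-Carlo error small relative
to the tolerances tested: moment convergence at n = 50 000; parameter
recovery over 200 replicates of n = 1000 (mean estimates within 2% of
truth, 95% interval coverage within [90%, 98%]); the null-malaria
prevalence comparison over 50 replicates of n = 1000 (mean absolute
difference below one percentage point).

## A short tour

```{r example}
svy <- generate_survey(survey_config(n = 800, seed = 7))
qc <- qc_summary(svy, group = "PSC")
qc$reference

res <- adjust_biomarker(svy, "ferritin", "PSC", output_format = "full")
glance(res)
tidy(res)[, 1:3]
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(res)
```

The deficiency consequences, before and after:

```{r prevalence}
dplyr::bind_rows(
  unadjusted = prevalence(svy$ferritin, 12, "below"),
  adjusted   = prevalence(res$data$ferritin_adj, 12, "below"),
  .id = "series")
```

## Known limitations

* No adjustment rules exist here for vitamin D or for population groups
  beyond PSC and WRA (pregnant women in particular); `MANUAL` mode is an
  escape hatch, not a validated rule set.
* Prevalence standard errors use the binomial approximation and, with
  weights, ignore the design effect; survey-design-aware variance is out
  of scope.
* The malaria covariate is a binary main effect; infection staging or
  parasitemia intensity is not modelled.
* Single random imputation below the LoD understates imputation
  uncertainty relative to multiple imputation; the hook for user-supplied
  imputed values exists for that reason.
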