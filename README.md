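# inflammadjust

Inflammation distorts several of the serum biomarkers used to assess
micronutrient status in population surveys: ferritin and soluble
transferrin receptor (sTfR) rise as acute-phase reactants while retinol,
retinol binding protein (RBP) and zinc fall, so unadjusted survey data can
badly over- or under-estimate the prevalence of iron, vitamin A and zinc
deficiency wherever infection is common. `inflammadjust` implements the
BRINDA regression-correction approach to remove that confounding, for
analysts of nutrition surveys (national micronutrient surveys, evaluation
studies, research cohorts) who need adjusted biomarker values and
deficiency prevalences without writing the statistics themselves.

## The method

For a biomarker MB whose rule calls for adjustment, an unweighted ordinary
least squares regression is fitted on the log scale, jointly on both
inflammation markers (α-1-acid glycoprotein, AGP, in g/L, and C-reactive
protein, CRP, in mg/L):

    ln(MB) = β0 + β1 ln(AGP) + β2 ln(CRP) + ε

Each observation is then corrected only for its *excess* inflammation over
a reference decile (the 10th percentile of the marker in a reference
population; 0.59 g/L AGP and 0.10 mg/L CRP for preschool-age children,
0.54 g/L and 0.16 mg/L for women of reproductive age):

    ln(MB_adj) = ln(MB) − β1 · max(ln AGP − ln AGP_ref, 0)
                        − β2 · max(ln CRP − ln CRP_ref, 0)

and exponentiated back to the original units, so participants at or below
the reference deciles are returned unchanged. Which markers enter the
model is biomarker-specific (sTfR uses AGP only; folate and vitamin B-12
are never adjusted; serum zinc is adjusted only in preschool-age children
and only when a Spearman screen finds r < −0.1 with P < 0.1 against AGP or
CRP). The package also bundles the recommended pre-adjustment checks:
summary statistics, random single imputation of values censored below the
limit of detection, the internal-versus-external reference decile
comparison (20% rule), and sign screening of the biomarker–inflammation
relation.

## Worked example

```r
library(inflammadjust)

# a synthetic preschool-age survey with known confounding structure
svy <- generate_survey(survey_config(n = 1000, seed = 42))

res <- adjust_biomarker(svy, "ferritin", "PSC")
res
#> BRINDA inflammation adjustment: ferritin (PSC)
#>   markers: AGP + CRP; n fitted = 1000; reference source: external
#>   beta1 [ln(AGP)] = 0.7850
#>   beta2 [ln(CRP)] = 0.2894

head(dplyr::select(res$data, agp, crp, ferritin, ferritin_adj), 4)
#>     agp    crp ferritin ferritin_adj
#> 1 1.95  11.9      83.2          8.18
#> 2 0.815  0.572    12.1          5.69
#> 3 1.24   1.59      9.67         2.43
#> 4 1.40   1.01      7.85         2.05

prevalence(res$data$ferritin_adj, cutoff = 12, direction = "below")
#> # A tibble: 1 × 4
#>       n n_deficient prevalence    se
#>   <int>       <int>      <dbl> <dbl>
#> 1  1000         849       84.9  1.13
```

The fitted slopes (0.785 on ln AGP, 0.289 on ln CRP) recover the
generator's true coefficients (0.8 and 0.3). Every participant's ferritin
is corrected downward in proportion to their log-excess inflammation over
the reference deciles — the first row, with AGP 1.95 g/L and CRP 11.9
mg/L, drops from 83.2 to 8.2 — and iron deficiency prevalence (ferritin
below 12 µg/L) rises from 36.9% unadjusted to 84.9% adjusted, the expected
direction when inflammation inflates ferritin. `glance()` and `tidy()`
give model-level and coefficient-level summaries; `autoplot()` overlays
the adjusted and unadjusted distributions.

A file-based pipeline with column mapping, limit-of-detection handling and
simple/full output formats is available as `run_adjustment()`, and as a
command line tool:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "brinda-adjust.R", package = "inflammadjust"))')" \
  --input survey.csv --output adjusted.csv --group psc \
  --ferritin sf --agp agp --crp crp --output-format full
```

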