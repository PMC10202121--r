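Package: inflammadjust
Title: Inflammation Adjustment of Micronutrient Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adjusts micronutrient biomarkers (ferritin, soluble transferrin
    receptor, retinol, retinol binding protein, zinc) for the confounding
    effect of inflammation using the BRINDA regression-correction method.
    Encodes the published per-biomarker adjustment rules and external
    reference deciles for preschool-age children and women of reproductive
    age, performs the recommended data checks (limit-of-detection
    imputation, internal-versus-external reference decile comparison,
    sign screening of the biomarker-inflammation relation, the serum zinc
    decision rule), fits the unweighted log-log regression, applies the
    reference-truncated correction, and estimates deficiency prevalence.
    Includes a synthetic survey generator with known confounding structure
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
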