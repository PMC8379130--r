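Package: washoutCT
Title: Quantitative Wash-In/Wash-Out Analysis of Hepatocellular Carcinoma on Multiphase CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hepatocellular carcinoma (HCC) wash-in and
    wash-out from Hounsfield-unit region-of-interest measurements on
    four-phase contrast-enhanced CT, and to evaluate these indices as
    predictors of early complete response to drug-eluting-bead
    chemoembolization (DEB-TACE). Implements the contrast enhancement ratio
    (CER), lesion-to-liver contrast ratio (LLC), absolute and relative
    wash-out, and the delayed percentage attenuation ratio (DPAR); elliptical
    ROI extraction from raster images; ROC analysis with multi-criteria
    threshold selection; contingency-table effect measures (Woolf odds-ratio
    and Katz risk-ratio intervals, Fisher's exact test); binary logistic
    regression; inter-reader agreement statistics (ICC, Cronbach's alpha,
    Cohen's kappa, Wilcoxon matched-pairs); and a calibrated synthetic
    cohort and phantom generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
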