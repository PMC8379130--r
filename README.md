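# washoutCT

Quantitative assessment of hepatocellular carcinoma (HCC) wash-in and
wash-out on four-phase contrast-enhanced CT, and evaluation of these indices
as predictors of early complete response (CR, by mRECIST) to drug-eluting-bead
transarterial chemoembolization (DEB-TACE).

The package is written for radiologists and biostatisticians working with
per-lesion Hounsfield-unit (HU) region-of-interest (ROI) measurements: one
elliptical ROI on the lesion in the unenhanced (UE), arterial (ART) and
delayed (DEL) phases, and two ROIs on adjacent healthy liver in each contrast
phase (averaged into a liver reference).

## The indices

With `HU_ue`, `HU_art`, `HU_del` the lesion means and `HU_liv,art`,
`HU_liv,del` the liver references:

| index | formula | meaning |
|---|---|---|
| CER | (HU_art − HU_ue) / HU_ue × 100 | wash-in vs own baseline |
| LLC | (HU_art − HU_liv,art) / HU_liv,art × 100 | wash-in vs liver |
| WO_abs | (HU_art − HU_del) / (HU_art − HU_ue) × 100 | wash-out vs enhancement |
| WO_rel | (HU_art − HU_del) / HU_art × 100 | wash-out vs arterial value |
| DPAR | HU_liv,del / HU_del × 100 | delayed percentage attenuation ratio |

DPAR > 100 means the lesion is hypoattenuating relative to liver in the
delayed phase (visible wash-out); DPAR ≥ 120 together with smooth lesion
margins defines the most favorable preprocedural stratum for early CR.
The indices satisfy the exact identity `WO_abs = WO_rel (CER + 100) / CER`
and are invariant to rescaling all five HU values, so a profile can be
reconstructed from printed index values up to one anchored HU value
(`reconstruct_profile()`).

Downstream analysis: Mann-Whitney and Fisher univariate tests, empirical ROC
with DeLong AUC interval and three-criterion threshold selection (Youden,
harmonic mean of sensitivity/specificity, distance to the upper-left corner),
Woolf odds-ratio and Katz risk-ratio intervals, binary logistic regression,
four-cell lesion stratification, and inter-reader agreement (Wilcoxon
matched-pairs, ICC(2,1), two-rater Cronbach's alpha, Cohen's kappa). A
calibrated synthetic cohort and phantom-image generator replaces patient
data end to end.

## Worked example

```r
library(washoutCT)

# indices for a single measured profile (a well-defined responding nodule)
enhancement_indices(ue = 50, art = 104.7, del = 79.26,
                    liver_art = 66.99, liver_del = 97.65)
#> # A tibble: 1 × 5
#>     cer   llc wo_abs wo_rel  dpar
#>   <dbl> <dbl>  <dbl>  <dbl> <dbl>
#> 1  109.  56.3   46.5   24.3  123.

# full pipeline on the synthetic reference cohort (129 lesions)
cohort <- generate_cohort()
report <- run_full_analysis(cohort, analysis_config(threshold = 120))
report
#> washoutCT analysis report (129 lesions)
#>   DPAR AUC = 0.66 (0.57-0.76); threshold 120.0 [fixed]
#>   DPAR >= 120.0: OR 3.7 (1.8; 7.7), Fisher p 0.0004
#> Lesion stratification at DPAR >= 120 (n = 129, 0 excluded)
#>   DPAR >= 120, smooth margins  CR+ 26/33 = 78.8%
#>   DPAR >= 120, other margins   CR+ 15/29 = 51.7%
#>   DPAR < 120, smooth margins   CR+ 12/25 = 48.0%
#>   DPAR < 120, other margins    CR+ 11/42 = 26.2%
#>   one favorable predictor (pooled): 27/54 = 50.0%
#>   both vs neither: OR 10.5 (3.5; 30.9), RR 3.0 (1.8; 5.2)
```

The CER of 109.4 says the lesion more than doubled its attenuation from the
unenhanced to the arterial phase (wash-in); the DPAR of 123.2 says adjacent
liver is 23% more attenuating than the lesion in the delayed phase (clear
wash-out) — a favorable profile, which the stratification quantifies: lesions
with DPAR ≥ 120 have a CR odds ratio of 3.7 (95% CI 1.8–7.7, Fisher
p = 0.0004), rising to a 78.8% CR rate when margins are also smooth versus
26.2% with neither predictor (risk ratio 3.0).

Individual pieces compose with the pipe:

```r
library(dplyr)
cohort |>
  add_enhancement_indices() |>
  mutate(cr = dichotomize_response(response)) |>
  roc_auc(dpar, cr) |>
  select_threshold()
```

`autoplot()` methods draw the ROC curve and the stratification bars;
`tidy()`/`glance()` extract tabular results from ROC and logistic fits.

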