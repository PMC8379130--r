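---
title: "Quantifying HCC wash-out on multiphase CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HCC wash-out on multiphase CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washoutCT)
```

## The measurement model

Hepatocellular carcinoma is diagnosed and monitored on multiphase
contrast-enhanced CT through two kinetic hallmarks: *wash-in* (arterial-phase
hyperenhancement) and *wash-out* (relative hypoattenuation in later phases).
washoutCT works from the minimal quantitative reduction of that exam: mean
Hounsfield-unit values of one elliptical ROI traced on the lesion in the
unenhanced, arterial and delayed phases, plus two ROIs on adjacent healthy
liver in each contrast phase, averaged into a liver reference
(`liver_reference()`). The portal venous phase is carried in data files but
never used by an index; the per-reader bookkeeping is therefore 7 ROIs per
lesion (`count_protocol_rois()`).

ROI extraction (`roi_mean()`) uses a deterministic pixel-inclusion rule: a
pixel belongs to the ellipse iff its center (integer coordinates, 0-based)
lies inside or on the boundary. This makes every extraction exactly
reproducible and testable against exhaustive pixel enumeration. ROI sizes are
free parameters; the phantom defaults produce discrete ROI areas around the
1.4 cm² scale typical of such protocols at ordinary in-plane resolutions.
Whether the liver ROIs are size-matched to the lesion ROI is protocol-
dependent and left configurable.

Five indices summarize the kinetics (`enhancement_indices()`): CER and LLC
for wash-in; WO\_abs, WO\_rel and DPAR for wash-out. Two structural facts
shape the implementation:

* **Scale invariance.** All five indices are ratios, so the index vector
  determines an HU profile only up to a global factor.
  `reconstruct_profile()` inverts the system around an anchored unenhanced
  value; the round-trip is the identity to 1e-9, which is how published
  per-lesion index values can be turned back into working profiles.
* **The wash-out identity.** WO\_abs = WO\_rel (CER + 100) / CER exactly.
  `wo_abs_from_identity()` exposes it; `reconstruct_profile()` uses it to
  validate a supplied WO\_abs, warning when the residual exceeds a tolerance
  of 0.15 index points — the slack produced by one-decimal display rounding
  of the other two indices. (One published example triple carries exactly
  such a residual, ≈ 1.8 implied vs 1.7 printed; the package treats WO\_rel
  rounding as the cause and does not "correct" anything.)

**Domain rule.** HU values can legitimately be ≤ 0 (necrosis, fat), so each
index is defined only where its denominator is strictly positive; a failed
rule yields a *non-evaluable* (`NA`) index rather than an error or a silent
drop, and downstream stages report how many lesions they excluded.
Dichotomization at the DPAR threshold is inclusive (`dpar >= 120` is "high"),
and mRECIST responses collapse to CR+ vs CR− (`dichotomize_response()`).

## The synthetic generator

No per-lesion raw data accompany the study conditions the package targets,
so the generator is *summary-matched by construction* — a stand-in with the
published joint structure, not a reconstruction of patients.

`sample_dpar()` draws group-conditional DPAR from a monotone
piecewise-linear quantile function anchored at the published quartiles
(CR+ 116/124/139; CR− 108/115/123) **plus an exceedance knot at 120** fixing
P(DPAR ≥ 120) to 41/64 (CR+) and 21/65 (CR−) exactly, with density-matched
exponential tails outside the interquartile range. The knot is needed
because 120 lies inside both groups' interquartile ranges: with only the
three quartile anchors, linear interpolation would give exceedances of 0.625
and 0.656 — close, but the knot honors the counts exactly, and the cost is
one extra (published) anchor rather than a parametric family that cannot fit
all the summaries at once. Population quartiles, median and exceedance are
exact by construction; tails affect only extreme quantiles.

`generate_cohort()` builds the full lesion table. In `exact_counts` mode
(n = 129) the four (DPAR ≥ 120) × margins cells and their CR+ counts are
reproduced verbatim — (33, 26), (29, 15), (25, 12), (42, 11) — which is
internally consistent with the group exceedances above, so mixing the
side-truncated draws across cells recovers each group's untruncated
distribution. mRECIST categories among CR− follow the 53:7:5 PR/SD/PD ratio;
diameters come from quartile-calibrated samplers (CR+ 14/19/25.5 mm, CR−
16/23/33 mm); locations follow the overall right/median/left mix. `sampled`
mode replaces the fixed counts with multinomial cell draws and Bernoulli
response at the cell rates.

HU profiles are then synthesized by inverting the index system: UE ~ N(55,
7²) HU (a realistic unenhanced lesion attenuation; MAD ≈ 5 HU), CER/LLC/
WO\_rel from group-calibrated quartile samplers, DPAR from the truncated
sampler above. CER and WO\_rel are drawn **comonotonically** (Gaussian
copula, ρ = 0.7): strongly arterialized lesions wash out more, which is the
physiologic reading of wash-out as the downside of hyper-arterialization.
This dependence also compresses the delayed phase toward its "steady state"
and yields the characteristic dispersion ordering MAD(ART) > MAD(DEL) >
MAD(UE) — the ordering, not the printed MAD values, is what the generator
asserts and the tests check. Exponential sampler tails are clamped far
outside every calibrated interquartile range (CER to [10, 500], WO\_rel to
[−60, 85], LLC to [−60, 400]) to keep ART, DEL and the liver references
positive; the clamps are unreachable at cohort sizes below ~10⁴ draws and do
not move any calibrated quantile.

What the generator does **not** emulate: anatomic texture, vessels and bile
ducts, registration error between phases, reader variation in ROI placement
on real anatomy, and — deliberately — any target AUC. Quartile summaries do
not determine tail behavior, so the discrimination of the synthetic DPAR
(AUC ≈ 0.65–0.70) is checked only as "> 0.5 and consistent with the
sampler's own concordance", never against the published 0.80; calibrating
the generator to hit a published AUC would make the downstream ROC analysis
circular. Consequently, passing tests demonstrate correctness of the
*machinery* on data with the published joint counts and quartiles, not
reproduction of patient-level discrimination.

`generate_phantom_series()` renders a profile as three co-registered rasters
(uniform liver, one elliptical lesion, optional per-phase Gaussian noise);
with zero noise the measurement chain `roi_mean()` → `liver_reference()` →
`enhancement_indices()` reproduces the requested indices exactly, closing
the loop between the imaging and tabular halves of the package.
`jitter_reader()` emulates a second blinded reader by adding independent
N(0, σ²) noise to every HU measurement and flipping the margins call with a
fixed probability; the `"calibrated"` preset (σ = 6.5 HU, flip 0.115) was
tuned once, by simulation on the reference cohort, to land mean downstream
agreement near the published levels (ICC ≈ 0.8 for DPAR, κ ≈ 0.76 for
margins) and is treated as qualitative: tests assert bands and monotonicity
(more jitter, less agreement), not point values.

## Statistical choices

* **Mann-Whitney / Wilcoxon matched-pairs** wrap `stats::wilcox.test`:
  exact enumeration for small untied samples (≤ 8 per group unpaired, ≤ 12
  nonzero pairs paired), otherwise normal approximation with tie and
  continuity corrections. Zero paired differences are excluded; all-zero
  input returns p = 1 with a warning.
* **Fisher's exact test** uses the "sum of tables with probability ≤
  observed" two-sided rule (`stats::fisher.test`), the convention that gives
  p = 0.0004 on the (41, 21, 23, 44) DPAR×CR table.
* **Effect measures.** OR CI by the Woolf log method with z = 1.96 and no
  continuity correction — this reproduces the published (1.8; 7.7); a 0.5
  Haldane fallback on zero cells is opt-out and always warns. RR CI by the
  Katz log method, which reproduces the published (2–5) on the extreme-strata
  table (26, 7, 11, 31).
* **ROC.** The empirical curve, trapezoidal AUC (≡ tie-corrected concordance
  ≡ scaled Mann-Whitney U) and DeLong CI are implemented in-package, with
  pROC used as an independent cross-check in tests. Owning the curve keeps
  the threshold machinery under the package's conventions: candidate cuts
  are the distinct scores with a `>=` rule; criterion ties break toward the
  higher (more specific) cut — deterministic, and consistent with preferring
  120 over lower equally-performing cuts; the reported threshold is the
  midpoint of the score interval realizing the optimal confusion table (for
  separated classes, the gap midpoint). The DeLong interval is reported but
  never used as a calibration target, since the interval method behind
  published values of this kind is typically unstated.
* **Logistic regression** is `stats::glm(binomial)` — iteratively reweighted
  least squares with epsilon 1e-10 and 100-iteration cap — plus explicit
  detection of (quasi-)separation, raised as an error naming the worst
  predictor. A single binary predictor reproduces the cross-product OR
  analytically; the two-predictor fit on the published cell counts is tested
  against an independent likelihood optimization and against the published
  CI memberships only (the published point ORs 3.3/2.5 depend on an
  ambiguous covariate set — diameter in or out — so they are not golden
  values; `blr_covariates` makes diameter optional).
* **Diagnostic parameters** at DPAR = 120 are computed from the counts;
  the published 0.72/0.67/0.69/0.70 panel is inconsistent with the published
  counts (41/64 = 0.64 sensitivity) — possibly a single reader's data — and
  is therefore never asserted.
* **Agreement.** ICC is fixed to ICC(2,1): two-way random effects, absolute
  agreement, single measurement — the standard form for a fixed pair of
  human readers, stated here prominently because the choice is often left
  implicit. The "η²/Cronbach" coefficient reported alongside ICC in this
  literature conflates two statistics; the package implements two-rater
  Cronbach's alpha, `2(1 − (V₁+V₂)/V_sum)`, labels it as such, and treats it
  as descriptive. Cohen's kappa uses marginal-product expected agreement.
* **Display conventions:** indices and percentages to one decimal, ORs/RRs
  to one decimal, coefficients to two, p-values to four decimals or
  "<0.0001". Computation is always full precision; rounding happens only in
  print methods and reports.

## The pipeline

`run_full_analysis()` chains the stages deterministically given (input,
config): index computation, group summaries, univariate tests, phase-wise
MAD, ROC with threshold selection (`threshold = "auto"` uses the consensus
criterion; the fixed default is 120), dichotomized effect measures, the
four-cell stratification (`stratify_lesions()`), logistic regression, and
the agreement table when a second reader is supplied. Non-evaluable lesions
are excluded with counts surfaced in the report's warnings; cohorts with
fewer than two lesions per response class produce a report with inferential
blocks omitted and an "insufficient n" note rather than an error.
`report_json()` serializes with a schema tag (`washoutCT-report/1`).
Configurations round-trip through JSON and reject unknown keys.

## Problem sizes and determinism

Every stochastic operation takes a seed and is bit-reproducible from it
(generator version and seed are recorded in output metadata; the reference
cohort uses seed 20160101). The test suite sizes its Monte-Carlo runs for
tight feedback: permutation oracles up to 8–12 per group, 2×10⁵ draws for
population-quantile checks, ~10² replicates for noise and agreement bands,
which keeps the whole suite in the low minutes on one CPU while leaving all
population-exact assertions (quartiles, exceedances, joint counts) at
machine precision.

## Known limitations

Analysis is per-lesion, not per-patient — lesions from the same liver are
treated as independent, as is conventional in this setting but optimistic
for clustered data. The generator matches published summaries by
construction and cannot validate discrimination (AUC) or patient-level
heterogeneity. No DICOM ingestion, inter-phase registration, 3-D ROIs,
survival endpoints, or more than two readers.
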