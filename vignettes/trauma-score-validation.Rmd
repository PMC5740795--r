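---
title: "Validating trauma mortality scores: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating trauma mortality scores: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumascore)
```

## The problem

Trauma units triage with mortality prediction scores: anatomic scores built
from Abbreviated Injury Scale (AIS) grades, physiological scores built from
first-recorded vital signs, and combined logistic models. External
validation asks, for a given population, which score best discriminates the
patients who will die in hospital from those who will survive. traumascore
implements that validation workflow end to end — scoring, discrimination
analysis, optimal cutoffs — together with a calibrated synthetic cohort
generator, so the full analysis can be exercised and reproduced without
access to a hospital registry (trauma registries are essentially never
deposited publicly).

## The scoring systems

Each patient record carries AIS-coded injuries (body region and severity
1–6), first-recorded physiology (respiratory rate, systolic blood pressure,
Glasgow Coma Scale), age, sex, injury mechanism, and the in-hospital
outcome.

**ISS and NISS.** The Injury Severity Score squares the single highest AIS
grade in each of the three most severely injured *distinct* body regions
and sums the squares; the New Injury Severity Score squares the three
highest grades *regardless* of region, so NISS ≥ ISS, with equality when no
region contributes more than one of the top injuries. Both range 0–75, and
we adopt the universal registry convention that any AIS 6 (unsurvivable)
injury forces the maximum of 75; records carrying AIS 6 are additionally
flagged by `validate_cohort()`, since the source study does not state how
such records were handled.

**RTS.** Each vital sign is banded to a category score 0–4 (the normal band
scoring 4) and the Revised Trauma Score is the weighted sum
\[
\mathrm{RTS} = 0.2908\,\mathrm{RR_s} + 0.7326\,\mathrm{SBP_s} + 0.9368\,\mathrm{GCS_s},
\]
ranging 0 to 7.8408.

**TRISS.** The Trauma and Injury Severity Score family maps covariates to a
survival probability \(P_s = 1/(1+e^{-b})\). The MTOS variant uses the
Major Trauma Outcome Study coefficients with separate blunt and penetrating
sets, \(b\) linear in RTS, ISS and a binary AgeIndex (1 for age ≥ 55); the
blunt set is applied to children under 15 regardless of mechanism. The NTrD
variant uses a single coefficient set refit on the Malaysian National
Trauma Database, \(b\) linear in NISS, AgeIndex and the three RTS category
scores. Coefficients are used at exactly their published precision.

Three mapping decisions the published models leave open are fixed here and
recorded per patient in the `coefficient_set` column: blast injuries use the
blunt MTOS set (the conservative default for an undefined mechanism);
AgeIndex is 0 below age 15 (the models define it only for 15–54 / ≥ 55, and
the cohort floor is 14); and NTrD reuses the same AgeIndex definition.

## Discrimination analysis

All four scores are evaluated as predictors of death: NISS in the
`"higher"` orientation, RTS and both \(P_s\) in `"lower"`. Internally a
lower-oriented score is negated once, so one code path serves both.

The AUC is computed as the concordance probability (ties one half), which
equals the trapezoidal area under the empirical ROC curve — a property
tested identity. Standard errors and confidence intervals come from the
DeLong nonparametric structural components; the interval is the plain
normal approximation truncated to [0, 1], with no logit transform. Pairs of
correlated AUCs are compared with the paired DeLong test,
\(z = (\hat A_a - \hat A_b)/\sqrt{\hat v_a + \hat v_b - 2\hat c_{ab}}\); the
source study reports pairwise p-values without naming the procedure, and
the paired DeLong test is the standard choice (it is also what the named
software uses by default). The test suite cross-checks the implementation
against pROC and against a within-patient label-swap permutation test.

Optimal cutoffs maximise the Youden index \(J = \text{sens} + \text{spec} - 1\).
Candidate cutoffs are the midpoints between consecutive distinct observed
values plus one point beyond each extreme, so every achievable confusion
table is reachable under the strict-inequality classification rule
(predict death when the value is strictly beyond the cutoff in the severe
direction, matching the printed `>` / `<` directions of cutoff tables in
this literature). When several cutoffs attain the maximal \(J\), the one
with the higher specificity is reported — fewer false positives at equal
Youden height. An empty predicted margin leaves PPV or NPV undefined
(`NaN` with a warning), never 0 or 1.

`metrics_from_rates()` carries the analytic identities
\(\text{acc} = \text{sens}\,p + \text{spec}\,(1-p)\) and the Bayes
expressions for PPV/NPV at prevalence \(p\). Besides reconstructing
published table cells from printed rates, it doubles as an internal
consistency check: every cutoff row must reproduce itself through these
identities, which the pipeline asserts.

## The synthetic cohort generator

The generator emulates, not infers: no patient-level data from the source
population exist publicly, so the model is the simplest structure that
reproduces the published cohort summaries and lets mortality load on
anatomy and physiology jointly.

Per patient: age is a rounded normal (mean 36, SD 16) truncated below at 14
— the study excluded ages ≤ 13, and the floor is deliberately 14 rather
than 15 to exercise the age-14 MTOS edge case; sex and mechanism are
categorical (88.6% male; 90.5/9.3/0.2% blunt/penetrating/blast, the blast
sliver kept to exercise the mechanism mapping). A latent frailty
\(z \sim N(0,1)\) tilts both the injury count (1 + Poisson) and the
per-injury severity distribution over AIS 1–5. Injuries concentrate in a
per-patient primary body region with probability `region_cluster`:
same-region multiplicity is precisely what separates NISS from ISS, and it
is what lets NISS outrank the ISS-based MTOS model, as observed in real
trauma cohorts. A shared deterioration latent, correlated with standardised
NISS through `physiology_coupling`, drives the three vital-sign bands
through common thresholds (per-channel correlation 0.85, so RR, SBP and GCS
derange together but not in lockstep); the raw value is then uniform within
its band — band membership, not the within-band value, is all any score
sees. Death is Bernoulli with
\[
\operatorname{logit} p = \beta_0 + \beta_1\,\mathrm{NISS}
 + \beta_2\,(12 - \mathrm{RR_s} - \mathrm{SBP_s} - \mathrm{GCS_s}),
\]
so severing \(\beta_1\), \(\beta_2\) and the coupling drives every AUC to
chance — the null-model property the tests check at n = 20 000 (with the
intercept reset to keep the ~10.8% prevalence, so the check is not
noise-dominated).

**Calibration.** Free parameters were tuned once by a staged coarse grid
search (shipped as `analysis/00_calibrate.R`): the injury model against the
published NISS mean/SD (19.39/14.01), the physiology thresholds and
coupling against the RTS mean/SD (7.384/0.994), then the outcome
coefficients, coupling and region clustering against crude mortality
(10.8%), the published NISS AUC (0.878) and the requirement that NISS rank
first among the four scores. The frozen defaults give, over 20 cohorts of
n = 2208 (seeds 1–20): mortality 0.110, NISS mean 19.80 (SD 14.3), RTS mean
7.356, mean NISS AUC 0.877 (replicate SD 0.011), NISS first in 19/20
replicates. Two published summaries are knowingly not matched: the MTOS-
and NTrD-TRISS cohort means land near 0.94/0.87 rather than 0.917/0.893,
and their AUCs near 0.86/0.85 rather than 0.812/0.848 — matching those
simultaneously with this generator structure would require score-specific
distortions we judged not worth the added model freedom, and the ordering
that matters (NISS on top, all scores ≥ 0.8) is preserved.

**What passing does and does not show.** The generator reproduces summary
moments and one discrimination target under a clean missing-data-free
model. Real registries have correlated measurement error, informative
missingness, transfer-time physiology drift and coding variation, none of
which are modelled; agreement on synthetic cohorts validates the
*implementation* of the scores and the analysis engine, not the clinical
claim, and registry-specific realisations (the exact cutoff 24, sensitivity
86.6%, …) are sampling outcomes, not model properties, so they are checked
only through the analytic rate identities.

**Reproducibility.** One seed governs a cohort through R's Mersenne-Twister
stream with a fixed field-draw order; `generate_cohort(config, seed)` is a
pure function of its arguments. Records are not independent of `n` (a
smaller cohort is not a prefix of a larger one); every analysis in the
package works per (config, seed), where reproducibility is exact.

## Numerical choices and degenerate inputs

* AUC and the DeLong components are computed from midranks
  (O(n log n), no case-by-control matrix), making n = 20 000 cohorts cheap.
* A zero-variance AUC difference with equal AUCs (identical scores) returns
  z = 0, p = 1 by contract; with unequal AUCs it warns and reports p = 0.
* Degenerate outcome vectors (all died / all survived) are hard errors
  naming the empty class, at both the engine and pipeline level.
* Youden ties are resolved at 1e-12 resolution before the specificity
  tie-break.
* Displayed p-values are rounded to 4 decimals and printed as "< 0.001"
  below 1e-4; stored values are exact.

## Problem sizes

The shipped analyses use the study-sized cohort (n = 2208) and 20
replicate seeds; the oracle-equivalence test suites use 500 random
instances (n ≤ 200) for AUC, 200 for the Youden scan, 10 permutation
fixtures (n = 60, 10⁴ replicates), and single n = 20 000 cohorts for the
null-model and parameter-recovery properties. These sizes put Monte-Carlo
error well below every tolerance asserted while keeping the whole suite in
the minutes range.

## A worked example

```{r example, eval = FALSE}
report <- run_study(config = calibrate_defaults(), seed = 1)
print(report)
render_report(report, "report")
```

See the README for the output of this exact run, and `analysis/01–04` for
the scripted version of the full workflow.

## Known limitations

* Only region + severity of each AIS injury is modelled; full AIS coding
  (and hence AIS-code-level exclusion rules) is out of scope.
* The study-population exclusions that depend on information outside the
  record schema (burns, hangings, pathological fractures, isolated
  uncompromised head injury) must be applied upstream by the caller.
* Missing physiology is a hard read error; no imputation is attempted.
* TRISS coefficients are consumed, not re-estimated; calibration analysis
  (e.g. Hosmer–Lemeshow) is deliberately out of scope.
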