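---
title: "Methods: 10-year CVD risk engines, cloglog recalibration, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 10-year CVD risk engines, cloglog recalibration, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
risk engines, the recalibration procedure, the evaluation statistics, the
synthetic-cohort generator, and the numerical and design choices behind
each — including the ones that were genuinely open and the known
limitations of the method itself.

## 1. Risk engines

All engines are instances of one survival-model form. A coefficient set
holds an ordered list of terms — each a product of one or more predictors,
with optional per-factor truncation (`cap`), affine standardisation
(`center`, `scale`), and a transform (`identity`, `ln`, `ln2`) — plus a
population mean linear predictor and an average 10-year event-free
survival $S_0(10)$:

$$\mathrm{risk}_i \;=\; 1 - S_0(10)^{\exp(LP_i - \overline{LP})},
\qquad LP_i = \sum_j \beta_j\, x_{ij}.$$

Engines are deliberately *generic evaluators*: the published models (PCE
for Whites and African Americans, the ATP-III hard-CHD Framingham
equations, SCORE2) are plain JSON data files under
`inst/extdata/coefficients/`, each carrying a `source` citation and
covered by an md5 manifest (`verify_coefficients()`). Transcription
mistakes are therefore data bugs, and the engine itself is testable with
synthetic coefficient sets. The shipped transcriptions are verified in the
test suite against the source publications' own worked examples (the PCE
reference profile; the SCORE2 low-risk example).

Conventions worth knowing:

* **Units.** The canonical cohort units are mmol/L (lipids, glucose),
  mmHg, years. A coefficient set declares its units; cholesterol is
  converted by 38.67 mg/dL per mmol/L on the fly.
* **Indicators.** Smoking, treatment, diabetes are 0/1 and pass through
  products untransformed; they are never log-transformed or centred. This
  also lets a *mean risk-factor profile* (indicators as prevalences) be
  evaluated directly, which the recalibration module relies on.
  Treated/untreated blood-pressure terms are written as products with the
  `on_bp_treatment` indicator or its complement `off_bp_treatment`
  (computed as `1 - on_bp_treatment` so fractional prevalences behave).
* **Smoking** is a single current-smoker flag; former smokers count as
  non-smokers.
* **Regional factors for SCORE2.** The low-risk-region rescaling factors
  shipped are the 2021 European publication's low-risk pair; region
  factors are configuration, not code, and can be overridden with any
  JSON file of the same shape.

Local adaptation of the Framingham/ATP-III score (`sg_frs_localize()`)
replaces $S_0(10)$ by each sex-by-ethnicity stratum's Kaplan–Meier
10-year event-free survival for the CHD endpoint and touches nothing
else. Because this is a monotone transform of the linear predictor,
within-stratum discrimination is exactly preserved — the tests assert
identity of the C-index, not approximate equality. Only the substitution
of the average survival is performed; mean risk-factor values are *not*
re-centred, the literal reading of the construction.

## 2. Endpoints and eligibility

Endpoints are sets of ICD-10 ranges, split into non-fatal and fatal
qualifying events. Range semantics are root-based: a code qualifies when
its 3-character root falls in an inclusive letter–number interval, so
`I63.9` matches `I60-I63`. The shipped defaults are CHD (non-fatal MI
`I21-I22`; fatal `I20-I25`), ASCVD (CHD plus non-fatal stroke `I60-I64`
and cerebrovascular mortality `I60-I63`, `I67-I69`) and a broad CVD set
(`I10-I16`, `I20-I25`, `I44-I50`, `I60-I69`, `I70` for both fatal and
non-fatal) standing in for the SCORE2 endpoint, whose exact code list is
external — hence endpoints are a JSON configuration, and the nesting
CHD ⊂ ASCVD ⊂ CVD is property-tested on the defaults.

Non-qualifying first events (including deaths from other causes) censor
at the recorded end of follow-up; no competing-risk model is fitted.
Eligibility windows are 20–79 years (ATP-III/SG-FRS-type, diabetes
excluded), 40–79 (PCE, diabetes included as a predictor) and 40–69
(SCORE2, diabetes excluded); prevalent CVD is always excluded, and
`filter_eligible()` returns flow-chart-style exclusion ledgers.

## 3. Recalibration on the cloglog scale

The recalibration procedure relates, within each sex-by-ethnicity
stratum, the age-band average *expected* 10-year risk to the age-band
average *predicted* risk and fits

$$\operatorname{cloglog}(\text{expected}) = s_1 + s_2
\operatorname{cloglog}(\text{predicted}),
\qquad \operatorname{cloglog}(p) = \ln(-\ln(1-p)),$$

by least squares weighted by band size. Applying $(s_1, s_2)$ to an
individual prediction is strictly monotone whenever $s_2 > 0$, so
recalibration cannot change any rank statistic — C-index and quantile
membership are asserted *exactly* invariant. The same transform implements
SCORE2's regional rescaling.

Choices that were genuinely open, and what this package does:

* **Band width**: 5-year bands over the model's eligible window,
  the convention of regional SCORE2-style recalibrations; width is an
  argument of `age_bands()`.
* **Usability rules**: bands with fewer than 30 members, zero events, or
  degenerate risks are dropped; fewer than two usable bands is an error;
  a non-positive fitted slope is flagged with a warning because it would
  break rank preservation.
* **Predicted side**: the default evaluates the engine once at the band's
  mean risk-factor profile (indicators as prevalences), matching the
  description of predicted risk "at the means of the risk factors";
  `predicted = "mean_risk"` averages individual predictions instead.
* **Reconstruction caveat**: the exact published variant of this
  derivation is not fully specified in the available sources; the
  weighted cloglog line above is this package's documented base method,
  with weights, bands and the predicted-side convention all exposed.

**Known limitation — band-aggregation bias.** The cloglog map commutes
with band aggregation only when band members share one risk. Under
realistic within-band heterogeneity (smoking, blood pressure, lipids
spread risk widely within an age band), the fitted factors converge to
the *population-level* band map rather than any individual-level
distortion. The acceptance suite makes this measurable: a known
individual-level distortion $(s_1, s_2) = (\ln 2, 1.2)$ applied to the
generating engine is recovered with a bias of roughly $-0.15$ on both
parameters at $n = 50{,}000$ in a heterogeneous single-stratum cohort,
while the same pipeline on a cohort whose bands are homogeneous (age the
only varying factor) recovers both parameters well within $\pm 0.05$.
For slope-1 distortions (pure level shifts) the procedure is unbiased
either way — which is why self-calibration checks pass. Users should read
derived factors as the population recalibration the procedure defines,
not as estimates of a structural individual-level distortion.

## 4. Evaluation statistics

All risks are 10-year risks, so follow-up is truncated at the horizon
(events after 10 years count as censored at 10). Throughout, the
Kaplan–Meier machinery comes from the `survival` package.

* **C-index**: Harrell's concordance over comparable pairs (the shorter
  time must end in an event; an event precedes a censoring at the same
  time; risk ties count 1/2), computed by `survival::concordance` and
  verified in the tests against a from-scratch $O(n^2)$ pair enumeration
  — exact equality on random censored data. The confidence interval is a
  Wald interval from the analytic concordance variance. Discrimination
  bands: $<0.6$ poor, $0.60$–$0.75$ possibly helpful, $>0.75$ clearly
  useful (both boundaries fall in the middle band).
* **KM observed risk** at the horizon, with a Greenwood interval on the
  log–log scale; when no one is at risk at exactly 10 years, the estimate
  is carried forward from the last earlier event time. The KM-adjusted
  event count $n(1 - S_{KM}(10))$ accounts for follow-up shorter than the
  horizon, and reduces exactly to the crude count without such censoring.
* **Calibration (Poisson framework).** Each subject contributes an
  expected cumulative hazard
  $H_i = -\ln(1 - \mathrm{risk}_i)\cdot\min(t_i, 10)/10$, i.e. the
  10-year hazard accrued uniformly over observed follow-up — the standard
  person-time approximation, and exactly right for the generator's
  exponential event times. Calibration-in-the-large is the intercept of a
  Poisson model with offset $\ln H_i$ (negative = overestimation). The
  calibration slope is the coefficient of the *predicted* log hazard
  $\ln(-\ln(1-\mathrm{risk}_i))$ with the log exposure fraction
  $\ln(\min(t_i,10)/10)$ as offset. The split matters: folding observed
  exposure into the covariate makes it outcome-dependent (events have
  short follow-up) and collapses the slope of even a perfectly calibrated
  model to far below 1; with the offset formulation the suite verifies
  slope $\approx 1$ with nominal interval coverage under a correctly
  specified model. Intervals are Wald.
* **Analysis-of-deviance GOF**: the base Poisson model (predicted log
  hazard plus exposure offset) against the same model with risk-quintile
  indicators added; the deviance difference is $\chi^2_{g-1}$ under
  adequate fit, giving the familiar 9.5 gate at 5% for quintiles. Note
  that *affine* cloglog miscalibration is absorbed by the base model's
  intercept and slope — the test has power against non-affine (shape)
  miscalibration, which is its purpose. Quantile grouping sends ties to
  the lower group; a constant risk vector collapses groups with a warning
  rather than an error. A companion rule warns when fewer than 80% of
  groups have at least 5 (KM-adjusted) events.
* **Decision curves**: net benefit
  $P(\text{flagged} \wedge \text{event}) - P(\text{flagged} \wedge
  \text{no event})\, t/(1-t)$ with the event probability among the
  flagged estimated by KM at 10 years; treat-all and treat-none
  references included; default grid 0.01–0.30 by 0.01, covering the
  clinically relevant 5–20% window.

## 5. The synthetic-cohort generator

The generator emulates the structure the analysis needs, not any real
dataset:

* **Templates.** A development-style template (mean age 45.4, SD 12.8,
  ages 21–80, 43% male, 47/26/27% Chinese/Malay/Indian, administrative
  censoring uniform on 9.3–14.5 years) and an older validation-style
  template (58.1 ± 10.2, ages 40–80, 48% male, 35/33/32%, censoring
  7.4–13.8 years). Ages are truncated normals whose *parent* parameters
  are solved numerically so the truncated distribution hits the template
  mean and SD.
* **Risk factors.** SBP, total and HDL cholesterol are drawn jointly with
  age from a Gaussian copula-style conditional construction (correlations
  age–SBP 0.4, age–TC 0.2, TC–HDL 0.2 by default). These dispersions and
  correlations are plausible fabrications — no real covariance structure
  was available — and are fully overridable; they are the single largest
  lever on within-band heterogeneity (see the recalibration limitation
  above). Diabetes is derived from generated physician diagnosis,
  fasting glucose and HbA1c through the same rule applied to real data
  (physician diagnosis, or fasting glucose ≥ 7 mmol/L, random glucose
  ≥ 11 mmol/L, HbA1c ≥ 6.5%).
* **Outcomes.** The true 10-year event probability is a configurable
  cloglog distortion $(s_1, s_2)$ of a chosen engine's prediction. Event
  indicators are Bernoulli; event times are exponential *conditioned to
  fall inside the horizon* — memoryless by design, because every
  downstream statistic consumes only the 10-year cumulative risk, and
  because exponential accrual makes the Poisson person-time approximation
  in the calibration module exact rather than approximate. Censoring is
  administrative and independent. Events are coded `I21` (non-fatal MI),
  which qualifies for all three shipped endpoints.
* **What passing tests do not show.** The generator has no competing
  mortality, no calendar-time effects, no measurement error, no
  non-proportional hazards, and its correlation structure is invented.
  Green tests demonstrate that the *procedures* are correct on data
  satisfying their assumptions — not that any particular published model
  is well calibrated for a real population.

## 6. Problem sizes and reproducibility

The test and acceptance workloads were sized to be statistically
informative yet quick: 20,000-participant cohorts (5 seeds) for
self-calibration coverage, 50,000 for distortion recovery and net-benefit
dominance, 1,000 replicate cohorts of ≈5,000 eligible participants for
the null rejection rate of the deviance test, and 100 random datasets of
up to 200 rows for exact brute-force verification of the concordance
estimator. Every stochastic step is seeded; `run_study()` derives all
cohort seeds from one root seed, records config hashes and coefficient
versions in a provenance block, and writes byte-identical reports on
re-run. Recalibration factors are derived on the development cohort only;
the no-leakage property (factors unchanged when the validation cohort
changes) is asserted in the tests.
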