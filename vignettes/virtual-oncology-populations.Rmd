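---
title: "Simulating virtual oncology populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating virtual oncology populations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopop)
```

## The model

`oncopop` builds virtual adult oncology patients in two layers.

The *primary* layer samples the fixed patient characteristics
independently, with one exception: tumour type is drawn first from a
multinomial distribution over nine categories, and sex is then Bernoulli
conditional on the tumour (breast, endometrial and ovarian cancers are
female-only; the male probabilities for the remaining tumours default to
the sex-stratified count ratios of the source cohort, e.g. 513/865 for
lung). Biogeographic origin and ECOG performance status are independent
multinomials, and age is Weibull-distributed per (sex × sarcoma) group,
truncated to the adult range.

The *secondary* layer is a directed acyclic cascade of ten linear
regression equations (see the README table). Each stage models its response
on either the linear or the natural-log scale; a Gaussian residual is added
on the modeled scale, log responses are exponentiated, and physiologic
bounds are enforced. Because each stage only references primaries and
strictly earlier responses, one forward pass per patient produces a
complete record; body surface area (Mosteller) and BMI are derived from the
simulated height and weight, exactly, at the end.

Assumptions inherited from this structure:

* residuals are Gaussian and homoscedastic on each modeled scale;
* primaries are mutually independent apart from the sex-on-tumour link
  (no origin×tumour or ECOG×tumour dependence);
* the regression coefficients transfer to any population whose primaries
  stay within the training ranges (adult, ECOG 0–2).

### The logarithm base and the haematocrit stage

The published equations do not state the logarithm base. We use the natural
log because exponentiating the printed intercepts then yields physiologic
values (e.g. `exp(4.32)` ≈ 75 mg/dL for AAG at all reference levels,
`exp(5.709)` ≈ 301 U/L for LDH), which base 10 does not.

The final stage is printed with a log-scale left-hand side
(`Log HTC (%) = 5.93 + 0.04·logAAG + 2.515·Hb`), but exponentiating that
expression gives astronomically large values, whereas reading the left-hand
side as *linear* haematocrit yields 30–45% for physiologic inputs. The
linear reading is therefore the default; `default_coefficients(htc_scale =
"log")` restores the literal printed form for users who want it. This is an
inference, not something the source states.

### Mixed covariate scales

The cascade uses covariates exactly as printed even where the choice looks
inconsistent: stage 6 consumes *log* AAG while stage 7 consumes raw AAG
(mg/dL) and the raw N-L ratio, stage 8 the raw P-L ratio, and stage 9 raw
CRP. Similarly, stage 6's coefficient on log AAG (−0.0073) is two orders of
magnitude smaller than its neighbours; it is implemented as printed. The
height slope in the log-weight stage is sex-conditional (0.012 for males,
0.008 for females), which we implement as a common 0.012 slope plus a
−0.004 height-by-female interaction — algebraically identical, and the form
the refitting path estimates.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| cohort size `n` | 1259 (reference), 1200 (scenarios) | patients | sizes of the training set and extrapolated cohorts |
| age targets | male 62.3 (9.3), female 59.1 (11.2) | years | published sex-specific mean (SD); moment-matched to Weibull shape/scale |
| age bounds | [18, 95] | years | adult oncology cohort; pediatric extrapolation is explicitly out of range |
| residual sds | 0.1 (each log scale), 4 cm height, 0.3 g/dL albumin, 1.0 g/dL Hb, 2.0% HTC | modeled scale | documented placeholders of physiologic magnitude (see below) |
| physiologic bounds | albumin 1–6 g/dL, Hb 5–20 g/dL, HTC 15–60%, others > 0 | natural scale | prevent rare absurd draws from unbounded Gaussians |
| ECOG probabilities | 35/55/5 (renormalized) | — | printed percentages sum to 95; renormalization is the only self-consistent reading |

Two published parameter sets are referenced by the source but not printed
in its main text: the fitted Weibull shape/scale values of the four age
groups, and the per-stage residual variances. For the former we moment-match
the printed sex-specific mean (SD) ages — applied identically to the
sarcoma and non-sarcoma groups until a user overrides them per group (the
four-group structure is preserved in `age_targets`). For the latter the
defaults above are deliberate placeholders; `calibrate_residuals()` solves,
by bisection in network order, for the per-stage sd that reproduces a
user-supplied marginal SD target (e.g. a published cohort height SD) within
2% relative, reporting a stage as *saturated* (sd 0) when upstream
variability alone already exceeds the target.

## What the generator emulates — and what it does not

The generator reproduces: the reference cohort's primary-variable
composition (96/2/2% origins, 35/55/5 ECOG, the nine-tumour mix, sex fixed
by tumour), the published age moments, the full regression cascade, and the
eight extrapolation scenarios (every unspecified field inherits the
reference value exactly; the pancreatic-only scenario draws sex from the
conditional male-given-pancreatic probability 43/66).

It does **not** emulate: the sampling noise structure of real laboratories
(measurement error, digit preference, detection limits), missingness,
trial inclusion/exclusion truncation (e.g. very low albumin excluded by
protocol), within-patient longitudinal correlation, or any dependence of
origin/ECOG on tumour type. Passing tests therefore demonstrate
*self-consistency* — the package inverts and reproduces its own generative
model, and worked examples match printed values — not fidelity to any real
dataset, which is confidential and unavailable. The variables the source
could not model (bilirubin, transaminases, creatinine, INR, glucose, ...)
are not simulated. One consequence worth knowing: composing the cohort
tumour-first with conditional sex yields ≈ 65–66% females, slightly above
the printed 63% marginal; we keep the tumour-first reading because the
network defines sex as fixed *given* tumour.

## Numerical choices

* **Multinomial draws** use inverse-CDF over a fixed, documented category
  ordering, so results are reproducible across platforms; ties are
  impossible.
* **Weibull moment matching** root-finds the shape on the squared
  coefficient of variation (strictly decreasing in shape, evaluated via
  `lgamma` to stay finite), then sets the scale analytically; the round
  trip is verified to 1e-6 relative and cv > 5 is rejected as unsolvable
  territory.
* **Truncation** (age, physiologic bounds) uses rejection sampling with a
  1000-round cap and clamping as the fallback; age bounds that exclude
  more than 99% of the distribution's mass are refused as configuration
  errors.
* **Refitting** is ordinary least squares via a QR decomposition with
  classical homoscedastic standard errors, on the stage's modeled scale,
  always against *observed* upstream covariates; rank deficiency is
  reported with the collinear columns named, and rows with missing
  required values are dropped per stage with a logged count.
* **Stepwise selection** defaults to bidirectional AIC (the conventional
  default of the toolchain the source used), with BIC and a backward
  p-value (0.05) mode; the candidate list is the template's terms, since
  the source's entry/exit thresholds and "biological causality" constraint
  are unspecified.
* **Train/validation split** takes `round(fraction·n)` training rows
  (1793 → 1255/538 at 70%); the source's printed 1259/534 arises from its
  own tool's internal stratification and is treated as descriptive.
* **GOF R²** is `1 − SSE/SST`, computed on the modeled (log) scale for
  log-scale variables by default since the source's choice is not stated;
  the qualitative bands put boundary values on the closed side of the
  printed ranges (0.9 and 0.4 → good, 0.1 → modest).
* **Seeding**: every sampler accepts a seed and restores the caller's RNG
  state; scenario batches derive per-scenario sub-seeds from the master
  seed and the scenario *name*, so adding a scenario never changes another
  scenario's draws.

## Problem sizes

The test suite exercises parameter recovery at n = 200,000 (one shared
simulation), the directional extrapolation contrasts at n = 100,000 for two
seeds, distributional properties at n = 1000 random moment targets, and
everything else at 200–20,000 patients; the acceptance script simulates
200,000 patients once. These sizes make OLS standard errors small relative
to the recovery tolerances while keeping a full run in minutes on one CPU.

## Known limitations

* Fidelity to real oncology populations cannot be established here; only
  published summary values and internal consistency are testable.
* The default residual sds are calibratable placeholders, not the source's
  fitted values; marginal spreads of secondary variables should be
  calibrated before quantitative downstream use.
* Extrapolation outside the validated ranges (pediatric ages, ECOG > 2,
  origins beyond the three modeled) is unsupported by design.
* ECOG-PS and origin are independent of tumour type in the generator even
  though real cohorts show such dependence.
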