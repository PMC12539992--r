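---
title: "Updating a points-based risk score for cisplatin-induced AKI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating a points-based risk score for cisplatin-induced AKI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cakiscore)
```

## The problem

Cisplatin is nephrotoxic: even at first exposure, roughly one patient in ten
develops cisplatin-induced acute kidney injury (C-AKI), defined here as a
serum-creatinine rise of at least 0.3 mg/dL within 14 days of the first dose,
graded by AKIN fold-change criteria (stage 1 below 2-fold, stage 2 from 2- to
3-fold inclusive, stage 3 above 3-fold). The Motwani points score estimates
this risk before administration from four binned factors — age, serum
albumin, absolute first-course cisplatin dose and hypertension — summing to
0–9.5 points on a 0.5 grid, with a published logistic anchor (probability
0.04 at score 0, odds ratio 1.49 per point, hence intercept
$\alpha = \mathrm{logit}(0.04) = -3.178$ and slope
$\beta = \ln 1.49 = 0.399$).

`cakiscore` implements the full life cycle of validating such a score on a
new cohort and updating it with a supportive-care predictor (magnesium
supplementation), in five stages:

1. **Univariate screening** — Woolf odds ratios and Fisher's exact test for
   binary covariates, per-unit logistic odds ratios and Mann–Whitney tests
   for continuous ones.
2. **External-style validation of the anchored score** — the metric battery
   below with the published coefficients held fixed (no refitting).
3. **Recalibration and extension** — the score enters a logistic model as a
   single predictor ($\mathrm{logit}\,p = \alpha + \beta_1 s + \beta_2 x$);
   the component coefficients inside the score are never re-estimated.
   Candidate predictors are scanned one at a time, ranked by AIC, and a drop
   greater than 10 is treated as significant. The winning predictor receives
   score points equal to its odds ratio divided by the odds ratio per one
   existing-score point, rounded to the nearest 0.5 (ties away from zero).
4. **Internal validation** — bootstrap optimism correction of the
   C-statistic: the model-building procedure is repeated on each resample and
   the mean of (bootstrap-sample C − original-cohort C) is subtracted from
   the apparent C.
5. **Clinical usefulness** — categorical net reclassification improvement
   across the bands <10% / 10–20% / ≥20%, integrated discrimination
   improvement, and decision curve analysis.

## The metric battery

For fixed predicted probabilities $p_i$ with linear predictors $\ell_i$ and
outcomes $y_i$:

* **Cox–Snell $R^2$** $= 1 - \exp(-2(\ell_m - \ell_0)/n)$ with $\ell_m$ the
  model log-likelihood under the *fixed external coefficients* and $\ell_0$
  the intercept-only maximum. Because the evaluated model is not refit,
  $\ell_m < \ell_0$ is possible and $R^2$ legitimately negative — this is
  what a badly transported score looks like, and the implementation
  deliberately permits it. Nagelkerke rescales by the maximum attainable
  value.
* **Brier score** $= \frac1n \sum (p_i - y_i)^2$.
* **Calibration-in-the-large** — intercept of a logistic fit with $\ell_i$
  as fixed offset; **calibration slope** — slope of a logistic fit on
  $\ell_i$ with free intercept (below 1 means overdispersed predictions);
  **O/E ratio** $= \sum y_i / \sum p_i$ (below 1 means overestimation).
* **ICI** — mean absolute difference between $p_i$ and a loess smooth
  (span 0.75, degree 1, tricube weights) of $y$ on $p$. The span is
  exposed as an argument; the value 0.75 is the conventional default, since
  no smoother is specified for this metric in the source material.
* **C-statistic** — concordance with ties counted 0.5, computed via
  midranks in $O(n \log n)$ and tested against brute-force pair counting.

Confidence intervals are percentile bootstrap over patient resamples
(default $B = 10{,}000$ as in the study; tests and the default pipeline use a
few hundred to stay within CI budgets — this widens nothing, it only adds
Monte-Carlo noise to the interval endpoints). Resamples containing a single
outcome class are skipped and counted; a warning is raised if more than 1%
are skipped. Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before
any logit.

## Logistic fitting

`fit_logistic()` is an in-package iteratively-reweighted-least-squares
implementation with step-halving, kept deliberately transparent because the
package's contracts reference iterate-level behaviour: the log-likelihood
trace is stored and never decreases, convergence requires a gradient norm
below $10^{-8}$ or a relative log-likelihood change below $10^{-10}$ within
100 iterations, rank-deficient designs and perfectly separated outcomes
raise typed errors rather than returning diverged estimates. It is tested
against `glm()` and against an independent fine-grid likelihood
maximisation.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` emulates the
published cohort's marginal structure (n = 1785): 69.0% male, 37.1%
hypertension, 13.1% diabetes, 19.7% without magnesium supplementation, 20.8%
short hydration, and per-drug exposure prevalences from the published
univariate table. Continuous covariates (age 66 [59–71] years, albumin 3.9
[3.5–4.2] g/dL, dose 110 [90–128] mg, creatinine 0.7 [0.6–0.9] mg/dL,
weight 57.6 [50.1–65.5] kg) are log-normal, parameterised by matching the
printed median (meanlog) and IQR ratio (sdlog), truncated to plausible
clinical ranges. Only median and IQR are published, so the distributional
family is a modelling choice; log-normal keeps all record invariants
positive with right-skew typical of clinical measurements.

Outcomes follow the fitted updated model reported for the cohort:
$\mathrm{logit}\,p = \ln 0.04 + \ln 1.29 \cdot s + \ln 3.91 \cdot
(1-\mathrm{Mg})$, where $s$ is the base score. The follow-up creatinine is
then constructed so that `classify_aki()` reproduces the drawn outcome
exactly: events receive an increase of 0.3 mg/dL plus an exponential tail
with mean 0.25 mg/dL (chosen once so that about 20% of events exceed the
2-fold AKIN-stage-2 boundary, close to the published stage mix), non-events
an increase uniform on [0, 0.295) (the 0.295 ceiling leaves a floating-point
margin below the 0.3 threshold). Each field draws from its own child stream
of the root seed, so adding a field never shifts existing draws.

**What the generator does not emulate** — and therefore what a green test
does not establish: covariates are drawn independently (the real cohort
surely correlates age, dose, renal function and the magnesium era), there is
no tumour-type structure, no time-series creatinine, and no confounding
between magnesium supplementation and calendar period. A pipeline that is
correct on this generator is correct *as software*; transportability claims
still need real data.

## Design choices where the design was open

* **Band boundaries.** Scores live on a 0.5 grid so the printed bands
  0–3.5 / 4–6.5 / ≥7 are unambiguous; probability bands assign both 0.10
  and 0.20 upward ("20% or more" is explicit; 0.10 is treated
  symmetrically).
* **AKIN stage 2 upper bound.** "2- to 3-fold" is read as closed at 3.0,
  consistent with stage 3 being "> 3.0-fold".
* **Odds-ratio intervals.** Woolf (log-normal) intervals reproduce the
  printed capecitabine interval (1.09–55.5) exactly; the conditional-MLE
  interval from Fisher's framework does not. Zero cells are flagged
  undefined (printed as "—") rather than continuity-corrected.
* **Fisher two-sided definition.** Probability-mass method: sum of
  hypergeometric probabilities not exceeding the observed table's, the
  convention shared by `stats::fisher.test` and scipy.
* **Points division on the OR scale.** The published rule divides odds
  ratios (3.91 / 1.29 = 3.03 → 3.0 points), not log-odds; dividing
  log-odds would give about 5.4 and a different score. The OR-scale rule is
  the implemented default because its printed arithmetic fixes the intended
  behaviour; the log-odds alternative is deliberately *not* offered as a
  default anywhere.
* **Exact-tie rounding.** A raw ratio exactly between 0.5 grid points
  rounds away from zero (unspecified in the source; stated once here).
* **CKD-EPI version.** The 2009 creatinine equation without the race
  coefficient — the cohort is Japanese and no race field exists in the
  schema.
* **Short hydration.** Volume < 3 L *and* duration < 5 h, both strict;
  "duration" is the infusion duration.
* **Decision curves.** A patient is treated when $p \ge$ threshold (ties
  treated); the default grid is 0.01–0.99 in steps of 0.005.
* **Treat-all reference.** Implemented as $p \equiv 1$, which crosses zero
  exactly at the cohort prevalence.

## Numerical and degenerate-input policy

Non-positive creatinine, probabilities outside the unit interval and
malformed configs raise typed `invalid-input`/`config` errors. Empty risk
bands report an undefined (`NA`) rate rather than raising. Constant
predictors are fit errors for the univariate logistic but are flagged (not
fatal) inside table builders, mirroring how published tables print "—" for
degenerate rows. The bootstrap never refits the evaluated score model;
optimism correction, by contrast, refits the whole updating procedure per
replicate, because that is the quantity being measured.

## Known limitations

* The optimism of the 3-parameter updated model at n = 1785 is genuinely
  tiny (the study reports 0.0012), so at the scaled-down replicate counts
  used in tests its *sign* is at the edge of Monte-Carlo resolution; the
  acceptance property asserting non-negative mean optimism at B = 500 fails
  in roughly 15% of seeds. The package reports whatever the resamples say —
  at the study's B = 10,000 the sign is stable.
* The Mann–Whitney p-value uses the normal approximation with tie
  correction and continuity correction; for tiny, heavily tied samples it
  can differ from the exact permutation p by up to ~0.06.
* NRI/IDI intervals are patient-level percentile bootstrap; when only a
  printed reclassification table is available (no patient-level data), only
  the point estimate is computable.

None of the numbers quoted above are asserted by this vignette itself; every
one is computed by the test suite or the acceptance script.
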