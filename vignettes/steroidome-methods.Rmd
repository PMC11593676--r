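---
title: "Steroidomic case-control analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steroidomic case-control analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidome)
```

## The problem

Comprehensive serum steroid panels ("steroidomes") measured by
GC-MS/MS compare dozens of strongly inter-correlated, right-skewed,
positive concentrations between a patient group and controls. Three
statistical problems dominate such studies:

1. **Per-variable screening is massively multiple.** With 81 analytes
   and ~190 enzyme-panel molar ratios, 0.05-level tests produce false
   positives by the handful. Rather than correcting each test, the
   package aggregates a panel's *significance directions* into one
   meta-statistic (the sign-trend test below), asking whether the
   panel as a whole trends up or down in patients.
2. **Raw concentrations are far from Gaussian.** Every variable is
   power-transformed toward normality before parametric analysis.
3. **Predictors are collinear by biology** (shared pathways, shared
   regulation), which defeats ordinary multiple regression. Group
   classification therefore uses OPLS, which concentrates the
   class-predictive variation into one component and shunts the
   shared, class-irrelevant variation into an orthogonal component.

`run_pipeline()` chains these stages: transform → ratios → ANOVA
screen → direction coding → per-panel trend tests → per-panel OPLS
with VIP selection, Hotelling screening, cross-validation and an
LLR-based classification report.

## The analyte and ratio registry

The packaged registry (`load_catalog()`) is a declarative text file,
not code, so panel membership can be audited line by line: 81
analytes (46 unconjugated, 35 polar conjugates; units pM/nM/µM) and
15 enzyme panels of product/precursor molar ratios (e.g.
17-OH-Preg/Preg for the CYP17A1 hydroxylase step, F/E for HSD11B1,
conjugate/free ratios for the SULT2A1-vs-STS balance). All ratio
arithmetic converts to nM first, so ratios are dimensionless and
invariant to the unit each analyte happens to be recorded in.

Registry conventions worth knowing:

* A `", C"` suffix in a printed ratio name denotes the conjugated
  counterpart of each constituent that has one; constituents without
  a registered conjugate stay free. The registry stores fully
  resolved keys, so no name parsing happens at evaluation time.
* `"3α/β"` shorthand expands to both epimers, summed in the
  numerator (multi-key sides are summed before division).
* Two source entries share the printed key "3α,5β-THPC"; the second
  (conjugated epipregnanolone) is registered under the disambiguated
  key `3β,5β-THPC`, with the ambiguity recorded in its note field.
* Missing constituents propagate to a missing ratio — no imputation;
  a zero denominator yields `NA` with a warning, not an error.

## Power transformation

Concentrations are Gaussianized per variable with a one-parameter
Box-Cox transform, `y = (x^λ − 1)/λ` (`log x` at `λ = 0`), fitted on
patients and controls pooled (no group-wise rule is defensible when
the groups are later compared on the transformed scale). λ is chosen
by exhaustive scan of `seq(-3, 3, by = 0.01)` — deterministic and
reproducible, no local optima. The normality criterion is the
Shapiro–Wilk W for n ≤ 50 and the (negated) Anderson–Darling
statistic above that, both oriented so larger is more normal; by
construction the selected λ never scores worse than the identity.
The transform is monotone for every λ, so rank-based quantities are
unaffected, and the stored mean/SD standardize variables for the
OPLS stage. Degenerate inputs (constant vectors, non-positive values
without a sufficient shift, fewer than 8 observations) are errors,
not silent fallthroughs.

## Univariate screening

Each transformed variable is modelled as
`value ~ status + age_group`, with age dichotomized at 38 years —
age structure is strong in steroid panels and this two-level
adjustment is the model the screening stage is defined with. The
model has main effects only; with no interaction term, Type-II and
Type-III sums of squares coincide, so the status SS is computed
exactly as the residual-SS increase when status is dropped. Effect
size is partial eta-squared, `SS_status / (SS_status + SS_resid)`.
If one age stratum is empty the model falls back to one-way ANOVA
with a warning. Severity indices (EDSS, timed 25-foot walk, 9-hole
peg tests) are correlated with each variable in patients only
(controls have no severity scores), Pearson by default — consistent
with the Gaussianizing step — with a Spearman switch.

Direction codes are ±1 when the status p-value is below 0.05 (the
screening level is deliberately uncorrected: multiplicity is handled
by the trend meta-test, not per variable), 0 otherwise.

## The sign-trend meta-statistic

A panel of codes `(u, m, d)` — u up, m null, d down — is tested with
the one-sample Wilcoxon signed-rank test under the **Pratt**
convention: zeros are ranked with everything else (they occupy the
lowest ranks because |0| < 1) and then dropped from the rank sums.
All non-zero codes tie at the shared mid-rank `m + (k+1)/2`
(`k = u + d`), giving

* `W⁺ = u · (m + (k+1)/2)`,
* `μ = [N(N+1)/2 − m(m+1)/2] / 2`,
* `σ² = [N(N+1)(2N+1) − m(m+1)(2m+1)]/24 − (k³ − k)/48`

(the last term is the Cureton tie correction for the single non-zero
tie group), and `z = (W⁺ − μ − 0.5·sign(W⁺ − μ))/σ`, two-sided
normal. The 0.5 is the continuity correction; |W⁺ − μ| ≤ 0.5 clamps
z to 0. This exact recipe — Pratt zeros, Cureton ties, 0.5
continuity, normal tail — is pinned down by the reference results it
must reproduce: dropping zeros instead of Pratt-ranking them gives
0.149 instead of 0.102 for the (0/4/3) panel, for example. The
normal approximation is used even at k = 2 (matching the reference
values); exact enumeration is available behind `exact = TRUE` for
methodological comparison only. `signed_rank_general()` implements
the same statistic for arbitrary reals (mid-ranks, per-tie-group
correction) and the closed form is tested to agree with it
exhaustively for all `u, d ≤ 25`, `m ≤ 70`.

The test treats panel members as exchangeable and independent;
correlated variables within a panel widen the true dispersion of
`u − d` and make the meta-test mildly anti-conservative, which is
why the calibration study below simulates correlated pathway blocks
rather than independent analytes.

## OPLS with one predictive and one orthogonal component

The class response is coded +1 (patient) / −1 (control). On
standardized predictors, the model is `X = Tp Pp' + To Po' + E` with
the response regressed on the single predictive score `Tp`; the
component counts are fixed at 1 + 1 by construction (requesting more
is an error). The orthogonal weight is the part of the X-loading of
the initial PLS component that is orthogonal to its weight; after
deflating the orthogonal variation, the predictive component is
refit. One consequence worth stating plainly: deflation cannot
change the one-component weight vector itself (`t_o'y = 0` exactly),
so the orthogonal component improves the predictive *scores* and
their interpretability, not the weight direction — our tests assert
this identity against a NIPALS PLS1 oracle rather than pretending
otherwise.

Design choices:

* **Sign convention**: the predictive component is oriented so
  patients have positive mean score; outputs are deterministic.
* **LLR link**: the predictive score is mapped to a
  log-likelihood-ratio of class membership by a pooled-variance
  linear discriminant on the score, `llr = (m₁−m₀)/s² · (Tp −
  (m₁+m₀)/2)`. The training decision point maps to `llr = 0` and
  `probability = exp(llr)/(1+exp(llr))`, so probabilities are proper
  and the label rule is `probability > 0.5`. The reported
  coefficients `b` reproduce the fitted LLR from standardized
  predictors to 1e-8.
* **VIP**: with one predictive component,
  `vip_j = sqrt(p)·|w_j|/‖w‖`, so `mean(vip²) = 1` identically.
  `select_predictors()` drops variables below the threshold
  (default 1.0 — the conventional cutoff; the value is configurable)
  and refits once. A second elimination pass is possible but
  over-prunes in our simulations (it halves the retained informative
  variables), so one pass is the default behaviour.
* **Hotelling screening**: T² of the (Tp, To) score pair against the
  `a(n−1)/(n−a)·F(a, n−a)` ellipse; flagged subjects are removed and
  the model refit, at most twice. The flagging rule is calibrated
  (≈3% flags on clean scores at the 0.95 level); note that each
  refit re-flags ~5% of the remaining data by construction, which is
  exactly why the rounds are capped.
* **Cross-validation**: venetian blinds, subject `i` to fold
  `((i−1) mod 7)+1`, deterministic in table order; each training
  remainder re-estimates its own centering/scaling. If a remainder
  lacks a class the subjects are re-interleaved by class once,
  deterministically. `explained_cv = 100·(1 − PRESS/SS_tot)` may be
  negative on uninformative data.
* **Model export**: per-variable loading correlations (`loading_R`),
  VIP and LLR-scale coefficients via `tidy()`; per-subject LLR,
  probability and label via `classification_report()`. Sensitivity
  and specificity are in-sample, after outlier removal, with Wald
  intervals `p̂ ± 1.96·sqrt(p̂(1−p̂)/n)` clipped to [0, 1].

## The simulator and what it does (not) show

`simulate_steroidome()` draws log-normal concentrations: the
log-scale baselines (geometric mean and SD) of every analyte come
from the registry's reference control medians and quartiles, so
simulated tables have realistic scales in each analyte's native unit
and exercise the unit conversion and every ratio panel. Structure:

* **Cohort**: 25 patients / 15 controls by default, ages ~N(40, 10²)
  truncated to 20–65 — the scale of the reference cohort.
* **Correlation**: block-exchangeable ρ = 0.5 within steroid classes
  (Δ5, Δ4, 5α/5β-reduced, corticoids, 11β-hydroxy-androstanes) —
  pathway neighbours are strongly correlated in real steroidomes.
* **Conjugate coupling**: each conjugate is its parent's log
  concentration plus a registry-derived offset and N(0, 0.3²) noise,
  so conjugate/free ratios carry realistic dependence.
* **Age**: Δ5 sulfates plus free DHEA and androstenediol decline at
  1.5%/year — adrenal androgen aging, the reason the screening model
  adjusts for age.
* **Effects**: the default plants 5 analytes up and 15 down at one
  log-SD, the aggregate direction pattern the screening stage is
  meant to recover; ground truth (signs, shifts, affected keys) is
  returned alongside the data.
* **Severity**: patients get a latent severity ~N(0,1); EDSS (0–7 in
  0.5 steps), walk and peg-test times are monotone noisy functions
  of it. Affected analytes are coupled to severity with sign
  *opposite* to their group effect, so the discordance scenario —
  patient-vs-control differences that attenuate with advancing
  disease — can be planted and detected.

What the simulator does **not** emulate: measurement
heteroscedasticity and limits of quantification, menstrual-phase and
diurnal structure, medication effects, non-lognormal tails, and
missingness. Passing calibration and recovery tests on simulated
data therefore demonstrates correctness of the statistical
machinery under the stated model, not field performance on real
cohorts.

## Calibration and problem sizes used by the test suite

The suite fixes seeds everywhere and uses these study sizes, chosen
to give stable Monte-Carlo estimates at desk scale: 100 null cohorts
(25/15 subjects, zero effects) for the pipeline-wide false-trend
rate, pooled over all ~25 panels per cohort, required ≤ 10% at
α = 0.05; 100 seeded datasets (40 subjects, 20 variables, 6
informative at 1 SD) for discriminant-direction recovery; 200 null
runs for cross-validation calibration; 40 replicates for the
planted-pattern power study. The replicate loops use a coarsened
Box-Cox grid (step 0.25–0.5): λ resolution beyond that does not
change significance-direction codes, and the full 0.01 grid remains
the single-analysis default.

Two honest quantitative notes, both visible in the test suite: the
discriminant-recovery target of median |r| ≥ 0.9 is not reachable at
40 subjects total — the per-coordinate information bound puts the
raw-weight correlation near 0.82 (measured 0.83; 0.87 after VIP
selection); roughly twice the subjects would be needed. And with
per-variable power ≈ 0.85, the planted (5 up/15 down) pattern yields
a significant down-trend in only ~55% of replicates — the ideal
triplet (5/61/15) itself sits at p = 0.026, so sampling noise
frequently crosses 0.05. Both are properties of the study design,
not of the implementation, and the tests assert the oracle-computed
values.
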