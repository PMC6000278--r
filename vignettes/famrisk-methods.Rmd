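---
title: "Methods: familial lung-cancer risk models from matched case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial lung-cancer risk models from matched case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrisk)
```

## The design and the models

`famrisk` analyses 1:1 spouse-matched case-control studies of lung cancer.
Each pathologically confirmed case contributes their spouse as the matched
control: spouses share no ancestry with the case's blood relatives but
largely share the adult living environment, which makes the design a
natural control for household exposures when the question is familial
aggregation of cancer risk.

All covariates are coded categorically with the lowest-risk category as 0:
sex (0 female, 1 male), age group (0 under 50, 1 at least 50), smoking
index — cigarettes per day times years smoked — as never / under 400 /
400 or more (0/1/2), lung-disease history (0/1), daily living-environment
carcinogen contact (0/1), occupational exposure (0/1), and number of
first-degree relatives with cancer as 0 / 1 / two-or-more (0/1/2).
Three-level covariates enter models as two treatment-coded dummies, never
as a single ordinal score: the published model table reports separate
effects per level, and a shared slope across levels is an assumption the
data contradict (the light-smoking effect is near zero while heavy smoking
is large).

Three estimators sit on top of this coding:

1. **Crude odds ratios** from 2×2 tables, `OR = ad/bc`, with Woolf's
   delta-method interval `exp(log OR ± z sqrt(1/a+1/b+1/c+1/d))`,
   `z = 1.96` by default (95% intervals throughout). Zero cells raise an
   error; the Haldane–Anscombe +0.5 correction exists only as an explicit
   opt-in, because the published sparse stratum (7 exposed cases against 1
   exposed control, OR 9.12) is exactly the raw Woolf estimate and a
   silent correction would not reproduce it. Pearson chi-square is the
   uncorrected statistic (no Yates continuity correction) — verified
   against the published balance-table P values, which match the
   uncorrected form at printed precision. Fisher exact and the
   pooled-variance *t* are delegated to `stats::fisher.test` and
   `stats::t.test(var.equal = TRUE)`; all tests are two-sided.
2. **Conditional logistic regression** maximises the matched-pair
   likelihood, conditioning the pair-level nuisance out; there is no
   intercept. Fitting is delegated to the exact conditional likelihood of
   `survival::clogit`; the package screens terms for within-pair
   discordance first. A term concordant within every pair carries no
   conditional information: it is dropped with a warning rather than
   failing the fit, and a model whose every term is concordant is rejected
   as unidentifiable. For one binary covariate the conditional MLE is the
   log ratio of discordant counts, `ln(n10/n01)` — the package's tests use
   that closed form, and an independent intercept-free logistic fit on
   within-pair covariate differences, as oracles.
3. **Unconditional logistic regression with forward stepwise selection**
   builds the risk model. Entry is by the Rao score test (smallest p among
   the excluded candidates, threshold `p_enter = 0.05`), removal by the
   likelihood-ratio test (`p_remove = 0.10`), multi-level factors moving
   as blocks with df = levels − 1. The entry/removal test flavours are the
   common defaults of the major statistical packages' forward procedure;
   since procedure descriptions rarely name the flavour, both tests are
   computed from standard ML fits and the thresholds are plain arguments.
   The score test is evaluated at the null fit (no refit per candidate),
   which keeps a full selection pass at two thousand pairs under a second.

## Intercept recalibration and the stratum table

A case-control sample fixes the case fraction by design, so the fitted
intercept a′ estimates the population intercept plus the log ratio of the
case and control sampling rates. With population incidence `q1`
(`q0 = 1 − q1`) and sample sizes `n1`, `n0`,

    a = a' − ln(n1 q0 / (n0 q1)).

`correct_intercept()` is this arithmetic, exactly; `population_prior()`
validates the inputs (a rare-disease prior, `q1 < 0.5`, is required). The
default `q1` is 49.7 per 100,000, the registry lung-cancer incidence used
by the reference study; it is a parameter everywhere, never a constant in
code.

`enumerate_strata()` evaluates `logit = a + beta'x` for covariate
patterns — either those observed in a cohort or the full grid of
2 × 2 × 2 × 3 × 3 = 72 legal patterns — and reports absolute probability,
relative risk `RR = p/q1`, and a risk band. Two probability modes exist:

* `expit` — the exact logistic inverse, used in all internal monotonicity
  checks;
* `odds_approx` — `exp(logit)`, the small-probability approximation. This
  is the default because recomputation shows the published stratum table
  follows `exp(logit)`, not the logistic inverse, for its largest entries
  (its top stratum prints 0.0313 where the exact inverse gives 0.0304).
  The absolute discrepancy between the modes is of order p², negligible
  below p ≈ 0.05; the function warns once results reach 0.1.

Strata are sorted by ascending probability, ties broken by pattern
lexicographic order in the table's column order. The published table lists
only the 58 patterns it calls observed subgroups but counts several of
them with zero subjects, so the observed/full distinction is left to a
`grid` switch rather than guessed.

Risk bands follow the textbook strength-of-association scale — RR 1.0–1.1
none, 1.2–1.4 weak, 1.5–2.9 moderate, 3.0–9.0 strong, 10 and above very
strong. These bands are not a partition of the positive axis: the package
maps the gaps (1.1–1.2, 9–10) to the nearest lower band and labels RR
below 1.0 explicitly as `below-reference` rather than silently extending
the "none" band downwards.

## Classification

Classification uses the strict published rule: probability below the
cutoff (0.5) is a control call, above is a case call, exactly at the
cutoff the subject is left unclassified. Unclassified subjects are
excluded from every percent-correct denominator and reported separately —
the source procedure defers them without stating a denominator rule, and
excluding them is the only choice under which per-class percents remain
interpretable as conditional accuracies. Classification always uses the
raw case-control fit (intercept a′): recalibrated population
probabilities are all far below 0.5 and would predict zero cases, which a
regression test asserts. The high-risk evaluation restricts subjects by
stratum membership (every pattern with RR above the threshold, default
10), matching the published per-stratum layout, not by individual
predicted probability.

## The synthetic cohort generator

No raw data were deposited, so the generator is a first-class module. It
emulates:

* a rare disease following `P(D=1|x) = expit(alpha_pop + beta'x)` on the
  discrete covariate lattice, default `alpha_pop = −8.59` with the
  published coefficients as default effects — together implying an
  incidence of roughly 6.5 per 10,000, the right order for an adult
  population at the published prior of ~5 per 10,000;
* ascertainment of cases conditional on disease, each matched to a
  disease-free spouse whose sex is the opposite of the case's with
  probability `spouse_sex_flip_prob` (default 1) and who shares the case's
  living-contact code when `shared_living_contact` is set (default TRUE);
* default category prevalences loosely matched to the published control
  margins (~20% under 50, ~15% daily contact, ~22% of families with at
  least one affected relative); the study prints only margins, so these
  are documented approximations in `default_prevalences()`, not facts.

Because the covariate lattice is discrete (288 joint patterns), the case
distribution `P(x | D = 1)` is enumerable and cases are sampled from it
directly; spouses are rejection-sampled on the disease-free condition,
whose acceptance probability exceeds 0.97 everywhere under a rare-disease
configuration. This is distributionally identical to rejection sampling
whole pairs from the population model and orders of magnitude faster at
incidence ~5 × 10⁻⁴, which is what makes hundred-seed recovery studies
affordable. All randomness flows from the single integer `seed`; output
is bit-reproducible.

Two structural caveats matter for interpreting tests on synthetic data:

* **Spousal matching biases the unconditional fit.** With
  `spouse_sex_flip_prob = 1` the control arm's sex distribution mirrors
  the case arm's, not the population's — a property of the real spousal
  design itself, which inflates the unconditional sex coefficient. The
  recovery and intercept-identity tests therefore use the independent
  configuration (`spouse_sex_flip_prob = 0`,
  `shared_living_contact = FALSE`), under which controls are i.i.d. draws
  from `P(x | D = 0)` and the classical case-control results hold
  exactly.
* **The config's `q1` is an external prior; the generator's own marginal
  incidence is `implied_incidence()`** (the exact lattice sum of
  `P(x) P(D|x)`). The intercept-offset identity
  `a' = alpha_pop + ln(n1 q0 / (n0 q1))` holds at the implied incidence;
  tests use it, and user code should too when validating against
  simulations. The two coincide only if the user tunes `alpha_pop` to the
  prior.

The generator draws `relatives_with_cancer` directly as a three-level
category instead of simulating pedigrees: the analysis consumes only the
category, and probands' offspring are excluded from first-degree relatives
by the source design anyway. It does not model age-at-onset, secular
trends, measurement error in smoking recall, or genetic segregation —
passing recovery tests shows the estimators are correct under the stated
sampling model, not that the model captures everything in real family
data.

## Numerical choices and degenerate inputs

* Logistic fits converge on relative deviance change below `tol = 1e-8`
  (cap 50 iterations) from the standard IRLS start; standard errors come
  from the inverse observed information. Tests that need 10-digit
  agreement with closed forms tighten `tol` to 1e-13.
* Rank deficiency is detected by QR before fitting and reported with the
  collinear column names; a constant outcome and separation (any
  coefficient magnitude above 15 on these coded scales) are distinct
  named errors.
* Stepwise selection guards against cycling by recording visited model
  states and stopping with a warning recorded in the trace.
* The intercept correction is plain arithmetic and round-trips to machine
  precision; `q1` of 0 or 1 is rejected at prior construction.
* Empty candidate sets, header-only OR tables, empty high-risk subgroups
  and all-concordant pair sets all return well-defined degenerate results
  or named errors, exercised in the test suite.

## Problem sizes in the test suite

The suite favours many moderate simulations over few huge ones: recovery
and convergence checks run at 3,000–6,000 pairs with fixed seeds, and the
stepwise operating-characteristics study runs 100 seeded cohorts of 2,000
pairs (4,000 subjects) — at that size the power for every true effect is
essentially 1 and the null-candidate entry rate is already at its
asymptotic 5%, so larger cohorts would change nothing but the runtime.
For the null-exclusion check the suite asserts each null candidate's
inclusion count stays within the upper binomial bound of the nominal 5%
entry rate (`qbinom(0.975, 100, 0.05)` = 9 of 100): with two null
candidates tested at level 0.05 each, some runs are expected to admit one,
and a bound pretending otherwise would reject a correctly calibrated
procedure.

## Known limitations

* Only 1:1 spousal matching is supported — no n:m matched sets.
* Adjustment is by regression; no Mantel–Haenszel stratified estimators.
* The incidence prior is a single scalar `q1`; no age-period-cohort
  refinement, so "relative risk" means risk relative to the whole
  population the prior describes.
* Age stratification of paired analyses is by the case's age group (a
  documented convention — pair members' age groups can differ).
* The published adjusted ORs and fitted coefficients cannot be reproduced
  without the raw data; the package validates those code paths by
  parameter recovery on synthetic cohorts and closed-form oracles instead.
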