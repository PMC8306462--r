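---
title: "Beta-binomial comparison of pCR between two strata: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-binomial comparison of pCR between two strata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrbayes)
```

## The problem and the model

Small clinical cohorts with an imbalanced binary stratum — here 24
carriers of a BRCA1 founder mutation against 119 non-carriers, endpoint
pathologic complete response (pCR) after neoadjuvant chemotherapy — leave
frequentist contrasts underpowered: the 2×2 odds ratio of 1.75 carries a
confidence interval from 0.72 to 4.3. The package therefore complements
the frequentist analysis with a conjugate Bayesian one that yields direct
probability statements.

Each arm's pCR rate θ is given a beta model. Three distributions appear:

* **data-only**: `Beta(s, f)` with shape parameters equal to the observed
  responder/non-responder counts. This is a deliberate convention (not the
  `Beta(s+1, f+1)` posterior under a flat prior): it treats the counts
  themselves as the pseudo-count content of the evidence, and it is the
  convention that reproduces the reference analysis's data-only intervals
  exactly. It is improper when either count is zero, in which case
  `likelihood_beta()` refuses and directs the user to a proper prior.
* **prior**: elicited from literature pCR rates — `Beta(3, 7)` (mean 0.30)
  for non-carriers and `Beta(4, 6)` (mean 0.40) for carriers are the
  package defaults. The small pseudo-count total (10) keeps the priors
  weak: each is worth ten patients of evidence.
* **posterior**: `Beta(α₀ + s, β₀ + f)` by conjugacy. For the reference
  counts this gives `Beta(17, 17)` (carriers) and `Beta(51, 78)`.

Intervals are **equal-tailed** quantile intervals (0.025/0.975 at the 95%
level) from `qbeta`; highest-density intervals are intentionally not
offered, because the replicated procedure is defined by quantiles and the
two differ for skewed betas.

## Superiority and relative improvement

`sample_pair()` draws `n_trials` (default 100,000) index-paired samples
from the two posteriors. The paired design means each trial is the vector
`(θ_A, θ_B)`; independence across arms makes pairing a pure variance
bookkeeping device for the superiority estimate.

* `prob_superior()` is the fraction of trials with `θ_A > θ_B`. Ties count
  as non-superior; for continuous draws they occur with probability zero,
  so this is documentation, not policy. The Monte Carlo standard error
  `sqrt(p(1−p)/n)` is attached to every result.
* `relative_improvement()` summarises the per-trial ratio `θ_A/θ_B`. The
  numerator defaults to the arm whose *exact* superiority probability is
  ≥ 0.5 — the arm more likely to have the higher rate — and can be forced.
  Percentiles use order-statistic linear interpolation (R's type-7
  quantile); at n = 100,000 the difference between quantile conventions is
  far below reporting precision.

Both Monte Carlo quantities have **exact oracles** used throughout the
tests: `prob_superior_exact()` (closed-form finite sum for integer shapes
≤ 1000, otherwise adaptive quadrature of `∫ pdf_A·CDF_B`) and
`prob_ratio_exact()` (quadrature of `∫ pdf_B(y)·(1 − CDF_A(t·y)) dy`).
The dual route is the package's main defence against silent Monte Carlo
bugs: the sampler is never validated against itself.

### Reproducibility and tolerances

All randomness flows from one seed (default 20210623, documented so
published reports are bit-reproducible) fanned out to named substreams, so
cohort generation and Monte Carlo are independently reproducible. No
correctness claim depends on a specific seed: stochastic assertions use
the error model *published value = exact value + print rounding (half a
reporting unit) + Monte Carlo noise (≤ 3 SE on each side of the
comparison)*.

Two reference values sit essentially on a rounding boundary and are worth
knowing about. The exact ratio percentiles are 1.0980 / 1.2652 / 1.4454,
so two-decimal roundings of MC estimates legitimately flip between
1.26/1.27 and 1.44/1.45 across seeds. And the exact
`P(ratio ≥ 1.5) = 0.1924`, which rounds to 19%, not the conventionally
quoted 20% — the package reports the computed value.

Similarly, the Welch test on the reference Ki-67 summaries
(64.3 ± 25.8 vs 77.3 ± 17.6, n = 119/24) gives p ≈ 0.0041; quotes of
p < 0.001 for these summaries are not reproducible from the printed
moments, and the package reports the computation.

## Frequentist companion analyses

`odds_ratio()` is the cross-product ratio with arm 1 = exposed;
a zero cell is an error unless the Haldane–Anscombe +0.5 correction is
explicitly enabled. "Confidence intervals based on the log-likelihood
ratio" is implemented as **profile-likelihood inversion**: the two roots in
log-OR of `2[ℓ(θ̂) − ℓ_profile(θ)] = χ²₁(level)` for the two-binomial
model, found by bracket expansion plus `uniroot` to 1e−8 on the log-OR
scale, with the nuisance log-odds maximised by `optimize` at each θ. The
Wald closed form is available as a labelled alternative and is never the
default; on the reference table the two intervals differ visibly at the
upper end (4.296 vs 4.225), which the tests assert. `logistic_univariate()`
fits the same model via `glm` and profiles each coefficient by offset
refits; for a binary predictor it reproduces the closed-form OR to 1e−6,
an equivalence the acceptance suite checks.

The descriptive stage dispatches the t-test on a two-sided F test of
variance equality at 0.05 (the global significance convention; the
dispatch level is configurable). The t/F machinery is written against
`(n, mean, sd)` summaries and the raw-data path reduces to summaries
first, so raw-vs-summary equality is exact by construction rather than a
tolerance claim. Chi-square is Pearson without continuity correction by
default — the uncorrected form matches the reference significance pattern
for lymphovascular invasion — with Yates available by flag.

## What the synthetic generator does and does not emulate

`cohort_config()` defaults encode the reference cohort as a *stated
world*: n = 143, mutation prevalence 24/143, per-stratum pCR probabilities
0.403/0.542, age and Ki-67 normal with the per-stratum moments of the
reference table, and tumour size/stage/LVI drawn from the observed
marginal frequencies. Only first and second moments and marginal category
frequencies are emulated. Deliberately **not** emulated: the joint
dependence structure between covariates (not reported anywhere), any
causal effect of chemotherapy schedule, truncation of Ki-67 to [0, 100]
(untruncated normals keep the stated moments exact; a few draws fall
outside the physical range and are left as-is), and survival endpoints.
A green recovery test therefore establishes that the *inference chain* is
calibrated for two-stratum Bernoulli data with these rates — not that the
generator is a realistic patient simulator.

`recovery_study()` defaults to uniform `Beta(1, 1)` priors so
credible-interval coverage is assessed without informative-prior
shrinkage; superiority calls use the exact (closed-form) posterior
comparison rather than Monte Carlo, which makes 200-replicate studies run
in seconds.

## Numerical and design choices

* Reported rates are rounded half-up (`round_half_up()`) at the report
  layer only; all internal arithmetic is full precision. ORs and CI
  bounds print at two decimals (a display convention of one decimal for
  bounds ≥ 4 seen in some reports is not reproduced).
* `prob_superior_exact()` clamps to [0, 1] against last-bit rounding in
  the closed-form sum; the sum is evaluated on the log scale.
* Profile bracketing grows geometrically from the MLE and reports
  degenerate tables (any zero cell) as errors suggesting the Wald
  fallback rather than returning an unreliable root.
* Complete separation in `logistic_univariate()` is detected before
  fitting (a predictor level with all-0 or all-1 outcomes) and reported
  with the offending level.
* Configs are JSON (via `jsonlite`); YAML was dropped to keep the
  dependency footprint to packages guaranteed present.
* The fixed reference cohort orders records stratum → outcome → index, so
  its bytes, and hence downstream hashes, never change.

## Known limitations

No hierarchical or covariate-adjusted Bayesian models; no multi-arm
comparisons, sequential stopping, or decision-theoretic layer; no exact
(Fisher/conditional) OR inference; no survival analysis. The Bayesian
comparison inherits the usual caveat that the priors are a modelling
choice: alternative priors are accepted everywhere, but sensitivity
analysis is left to the user.
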