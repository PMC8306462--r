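# pcrbayes

Bayesian beta-binomial A/B comparison of a binary clinical endpoint between
two patient strata, built for the question: *does a BRCA1 founder mutation
predict pathologic complete response (pCR) to neoadjuvant chemotherapy in
triple-negative breast cancer?* The package is aimed at clinical
biostatisticians working with small, imbalanced cohorts where frequentist
tests are underpowered and the interesting output is a probability
statement, not a p-value.

## The model

Each arm's pCR rate is modelled as a beta random variable. With a
`Beta(α₀, β₀)` prior and `s` responders / `f` non-responders observed,
conjugacy gives the posterior

    θ | data  ~  Beta(α₀ + s, β₀ + f),      E[θ] = α / (α + β)

The package computes, per arm, the *data-only* distribution
`Beta(s, f)` and the posterior, with equal-tailed 95% credible intervals
from the beta quantile function. The arms are then compared by:

- **probability of superiority** `P(θ_A > θ_B)` — estimated from 100,000
  index-paired Monte Carlo draws and checked against an exact closed-form /
  quadrature oracle;
- the **relative improvement (lift)** `θ_A / θ_B` per paired draw —
  summarised by its 25/50/75th percentiles, full ECDF, and threshold
  exceedance probabilities such as `P(lift ≥ 1.5)`;
- the frequentist **2×2 odds ratio** with a profile-likelihood
  (log-likelihood-ratio) confidence interval, equivalent to univariate
  logistic regression;
- descriptive **group comparisons** (F-dispatched pooled/Welch t-test,
  chi-square).

A synthetic cohort generator (`generate_cohort()`, `recovery_study()`)
reproduces the statistical structure of the reference cohort so the whole
pipeline is testable without patient data.

## Worked example

The reference cohort reduces to the published 2×2 table: 13/24 pCR in
mutation carriers, 48/119 in non-carriers, with priors `Beta(4, 6)` and
`Beta(3, 7)`.

```r
library(pcrbayes)
report <- run_full_analysis(list(counts = list(arm1 = c(13, 11),
                                               arm2 = c(48, 71))))
print(report)
```

prints (seed 20210623, the package default):

```
| arm | data-only | CI | posterior | CI |
|---|---|---|---|---|
| BRCA1_pos | Beta(13, 11) | 34.5% -- 73.2% | Beta(17, 17) | 33.5% -- 66.5% |
| BRCA1_neg | Beta(48, 71) | 31.7% -- 49.3% | Beta(51, 78) | 31.3% -- 48.1% |

- P(BRCA1_pos rate > BRCA1_neg rate) = 0.86 (Monte Carlo, n = 100000, se = 0.0011; exact 0.8633)
- ratio percentiles (BRCA1_pos / BRCA1_neg): p25 = 1.10, p50 = 1.27, p75 = 1.45
- P(ratio >= 1.5) = 0.19
- BRCA1_pos vs BRCA1_neg: OR = 1.75 (95% profile-likelihood CI 0.72, 4.30; Wald 0.72, 4.23)
```

Reading: the carriers' posterior pCR rate exceeds the non-carriers' in 86%
of paired posterior draws; the median lift is ~1.26–1.27 (the exact median
is 1.2652, so two-decimal roundings straddle 1.26/1.27 across seeds); there
is a ~19% probability that pCR is at least 1.5× as frequent in carriers
(exact quadrature value 0.1924). The odds ratio 1.75 (0.72, 4.30) shows why
the frequentist view alone is inconclusive in a 24-patient arm.

## Command line

```sh
Rscript inst/scripts/pcrbayes analyze  --config cfg.json --format markdown
Rscript inst/scripts/pcrbayes simulate --config cohort.json --out cohort.csv
Rscript inst/scripts/pcrbayes recover  --config cohort.json --out recovery.json
```

Configs are JSON; see `?run_full_analysis`, `?cohort_config`.

## Vignette

`vignettes/beta-binomial-pcr.Rmd` documents the model and its assumptions,
the prior elicitation, the Monte Carlo design and its exact oracles, the
synthetic-data generator's scope, and known numerical edge cases.
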