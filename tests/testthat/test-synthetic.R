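# Synthetic cohort generation and the parameter-recovery study.

test_that("same seed gives byte-identical cohorts, different seeds differ", {
  cfg <- cohort_config(seed = 404)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 405))
  expect_false(identical(c1$outcome, c3$outcome))
})

test_that("empirical prevalence and outcome rates converge", {
  cfg <- cohort_config(n_patients = 2e4, stratum_prevalence = 24 / 143,
                       covariates = list(), seed = 7)
  cohort <- generate_cohort(cfg)
  prev <- mean(cohort$stratum == cfg$stratum_levels[2])
  p <- 24 / 143
  expect_lt(abs(prev - p), 3 * sqrt(p * (1 - p) / 2e4))
  # equal outcome probabilities: pooled fraction near 0.5
  cfg2 <- cohort_config(n_patients = 1e5, p_outcome = c(0.5, 0.5),
                        covariates = list(), seed = 8)
  expect_lt(abs(mean(generate_cohort(cfg2)$outcome) - 0.5), 0.005)
})

test_that("prevalence 0 puts every record in the reference stratum", {
  cfg <- cohort_config(n_patients = 50, stratum_prevalence = 0,
                       covariates = list(), seed = 1)
  expect_true(all(generate_cohort(cfg)$stratum == cfg$stratum_levels[1]))
})

test_that("default covariates track the configured per-stratum moments", {
  cfg <- cohort_config(n_patients = 2e4, seed = 12)
  cohort <- generate_cohort(cfg)
  in2 <- cohort$stratum == cfg$stratum_levels[2]
  expect_lt(abs(mean(cohort$age[!in2]) - 57.1), 0.5)
  expect_lt(abs(mean(cohort$age[in2]) - 47.0), 1.0)
  expect_lt(abs(sd(cohort$ki67[in2]) - 17.6), 1.0)
  expect_true(all(cohort$tumour_size[in2] != "T4"))  # zero probability cell
})

test_that("config validation rejects impossible parameters", {
  expect_error(cohort_config(p_outcome = c(0, 0.5)), "outside")
  expect_error(cohort_config(stratum_prevalence = 1.2), "outside")
  expect_error(cohort_config(covariates = list(
    list(name = "x", kind = "normal-by-stratum",
         mean = c(0, 0), sd = c(1, 0)))), "sd must be > 0")
  expect_error(cohort_config(covariates = list(
    list(name = "x", kind = "categorical-by-stratum",
         levels = c("a", "b"), probs = rbind(c(0.5, 0.4), c(0.5, 0.5))))),
    "sum to 1")
})

test_that("the fixed reference cohort encodes the published table exactly", {
  cohort <- fixed_paper_cohort()
  expect_equal(nrow(cohort), 143)
  expect_equal(table(cohort$stratum)[["BRCA1_neg"]], 119)
  expect_equal(table(cohort$stratum)[["BRCA1_pos"]], 24)
  agg <- aggregate_arms(cohort, c("BRCA1_pos", "BRCA1_neg"))
  expect_equal(unlist(agg$table[c("a", "b", "c", "d")], use.names = FALSE),
               c(13, 11, 48, 71))
  expect_equal(round_half_up(100 * 13 / 24, 1), 54.2)
  # deterministic: two calls identical
  expect_identical(cohort, fixed_paper_cohort())
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  cohort <- generate_cohort(cohort_config(n_patients = 80, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- suppressMessages(read_cohort(path))
  expect_equal(back$stratum, cohort$stratum)
  expect_equal(back$outcome, cohort$outcome)
  expect_equal(back$age, cohort$age, tolerance = 1e-12)
})

test_that("logistic-linked outcomes follow the stated linear predictor", {
  cfg <- cohort_config(
    n_patients = 5000,
    covariates = list(
      list(name = "age", kind = "normal-by-stratum",
           mean = c(55, 55), sd = c(10, 10)),
      list(name = "risk", kind = "logistic-linked",
           intercept = 1.5, slopes = list(age = -0.03))),
    seed = 44)
  cohort <- generate_cohort(cfg)
  fit <- glm(outcome ~ age, binomial, data = cohort)
  expect_lt(abs(coef(fit)[["age"]] - (-0.03)), 3 * 0.004)
})

test_that("recovery study scores coverage, bias, and superiority calls", {
  cfg <- cohort_config(n_patients = 400, stratum_prevalence = 0.5,
                       p_outcome = c(0.30, 0.40), covariates = list(),
                       seed = 202)
  rec <- recovery_study(cfg, n_replicates = 25)
  expect_equal(nrow(rec$replicates), 25)
  expect_true(all(rec$replicates$prob_superior >= 0 &
                    rec$replicates$prob_superior <= 1))
  expect_true(all(c("coverage", "mean_abs_error", "superiority_agreement")
                  %in% names(rec$summary)))
  # reproducible
  rec2 <- recovery_study(cfg, n_replicates = 25)
  expect_identical(rec$replicates, rec2$replicates)
})

test_that("null configuration centres the superiority probability at 0.5", {
  # under the null the per-replicate superiority probability is ~uniform,
  # so the mean over R replicates has sd ~ 0.29/sqrt(R); 200 replicates
  # put 0.05 at ~2.4 sd
  cfg <- cohort_config(n_patients = 400, stratum_prevalence = 0.5,
                       p_outcome = c(0.4, 0.4), covariates = list(),
                       seed = 303)
  rec <- recovery_study(cfg, n_replicates = 200)
  expect_lt(abs(mean(rec$replicates$prob_superior) - 0.5), 0.05)
})

test_that("a large true effect is called correctly in >= 99% of replicates", {
  cfg <- cohort_config(n_patients = 1000, stratum_prevalence = 0.5,
                       p_outcome = c(0.30, 0.60), covariates = list(),
                       seed = 505)
  rec <- recovery_study(cfg, n_replicates = 100)
  expect_gte(rec$summary$superiority_agreement, 0.99)
})

test_that("posterior mean bias shrinks as the cohort grows", {
  mae <- vapply(c(100, 1000, 10000), function(n) {
    cfg <- cohort_config(n_patients = n, stratum_prevalence = 0.5,
                         p_outcome = c(0.30, 0.40), covariates = list(),
                         seed = 600 + n)
    rec <- recovery_study(cfg, n_replicates = 30)
    stats::median(abs(c(rec$replicates$err1, rec$replicates$err2)))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})
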