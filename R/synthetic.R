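## Synthetic two-stratum cohort generation.
##
## The default configuration emulates the reference TNBC cohort: 143
## patients, mutation prevalence 24/143, per-stratum pCR probabilities
## 0.403 / 0.542, age and Ki-67 normal with stratum-specific moments, and
## categorical covariates (tumour size, stage, LVI) matching the observed
## marginal frequencies.  Only first/second moments and marginal category
## frequencies are emulated; the joint dependence structure of real
## clinico-pathological covariates is not.

default_covariate_specs <- function() {
  list(
    list(name = "age", kind = "normal-by-stratum",
         mean = c(57.1, 47.0), sd = c(12.5, 12.9)),
    list(name = "ki67", kind = "normal-by-stratum",
         mean = c(64.3, 77.3), sd = c(25.8, 17.6)),
    list(name = "tumour_size", kind = "categorical-by-stratum",
         levels = c("T1", "T2", "T3", "T4"),
         probs = rbind(c(5, 62, 35, 17) / 119, c(3, 16, 5, 0) / 24)),
    list(name = "stage", kind = "categorical-by-stratum",
         levels = c("I", "II", "III"),
         probs = rbind(c(44, 56, 19) / 119, c(17, 7, 0) / 24)),
    list(name = "lvi", kind = "categorical-by-stratum",
         levels = c("no", "yes"),
         probs = rbind(c(89, 30) / 119, c(23, 1) / 24))
  )
}

#' Synthetic cohort configuration
#'
#' Validated parameter set for [generate_cohort()].  Defaults reproduce the
#' structure of the reference cohort: n = 143, mutation-stratum prevalence
#' 24/143, per-stratum response probabilities 0.403 (reference arm) and
#' 0.542 (mutated arm).
#'
#' @param n_patients cohort size (default 143).
#' @param stratum_prevalence probability of the second (mutation) stratum,
#'   in \[0, 1\] (default 24/143; the boundary values force a one-stratum
#'   cohort and are allowed for degenerate testing).
#' @param p_outcome length-2 probabilities of outcome 1 in (0,1), ordered
#'   (reference stratum, mutation stratum).
#' @param stratum_levels labels, ordered (reference, mutation).
#' @param covariates list of covariate specs; each is a list with `name`,
#'   `kind` in `"normal-by-stratum"`, `"categorical-by-stratum"` or
#'   `"logistic-linked"`, and kind-specific parameters: `mean`/`sd`
#'   length-2 vectors (reference first); `levels` plus a 2 x L row-stochastic
#'   `probs` matrix; or `intercept`/`slopes` (named by covariate) for a
#'   logistic-linked *outcome* override.
#' @param seed RNG seed (default 20210623).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 143,
                          stratum_prevalence = 24 / 143,
                          p_outcome = c(0.403, 0.542),
                          stratum_levels = c("BRCA1_neg", "BRCA1_pos"),
                          covariates = default_covariate_specs(),
                          seed = 20210623) {
  n_patients <- assert_count(n_patients, "n_patients", min = 1)
  assert_number(stratum_prevalence, "stratum_prevalence", lower = 0, upper = 1)
  if (length(p_outcome) != 2L)
    stop_pcr("p_outcome must have two elements (reference, mutation)")
  for (p in p_outcome)
    assert_number(p, "p_outcome", lower = 0, upper = 1,
                  open_lower = TRUE, open_upper = TRUE)
  stopifnot(length(stratum_levels) == 2L)
  for (cv in covariates) {
    if (!cv$kind %in% c("normal-by-stratum", "categorical-by-stratum",
                        "logistic-linked"))
      stop_pcr("unknown covariate kind '%s' for '%s'", cv$kind, cv$name)
    if (cv$kind == "normal-by-stratum" && any(cv$sd <= 0))
      stop_pcr("covariate '%s': per-stratum sd must be > 0", cv$name)
    if (cv$kind == "categorical-by-stratum") {
      if (any(abs(rowSums(cv$probs) - 1) > 1e-8))
        stop_pcr("covariate '%s': level probabilities must sum to 1 per stratum",
                 cv$name)
      if (ncol(cv$probs) != length(cv$levels))
        stop_pcr("covariate '%s': probs/levels mismatch", cv$name)
    }
  }
  structure(list(n_patients = n_patients,
                 stratum_prevalence = stratum_prevalence,
                 p_outcome = as.double(p_outcome),
                 stratum_levels = as.character(stratum_levels),
                 covariates = covariates, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic patient-level cohort
#'
#' Stratum assignment is Bernoulli(`stratum_prevalence`); the binary outcome
#' is Bernoulli with the assigned stratum's probability; covariates are
#' drawn per their specs.  A `"logistic-linked"` spec replaces the
#' stratum-probability outcome with a Bernoulli draw from
#' `plogis(intercept + sum(slopes * covariate))`, enabling
#' parameter-recovery tests of the regression stage.  Reproducible:
#' identical seeds give byte-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return A `cohort` data.frame.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(substream_seed(config$seed, "cohort"), {
    stratum_idx <- stats::rbinom(n, 1, config$stratum_prevalence) + 1L
    out <- data.frame(
      patient_id = sprintf("S%04d", seq_len(n)),
      stratum = config$stratum_levels[stratum_idx],
      outcome = stats::rbinom(n, 1, config$p_outcome[stratum_idx]),
      stringsAsFactors = FALSE)
    logistic_spec <- NULL
    for (cv in config$covariates) {
      if (cv$kind == "normal-by-stratum") {
        out[[cv$name]] <- stats::rnorm(n, cv$mean[stratum_idx],
                                       cv$sd[stratum_idx])
      } else if (cv$kind == "categorical-by-stratum") {
        draws <- character(n)
        for (s in 1:2) {
          idx <- which(stratum_idx == s)
          if (length(idx))
            draws[idx] <- sample(cv$levels, length(idx), replace = TRUE,
                                 prob = cv$probs[s, ])
        }
        out[[cv$name]] <- draws
      } else if (cv$kind == "logistic-linked") {
        logistic_spec <- cv
      }
    }
    if (!is.null(logistic_spec)) {
      eta <- rep(logistic_spec$intercept, n)
      for (nm in names(logistic_spec$slopes))
        eta <- eta + logistic_spec$slopes[[nm]] * out[[nm]]
      out$outcome <- stats::rbinom(n, 1, stats::plogis(eta))
    }
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' The fixed reference cohort
#'
#' A deterministic 143-record cohort whose stratum-by-outcome table is
#' exactly (mutation arm first) 13 pCR / 11 non-pCR vs 48 pCR / 71 non-pCR,
#' with per-stratum sizes 24 and 119.  Records are ordered stratum, then
#' outcome, then index, so downstream hashes are stable.  This cohort
#' carries no covariates: it encodes exactly the published counts, nothing
#' more.
#'
#' @param stratum_levels labels, ordered (reference, mutation).
#' @return A `cohort` data.frame with 143 rows.
#' @export
fixed_paper_cohort <- function(stratum_levels = c("BRCA1_neg", "BRCA1_pos")) {
  stopifnot(length(stratum_levels) == 2L)
  stratum <- rep(stratum_levels, c(119L, 24L))
  outcome <- c(rep(1L, 48L), rep(0L, 71L), rep(1L, 13L), rep(0L, 11L))
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(143L)),
                    stratum = stratum, outcome = outcome,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Parameter-recovery study for the Bayesian pipeline
#'
#' Repeatedly generates cohorts from a known configuration, runs the
#' conjugate analysis on each, and scores: posterior-mean error per arm,
#' coverage of the equal-tailed credible interval over the true per-arm
#' probabilities, and whether the exact superiority probability points at
#' the truly better arm.  Uniform `Beta(1,1)` priors are the default so
#' coverage is not confounded by informative-prior shrinkage.
#'
#' @param true_config a [cohort_config()]; its `p_outcome` are the recovery
#'   targets.
#' @param n_replicates number of simulated cohorts (>= 1).
#' @param priors list with `arm1`/`arm2` [beta_params()]; default uniform.
#' @param level credible level (default 0.95).
#' @return A list of class `recovery_report`: per-replicate data.frame
#'   `replicates` and a `summary` with coverage, mean absolute error, and
#'   superiority-agreement rate.
#' @export
recovery_study <- function(true_config, n_replicates,
                           priors = list(arm1 = beta_params(1, 1),
                                         arm2 = beta_params(1, 1)),
                           level = 0.95) {
  stopifnot(inherits(true_config, "cohort_config"))
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1)
  p_true <- true_config$p_outcome  # (reference arm1, mutation arm2)
  base_seed <- substream_seed(true_config$seed, "recovery")
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- true_config
    cfg$seed <- (base_seed + r) %% 2147483647
    cohort <- generate_cohort(cfg)
    agg <- aggregate_arms(cohort, true_config$stratum_levels)
    post1 <- posterior_update(priors$arm1, agg$arm1)
    post2 <- posterior_update(priors$arm2, agg$arm2)
    ci1 <- credible_interval(post1, level)
    ci2 <- credible_interval(post2, level)
    # exact P(arm2 rate > arm1 rate) from the conjugate posteriors
    p_sup <- prob_superior_exact(post2, post1)
    data.frame(
      replicate = r,
      err1 = beta_mean(post1) - p_true[1],
      err2 = beta_mean(post2) - p_true[2],
      cover1 = ci1$lower <= p_true[1] && p_true[1] <= ci1$upper,
      cover2 = ci2$lower <= p_true[2] && p_true[2] <= ci2$upper,
      prob_superior = p_sup,
      correct_call = if (p_true[2] == p_true[1]) NA
                     else (p_sup >= 0.5) == (p_true[2] > p_true[1]))
  })
  reps <- do.call(rbind, rows)
  structure(list(
    replicates = reps,
    summary = list(
      n_replicates = n_replicates,
      coverage = c(arm1 = mean(reps$cover1), arm2 = mean(reps$cover2)),
      mean_abs_error = c(arm1 = mean(abs(reps$err1)),
                         arm2 = mean(abs(reps$err2))),
      mean_prob_superior = mean(reps$prob_superior),
      superiority_agreement = mean(reps$correct_call)),
    level = level, p_true = p_true), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("recovery study: %d replicates, true p = (%.3f, %.3f)\n",
              s$n_replicates, x$p_true[1], x$p_true[2]))
  cat(sprintf("  %g%% CI coverage: arm1 %.3f, arm2 %.3f\n", 100 * x$level,
              s$coverage[["arm1"]], s$coverage[["arm2"]]))
  cat(sprintf("  mean |posterior mean error|: %.4f / %.4f\n",
              s$mean_abs_error[["arm1"]], s$mean_abs_error[["arm2"]]))
  cat(sprintf("  superiority agreement: %s\n",
              format(s$superiority_agreement)))
  invisible(x)
}

#' Write a cohort as CSV
#'
#' Emits the same schema [read_cohort()] reads back (columns `id`,
#' `stratum`, `outcome`, covariates), round-trip tested.
#'
#' @param cohort a `cohort` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- cohort
  names(out)[names(out) == "patient_id"] <- "id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
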