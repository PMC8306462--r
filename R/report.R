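## End-to-end analysis: aggregate -> data-only beta -> posterior ->
## credible intervals -> Monte Carlo superiority -> relative improvement ->
## odds ratio -> group comparisons, collected into a serialisable report.
##
## Arm ordering convention throughout the report: arm 1 is the exposed /
## candidate-superior stratum (mutation carriers), arm 2 the reference.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_pcr("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

default_analysis_config <- function() {
  list(
    arm_names = c("BRCA1_pos", "BRCA1_neg"),
    priors = list(arm1 = c(4, 6), arm2 = c(3, 7)),
    credible_level = 0.95,
    n_trials = 1e5,
    seed = 20210623,
    ratio_thresholds = 1.5
  )
}

merge_config <- function(config) {
  out <- default_analysis_config()
  for (nm in names(config)) out[[nm]] <- config[[nm]]
  out
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

#' Run the complete two-arm analysis
#'
#' Chains every stage of the pipeline on either inline 2x2 counts or a
#' cohort table: per-arm aggregation, the data-only beta distributions,
#' conjugate posterior update, equal-tailed credible intervals, paired
#' Monte Carlo sampling, probability of superiority (with its exact
#' oracle), the relative-improvement ratio summary, the 2x2 odds ratio with
#' profile-likelihood and Wald intervals, and (when a cohort with
#' covariates is supplied) the descriptive group comparisons.
#'
#' @param config a named list (or path to a JSON file) with entries:
#'   `counts` (list `arm1`/`arm2` of `c(successes, failures)`, arm 1 =
#'   exposed) *or* `cohort_csv` + `schema` + `stratum_levels` (exposed
#'   label first) *or* `cohort` (a cohort data.frame, programmatic use);
#'   `priors` (list `arm1`/`arm2`, defaults Beta(4,6)/Beta(3,7));
#'   `credible_level` (0.95); `n_trials` (100000); `seed` (20210623);
#'   `ratio_thresholds` (1.5); `arm_names`.
#' @return An object of class `analysis_report`.
#' @export
#' @examples
#' rep <- run_full_analysis(list(counts = list(arm1 = c(13, 11),
#'                                             arm2 = c(48, 71))))
#' rep$posterior$arm1  # Beta(17, 17)
run_full_analysis <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  cfg <- merge_config(config)
  run_stage("validate_config", {
    assert_count(cfg$n_trials, "n_trials", min = 1)
    assert_number(cfg$credible_level, "credible_level", 0, 1,
                  open_lower = TRUE, open_upper = TRUE)
  })

  cohort <- NULL
  if (!is.null(cfg[["counts"]])) {
    arms <- run_stage("aggregate", list(
      arm1 = as_arm_counts(cfg$counts$arm1, "counts$arm1"),
      arm2 = as_arm_counts(cfg$counts$arm2, "counts$arm2")))
  } else {
    cohort <- run_stage("read_cohort", {
      if (!is.null(cfg[["cohort"]])) as_cohort(cfg[["cohort"]])
      else if (!is.null(cfg[["cohort_csv"]]))
        suppressMessages(read_cohort(cfg[["cohort_csv"]],
                                     schema = cfg$schema %||%
                                       list(patient_id = "id",
                                            stratum = "stratum",
                                            outcome = "outcome"),
                                     stratum_levels = cfg$stratum_levels))
      else stop_pcr("config must supply `counts`, `cohort` or `cohort_csv`")
    })
    agg <- run_stage("aggregate",
                     aggregate_arms(cohort, cfg$stratum_levels))
    arms <- list(arm1 = agg$arm1, arm2 = agg$arm2)
    cfg$arm_names <- agg$stratum_levels
  }

  data_only <- run_stage("likelihood_beta", list(
    arm1 = likelihood_beta(arms$arm1), arm2 = likelihood_beta(arms$arm2)))
  posterior <- run_stage("posterior_update", list(
    arm1 = posterior_update(as_beta_params(cfg$priors$arm1), arms$arm1),
    arm2 = posterior_update(as_beta_params(cfg$priors$arm2), arms$arm2)))
  level <- cfg$credible_level
  intervals <- run_stage("credible_interval", list(
    data_only = lapply(data_only, credible_interval, level = level),
    posterior = lapply(posterior, credible_interval, level = level)))

  samples <- run_stage("sample_pair",
    sample_pair(posterior$arm1, posterior$arm2, n_trials = cfg$n_trials,
                seed = substream_seed(cfg$seed, "mc")))
  superiority <- run_stage("prob_superior", prob_superior(samples))
  sup_exact <- run_stage("prob_superior_exact",
                         prob_superior_exact(posterior$arm1, posterior$arm2))
  ratio <- run_stage("relative_improvement",
    relative_improvement(samples, thresholds = cfg$ratio_thresholds))

  tab <- two_by_two(arms$arm1$successes, arms$arm1$failures,
                    arms$arm2$successes, arms$arm2$failures)
  or_profile <- run_stage("or_confint", or_confint(tab, level = level))
  or_wald <- run_stage("or_confint",
                       or_confint(tab, level = level, method = "wald"))

  comparisons <- NULL
  if (!is.null(cohort) &&
      length(setdiff(names(cohort), c("patient_id", "stratum", "outcome"))))
    comparisons <- run_stage("describe_cohort",
      describe_cohort(cohort, stratum_levels = cfg$arm_names))

  structure(list(
    arm_names = cfg$arm_names,
    arms = arms,
    table = tab,
    priors = list(arm1 = as_beta_params(cfg$priors$arm1),
                  arm2 = as_beta_params(cfg$priors$arm2)),
    data_only = data_only,
    posterior = posterior,
    intervals = intervals,
    superiority = superiority,
    superiority_exact = sup_exact,
    ratio = ratio,
    odds_ratio = list(profile = or_profile, wald = or_wald),
    comparisons = comparisons,
    provenance = list(seed = cfg$seed, n_trials = cfg$n_trials,
                      credible_level = level,
                      config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("pcrbayes")))
  ), class = "analysis_report")
}

#' Read an analysis/simulation config file
#'
#' JSON only; keys as documented in [run_full_analysis()],
#' [cohort_config()] and [recovery_study()].
#'
#' @param path path to a `.json` config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_pcr("config file not found: %s", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

beta_block <- function(params, interval = NULL) {
  out <- list(alpha = params$alpha, beta = params$beta,
              mean = beta_mean(params))
  if (!is.null(interval))
    out$credible_interval <- list(lower = interval$lower,
                                  upper = interval$upper,
                                  level = interval$level)
  out
}

#' Serialise an analysis report
#'
#' `report_json()` renders the full report (minus the bulky ECDF, written
#' separately via [write_ecdf_tsv()]) as deterministic JSON: identical
#' configs and seeds give byte-identical output.  `report_markdown()`
#' renders a human-readable summary with report-layer rounding (rates as
#' percentages with one decimal, half up).
#'
#' @param report an `analysis_report`.
#' @return A JSON string (`report_json`) or character vector of markdown
#'   lines (`report_markdown`).
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  x <- list(
    arms = list(
      arm1 = list(name = report$arm_names[[1]],
                  successes = report$arms$arm1$successes,
                  failures = report$arms$arm1$failures),
      arm2 = list(name = report$arm_names[[2]],
                  successes = report$arms$arm2$successes,
                  failures = report$arms$arm2$failures)),
    priors = lapply(report$priors, beta_block),
    data_only = list(
      arm1 = beta_block(report$data_only$arm1,
                        report$intervals$data_only$arm1),
      arm2 = beta_block(report$data_only$arm2,
                        report$intervals$data_only$arm2)),
    posterior = list(
      arm1 = beta_block(report$posterior$arm1,
                        report$intervals$posterior$arm1),
      arm2 = beta_block(report$posterior$arm2,
                        report$intervals$posterior$arm2)),
    superiority = list(
      prob_superior = report$superiority$prob_superior,
      mc_standard_error = report$superiority$mc_standard_error,
      n_trials = report$superiority$n_trials,
      seed = report$superiority$seed,
      exact = report$superiority_exact),
    relative_improvement = list(
      numerator = report$ratio$numerator,
      percentiles = as.list(report$ratio$percentiles),
      threshold_probs = as.list(report$ratio$threshold_probs)),
    odds_ratio = lapply(report$odds_ratio, function(o)
      list(estimate = o$odds_ratio, ci_lower = o$ci_lower,
           ci_upper = o$ci_upper, level = o$level, method = o$method)),
    provenance = report$provenance)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' @rdname report_json
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  pc <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))
  ci <- function(iv) sprintf("%s -- %s", pc(iv$lower), pc(iv$upper))
  n1 <- report$arm_names[[1]]; n2 <- report$arm_names[[2]]
  a1 <- report$arms$arm1; a2 <- report$arms$arm2
  lines <- c(
    "# Two-arm beta-binomial analysis",
    "",
    "## Observed counts",
    "",
    "| arm | pCR | non-pCR | rate |",
    "|---|---|---|---|",
    sprintf("| %s | %d | %d | %s |", n1, a1$successes, a1$failures,
            pc(a1$successes / (a1$successes + a1$failures))),
    sprintf("| %s | %d | %d | %s |", n2, a2$successes, a2$failures,
            pc(a2$successes / (a2$successes + a2$failures))),
    "",
    "## Beta distributions (95% equal-tailed credible intervals)",
    "",
    "| arm | data-only | CI | posterior | CI |",
    "|---|---|---|---|---|",
    sprintf("| %s | Beta(%g, %g) | %s | Beta(%g, %g) | %s |", n1,
            report$data_only$arm1$alpha, report$data_only$arm1$beta,
            ci(report$intervals$data_only$arm1),
            report$posterior$arm1$alpha, report$posterior$arm1$beta,
            ci(report$intervals$posterior$arm1)),
    sprintf("| %s | Beta(%g, %g) | %s | Beta(%g, %g) | %s |", n2,
            report$data_only$arm2$alpha, report$data_only$arm2$beta,
            ci(report$intervals$data_only$arm2),
            report$posterior$arm2$alpha, report$posterior$arm2$beta,
            ci(report$intervals$posterior$arm2)),
    "",
    "## Superiority and relative improvement",
    "",
    sprintf("- P(%s rate > %s rate) = %.2f (Monte Carlo, n = %d, se = %.2g; exact %.4f)",
            n1, n2, round_half_up(report$superiority$prob_superior, 2),
            report$superiority$n_trials,
            report$superiority$mc_standard_error, report$superiority_exact),
    sprintf("- ratio percentiles (%s / %s): %s",
            if (report$ratio$numerator == "a") n1 else n2,
            if (report$ratio$numerator == "a") n2 else n1,
            paste(sprintf("%s = %.2f", names(report$ratio$percentiles),
                          round_half_up(report$ratio$percentiles, 2)),
                  collapse = ", ")),
    sprintf("- %s", paste(sprintf("P(ratio >= %s) = %.2f",
                                  sub("^ge_", "",
                                      names(report$ratio$threshold_probs)),
                                  round_half_up(report$ratio$threshold_probs, 2)),
                          collapse = "; ")),
    "",
    "## Odds ratio",
    "",
    sprintf("- %s vs %s: OR = %.2f (%g%% profile-likelihood CI %.2f, %.2f; Wald %.2f, %.2f)",
            n1, n2, round_half_up(report$odds_ratio$profile$odds_ratio, 2),
            100 * report$odds_ratio$profile$level,
            round_half_up(report$odds_ratio$profile$ci_lower, 2),
            round_half_up(report$odds_ratio$profile$ci_upper, 2),
            round_half_up(report$odds_ratio$wald$ci_lower, 2),
            round_half_up(report$odds_ratio$wald$ci_upper, 2)),
    "",
    sprintf("_seed %s, n_trials %d, config %s, pcrbayes %s_",
            format(report$provenance$seed), report$provenance$n_trials,
            report$provenance$config_hash,
            report$provenance$package_version))
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Write the ratio ECDF as TSV
#'
#' Two columns (`value`, `fraction`), the numeric analogue of the published
#' cumulative-distribution figure.
#'
#' @param report an `analysis_report` (or a `ratio_summary`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecdf_tsv <- function(report, path) {
  ecdf <- if (inherits(report, "analysis_report")) report$ratio$ecdf
          else report$ecdf
  utils::write.table(ecdf, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
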