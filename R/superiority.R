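## Monte Carlo comparison of two beta-distributed response rates.
##
## Draws are index-paired: trial i compares draw i from arm A against draw i
## from arm B, so the pair (a_i, b_i) is one Monte Carlo "trial".  Exact
## counterparts (closed-form sum / quadrature) are provided as validation
## oracles for both the superiority probability and the ratio exceedance
## probability.

#' Paired posterior samples from two beta distributions
#'
#' Draws `n_trials` independent samples from each arm's beta distribution,
#' index-paired.  Reproducible: the same `(seed, n_trials)` yields identical
#' arrays; the caller's global RNG state is left untouched.
#'
#' @param dist_a,dist_b [beta_params()] of the two arms (A is the candidate
#'   "superior" arm, e.g. mutation carriers).
#' @param n_trials number of paired draws (default 100000).
#' @param seed integer RNG seed recorded in the result (default 20210623).
#' @return An object of class `paired_samples` with fields `arm_a`, `arm_b`,
#'   `n_trials`, `seed`, `dist_a`, `dist_b`.
#' @export
sample_pair <- function(dist_a, dist_b, n_trials = 1e5, seed = 20210623) {
  dist_a <- as_beta_params(dist_a, "dist_a")
  dist_b <- as_beta_params(dist_b, "dist_b")
  n_trials <- assert_count(n_trials, "n_trials", min = 1)
  draws <- with_seed(seed, {
    a <- stats::rbeta(n_trials, dist_a$alpha, dist_a$beta)
    b <- stats::rbeta(n_trials, dist_b$alpha, dist_b$beta)
    list(a = a, b = b)
  })
  structure(list(arm_a = draws$a, arm_b = draws$b, n_trials = n_trials,
                 seed = seed, dist_a = dist_a, dist_b = dist_b),
            class = "paired_samples")
}

#' Monte Carlo probability of superiority
#'
#' Fraction of paired trials in which the arm-A draw strictly exceeds the
#' arm-B draw.  Ties count as non-superior (they have probability zero for
#' continuous draws).  The Monte Carlo standard error
#' `sqrt(p(1-p)/n_trials)` is attached.
#'
#' @param samples a [sample_pair()] result.
#' @return An object of class `superiority_result` with fields
#'   `prob_superior`, `n_trials`, `seed`, `mc_standard_error`.
#' @export
prob_superior <- function(samples) {
  stopifnot(inherits(samples, "paired_samples"))
  p <- mean(samples$arm_a > samples$arm_b)
  structure(list(prob_superior = p, n_trials = samples$n_trials,
                 seed = samples$seed,
                 mc_standard_error = sqrt(p * (1 - p) / samples$n_trials)),
            class = "superiority_result")
}

#' @export
print.superiority_result <- function(x, ...) {
  cat(sprintf("P(arm A > arm B) = %.4f (MC, n = %d, se = %.2g, seed = %d)\n",
              x$prob_superior, x$n_trials, x$mc_standard_error, x$seed))
  invisible(x)
}

# Closed-form P(X > Y), X ~ Beta(a1,b1), Y ~ Beta(a2,b2), integer a1:
#   P(X > Y) = sum_{i=0}^{a1-1} B(a2+i, b1+b2) / ((b1+i) B(1+i, b1) B(a2, b2))
# computed on the log scale for stability.
prob_superior_sum <- function(a1, b1, a2, b2) {
  i <- 0:(a1 - 1)
  sum(exp(lbeta(a2 + i, b1 + b2) - log(b1 + i) -
            lbeta(1 + i, b1) - lbeta(a2, b2)))
}

#' Exact probability of superiority
#'
#' `P(X > Y)` for independent `X ~ dist_a`, `Y ~ dist_b`.  Uses the
#' closed-form finite sum when all four shape parameters are integers not
#' exceeding 1000, and adaptive quadrature of
#' `integral of pdf_a(x) * CDF_b(x) dx` otherwise.  Serves as the validation
#' oracle for [prob_superior()].
#'
#' @param dist_a,dist_b [beta_params()] objects.
#' @return `P(X > Y)`, accurate to about 1e-8 or better.
#' @export
#' @examples
#' prob_superior_exact(beta_params(2, 1), beta_params(1, 1))  # 2/3
prob_superior_exact <- function(dist_a, dist_b) {
  da <- as_beta_params(dist_a, "dist_a")
  db <- as_beta_params(dist_b, "dist_b")
  shapes <- c(da$alpha, da$beta, db$alpha, db$beta)
  p <- if (all(shapes == floor(shapes)) && all(shapes <= 1000))
    prob_superior_sum(da$alpha, da$beta, db$alpha, db$beta)
  else
    stats::integrate(function(x) stats::dbeta(x, da$alpha, da$beta) *
                       stats::pbeta(x, db$alpha, db$beta),
                     0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  min(max(p, 0), 1)  # guard against rounding just outside [0, 1]
}

#' Exact ratio-exceedance probability
#'
#' `P(X / Y >= threshold)` for independent beta-distributed `X` (numerator)
#' and `Y`, by one-dimensional quadrature of
#' `integral of pdf_Y(y) * (1 - CDF_X(min(1, threshold * y))) dy`.
#' Validation oracle for the threshold probabilities of
#' [relative_improvement()].
#'
#' @param dist_a numerator arm's [beta_params()].
#' @param dist_b denominator arm's [beta_params()].
#' @param threshold positive ratio threshold.
#' @return `P(X/Y >= threshold)`, accurate to about 1e-6.
#' @export
prob_ratio_exact <- function(dist_a, dist_b, threshold) {
  da <- as_beta_params(dist_a, "dist_a")
  db <- as_beta_params(dist_b, "dist_b")
  assert_number(threshold, "threshold", lower = 0, open_lower = TRUE)
  stats::integrate(function(y) {
    stats::dbeta(y, db$alpha, db$beta) *
      stats::pbeta(pmin(1, threshold * y), da$alpha, da$beta,
                   lower.tail = FALSE)
  }, 0, 1, rel.tol = 1e-9, abs.tol = 1e-10)$value
}

#' Empirical cumulative distribution table
#'
#' Sorted unique values with cumulative fractions: the right-continuous step
#' function F(x) = fraction of sample values <= x.  The fraction at the
#' maximum is exactly 1.
#'
#' @param values non-empty numeric vector.
#' @return A data.frame with columns `value` (sorted, unique) and `fraction`.
#' @export
ecdf_table <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stop_pcr("`values` must be a non-empty finite numeric vector")
  s <- sort(values)
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each unique value
  data.frame(value = s[keep],
             fraction = seq_along(s)[keep] / length(s))
}

#' Relative-improvement (lift) ratio distribution
#'
#' Per-trial ratio of the numerator arm's draw over the denominator arm's
#' draw, summarised by percentiles, an ECDF, and threshold exceedance
#' probabilities `P(ratio >= t)`.  By default the numerator is chosen
#' automatically as the arm whose exact superiority probability is at least
#' 0.5 (the arm more likely to have the higher response rate).
#'
#' @param samples a [sample_pair()] result.
#' @param numerator `"auto"` (default), `"a"` or `"b"`.
#' @param thresholds numeric vector of ratio thresholds (default 1.5, i.e.
#'   "50% or more times as frequent").
#' @param probs percentile grid (default 25/50/75).
#' @return An object of class `ratio_summary` with fields `percentiles`,
#'   `ecdf`, `threshold_probs`, `numerator`, `n_trials`, `seed`.
#' @export
relative_improvement <- function(samples, numerator = c("auto", "a", "b"),
                                 thresholds = 1.5,
                                 probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(samples, "paired_samples"))
  numerator <- match.arg(numerator)
  if (numerator == "auto") {
    p_exact <- prob_superior_exact(samples$dist_a, samples$dist_b)
    numerator <- if (p_exact >= 0.5) "a" else "b"
  }
  ratio <- if (numerator == "a") samples$arm_a / samples$arm_b
           else samples$arm_b / samples$arm_a
  # order-statistic linear interpolation (quantile type 7)
  pct <- stats::quantile(ratio, probs = probs, names = FALSE, type = 7)
  names(pct) <- sprintf("p%g", 100 * probs)
  thr <- vapply(thresholds, function(t) mean(ratio >= t), numeric(1))
  names(thr) <- sprintf("ge_%g", thresholds)
  structure(list(percentiles = pct, ecdf = ecdf_table(ratio),
                 threshold_probs = thr, numerator = numerator,
                 n_trials = samples$n_trials, seed = samples$seed),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("relative improvement (numerator = arm %s, n = %d):\n",
              x$numerator, x$n_trials))
  cat("  percentiles:",
      paste(sprintf("%s = %.2f", names(x$percentiles), x$percentiles),
            collapse = ", "), "\n")
  cat("  exceedance:",
      paste(sprintf("P(ratio >= %s) = %.3f",
                    sub("^ge_", "", names(x$threshold_probs)),
                    x$threshold_probs), collapse = ", "), "\n")
  invisible(x)
}
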