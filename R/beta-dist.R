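## Conjugate beta algebra for the binomial pCR model.
##
## The rate of a binary endpoint in one arm is modelled as theta ~ Beta(a, b).
## Two parameterisations appear in practice:
##   * "data-only" (likelihood-shaped): a = observed successes, b = observed
##     failures -- the distribution plotted before any prior is introduced;
##   * posterior: Beta(a_prior + successes, b_prior + failures).
## Both are plain `beta_params` objects here.

#' Beta distribution parameters
#'
#' Constructs a validated pair of beta shape parameters.  In the pCR model
#' `alpha` plays the role of a pseudo-count of responders (pCR events) and
#' `beta` of non-responders.
#'
#' @param alpha,beta positive reals.
#' @return An object of class `beta_params`.
#' @export
#' @examples
#' beta_params(3, 7)   # literature-based prior for the non-mutated arm
#' beta_params(4, 6)   # prior for the mutated arm
beta_params <- function(alpha, beta) {
  assert_number(alpha, "alpha", lower = 0, open_lower = TRUE)
  assert_number(beta, "beta", lower = 0, open_lower = TRUE)
  structure(list(alpha = as.double(alpha), beta = as.double(beta)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g), mean %.4f\n", x$alpha, x$beta, beta_mean(x)))
  invisible(x)
}

as_beta_params <- function(x, name = "x") {
  if (inherits(x, "beta_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(beta_params(x[[1]], x[[2]]))
  stop_pcr("`%s` must be a beta_params object or a numeric pair", name)
}

#' Mean of a beta distribution
#'
#' The prior/posterior point estimate of the response rate:
#' `alpha / (alpha + beta)`.
#'
#' @param params a [beta_params()] object (or numeric pair).
#' @return A number in (0, 1).
#' @export
#' @examples
#' beta_mean(beta_params(3, 7))  # 0.3
beta_mean <- function(params) {
  p <- as_beta_params(params, "params")
  p$alpha / (p$alpha + p$beta)
}

#' Data-only beta distribution from arm counts
#'
#' Maps the observed counts of one arm to the beta distribution whose shape
#' parameters are the counts themselves: `Beta(successes, failures)`.  This
#' is the "available data" distribution shown before prior information is
#' brought in.  Note the convention: no +1 is added, so both counts must be
#' at least 1 for the distribution to be proper; with a zero count, supply a
#' proper prior and use [posterior_update()] instead.
#'
#' @param counts an [arm_counts()] object.
#' @return A [beta_params()] object.
#' @export
#' @examples
#' likelihood_beta(arm_counts(13, 11))  # mutated arm of the worked example
likelihood_beta <- function(counts) {
  counts <- as_arm_counts(counts, "counts")
  if (counts$successes < 1L || counts$failures < 1L)
    stop_pcr(paste0(
      "the data-only distribution Beta(successes, failures) is improper ",
      "when either count is zero (got %d/%d); supply a proper prior and ",
      "use posterior_update() instead"), counts$successes, counts$failures)
  beta_params(counts$successes, counts$failures)
}

#' Conjugate posterior update
#'
#' Beta-binomial conjugacy: a `Beta(a, b)` prior combined with `s` successes
#' and `f` failures yields the posterior `Beta(a + s, b + f)`.
#'
#' @param prior a [beta_params()] prior.
#' @param counts an [arm_counts()] object or numeric pair; the no-data pair
#'   `c(0, 0)` returns the prior unchanged.
#' @return The posterior [beta_params()].
#' @export
#' @examples
#' posterior_update(beta_params(4, 6), arm_counts(13, 11))  # Beta(17, 17)
posterior_update <- function(prior, counts) {
  prior <- as_beta_params(prior, "prior")
  if (is.numeric(counts) && length(counts) == 2L && all(counts == 0))
    return(prior)  # no data: posterior equals prior
  counts <- as_arm_counts(counts, "counts")
  beta_params(prior$alpha + counts$successes, prior$beta + counts$failures)
}

#' Beta quantile function
#'
#' Inverse of the regularised incomplete beta function, i.e. the value x with
#' `P(theta <= x) = q` for `theta ~ Beta(alpha, beta)`.
#'
#' @param params a [beta_params()] object.
#' @param q probability in (0, 1); vectorised.
#' @return Quantile value(s) in (0, 1).
#' @export
beta_quantile <- function(params, q) {
  p <- as_beta_params(params, "params")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop_pcr("`q` must lie strictly inside (0, 1)")
  stats::qbeta(q, p$alpha, p$beta)
}

#' Equal-tailed credible interval
#'
#' The central interval bounded by the `(1 - level)/2` and `1 - (1 - level)/2`
#' quantiles of the beta distribution (for `level = 0.95`, the 0.025 and
#' 0.975 quantiles).  Highest-density intervals are deliberately not offered.
#'
#' @param params a [beta_params()] object.
#' @param level credible level in (0, 1); default 0.95.
#' @return An object of class `credible_interval` with fields `lower`,
#'   `upper`, `level`.
#' @export
#' @examples
#' credible_interval(beta_params(17, 17))  # 33.5--66.5% at the default level
credible_interval <- function(params, level = 0.95) {
  assert_number(level, "level", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)
  tail <- (1 - level) / 2
  q <- beta_quantile(params, c(tail, 1 - tail))
  structure(list(lower = q[[1]], upper = q[[2]], level = level),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%g%% equal-tailed credible interval: %.1f%% -- %.1f%%\n",
              100 * x$level, round_half_up(100 * x$lower, 1),
              round_half_up(100 * x$upper, 1)))
  invisible(x)
}
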