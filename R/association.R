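## Frequentist effect estimation for the 2x2 stratum-by-outcome table:
## odds ratio, likelihood-ratio (profile) confidence interval, and the
## equivalent univariate logistic regression.
##
## The profile interval inverts the likelihood-ratio statistic of the
## two-independent-binomials model: with eta1 = mu + theta (exposed arm) and
## eta2 = mu on the log-odds scale, theta is the log odds ratio; the CI
## bounds are the two roots of 2*[l(theta_hat) - l_profile(theta)] =
## qchisq(level, 1), found by bracketed root-finding to 1e-8 on log-OR.

or_result <- function(odds_ratio, ci_lower, ci_upper, level, method,
                      term = NULL) {
  structure(list(odds_ratio = odds_ratio, ci_lower = ci_lower,
                 ci_upper = ci_upper, level = level, method = method,
                 term = term),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  stars <- ""  # significance stars per the 0.05/0.01/0.001 convention
  if (x$ci_lower > 1 || x$ci_upper < 1) stars <- " *"
  cat(sprintf("%sOR = %.2f (%g%% CI %.2f, %.2f; %s)%s\n",
              if (!is.null(x$term)) paste0(x$term, ": ") else "",
              x$odds_ratio, 100 * x$level, x$ci_lower, x$ci_upper,
              x$method, stars))
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)` with arm 1 = exposed and column 1 = success, so values
#' above 1 mean the exposed arm has higher odds of the outcome.
#'
#' @param table a [two_by_two()] object.
#' @param correction apply the Haldane-Anscombe +0.5 to every cell when any
#'   cell is zero (default `FALSE`: a zero cell is an error).
#' @return The odds ratio, a positive real.
#' @export
#' @examples
#' odds_ratio(two_by_two(13, 11, 48, 71))  # 1.75
odds_ratio <- function(table, correction = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    if (!correction)
      stop_pcr(paste0("zero cell in the 2x2 table; enable the ",
                      "Haldane-Anscombe correction (correction = TRUE) ",
                      "or use a Bayesian analysis"))
    cells <- cells + 0.5
  }
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

# Profile log-likelihood of the two-binomial model at fixed log-OR `theta`:
# maximises over the nuisance log-odds `mu` of the reference arm.
profile_loglik_2x2 <- function(theta, a, b, c, d) {
  ll <- function(mu) {
    e1 <- mu + theta; e2 <- mu
    a * e1 - (a + b) * log1p(exp(e1)) + c * e2 - (c + d) * log1p(exp(e2))
  }
  stats::optimize(ll, interval = c(-30, 30), maximum = TRUE,
                  tol = 1e-12)$objective
}

#' Confidence interval for the 2x2 odds ratio
#'
#' Default method `"profile"` inverts the likelihood-ratio statistic of the
#' two-binomial model (confidence bounds based on the log-likelihood ratio);
#' `"wald"` is the closed-form normal-approximation alternative
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, offered for
#' comparison and never the default.
#'
#' @param table a [two_by_two()] object with all cells >= 1 for the profile
#'   method.
#' @param level confidence level in (0, 1), default 0.95.
#' @param method `"profile"` (default) or `"wald"`.
#' @return An `or_result` with the point estimate and interval.
#' @export
#' @examples
#' or_confint(two_by_two(13, 11, 48, 71))  # 1.75 (0.72, 4.30)
or_confint <- function(table, level = 0.95,
                       method = c("profile", "wald")) {
  stopifnot(inherits(table, "two_by_two"))
  method <- match.arg(method)
  assert_number(level, "level", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) == 0))
    stop_pcr("degenerate table (zero cell): no finite interval; consider Wald on a corrected table")
  or <- odds_ratio(table)
  theta_hat <- log(or)
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    return(or_result(or, exp(theta_hat - z * se), exp(theta_hat + z * se),
                     level, "wald"))
  }
  crit <- stats::qchisq(level, df = 1)
  l_hat <- profile_loglik_2x2(theta_hat, a, b, c, d)
  dev <- function(theta) 2 * (l_hat - profile_loglik_2x2(theta, a, b, c, d)) - crit
  bound <- function(direction) {
    step <- 0.5
    lo <- theta_hat
    hi <- theta_hat + direction * step
    for (k in 1:60) {
      if (dev(hi) > 0) break
      lo <- hi
      hi <- hi + direction * step
      step <- step * 1.6
      if (k == 60) stop_pcr("root bracketing failed; table too degenerate for a profile interval (try method = 'wald')")
    }
    stats::uniroot(dev, sort(c(lo, hi)), tol = 1e-8)$root
  }
  or_result(or, exp(bound(-1)), exp(bound(1)), level, "profile-likelihood")
}

# Profile-likelihood CI for one coefficient of a logistic fit, by refitting
# with the coefficient fixed via an offset and root-finding on the deviance
# difference.
profile_ci_glm <- function(formula, data, term, level = 0.95) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  if (!term %in% names(stats::coef(fit)))
    stop_pcr("term '%s' not in the fitted model", term)
  est <- stats::coef(fit)[[term]]
  if (abs(est) > 15)
    stop_pcr("complete separation detected for term '%s'", term)
  X <- stats::model.matrix(fit)
  y <- fit$y
  others <- setdiff(colnames(X), term)
  dev_at <- function(b) {
    off <- b * X[, term]
    f2 <- suppressWarnings(stats::glm.fit(
      X[, others, drop = FALSE], y, family = stats::binomial(),
      offset = off))
    f2$deviance
  }
  crit <- stats::qchisq(level, df = 1)
  d0 <- fit$deviance
  g <- function(b) dev_at(b) - d0 - crit
  bound <- function(direction) {
    step <- 0.5; lo <- est; hi <- est + direction * step
    for (k in 1:60) {
      if (g(hi) > 0) break
      lo <- hi; hi <- hi + direction * step; step <- step * 1.6
      if (k == 60) stop_pcr("profile bracketing failed for '%s'", term)
    }
    stats::uniroot(g, sort(c(lo, hi)), tol = 1e-8)$root
  }
  list(estimate = est, lower = bound(-1), upper = bound(1), fit = fit)
}

#' Univariate logistic regression odds ratios
#'
#' Fits `outcome ~ predictor` by maximum likelihood and reports, per
#' non-reference level (or per unit for a numeric predictor), the odds ratio
#' with a profile-likelihood confidence interval.  For a binary predictor
#' the fitted OR equals the closed-form `(a*d)/(b*c)` of the corresponding
#' 2x2 table.
#'
#' @param cohort a `cohort` data.frame.
#' @param predictor name of a column in `cohort` (the stratum column or any
#'   covariate).
#' @param reference reference level for a categorical predictor (default:
#'   first level in sort order).
#' @param level confidence level, default 0.95.
#' @return A list of `or_result` objects, one per non-reference level (a
#'   single element named `"unit"` for numeric predictors).
#' @export
logistic_univariate <- function(cohort, predictor, reference = NULL,
                                level = 0.95) {
  cohort <- as_cohort(cohort)
  if (!predictor %in% names(cohort))
    stop_pcr("predictor '%s' not found in cohort", predictor)
  keep <- !is.na(cohort[[predictor]])
  dat <- data.frame(.y = cohort$outcome[keep], .x = cohort[[predictor]][keep])
  if (is.numeric(dat$.x)) {
    terms <- ".x"
    labels <- "unit"
  } else {
    dat$.x <- factor(dat$.x)
    if (!is.null(reference)) {
      if (!reference %in% levels(dat$.x))
        stop_pcr("reference level '%s' absent from predictor '%s'",
                 reference, predictor)
      dat$.x <- stats::relevel(dat$.x, ref = reference)
    }
    # guard against complete separation per level before fitting
    tab <- table(dat$.x, dat$.y)
    sep <- rownames(tab)[rowSums(tab == 0) > 0 & rowSums(tab) > 0]
    if (length(sep))
      stop_pcr("complete separation: level(s) %s of '%s' have all-0 or all-1 outcomes",
               paste(sep, collapse = ", "), predictor)
    labels <- levels(dat$.x)[-1]
    terms <- paste0(".x", labels)
  }
  res <- lapply(seq_along(terms), function(i) {
    pr <- profile_ci_glm(.y ~ .x, dat, terms[[i]], level)
    or_result(exp(pr$estimate), exp(pr$lower), exp(pr$upper), level,
              "profile-likelihood",
              term = paste0(predictor, ":", labels[[i]]))
  })
  names(res) <- labels
  res
}
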