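## Group-comparison tests: F-dispatched pooled/Welch t for continuous
## covariates, Pearson chi-square for categorical ones.
##
## The t and F machinery is written against (n, mean, sd) summaries so that
## a comparison run on raw data and one run on the summaries of that data
## agree exactly: the raw path reduces to summaries first.

comparison_result <- function(test_name, statistic, df, p_value,
                              details = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(test_name = test_name, statistic = statistic,
                   df = df, p_value = p_value), details),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

as_arm_summary <- function(x, name) {
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x)))
    s <- c(n = x$n, mean = x$mean, sd = x$sd)
  else if (is.numeric(x) && length(x) == 3L && !is.null(names(x)) &&
           all(c("n", "mean", "sd") %in% names(x)))
    s <- x[c("n", "mean", "sd")]
  else if (is.numeric(x) && length(x) > 3L || (is.numeric(x) && is.null(names(x)) && length(x) != 3L)) {
    s <- c(n = length(x), mean = mean(x), sd = stats::sd(x))
  } else if (is.numeric(x) && length(x) == 3L && is.null(names(x))) {
    # unnamed triple is read positionally as (n, mean, sd)
    s <- c(n = x[[1]], mean = x[[2]], sd = x[[3]])
  } else stop_pcr("`%s` must be a numeric vector or an (n, mean, sd) summary",
                  name)
  if (s[["n"]] < 2) stop_pcr("insufficient data in `%s`: n = %g < 2",
                             name, s[["n"]])
  if (!is.na(s[["sd"]]) && s[["sd"]] < 0)
    stop_pcr("`%s` has negative sd", name)
  s
}

#' Compare a continuous covariate between two arms
#'
#' Tests equality of variances with the two-sided F test; if equality is not
#' rejected at `var_alpha`, runs the pooled-variance t-test, otherwise
#' Welch's unequal-variance t-test (Welch-Satterthwaite degrees of freedom).
#' Accepts raw numeric vectors or `(n, mean, sd)` summaries for either arm,
#' with identical results because raw data is reduced to its summaries.
#'
#' @param arm1,arm2 numeric vector of raw values, or an `(n, mean, sd)`
#'   summary (named vector or list).  An unnamed numeric triple is read as a
#'   summary.
#' @param var_alpha two-sided significance level of the F dispatch
#'   (default 0.05).
#' @return A `comparison_result` with `test_name` one of `"pooled-t"`,
#'   `"welch-t"`, plus the dispatching F statistic and its p-value.
#' @export
#' @examples
#' # age in the worked example: pooled t fires (variances comparable)
#' compare_continuous(c(n = 119, mean = 57.1, sd = 12.5),
#'                    c(n = 24, mean = 47.0, sd = 12.9))
compare_continuous <- function(arm1, arm2, var_alpha = 0.05) {
  s1 <- as_arm_summary(arm1, "arm1")
  s2 <- as_arm_summary(arm2, "arm2")
  n1 <- s1[["n"]]; m1 <- s1[["mean"]]; sd1 <- s1[["sd"]]
  n2 <- s2[["n"]]; m2 <- s2[["mean"]]; sd2 <- s2[["sd"]]
  if (sd1 <= 0 || sd2 <= 0)
    stop_pcr("both arms must have sd > 0 (got %g, %g)", sd1, sd2)

  f_stat <- sd1^2 / sd2^2
  f_p <- 2 * min(stats::pf(f_stat, n1 - 1, n2 - 1),
                 stats::pf(f_stat, n1 - 1, n2 - 1, lower.tail = FALSE))
  f_p <- min(f_p, 1)
  equal_var <- f_p >= var_alpha

  if (equal_var) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    test <- "pooled-t"
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    test <- "welch-t"
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  comparison_result(test, tstat, df, p,
                    details = list(f_statistic = f_stat, f_df = c(n1 - 1, n2 - 1),
                                   f_p_value = f_p, var_alpha = var_alpha))
}

#' Compare a categorical covariate between arms
#'
#' Pearson chi-square test of independence on an r x c contingency table.
#' Continuity correction is off by default (configurable), matching the
#' uncorrected convention used for the package's reference analyses.
#'
#' @param table a [two_by_two()] object or an r x c matrix/table of
#'   non-negative counts.
#' @param correct logical; apply Yates continuity correction (2x2 only).
#' @return A `comparison_result` with `test_name = "chi-square"`.
#' @export
compare_categorical <- function(table, correct = FALSE) {
  m <- if (inherits(table, "two_by_two")) as.matrix(table)
       else as.matrix(table)
  storage.mode(m) <- "double"
  if (any(m < 0) || any(!is.finite(m)))
    stop_pcr("counts must be finite and non-negative")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_pcr("need at least a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_pcr("chi-square test undefined: a marginal row/column is zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  comparison_result("chi-square", unname(ct$statistic),
                    unname(ct$parameter), ct$p.value,
                    details = list(correct = correct))
}
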