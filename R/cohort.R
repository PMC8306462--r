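## Patient-level cohort handling: validated CSV ingestion, per-arm count
## aggregation, and descriptive summaries.
##
## A cohort is a plain data.frame (class "cohort") with mandatory columns
## `patient_id`, `stratum`, `outcome` (0/1) plus arbitrary covariate columns.

# Outcome value aliases accepted at read time (case-insensitive).
.outcome_aliases <- list(
  `1` = c("1", "yes", "y", "pcr", "true", "t"),
  `0` = c("0", "no", "n", "non-pcr", "non_pcr", "nonpcr", "false", "f")
)

#' Per-arm success/failure counts
#'
#' The sufficient statistic of the binomial likelihood for one stratum:
#' counts of responders (pCR) and non-responders.
#'
#' @param successes,failures non-negative integers, summing to at least 1.
#' @return An object of class `arm_counts`.
#' @export
arm_counts <- function(successes, failures) {
  successes <- assert_count(successes, "successes")
  failures <- assert_count(failures, "failures")
  if (successes + failures < 1L)
    stop_pcr("an arm must contain at least one patient")
  structure(list(successes = successes, failures = failures),
            class = "arm_counts")
}

as_arm_counts <- function(x, name = "x") {
  if (inherits(x, "arm_counts")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(arm_counts(x[[1]], x[[2]]))
  stop_pcr("`%s` must be an arm_counts object or a numeric pair", name)
}

#' @export
print.arm_counts <- function(x, ...) {
  n <- x$successes + x$failures
  cat(sprintf("arm counts: %d/%d events (%.1f%%)\n", x$successes, n,
              100 * x$successes / n))
  invisible(x)
}

#' 2x2 stratum-by-outcome table
#'
#' Cell layout `(a, b, c, d)` = (arm-1 successes, arm-1 failures, arm-2
#' successes, arm-2 failures); arm 1 is the exposed stratum (e.g. mutation
#' carriers) so that `odds_ratio()` reads exposure vs reference directly.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- vapply(list(a = a, b = b, c = c, d = d), assert_count,
                  integer(1), name = "cell")
  structure(as.list(cells), class = "two_by_two")
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(arm = c("arm1", "arm2"),
                         outcome = c("success", "failure")))
}

#' @export
print.two_by_two <- function(x, ...) {
  print(as.matrix(x))
  invisible(x)
}

normalize_outcome <- function(values) {
  v <- tolower(trimws(as.character(values)))
  out <- rep(NA_integer_, length(v))
  out[v %in% .outcome_aliases[["1"]]] <- 1L
  out[v %in% .outcome_aliases[["0"]]] <- 0L
  out
}

#' Read and validate a patient-level cohort CSV
#'
#' Reads a comma-separated, UTF-8, headered file; maps the declared stratum
#' and outcome columns; normalises outcome aliases ("yes"/"no", 1/0,
#' "pCR"/"non-pCR") to 0/1; and validates every row.  Malformed rows are
#' collected and reported together in a single error.
#'
#' @param path path to the CSV file.
#' @param schema named list mapping the roles `patient_id` (optional),
#'   `stratum` and `outcome` to column names in the file.  Columns not
#'   mentioned are carried along as covariates.
#' @param stratum_levels optional character pair declaring the two expected
#'   stratum labels (first = exposed arm); any other label is an error.
#' @return A `cohort` data.frame with columns `patient_id`, `stratum`,
#'   `outcome` and the remaining covariate columns; the number of rows read
#'   is reported via `message()`.
#' @export
read_cohort <- function(path,
                        schema = list(patient_id = "id", stratum = "stratum",
                                      outcome = "outcome"),
                        stratum_levels = NULL) {
  if (!file.exists(path)) stop_pcr("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  for (role in c("stratum", "outcome")) {
    col <- schema[[role]]
    if (is.null(col))
      stop_pcr("schema must name the `%s` column", role)
    if (!col %in% names(raw))
      stop_pcr("schema error: declared %s column '%s' missing from %s",
               role, col, path)
  }
  n <- nrow(raw)
  id_col <- schema[["patient_id"]]
  ids <- if (!is.null(id_col) && id_col %in% names(raw))
    as.character(raw[[id_col]]) else sprintf("P%04d", seq_len(n))

  stratum <- as.character(raw[[schema$stratum]])
  outcome_raw <- raw[[schema$outcome]]
  outcome <- normalize_outcome(outcome_raw)

  problems <- character(0)
  bad_out <- which(is.na(outcome))
  if (length(bad_out))
    problems <- c(problems, sprintf(
      "row %d: outcome value '%s' is not binary", bad_out,
      as.character(outcome_raw)[bad_out]))
  bad_str <- which(is.na(stratum) | !nzchar(trimws(stratum)))
  if (length(bad_str))
    problems <- c(problems, sprintf("row %d: missing stratum", bad_str))
  if (!is.null(stratum_levels)) {
    extra <- setdiff(unique(stratum[!is.na(stratum)]), stratum_levels)
    if (length(extra))
      problems <- c(problems, sprintf("unexpected stratum label(s): %s",
                                      paste(extra, collapse = ", ")))
  }
  if (length(problems))
    stop_pcr("cohort validation failed (%d problem%s):\n%s",
             length(problems), if (length(problems) > 1) "s" else "",
             paste(" -", problems, collapse = "\n"))

  used <- unlist(schema[c("patient_id", "stratum", "outcome")])
  covars <- raw[, setdiff(names(raw), used), drop = FALSE]
  out <- data.frame(patient_id = ids, stratum = stratum, outcome = outcome,
                    stringsAsFactors = FALSE)
  out <- cbind(out, covars)
  class(out) <- c("cohort", "data.frame")
  message(sprintf("read %d patient records from %s", n, path))
  out
}

as_cohort <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("patient_id", "stratum", "outcome") %in% names(df)))
  if (!inherits(df, "cohort")) class(df) <- c("cohort", "data.frame")
  df
}

#' Aggregate a cohort to per-arm counts and a 2x2 table
#'
#' Partitions the cohort by the two declared stratum levels (first level =
#' arm 1 = exposed) and tallies successes/failures in each.
#'
#' @param cohort a `cohort` data.frame (see [read_cohort()]).
#' @param stratum_levels ordered character pair of stratum labels; defaults
#'   to the levels present, in order of first appearance.
#' @return A list with components `arm1`, `arm2` ([arm_counts()]), `table`
#'   ([two_by_two()]) and `stratum_levels`.
#' @export
aggregate_arms <- function(cohort, stratum_levels = NULL) {
  cohort <- as_cohort(cohort)
  present <- unique(cohort$stratum)
  if (is.null(stratum_levels)) stratum_levels <- present
  if (length(stratum_levels) != 2L)
    stop_pcr("exactly two stratum levels required, got: %s",
             paste(stratum_levels, collapse = ", "))
  extra <- setdiff(present, stratum_levels)
  if (length(extra))
    stop_pcr("unexpected stratum label(s): %s", paste(extra, collapse = ", "))
  counts <- lapply(stratum_levels, function(lev) {
    y <- cohort$outcome[cohort$stratum == lev]
    if (!length(y)) stop_pcr("stratum '%s' contains no records", lev)
    arm_counts(sum(y == 1L), sum(y == 0L))
  })
  names(counts) <- stratum_levels
  list(arm1 = counts[[1]], arm2 = counts[[2]],
       table = two_by_two(counts[[1]]$successes, counts[[1]]$failures,
                          counts[[2]]$successes, counts[[2]]$failures),
       stratum_levels = stratum_levels)
}

#' Descriptive per-arm summary with group comparisons
#'
#' For each covariate, produces per-arm descriptives (mean +/- sd for
#' numeric, n (%) for categorical) and the matching group-comparison test:
#' F-dispatched pooled/Welch t-test for numeric covariates, chi-square for
#' categorical ones.  Missing covariate values are dropped pairwise per
#' comparison, never imputed.
#'
#' @param cohort a `cohort` data.frame.
#' @param stratum_levels ordered pair of stratum labels (first = arm 1).
#' @param covariates character vector of covariate columns to summarise;
#'   defaults to all non-mandatory columns.
#' @return A list of per-covariate entries (class `cohort_summary`), each
#'   with the per-arm descriptives and a [compare_continuous()] /
#'   [compare_categorical()] result.
#' @export
describe_cohort <- function(cohort, stratum_levels = NULL,
                            covariates = NULL) {
  cohort <- as_cohort(cohort)
  agg <- aggregate_arms(cohort, stratum_levels)
  stratum_levels <- agg$stratum_levels
  if (is.null(covariates))
    covariates <- setdiff(names(cohort),
                          c("patient_id", "stratum", "outcome"))
  in1 <- cohort$stratum == stratum_levels[[1]]
  entries <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    if (is.numeric(x)) {
      x1 <- x[in1 & !is.na(x)]; x2 <- x[!in1 & !is.na(x)]
      cmp <- tryCatch(compare_continuous(x1, x2), pcrbayes_error = function(e) NULL)
      list(name = cv, kind = "numeric",
           arm1 = c(n = length(x1), mean = mean(x1), sd = stats::sd(x1)),
           arm2 = c(n = length(x2), mean = mean(x2), sd = stats::sd(x2)),
           comparison = cmp)
    } else {
      keep <- !is.na(x)
      tab <- table(factor(cohort$stratum[keep], levels = stratum_levels),
                   x[keep])
      cmp <- tryCatch(compare_categorical(unclass(tab)),
                      pcrbayes_error = function(e) NULL)
      list(name = cv, kind = "categorical",
           counts = tab,
           percent = 100 * prop.table(tab, margin = 1),
           comparison = cmp)
    }
  })
  names(entries) <- covariates
  structure(list(n = nrow(cohort), stratum_levels = stratum_levels,
                 arms = list(arm1 = agg$arm1, arm2 = agg$arm2),
                 covariates = entries),
            class = "cohort_summary")
}
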