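#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical reports conventionally round
#' half up.  Used only at the reporting layer -- full precision is retained
#' internally.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_pcr <- function(fmt, ..., class = "pcrbayes_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pcr("`%s` must be a single finite number", name)
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_pcr("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
             if (open_lower) "(" else "[", lower, upper,
             if (open_upper) ")" else "]")
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x))
    stop_pcr("`%s` must be an integer >= %d (got %s)", name, min,
             paste(format(x), collapse = ","))
  invisible(as.integer(x))
}

## Deterministic sub-seed derivation so stages (cohort generation, Monte
## Carlo, replicates) are independently reproducible from one master seed.
## Kept below 2^31 - 1 because R seeds are 32-bit integers.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(cohort = 1L, mc = 2L, recovery = 3L)
  off <- if (is.character(stream)) {
    if (!stream %in% names(offsets))
      sum(utf8ToInt(stream)) %% 1000L
    else offsets[[stream]]
  } else as.integer(stream)
  as.integer((as.double(seed) * 48271 + off * 16807) %% 2147483647)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## global RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
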