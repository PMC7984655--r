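# Internal helpers shared across modules.

#' Round the way the source tables print
#'
#' In "paper" rounding mode intermediate quantities are rounded to the number
#' of decimals the epidemiological tables print before the computation
#' continues; in "full" mode nothing is rounded.  Several published display
#' values (e.g. the 1.32 prevalence inflation factor) are only reproducible
#' from rounded intermediates, so both modes are first-class.
#'
#' @param x numeric vector.
#' @param digits decimals to keep in paper mode.
#' @param mode `"full"` (default) or `"paper"`.
#' @return `x`, rounded if `mode == "paper"`.
#' @export
mode_round <- function(x, digits, mode = c("full", "paper")) {
  mode <- match.arg(mode)
  if (mode != "paper") return(x)
  # half-up rounding, the convention of the printed tables (0.3125 -> 0.313);
  # base round() is half-even and would give 0.312
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

assert_probability <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok)) {
    stop(sprintf("'%s' must be a probability in %s0, 1%s (got %s)",
                 name,
                 if (open_lower) "(" else "[",
                 if (open_upper) ")" else "]",
                 paste(signif(x, 6), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Probability interval
#'
#' A closed subinterval of \[0, 1\] used to carry every published range
#' (e.g. bounds on the susceptible fraction of the population).
#'
#' @param lo,hi endpoints, `0 <= lo <= hi <= 1`.
#' @return an object of class `probability_interval`.
#' @export
probability_interval <- function(lo, hi) {
  assert_probability(lo, "lo")
  assert_probability(hi, "hi")
  if (lo > hi) stop("'lo' must not exceed 'hi'", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "probability_interval")
}

#' @export
print.probability_interval <- function(x, ...) {
  cat(sprintf("[%.6g, %.6g]\n", x$lo, x$hi))
  invisible(x)
}

#' @export
format.probability_interval <- function(x, ...) {
  sprintf("[%.4g, %.4g]", x$lo, x$hi)
}

interval_contains <- function(interval, value) {
  value >= interval$lo & value <= interval$hi
}
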