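# prevalence: estimate the lifetime MS probability P(MS) from measured
# prevalence by three routes, and combine them.

#' A P(MS) estimate
#'
#' @param method one of `"ageband"`, `"age_restricted"`, `"death_certificate"`.
#' @param interval a [probability_interval].
#' @param point point estimate; must lie inside `interval`.
#' @return an object of class `pms_estimate`.
#' @export
pms_estimate <- function(method, interval, point) {
  stopifnot(inherits(interval, "probability_interval"))
  if (!interval_contains(interval, point)) {
    stop("point estimate must lie within its interval", call. = FALSE)
  }
  structure(list(method = method, interval = interval, point = point),
            class = "pms_estimate")
}

#' @export
print.pms_estimate <- function(x, ...) {
  cat(sprintf("P(MS) estimate (%s): %.4g %s\n",
              x$method, x$point, format(x$interval)))
  invisible(x)
}

#' Estimate P(MS) from overall prevalence and census age bands
#'
#' Clinical onset of MS falls almost entirely between 15 and 45 years, so a
#' cross-sectional prevalence mixes age groups with very different
#' probabilities of already having the disease.  Splitting the population
#' into bands A1 (<15y, essentially no prevalent cases), A2 (15-45y, about
#' half the lifetime risk realized for a symmetric onset distribution) and A3
#' (>45y, all onsets realized but thinned by excess MS mortality), the
#' measured prevalence satisfies
#' `prev = P * (w1*m1 + w2*m2 + w3*f)` with band multipliers `m1 = 0`,
#' `m2 = 0.5` and a mortality factor `f` swept over `a3_factor_range`.
#' Solving for `P` at both ends of the factor range gives the interval
#' (about `[1.7*prev, 2*prev]` with the 2010 US census weights).
#'
#' @param prev measured overall prevalence, in (0, 0.05).
#' @param weights three age-band proportions summing to 1.
#' @param a3_factor_range plausible range for the A3 survival factor,
#'   a subset of \[0.5, 1\].
#' @param band_multipliers the A1 and A2 multipliers; published approximations
#'   0 and 0.5 by default, exposed for sensitivity analysis.
#' @param undiagnosed_inflation optional multiplier in \[1, 2\] for
#'   undiagnosed (pathological) MS; 1 (off) by default.
#' @return a [pms_estimate] with method `"ageband"`.
#' @examples
#' estimate_from_agebands(0.0015, c(0.20, 0.41, 0.39))
#' @export
estimate_from_agebands <- function(prev, weights,
                                   a3_factor_range = c(0.75, 1.0),
                                   band_multipliers = c(a1 = 0, a2 = 0.5),
                                   undiagnosed_inflation = 1) {
  if (!is.finite(prev) || prev <= 0 || prev >= 0.05) {
    stop("'prev' must be in (0, 0.05)", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("'weights' must sum to 1", call. = FALSE)
  if (any(a3_factor_range < 0.5) || any(a3_factor_range > 1)) {
    stop("'a3_factor_range' must lie within [0.5, 1]", call. = FALSE)
  }
  if (undiagnosed_inflation < 1 || undiagnosed_inflation > 2) {
    stop("'undiagnosed_inflation' must be in [1, 2]", call. = FALSE)
  }
  denom <- function(f) {
    weights[1] * band_multipliers[["a1"]] +
      weights[2] * band_multipliers[["a2"]] + weights[3] * f
  }
  d <- vapply(range(a3_factor_range), denom, numeric(1))
  if (all(d <= 0)) {
    stop("degenerate weights: no age band contributes prevalent cases",
         call. = FALSE)
  }
  ests <- sort(undiagnosed_inflation * prev / d)
  pms_estimate("ageband",
               probability_interval(ests[1], ests[2]),
               point = mean(ests))
}

#' Estimate P(MS) from age-restricted (45-54y) prevalence
#'
#' In the 45-54y band nearly all onsets have occurred and little excess
#' mortality has accrued, so the band prevalence approximates the lifetime
#' probability directly.
#'
#' @param prev_45_54 measured prevalence in the 45-54y band, in (0, 0.05).
#' @inheritParams estimate_from_agebands
#' @return a [pms_estimate] with method `"age_restricted"` and a degenerate
#'   interval at the pass-through value.
#' @export
estimate_from_age_restricted <- function(prev_45_54, undiagnosed_inflation = 1) {
  if (!is.finite(prev_45_54) || prev_45_54 <= 0 || prev_45_54 >= 0.05) {
    stop("'prev_45_54' must be in (0, 0.05)", call. = FALSE)
  }
  v <- undiagnosed_inflation * prev_45_54
  pms_estimate("age_restricted", probability_interval(v, v), point = v)
}

#' Estimate P(MS) from death-certificate mentions
#'
#' By death, any clinically evident MS has declared itself, so the fraction
#' of death certificates mentioning MS estimates the lifetime probability.
#'
#' @param rate fraction of death certificates mentioning MS, in (0, 0.05).
#' @inheritParams estimate_from_agebands
#' @return a [pms_estimate] with method `"death_certificate"`.
#' @export
estimate_from_death_certificates <- function(rate, undiagnosed_inflation = 1) {
  if (!is.finite(rate) || rate <= 0 || rate >= 0.05) {
    stop("'rate' must be in (0, 0.05)", call. = FALSE)
  }
  v <- undiagnosed_inflation * rate
  pms_estimate("death_certificate", probability_interval(v, v), point = v)
}

#' Combine P(MS) estimates into an envelope interval
#'
#' No principled pooling rule exists for the three estimation routes, so the
#' combination is the union envelope `[min lo, max hi]` of the supplied
#' intervals — a deliberate package choice.
#'
#' @param estimates a list of [pms_estimate] objects (at least one).
#' @return a [probability_interval].
#' @export
combine_pms_estimates <- function(estimates) {
  if (!length(estimates)) stop("need at least one estimate", call. = FALSE)
  ok <- vapply(estimates, inherits, logical(1), what = "pms_estimate")
  if (!all(ok)) stop("all elements must be pms_estimate objects", call. = FALSE)
  lo <- min(vapply(estimates, function(e) e$interval$lo, numeric(1)))
  hi <- max(vapply(estimates, function(e) e$interval$hi, numeric(1)))
  probability_interval(lo, hi)
}
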