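# exposure_response: two-timepoint exponential failure curves for susceptible
# men and women, fitted from the temporal change in the F:M sex ratio.
#
# Exposure is transformed through the cumulative hazard so that the failure
# curve for men is c*(1 - exp(-(a - lambda_m))) in "exposure units" a, with
# one unit defined as the change between the two observation epochs.  Women
# follow the analogous curve with plateau d, threshold lambda_w, and a
# hazard proportionality constant R relative to men.

.E1 <- exp(-1)

#' Failure-probability anchors at the second timepoint
#'
#' `Zw2 = P(MS,E|G,F)_2 = P(F|MS)_2 * P(MS)_2 / P(G,F)` and the male
#' analogue: the per-sex case probabilities concentrated on the susceptible
#' subset of each sex.
#'
#' @param p_f_ms2 proportion of cases who are women at timepoint 2.
#' @param p_ms2 disease probability at timepoint 2.
#' @param p_g susceptible fraction of the population.
#' @param p_f_g proportion of women among susceptibles.
#' @return named numeric `c(zw2 = ..., zm2 = ...)`.
#' @examples
#' timepoint2_anchors(0.66, 0.003, 0.044, 0.25)  # c(0.180, 0.0309)
#' @export
timepoint2_anchors <- function(p_f_ms2, p_ms2, p_g, p_f_g) {
  assert_probability(p_f_ms2, "p_f_ms2", open_lower = TRUE, open_upper = TRUE)
  assert_probability(p_ms2, "p_ms2", open_lower = TRUE)
  if (p_g * p_f_g <= 0 || p_g * (1 - p_f_g) <= 0) {
    stop("both P(G,F) and P(G,M) must be positive", call. = FALSE)
  }
  zw2 <- p_f_ms2 * p_ms2 / (p_f_g * p_g)
  zm2 <- (1 - p_f_ms2) * p_ms2 / ((1 - p_f_g) * p_g)
  if (zw2 > 1 || zm2 > 1) {
    stop(sprintf("infeasible anchors (zw2 = %.3g, zm2 = %.3g): parameter combination impossible",
                 zw2, zm2), call. = FALSE)
  }
  c(zw2 = zw2, zm2 = zm2)
}

#' Upper bound on C = P(MS)_1 / P(MS)_2 from the sex-ratio change
#'
#' Male case counts cannot have fallen (the rise is driven by women), so
#' `C < P(M|MS)_2 / P(M|MS)_1`.
#'
#' @param sexratio1,sexratio2 F:M case ratios at the two timepoints;
#'   `sexratio2 > sexratio1` (the rising-ratio direction; otherwise the bound
#'   direction flips and an error is raised).
#' @param mode `"paper"` rounds the two male proportions to 3 decimals
#'   before dividing (0.238/0.313 = 0.760); `"full"` gives 3.2/4.2 relative
#'   to 2.2/3.2 = 0.7619.
#' @return the bound on C.
#' @export
c_upper_bound <- function(sexratio1, sexratio2, mode = c("full", "paper")) {
  mode <- match.arg(mode)
  if (sexratio1 <= 0 || sexratio2 <= 0) stop("sex ratios must be positive", call. = FALSE)
  if (sexratio2 <= sexratio1) {
    stop("'sexratio2' must exceed 'sexratio1': with a falling ratio the bound direction flips",
         call. = FALSE)
  }
  m2 <- mode_round(1 / (1 + sexratio2), 3, mode)
  m1 <- mode_round(1 / (1 + sexratio1), 3, mode)
  m2 / m1
}

#' Prevalence inflation factor 1/C
#'
#' @inheritParams c_upper_bound
#' @return `1 / C_bound`; in paper mode the reciprocal of C rounded to two
#'   decimals (1/0.76 = 1.32).
#' @export
prevalence_inflation_factor <- function(sexratio1, sexratio2,
                                        mode = c("full", "paper")) {
  mode <- match.arg(mode)
  cb <- c_upper_bound(sexratio1, sexratio2, mode = mode)
  1 / mode_round(cb, 2, mode)
}

#' Epoch ratios of per-sex case proportions
#'
#' @inheritParams c_upper_bound
#' @return `c(ratio_f = P(F|MS)_1/P(F|MS)_2, ratio_m = P(M|MS)_1/P(M|MS)_2)`.
#' @export
epoch_case_ratios <- function(sexratio1, sexratio2) {
  c(ratio_f = sexratio_to_proportion(sexratio1) / sexratio_to_proportion(sexratio2),
    ratio_m = (1 / (1 + sexratio1)) / (1 / (1 + sexratio2)))
}

#' Limiting failure probabilities (plateaus) c and d
#'
#' Two observations on an exponential failure curve determine it completely.
#' With timepoint-1 anchors re-expressed through `C` and the epoch case
#' ratios (`Zm1 = ratio_m * C * Zm2`), the plateaus are
#' `c = Zm2 * (1 - ratio_m * C * e^-1) / (1 - e^-1)` and the analogue for
#' `d`.  The timepoint-1 exposure coordinates are back-computed as
#' `a1 = -ln(1 - Zm1/c)` (men's scale) and the women's analogue on the
#' apparent scale.
#'
#' @param zw2,zm2 timepoint-2 anchors (see [timepoint2_anchors()]).
#' @param ratio_f,ratio_m epoch case ratios (see [epoch_case_ratios()]).
#' @param C ratio `P(MS)_1 / P(MS)_2`, in (0, 1\].
#' @return list with `c`, `d`, `zw1`, `zm1`, `a1`, `a1_app`.
#' @examples
#' r <- epoch_case_ratios(2.2, 3.2)
#' limiting_values(0.180, 0.031, r[["ratio_f"]], r[["ratio_m"]], C = 0.6)
#' @export
limiting_values <- function(zw2, zm2, ratio_f, ratio_m, C) {
  assert_probability(zw2, "zw2", open_lower = TRUE, open_upper = TRUE)
  assert_probability(zm2, "zm2", open_lower = TRUE, open_upper = TRUE)
  if (C <= 0 || C > 1) stop("'C' must be in (0, 1]", call. = FALSE)
  br_m <- 1 - ratio_m * C * .E1
  br_f <- 1 - ratio_f * C * .E1
  if (br_m <= 0 || br_f <= 0) {
    stop("inconsistent inputs: negative bracket in the plateau closed form",
         call. = FALSE)
  }
  cc <- zm2 * br_m / (1 - .E1)
  dd <- zw2 * br_f / (1 - .E1)
  zm1 <- ratio_m * C * zm2
  zw1 <- ratio_f * C * zw2
  if (zm1 >= cc || zw1 >= dd) {
    stop("inconsistent inputs: timepoint-1 anchor at or above its plateau",
         call. = FALSE)
  }
  list(c = cc, d = dd, zw1 = zw1, zm1 = zm1,
       a1 = -log(1 - zm1 / cc),
       a1_app = -log(1 - zw1 / dd))
}

#' Threshold difference lambda between women and men
#'
#' `lambda = ln[(1 - Zw2/d) / (1 - Zm2/c)]`, the difference between the
#' exposure thresholds at which disease first becomes possible for the two
#' sexes.  Valid under R = 1 but numerically independent of R.
#'
#' @param zw2,zm2 timepoint-2 anchors; must lie strictly below their
#'   plateaus.
#' @param c,d plateaus for men and women.
#' @return lambda (positive when women's threshold is higher).
#' @export
threshold_difference <- function(zw2, zm2, c, d) {
  if (zw2 >= d) stop("'zw2' must lie below its plateau d", call. = FALSE)
  if (zm2 >= c) stop("'zm2' must lie below its plateau c", call. = FALSE)
  log((1 - zw2 / d) / (1 - zm2 / c))
}

#' Lower bounds on the current exposure probability P(E)
#'
#' `P(E|G,M)_2 = Zm2/c = (1 - e^-1) / (1 - ratio_m * C * e^-1)`, increasing
#' in C, so evaluating at a minimum credible C bounds the current exposure
#' probability from below (women analogous).
#'
#' @inheritParams c_upper_bound
#' @param C_min minimum credible value of C, in (0, 1).
#' @return `c(bound_m = ..., bound_w = ...)`.
#' @examples
#' exposure_probability_bound(2.2, 3.2, 0.5)  # c(0.833, 0.758)
#' @export
exposure_probability_bound <- function(sexratio1, sexratio2, C_min) {
  if (C_min <= 0 || C_min >= 1) stop("'C_min' must be in (0, 1)", call. = FALSE)
  r <- epoch_case_ratios(sexratio1, sexratio2)
  br_m <- 1 - r[["ratio_m"]] * C_min * .E1
  br_w <- 1 - r[["ratio_f"]] * C_min * .E1
  if (br_m <= 0 || br_w <= 0) stop("infeasible: bracket <= 0", call. = FALSE)
  c(bound_m = (1 - .E1) / br_m, bound_w = (1 - .E1) / br_w)
}

#' Per-event probability for k independent equally likely exposure events
#'
#' @param p_e joint exposure probability, in (0, 1\].
#' @param k number of independent, equally likely component events (>= 1).
#' @return `p_e^(1/k)`.
#' @examples
#' multievent_decomposition(0.83, 3)  # 0.9396
#' @export
multievent_decomposition <- function(p_e, k) {
  assert_probability(p_e, "p_e", open_lower = TRUE)
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  p_e^(1 / k)
}

#' Fit the full response-curve parameter set
#'
#' Combines the anchor computation, the plateau closed forms and the
#' threshold difference into one parameter object.  The men's threshold is
#' fixed at zero (the lower-threshold sex starts at the origin by the
#' definition of the susceptible subset); when the fitted lambda is
#' negative the roles flip.
#'
#' @param p_f_ms2 proportion of cases who are women at timepoint 2 (anchor
#'   source; the curve preset deliberately mixes this case-series value with
#'   epoch ratios from the longitudinal sex-ratio series — the only
#'   combination consistent with both data sources).
#' @param p_ms2 disease probability at timepoint 2.
#' @param p_g susceptible fraction.
#' @param p_f_g proportion of women among susceptibles.
#' @param sexratio1,sexratio2 F:M case ratios at the two epochs.
#' @param C ratio `P(MS)_1/P(MS)_2`.
#' @param R hazard proportionality constant (women/men).
#' @param proportional are the hazards proportional?  When `FALSE` the
#'   women's curve cannot be co-plotted on the men's exposure axis.
#' @param pure_genetic_offset baseline failure probabilities `c(m, w)` for
#'   "purely genetic" disease (default `c(0, 0)`).
#' @return an object of class `response_curve_params`.
#' @export
fit_response_curves <- function(p_f_ms2, p_ms2, p_g, p_f_g,
                                sexratio1, sexratio2, C, R = 1,
                                proportional = TRUE,
                                pure_genetic_offset = c(0, 0)) {
  anchors <- timepoint2_anchors(p_f_ms2, p_ms2, p_g, p_f_g)
  ratios <- epoch_case_ratios(sexratio1, sexratio2)
  lim <- limiting_values(anchors[["zw2"]], anchors[["zm2"]],
                         ratios[["ratio_f"]], ratios[["ratio_m"]], C)
  lam <- threshold_difference(anchors[["zw2"]], anchors[["zm2"]],
                              lim$c, lim$d)
  lambda_m <- if (lam >= 0) 0 else -lam
  lambda_w <- if (lam >= 0) lam else 0
  structure(list(
    C = C, R = R, c = lim$c, d = lim$d,
    zw1 = lim$zw1, zw2 = anchors[["zw2"]],
    zm1 = lim$zm1, zm2 = anchors[["zm2"]],
    a1 = lambda_m + lim$a1, a1_app = lambda_w + lim$a1_app,
    lambda_m = lambda_m, lambda_w = lambda_w, lambda_diff = lam,
    ratio_f = ratios[["ratio_f"]], ratio_m = ratios[["ratio_m"]],
    proportional = proportional,
    pure_genetic_offset = pure_genetic_offset),
    class = "response_curve_params")
}

#' @export
print.response_curve_params <- function(x, ...) {
  cat("Exposure-response curve parameters\n")
  cat(sprintf("  C = %.3g, R = %.3g; plateaus c = %.4g (men), d = %.4g (women)\n",
              x$C, x$R, x$c, x$d))
  cat(sprintf("  anchors: Zm = (%.4g, %.4g), Zw = (%.4g, %.4g)\n",
              x$zm1, x$zm2, x$zw1, x$zw2))
  cat(sprintf("  thresholds: lambda_m = %.3g, lambda_w = %.3g (diff %.3g)\n",
              x$lambda_m, x$lambda_w, x$lambda_diff))
  invisible(x)
}

#' The packaged curve preset
#'
#' Mid-range parameter values (`P(G) = 0.044`, `P(F|G) = 0.25`, `C = 0.6`,
#' `R = 1`), anchors from the case-series `P(F|MS)_2 = 0.66` and epoch
#' ratios from the sex ratios 2.2 and 3.2.  Yields plateaus
#' `c = 0.035` and `d = 0.228`.
#'
#' @param ... overrides passed to [fit_response_curves()].
#' @return a `response_curve_params` object.
#' @export
fig_preset_curves <- function(...) {
  args <- list(p_f_ms2 = 0.66, p_ms2 = 0.003, p_g = 0.044, p_f_g = 0.25,
               sexratio1 = 2.2, sexratio2 = 3.2, C = 0.6, R = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(fit_response_curves, args)
}

#' Evaluate the response curves on an exposure grid
#'
#' Men: `c * (1 - exp(-(a - lambda_m)))` for `a >= lambda_m`, else 0.
#' Women (proportional hazards): `d * (1 - exp(-R * (a - lambda_w)))` on the
#' same axis; the apparent women's scale is divided by R for co-plotting,
#' valid only under proportionality — with `proportional = FALSE` the women's
#' curve is emitted on its own apparent axis and co-plotting is refused.
#' Any pure-genetic offset floors each curve at its baseline value.
#'
#' @param params a `response_curve_params` object.
#' @param a_max grid upper end (exposure units).
#' @param step grid step.
#' @return data.frame of class `curve_points` with columns `a`, `p_fail_m`,
#'   `p_fail_w` (the women's column is named `p_fail_w_app` and indexed by
#'   the apparent scale when co-plotting is refused).
#' @export
build_response_curves <- function(params, a_max = 6, step = 0.01) {
  stopifnot(inherits(params, "response_curve_params"))
  a <- seq(0, a_max, by = step)
  off <- params$pure_genetic_offset
  men <- pmax(off[1], params$c * (1 - exp(-(a - params$lambda_m))))
  men[a < params$lambda_m & off[1] == 0] <- 0
  if (!params$proportional) {
    women <- pmax(off[2], params$d * (1 - exp(-(a - 0))))
    out <- data.frame(a = a, p_fail_m = men, a_app = a, p_fail_w_app = women)
    attr(out, "co_plot") <- FALSE
    return(out)
  }
  women <- pmax(off[2], params$d * (1 - exp(-params$R * (a - params$lambda_w))))
  women[a < params$lambda_w & off[2] == 0] <- 0
  out <- data.frame(a = a, p_fail_m = men, p_fail_w = women)
  attr(out, "co_plot") <- TRUE
  class(out) <- c("curve_points", "data.frame")
  out
}

#' Recover (limit, threshold) of an exponential failure curve from two points
#'
#' Two observations `(a1, z1)` and `(a1 + delta, z2)` on
#' `z = L * (1 - exp(-(a - lambda)))` determine the curve uniquely:
#' `L = (z2 - z1 e^-delta) / (1 - e^-delta)`, then
#' `lambda = a1 + ln(1 - z1/L)`.
#'
#' @param a1 exposure coordinate of the first point.
#' @param z1,z2 failure probabilities at the two points, `0 < z1 < z2`.
#' @param delta spacing between the points (default one exposure unit).
#' @return `c(limit = L, threshold = lambda)`.
#' @export
fit_exponential_limit <- function(a1, z1, z2, delta = 1) {
  if (z2 <= z1 || z1 <= 0) stop("need 0 < z1 < z2", call. = FALSE)
  L <- (z2 - z1 * exp(-delta)) / (1 - exp(-delta))
  c(limit = L, threshold = a1 + log(1 - z1 / L))
}

#' Intersection of the two response curves
#'
#' Under R = 1 the curves `c (1 - e^-a)` and `d (1 - e^-(a - lambda)})`
#' cross once; the crossing height is the pure-genetic baseline at which the
#' threshold difference would vanish (both sexes would begin their
#' environmental response at the crossing).
#'
#' @param params a `response_curve_params` object (evaluated at R = 1).
#' @return `c(a = ..., z = ...)`, the crossing coordinate and height.
#' @export
curve_intersection <- function(params) {
  stopifnot(inherits(params, "response_curve_params"))
  lam <- params$lambda_diff
  y <- (params$d - params$c) / (params$d * exp(lam) - params$c)
  if (y <= 0 || y >= 1) stop("curves do not cross in the feasible region", call. = FALSE)
  a <- -log(y)
  c(a = a, z = params$c * (1 - y))
}

#' Compare curve plateaus with observed MZ concordance limits
#'
#' As the population exposure probability approaches 1, the adjusted MZ
#' recurrence approaches the raw MZ concordance, so the plateaus must
#' satisfy `c >= P(MS|M, MZ_MS)` and `d >= P(MS|F, MZ_MS)`.  Reports
#' deficits when the fitted plateaus fall short (the cue for the
#' reconciling constraint search).
#'
#' @param c,d fitted plateaus for men and women.
#' @param mz_by_sex named or ordered pair `c(F = ..., M = ...)` of MZ
#'   proband-wise concordance by sex.
#' @return a list with logical `consistent_m`, `consistent_f` and the
#'   deficits (observed minus plateau, positive when inconsistent).
#' @export
limit_consistency_check <- function(c, d, mz_by_sex) {
  mz_f <- if (!is.null(names(mz_by_sex))) mz_by_sex[["F"]] else mz_by_sex[1]
  mz_m <- if (!is.null(names(mz_by_sex))) mz_by_sex[["M"]] else mz_by_sex[2]
  list(consistent_m = c >= mz_m,
       consistent_f = d >= mz_f,
       deficit_m = mz_m - c,
       deficit_f = mz_f - d)
}
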