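# susceptibility_bounds: every bound on the size and composition of the
# genetically susceptible subset (G) — upper-branch bounds from P(G) =
# P(MS)/P(MS|G), the extreme sibling-floored bound, the sex-partition chain,
# the lower-branch constraint search, the HLA enrichment decomposition, and
# the multi-region batch.

#' Upper-branch bounds on the susceptible fraction P(G)
#'
#' On the upper branch the mean penetrance satisfies `x'/2 < x <= x'`, so
#' `P(G) = P(MS)/x` falls in `[p_ms/x', 2*p_ms/x']`.  The interval endpoints
#' always differ by exactly a factor of two.
#'
#' @param p_ms lifetime disease probability.
#' @param x_prime adjusted MZ recurrence `x'`.
#' @return a [probability_interval]; the upper end is clipped at 1 (with a
#'   warning) when `p_ms >= x'/2`.
#' @examples
#' pg_upper_solution(0.003, 0.134)  # [0.0224, 0.0448]
#' @export
pg_upper_solution <- function(p_ms, x_prime) {
  assert_probability(p_ms, "p_ms", open_lower = TRUE)
  assert_probability(x_prime, "x_prime", open_lower = TRUE)
  if (p_ms >= x_prime) {
    stop("'p_ms' must be below the adjusted recurrence x'", call. = FALSE)
  }
  hi <- p_ms / (x_prime / 2)
  if (hi > 1) {
    warning("upper P(G) bound exceeds 1; clipped", call. = FALSE)
    hi <- 1
  }
  probability_interval(p_ms / x_prime, hi)
}

#' Extreme bound on P(G) with x' floored at the sibling recurrence
#'
#' The adjusted recurrence cannot fall below the non-twin sibling recurrence
#' (siblings share half their genes and none of the twin environment), so
#' even the most conservative adjustment leaves `P(G) < p_ms / (sib/2)`.
#'
#' @param p_ms lifetime disease probability.
#' @param sib sibling recurrence risk (> 0).
#' @return the bound, clipped at 1.
#' @examples
#' pg_extreme_bound(0.003, 0.029)  # 0.207
#' @export
pg_extreme_bound <- function(p_ms, sib) {
  assert_probability(p_ms, "p_ms", open_lower = TRUE)
  assert_probability(sib, "sib", open_lower = TRUE)
  min(1, p_ms / (sib / 2))
}

#' Sex-partition bound chain on P(G|F), P(G|M) and P(F|G)
#'
#' From `P(MS,G|F) = P(F|MS) P(MS) / P(F)` (and the male analogue), dividing
#' by the adjusted per-sex penetrance ranges yields intervals for P(G|F) and
#' P(G|M).  The odds `P(F|G)/P(M|G)` at the extreme favouring women (female
#' numerator at its maximum, male at its minimum) convert to the maximum
#' proportion of women among susceptibles via `odds/(1+odds)`.
#'
#' @param p_f_ms proportion of cases who are women.
#' @param p_ms lifetime disease probability.
#' @param p_f proportion of women in the population.
#' @param x1_range adjusted female penetrance range `c(lo, hi)`.
#' @param x2_range adjusted male penetrance range `c(lo, hi)`; must lie
#'   entirely below `x1_range`.
#' @param mode `"full"` or `"paper"`; paper mode rounds the per-sex case
#'   probabilities and interval endpoints to 3 decimals as printed before
#'   continuing (e.g. 0.66*0.003/0.5 -> 0.004).
#' @return an object of class `bounds_result` with the two conditional
#'   susceptibility intervals, the extreme odds, and the maximum `P(F|G)`.
#' @examples
#' gender_bound_chain(0.66, 0.003, 0.5, c(0.093, 0.187), c(0.017, 0.034))
#' @export
gender_bound_chain <- function(p_f_ms, p_ms, p_f, x1_range, x2_range,
                               mode = c("full", "paper")) {
  mode <- match.arg(mode)
  assert_probability(p_f_ms, "p_f_ms", open_lower = TRUE, open_upper = TRUE)
  assert_probability(p_ms, "p_ms", open_lower = TRUE)
  assert_probability(p_f, "p_f", open_lower = TRUE, open_upper = TRUE)
  x1_range <- sort(x1_range); x2_range <- sort(x2_range)
  if (any(c(x1_range, x2_range) <= 0)) {
    stop("penetrance range endpoints must be positive", call. = FALSE)
  }
  if (x2_range[2] >= x1_range[1]) {
    stop("'x2_range' must lie entirely below 'x1_range'", call. = FALSE)
  }
  num_f <- mode_round(p_f_ms * p_ms / p_f, 3, mode)
  num_m <- mode_round((1 - p_f_ms) * p_ms / (1 - p_f), 3, mode)
  p_g_f <- mode_round(c(num_f / x1_range[2], num_f / x1_range[1]), 3, mode)
  p_g_m <- mode_round(c(num_m / x2_range[2], num_m / x2_range[1]), 3, mode)
  odds_max <- mode_round(p_g_f[2] / p_g_m[1], 3, mode)
  p_m_g_min <- mode_round(1 / (1 + odds_max), 3, mode)
  p_f_g_max <- odds_max * p_m_g_min
  structure(list(
    p_g_given_f = probability_interval(p_g_f[1], p_g_f[2]),
    p_g_given_m = probability_interval(p_g_m[1], p_g_m[2]),
    odds_f_over_m_max = odds_max,
    p_f_given_g_max = p_f_g_max,
    method = "gender_bound_chain",
    mode = mode,
    assumptions = c(
      "P(F) = P(M) = 0.5 in the population",
      "per-sex penetrance ranges from shared-environment-adjusted MZ concordance",
      "extreme taken at max female / min male conditional susceptibility")),
    class = "bounds_result")
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf("Susceptibility bounds (%s)\n", x$method))
  if (!is.null(x$p_g)) cat("  P(G)    ", format(x$p_g), "\n")
  if (!is.null(x$p_g1)) cat("  P(G1)   ", format(x$p_g1), "\n")
  if (!is.null(x$p_g_given_f)) cat("  P(G|F)  ", format(x$p_g_given_f), "\n")
  if (!is.null(x$p_g_given_m)) cat("  P(G|M)  ", format(x$p_g_given_m), "\n")
  if (!is.null(x$p_f_given_g_max)) {
    cat(sprintf("  max P(F|G) = %.3f\n", x$p_f_given_g_max))
  }
  invisible(x)
}

#' Lower-branch constraint search over partitioned penetrance models
#'
#' Enumerates two-subset penetrance models of the susceptible subset on a
#' grid of `(p, x1, x2)` — subset share and mean penetrances — and keeps the
#' combinations consistent with every observed quantity:
#' \enumerate{
#'   \item lower branch: `x = p x1 + (1-p) x2 < x'/2`;
#'   \item each subset upper-conforming: `x1'/2 < x1 <= x1'` and
#'     `x2'/2 < x2 <= x2'` (enforced by the grid ranges);
#'   \item the case-weighted mixture reproduces `x'`
#'     (`p a x1' + (1-p) b x2' = x'`) within tolerance;
#'   \item for the sex partition, G1-case accounting reproduces the
#'     proportion of cases who are women (`p x1 / x = P(F|MS)`) within
#'     tolerance;
#'   \item `P(G)` reproduces `P(MS)` through Eq 1A: since
#'     `P(MS) = P(G) x`, the feasible `P(G)` values at each grid point are
#'     the `p_g` grid points inside `p_ms (1 ± tol) / x`.
#' }
#' The published closed-form branch inequality
#' `p > (2 - b^2 s)/(a^2 r - b^2 s)` is evaluated numerically at every
#' feasible point as a cross-check rather than assumed.
#'
#' @param observed named list with `x_prime`, `x1_prime`, `x2_prime`,
#'   `p_ms`, `p_f_ms`.
#' @param grids named list of per-axis resolutions
#'   (`n_p`, `n_x1`, `n_x2`, `n_pg`), default 100 each; the `p_g` axis is
#'   log-spaced on \[0.001, 1\] (penetrances below 0.05 vary over orders of
#'   magnitude, so log spacing keeps relative resolution even).
#' @param tol relative tolerance for matching observed values (default 0.10;
#'   the observations are rounded summaries, not exact).
#' @param sex_partition apply constraint (iv)? `TRUE` for the package's
#'   default use (the partition is by sex).
#' @return a list of class `lower_search_result` with elements `p_g`
#'   (feasible envelope, [probability_interval]), `p_g1` (envelope),
#'   `feasible` (data.frame of feasible grid points with derived ratios and
#'   the branch-inequality flag), and `diagnostics` (points surviving each
#'   successive constraint).
#' @export
search_lower_solution <- function(observed,
                                  grids = list(n_p = 100, n_x1 = 100,
                                               n_x2 = 100, n_pg = 100),
                                  tol = 0.10,
                                  sex_partition = TRUE) {
  xp <- observed$x_prime; x1p <- observed$x1_prime; x2p <- observed$x2_prime
  p_ms <- observed$p_ms; p_f_ms <- observed$p_f_ms
  stopifnot(xp > 0, x1p > 0, x2p > 0, p_ms > 0)
  n_p <- grids$n_p %||% 100; n_x1 <- grids$n_x1 %||% 100
  n_x2 <- grids$n_x2 %||% 100; n_pg <- grids$n_pg %||% 100

  # Axis grids: p over (0,1) open; x1, x2 over their upper-conforming ranges.
  p_axis <- seq(1 / (n_p + 1), n_p / (n_p + 1), length.out = n_p)
  x1_axis <- seq(x1p / 2, x1p, length.out = n_x1 + 1)[-1]
  x2_axis <- seq(x2p / 2, x2p, length.out = n_x2 + 1)[-1]
  pg_axis <- exp(seq(log(0.001), log(1), length.out = n_pg))

  g <- expand.grid(p = p_axis, x1 = x1_axis, x2 = x2_axis,
                   KEEP.OUT.ATTRS = FALSE)
  n0 <- nrow(g)
  x <- g$p * g$x1 + (1 - g$p) * g$x2

  diagnostics <- c(grid = n0)
  keep <- x < xp / 2                              # (i) lower branch
  diagnostics["lower_branch"] <- sum(keep)
  mix <- (g$p * g$x1 * x1p + (1 - g$p) * g$x2 * x2p) / x
  keep <- keep & abs(mix - xp) <= tol * xp        # (iii) Eq 1C
  diagnostics["eq1c_match"] <- sum(keep)
  if (sex_partition) {
    keep <- keep & abs(g$p * g$x1 / x - p_f_ms) <= tol * p_f_ms  # (iv)
    diagnostics["sex_accounting"] <- sum(keep)
  }

  if (!any(keep)) {
    last <- names(diagnostics)[max(which(diagnostics > 0))]
    return(structure(list(
      p_g = NULL, p_g1 = NULL,
      feasible = data.frame(),
      diagnostics = diagnostics,
      message = sprintf("empty feasible set; last non-empty stage: %s", last)),
      class = "lower_search_result"))
  }

  f <- g[keep, , drop = FALSE]
  fx <- x[keep]
  # (v) Eq 1A: p_g band per point, intersected with the p_g grid.
  pg_lo <- pmax(p_ms * (1 - tol) / fx, min(pg_axis))
  pg_hi <- pmin(p_ms * (1 + tol) / fx, 1)
  has_pg <- vapply(seq_along(pg_lo), function(i) {
    any(pg_axis >= pg_lo[i] & pg_axis <= pg_hi[i])
  }, logical(1))
  diagnostics["pg_grid"] <- sum(has_pg)
  f <- f[has_pg, , drop = FALSE]
  fx <- fx[has_pg]; pg_lo <- pg_lo[has_pg]; pg_hi <- pg_hi[has_pg]
  if (!nrow(f)) {
    return(structure(list(
      p_g = NULL, p_g1 = NULL, feasible = data.frame(),
      diagnostics = diagnostics,
      message = "empty feasible set; p_g grid pruned all points"),
      class = "lower_search_result"))
  }

  pg_point <- vapply(seq_along(pg_lo), function(i) {
    cand <- pg_axis[pg_axis >= pg_lo[i] & pg_axis <= pg_hi[i]]
    cand[which.min(abs(cand - p_ms / fx[i]))]
  }, numeric(1))

  a <- f$x1 / fx; b <- f$x2 / fx
  r <- x1p / f$x1; s <- x2p / f$x2
  branch_threshold <- (2 - b^2 * s) / (a^2 * r - b^2 * s)
  feasible <- data.frame(
    p = f$p, x1 = f$x1, x2 = f$x2, x = fx,
    p_g = pg_point, p_g1 = f$p * pg_point,
    a = a, b = b, r = r, s = s,
    x1_prime = x1p, x2_prime = x2p,
    branch_inequality_ok = f$p > branch_threshold)
  structure(list(
    p_g = probability_interval(min(pg_lo), max(pg_hi)),
    p_g1 = probability_interval(min(f$p * pg_lo), max(f$p * pg_hi)),
    feasible = feasible,
    diagnostics = diagnostics,
    message = sprintf("%d feasible grid points", nrow(feasible))),
    class = "lower_search_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lower_search_result <- function(x, ...) {
  cat("Lower-branch constraint search\n")
  cat("  ", x$message, "\n")
  if (!is.null(x$p_g)) {
    cat("  P(G) envelope  ", format(x$p_g), "\n")
    cat("  P(G1) envelope ", format(x$p_g1), "\n")
  }
  invisible(x)
}

#' Susceptibility enrichment ratio for the HLA partition
#'
#' The H+ haplotype is enriched in cases (`P(H+|MS)` vs `P(H+)`).  Writing
#' the enrichment as a product of a susceptibility mechanism
#' (`P(G|H+)/P(G|H-)`) and a penetrance mechanism
#' (`P(MS|G,H+)/P(MS|G,H-)`), the case odds satisfy
#' `odds(H+|MS) = odds(H+) * ratio_susceptibility * ratio_penetrance`.
#' Under the pure-susceptibility mechanism (`penetrance_ratio = 1`, the
#' package default, matching the available epidemiology) the susceptibility
#' ratio is the plain odds ratio.
#'
#' @param p_hplus carrier probability in the population, in (0, 1).
#' @param p_hplus_ms carrier probability among cases, in (0, 1).
#' @param penetrance_ratio assumed `P(MS|G,H+)/P(MS|G,H-)` (mixing parameter
#'   between the two mechanisms); 1 attributes all enrichment to
#'   susceptibility.
#' @return the implied `P(G|H+)/P(G|H-)`.
#' @examples
#' hla_enrichment_ratio(0.23, 0.50)  # 3.348
#' @export
hla_enrichment_ratio <- function(p_hplus, p_hplus_ms, penetrance_ratio = 1) {
  assert_probability(p_hplus, "p_hplus", open_lower = TRUE, open_upper = TRUE)
  assert_probability(p_hplus_ms, "p_hplus_ms", open_lower = TRUE, open_upper = TRUE)
  if (penetrance_ratio <= 0) stop("'penetrance_ratio' must be positive", call. = FALSE)
  odds_cases <- p_hplus_ms / (1 - p_hplus_ms)
  odds_pop <- p_hplus / (1 - p_hplus)
  (odds_cases / odds_pop) / penetrance_ratio
}

#' Upper bound on the susceptible fraction of H+ carriers
#'
#' Even if every susceptible individual were an H+ carrier, at most
#' `P(G)_max / P(H+)` of carriers could be susceptible.
#'
#' @param p_g_max upper bound on the susceptible fraction of the population.
#' @param p_hplus carrier probability (> 0).
#' @return the bound, clipped at 1 with a warning.
#' @examples
#' hla_susceptible_fraction(0.073, 0.23)  # 0.317
#' @export
hla_susceptible_fraction <- function(p_g_max, p_hplus) {
  assert_probability(p_g_max, "p_g_max")
  assert_probability(p_hplus, "p_hplus", open_lower = TRUE)
  v <- p_g_max / p_hplus
  if (v > 1) {
    warning("bound exceeds 1; clipped", call. = FALSE)
    v <- 1
  }
  v
}

#' Batch upper-branch P(G) intervals for multiple regions
#'
#' Applies the standard recipe row-wise: `P(MS) = 2 * prevalence`, the MZ
#' concordance adjusted by the Canadian sibling/DZ ratio
#' (`x' = (sib/dz) * concordance`), then [pg_upper_solution()].  The lower
#' interval end uses the low end of the prevalence range against `x'`; the
#' upper end uses the high end against `x'/2`.
#'
#' @param rows data.frame with columns `region`, `prev_lo_per_100k`,
#'   `prev_hi_per_100k`, `mz_probandwise`.  Rows with missing fields are
#'   skipped with a warning.
#' @param sib,dz Canadian sibling and DZ recurrence used for the adjustment.
#' @return data.frame with `region`, `x_prime`, `p_g_lo`, `p_g_hi`.
#' @export
table4_batch <- function(rows, sib = 0.029, dz = 0.054) {
  needed <- c("region", "prev_lo_per_100k", "prev_hi_per_100k", "mz_probandwise")
  if (!all(needed %in% names(rows))) {
    stop("'rows' must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (anyNA(r[needed])) {
      warning(sprintf("row %d (%s): missing fields, skipped", i,
                      as.character(r$region)), call. = FALSE)
      return(NULL)
    }
    x_prime <- (sib / dz) * r$mz_probandwise
    p_ms_lo <- 2 * r$prev_lo_per_100k / 1e5
    p_ms_hi <- 2 * r$prev_hi_per_100k / 1e5
    lo <- pg_upper_solution(p_ms_lo, x_prime)$lo
    hi <- pg_upper_solution(p_ms_hi, x_prime)$hi
    data.frame(region = as.character(r$region), x_prime = x_prime,
               p_g_lo = lo, p_g_hi = hi)
  })
  do.call(rbind, out)
}

#' Packaged regional prevalence/concordance rows
#'
#' @return the packaged data.frame of per-region MS prevalence ranges
#'   (per 100,000) and MZ proband-wise concordance, for [table4_batch()].
#' @export
packaged_regional_rows <- function() {
  path <- system.file("extdata", "regional_prevalence.csv",
                      package = "mspenetrance", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
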