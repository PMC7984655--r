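# penetrance_model: the size-biased penetrance identity, the quadratic in x,
# variance bounds, Upper/Lower solution classification and partition algebra.
#
# Central identity: if {X} is the multiset of penetrance values in the
# susceptible subset (G), the recurrence observed through an affected proband
# is size-biased: x' = E[X^2]/E[X] = x + Var(X)/x.  Rearranged it is a
# quadratic x^2 - x'x + Var(X) = 0, whose two roots split the feasible mean
# penetrance into an "upper" (low-variance) and a "lower" (high-variance,
# asymmetric) branch.

#' Size-biased (case-weighted) recurrence of a penetrance multiset
#'
#' The expected penetrance of the genotype of a randomly chosen case's
#' co-twin: `sum(x_i^2) / sum(x_i)`.  Equal, exactly, to
#' `mean(x) + var(x)/mean(x)` (population variance) — the identity is
#' algebraic, not asymptotic.
#'
#' @param penetrances finite multiset of penetrance values, all in (0, 1\];
#'   zero-penetrance genotypes are by definition outside the susceptible
#'   subset and are rejected.
#' @return the size-biased recurrence `x'`.
#' @examples
#' size_biased_recurrence(c(0.05, 0.25))  # 0.21667
#' @export
size_biased_recurrence <- function(penetrances) {
  if (!length(penetrances)) stop("empty penetrance multiset", call. = FALSE)
  if (any(!is.finite(penetrances)) || any(penetrances <= 0) ||
      any(penetrances > 1)) {
    stop("all penetrances must lie in (0, 1]; zero-penetrance genotypes are outside (G)",
         call. = FALSE)
  }
  sum(penetrances^2) / sum(penetrances)
}

#' Solve the penetrance quadratic x^2 - x'x + variance = 0
#'
#' @param x_prime adjusted recurrence `x'`, in (0, 1\].
#' @param variance penetrance variance; feasible only for
#'   `0 <= variance <= (x_prime/2)^2` (the maximum variance of any
#'   distribution supported on \[0, x'\]).
#' @return named numeric of both roots, `c(lower = ..., upper = ...)`;
#'   they sum to `x_prime` and multiply to `variance`.
#' @export
solve_penetrance_quadratic <- function(x_prime, variance) {
  assert_probability(x_prime, "x_prime", open_lower = TRUE)
  if (!is.finite(variance) || variance < 0) {
    stop("'variance' must be nonnegative", call. = FALSE)
  }
  cap <- (x_prime / 2)^2
  if (variance > cap + 1e-15) {
    stop(sprintf(
      "infeasible variance %.6g: exceeds the maximum (x'/2)^2 = %.6g attainable on [0, x']",
      variance, cap), call. = FALSE)
  }
  disc <- max(x_prime^2 - 4 * variance, 0)
  half <- sqrt(disc) / 2
  c(lower = x_prime / 2 - half, upper = x_prime / 2 + half)
}

#' Classify the solution branch of a (x, x') pair
#'
#' @param x expected penetrance of the susceptible subset, `0 < x <= x_prime`.
#' @param x_prime adjusted recurrence.
#' @return `"upper"` if `x > x'/2`, `"lower"` if `x < x'/2`, `"degenerate"`
#'   at exact equality.
#' @export
classify_branch <- function(x, x_prime) {
  assert_probability(x, "x", open_lower = TRUE)
  assert_probability(x_prime, "x_prime", open_lower = TRUE)
  if (x > x_prime) {
    stop("x > x' is inconsistent with the size-biased identity", call. = FALSE)
  }
  if (x > x_prime / 2) "upper" else if (x < x_prime / 2) "lower" else "degenerate"
}

#' Penetrance state (x, x', variance, branch)
#'
#' @param x expected penetrance of the susceptible subset.
#' @param x_prime adjusted (size-biased) recurrence.
#' @return an object of class `penetrance_state` with the implied variance
#'   `x * (x' - x)` and branch label.
#' @export
penetrance_state <- function(x, x_prime) {
  branch <- classify_branch(x, x_prime)
  structure(list(x = x, x_prime = x_prime,
                 variance = x * (x_prime - x), branch = branch),
            class = "penetrance_state")
}

#' @export
print.penetrance_state <- function(x, ...) {
  cat(sprintf("Penetrance state: x = %.4g, x' = %.4g, var = %.4g (%s branch)\n",
              x$x, x$x_prime, x$variance, x$branch))
  invisible(x)
}

#' Minimum mean penetrance compatible with a unimodal distribution
#'
#' The maximum variance of a unimodal distribution on \[a, b\] is
#' `(b-a)^2/9`; substituting that cap into the upper quadratic root for a
#' distribution on (0, x'\] gives `x >= x' * (1/2 + sqrt(5)/6)`, i.e. about
#' `0.8727 * x'` (displayed as 0.87).  Whether the penetrance multiset
#' strictly attains the cap is treated as a stated constraint, not proven.
#'
#' @param x_prime adjusted recurrence, in (0, 1\].
#' @return the lower bound on `x`.
#' @export
unimodal_lower_bound <- function(x_prime) {
  assert_probability(x_prime, "x_prime", open_lower = TRUE)
  x_prime * (0.5 + sqrt(5) / 6)
}

#' Check the two-subset partition identities
#'
#' For a split of the susceptible subset into a high-penetrance part G1
#' (fraction `p` of G, penetrance `x1`, size-biased recurrence `x1'`) and a
#' low-penetrance part G2, three identities must hold:
#' * `P(MS) = P(G1) x1 + P(G2) x2`,
#' * `x  = p x1 + (1-p) x2`,
#' * `x' = p a x1' + (1-p) b x2'` with `a = x1/x`, `b = x2/x`
#'   (the case-weighted mixture of the subset recurrences).
#'
#' @param p fraction of G in G1, in (0, 1).
#' @param x1,x2 subset mean penetrances, `x1 > x2`.
#' @param x1_prime,x2_prime subset size-biased recurrences.
#' @param p_g probability of the susceptible subset.
#' @param p_ms observed disease probability (checked against Eq 1A).
#' @param x,x_prime whole-subset mean and size-biased recurrence (checked
#'   against Eqs 1B/1C); computed from the partition when omitted.
#' @param tol residual tolerance for the report flags.
#' @return an object of class `partition_report` with the residuals of the
#'   three identities, the implied ordering flag `x1 > x > x2`, and the
#'   derived ratios (a, b, r, s, v, w, t).
#' @export
partition_consistency <- function(p, x1, x2, x1_prime, x2_prime,
                                  p_g, p_ms,
                                  x = NULL, x_prime = NULL, tol = 1e-9) {
  assert_probability(p, "p", open_lower = TRUE, open_upper = TRUE)
  if (x1 <= x2) stop("'x1' must exceed 'x2' for a valid partition", call. = FALSE)
  x_mix <- p * x1 + (1 - p) * x2
  if (is.null(x)) x <- x_mix
  a <- x1 / x; b <- x2 / x
  xp_mix <- p * a * x1_prime + (1 - p) * b * x2_prime
  if (is.null(x_prime)) x_prime <- xp_mix
  p_g1 <- p * p_g; p_g2 <- (1 - p) * p_g
  res <- c(eq1a = p_g1 * x1 + p_g2 * x2 - p_ms,
           eq1b = x_mix - x,
           eq1c = xp_mix - x_prime)
  structure(list(
    residuals = res,
    within_tol = abs(res) < tol,
    ordering_ok = x1 > x && x > x2,
    subset_upper_conforming = c(
      g1 = x1 > x1_prime / 2 && x1 <= x1_prime,
      g2 = x2 > x2_prime / 2 && x2 <= x2_prime),
    ratios = c(a = a, b = b,
               r = x1_prime / x1, s = x2_prime / x2,
               v = x1_prime / x_prime, w = x2_prime / x_prime,
               t = (p_g1 * x1) / (p_g2 * x2)),
    x = x, x_prime = x_prime, tol = tol),
    class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat("Partition consistency report\n")
  for (nm in names(x$residuals)) {
    cat(sprintf("  %s residual %.3g (%s)\n", nm, x$residuals[[nm]],
                if (x$within_tol[[nm]]) "ok" else "VIOLATED"))
  }
  cat(sprintf("  ordering x1 > x > x2: %s\n", x$ordering_ok))
  invisible(x)
}

#' Worked bounds example: breast cancer with a rare high-risk subset
#'
#' A population where a rare high-penetrance subset G1 (mutation carriers,
#' probability `p_g1`, uniform penetrance `x1`) coexists with a larger
#' lower-penetrance subset G2 (uniform penetrance `x2 <= x1`).  Sweeping the
#' feasible size of G2 gives the attainable range of the total susceptible
#' fraction P(G), of the size-biased recurrence x', and of the ratio x/x'.
#' With lifetime risk 0.125, carrier frequency 0.01 and carrier penetrance
#' 0.7, the feasible band is P(G) in \[0.179, 1\], x' in \[0.152, 0.7\] and
#' x/x' >= 0.824.
#'
#' @param p_bc lifetime disease probability.
#' @param p_g1 probability of the high-penetrance subset; `p_g1 * x1 < p_bc`.
#' @param x1 penetrance of the high-penetrance subset.
#' @param n_grid sweep resolution over the feasible P(G) range.
#' @return a list with `p_g_min`, the swept `grid` (data.frame of p_g, x2,
#'   x, x_prime, ratio), `x_prime_range` and `min_ratio`.
#' @export
worked_example_breast_cancer <- function(p_bc, p_g1, x1, n_grid = 401) {
  assert_probability(p_bc, "p_bc", open_lower = TRUE)
  assert_probability(x1, "x1", open_lower = TRUE)
  if (p_g1 * x1 >= p_bc) {
    stop("infeasible: the high-risk subset alone exceeds the disease probability",
         call. = FALSE)
  }
  residual <- p_bc - p_g1 * x1          # cases that G2 must supply
  p_g2_min <- residual / x1             # x2 at its ceiling x1
  p_g_min <- p_g1 + p_g2_min
  p_g <- seq(p_g_min, 1, length.out = n_grid)
  p_g2 <- p_g - p_g1
  x2 <- residual / p_g2
  x <- p_bc / p_g
  ex2 <- (p_g1 * x1^2 + p_g2 * x2^2) / p_g
  x_prime <- ex2 / x
  ratio <- x / x_prime
  list(p_g_min = p_g_min,
       grid = data.frame(p_g = p_g, x2 = x2, x = x,
                         x_prime = x_prime, ratio = ratio),
       x_prime_range = range(x_prime),
       min_ratio = min(ratio))
}
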