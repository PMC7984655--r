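# synthetic_population: forward simulator of populations and twin/sibling
# families with the statistical structure the estimators assume — a rare
# susceptible subset carrying heterogeneous penetrances, a multiplicative
# early-environment factor shared by co-twins, sex-dependent penetrance and
# a two-epoch exposure probability.  Every estimator in the package is
# validated by recovering planted parameters from these cohorts.

#' Penetrance mixture component
#'
#' @param weight mixture weight.
#' @param type `"point"`, `"uniform"` or `"beta"`.
#' @param par component parameter: the point mass value, `c(lo, hi)` for
#'   uniform, or `c(shape1, shape2)` for beta.  Support must lie in (0, 1\];
#'   a point mass at 0 is rejected (zero-penetrance genotypes are outside
#'   the susceptible subset by definition).
#' @return a list describing the component.
#' @export
mixture_component <- function(weight, type = c("point", "uniform", "beta"), par) {
  type <- match.arg(type)
  if (weight < 0) stop("'weight' must be nonnegative", call. = FALSE)
  if (type == "point" && (par <= 0 || par > 1)) {
    stop("point mass must lie in (0, 1]", call. = FALSE)
  }
  if (type == "uniform" && (par[1] <= 0 || par[2] > 1 || par[1] >= par[2])) {
    stop("uniform support must be within (0, 1]", call. = FALSE)
  }
  if (type == "beta" && any(par <= 0)) {
    stop("beta shapes must be positive", call. = FALSE)
  }
  list(weight = weight, type = type, par = par)
}

.mixture_check <- function(mixture) {
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  invisible(mixture)
}

.component_moments <- function(comp) {
  p <- comp$par
  switch(comp$type,
    point = c(m1 = p, m2 = p^2),
    uniform = c(m1 = (p[1] + p[2]) / 2,
                m2 = (p[1]^2 + p[1] * p[2] + p[2]^2) / 3),
    beta = c(m1 = p[1] / (p[1] + p[2]),
             m2 = p[1] * (p[1] + 1) / ((p[1] + p[2]) * (p[1] + p[2] + 1))))
}

#' First two moments of a penetrance mixture
#'
#' @param mixture list of [mixture_component()]s.
#' @return `c(mean = ..., m2 = ..., var = ..., size_biased = m2/mean)`.
#' @export
mixture_moments <- function(mixture) {
  .mixture_check(mixture)
  m <- vapply(mixture, .component_moments, numeric(2))
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  m1 <- sum(w * m["m1", ]); m2 <- sum(w * m["m2", ])
  c(mean = m1, m2 = m2, var = m2 - m1^2, size_biased = m2 / m1)
}

.draw_mixture <- function(mixture, n) {
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_along(mixture)) {
    idx <- comp == k
    if (!any(idx)) next
    p <- mixture[[k]]$par
    out[idx] <- switch(mixture[[k]]$type,
      point = p,
      uniform = stats::runif(sum(idx), p[1], p[2]),
      beta = stats::rbeta(sum(idx), p[1], p[2]))
  }
  out
}

#' Cohort simulation specification
#'
#' @param n_individuals cohort size.
#' @param p_g probability of genetic susceptibility.
#' @param penetrance_mixture list of [mixture_component()]s describing the
#'   penetrance distribution inside the susceptible subset.
#' @param p_f_g proportion of women among susceptibles.
#' @param sex_penetrance_ratio multiplier applied to female penetrance
#'   (capped at 1); 1 means the mixture applies to both sexes.
#' @param shared_e1_factor multiplicative risk factor (>= 1) applied jointly
#'   to both co-twins, modelling the shared intrauterine/early post-natal
#'   exposure; does not apply to non-twin siblings.
#' @param sib_relatedness blend weight gamma in \[0, 1\]: a co-sibling's
#'   penetrance is `gamma * proband + (1 - gamma) * fresh draw`.
#' @param exposure_probability_by_epoch pair `(P(E)_1, P(E)_2)`.
#' @param seed integer seed; all stochastic draws in the simulator flow from
#'   this single generator.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 1e5,
                        p_g = 0.044,
                        penetrance_mixture = list(mixture_component(1, "point", 0.1)),
                        p_f_g = 0.25,
                        sex_penetrance_ratio = 1,
                        shared_e1_factor = 1,
                        sib_relatedness = 0.5,
                        exposure_probability_by_epoch = c(1, 1),
                        seed = 1L) {
  assert_probability(p_g, "p_g")
  assert_probability(p_f_g, "p_f_g")
  assert_probability(exposure_probability_by_epoch, "exposure_probability_by_epoch")
  if (shared_e1_factor < 1) stop("'shared_e1_factor' must be >= 1", call. = FALSE)
  if (sib_relatedness < 0 || sib_relatedness > 1) {
    stop("'sib_relatedness' must be in [0, 1]", call. = FALSE)
  }
  .mixture_check(penetrance_mixture)
  structure(list(n_individuals = n_individuals, p_g = p_g,
                 penetrance_mixture = penetrance_mixture, p_f_g = p_f_g,
                 sex_penetrance_ratio = sex_penetrance_ratio,
                 shared_e1_factor = shared_e1_factor,
                 sib_relatedness = sib_relatedness,
                 exposure_probability_by_epoch = exposure_probability_by_epoch,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate an individual-level cohort
#'
#' Each individual carries a latent susceptibility flag (probability
#' `p_g`), a sex (women make up `p_f_g` of susceptibles and the complement
#' is balanced so the population is half women), a latent penetrance (0
#' outside the susceptible subset; a mixture draw inside, scaled by the sex
#' ratio multiplier for women), an epoch exposure indicator, and a disease
#' status.  Disease requires susceptibility AND exposure AND the penetrance
#' Bernoulli — individuals outside the susceptible subset are never cases.
#'
#' @param spec a [cohort_spec()].
#' @param epoch which exposure epoch to simulate (1 or 2; default 2).
#' @return a data.frame of class `synthetic_cohort` with columns `id`,
#'   `susceptible`, `sex`, `penetrance`, `exposed`, `affected`; the spec is
#'   attached as attribute `"spec"`.
#' @export
simulate_cohort <- function(spec, epoch = 2) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  susceptible <- stats::runif(n) < spec$p_g
  n_s <- sum(susceptible)
  sex <- character(n)
  sex[susceptible] <- ifelse(stats::runif(n_s) < spec$p_f_g, "F", "M")
  # balance the complement so the whole population is half women
  p_f_rest <- if (spec$p_g < 1) {
    min(1, max(0, (0.5 - spec$p_g * spec$p_f_g) / (1 - spec$p_g)))
  } else 0.5
  sex[!susceptible] <- ifelse(stats::runif(n - n_s) < p_f_rest, "F", "M")
  penetrance <- numeric(n)
  if (n_s > 0) {
    base <- .draw_mixture(spec$penetrance_mixture, n_s)
    fem <- sex[susceptible] == "F"
    base[fem] <- pmin(1, base[fem] * spec$sex_penetrance_ratio)
    penetrance[susceptible] <- base
  }
  p_e <- spec$exposure_probability_by_epoch[epoch]
  exposed <- stats::runif(n) < p_e
  affected <- susceptible & exposed & (stats::runif(n) < penetrance)
  out <- data.frame(id = seq_len(n), susceptible = susceptible, sex = sex,
                    penetrance = penetrance, exposed = exposed,
                    affected = affected)
  attr(out, "spec") <- spec
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Simulate an ascertained twin/sibling study
#'
#' Pairs are built around a susceptible proband genotype.  MZ co-twins carry
#' the identical latent penetrance; DZ co-twins and non-twin siblings draw
#' theirs from the relatedness blend
#' `gamma * proband + (1 - gamma) * fresh`.  The shared early-environment
#' factor multiplies the penetrance of both members for MZ and DZ pairs
#' (capped at 1) but not for non-twin siblings — so the DZ/sibling
#' concordance ratio recovers the factor, and the sibling/DZ-adjusted MZ
#' concordance recovers the factor-free value.  Pairs with at least one
#' affected member are ascertained; concordant pairs are independently
#' re-ascertained through the second member with probability
#' `p_double_ascertainment`.
#'
#' @param spec a [cohort_spec()].
#' @param n_pairs_per_type named counts `c(mz = ..., dz = ..., sib = ...)`.
#' @param p_double_ascertainment probability that a concordant pair is
#'   ascertained twice (default 1, the fully double-ascertained design).
#' @return a named list of [twin_table()]s (`mz`, `dz`, `sib`).
#' @export
simulate_twin_study <- function(spec,
                                n_pairs_per_type = c(mz = 1e4, dz = 1e4, sib = 1e4),
                                p_double_ascertainment = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p_e <- spec$exposure_probability_by_epoch[2]
  one_type <- function(n, identical_pen, e1_factor, label) {
    x1 <- .draw_mixture(spec$penetrance_mixture, n)
    x2 <- if (identical_pen) x1 else {
      spec$sib_relatedness * x1 +
        (1 - spec$sib_relatedness) * .draw_mixture(spec$penetrance_mixture, n)
    }
    r1 <- pmin(1, e1_factor * x1) * p_e
    r2 <- pmin(1, e1_factor * x2) * p_e
    a1 <- stats::runif(n) < r1
    a2 <- stats::runif(n) < r2
    conc <- sum(a1 & a2)
    disc <- sum(xor(a1, a2))
    dbl <- stats::rbinom(1, conc, p_double_ascertainment)
    twin_table(conc, disc, doubly_ascertained = dbl,
               stratum = "simulated", label = label)
  }
  list(mz = one_type(n_pairs_per_type[["mz"]], TRUE, spec$shared_e1_factor, "MZ"),
       dz = one_type(n_pairs_per_type[["dz"]], FALSE, spec$shared_e1_factor, "DZ"),
       sib = one_type(n_pairs_per_type[["sib"]], FALSE, 1, "S"))
}

#' Simulate case counts at two exposure epochs
#'
#' Embeds sex-specific exponential response curves: at exposure probability
#' `u` the cumulative-hazard coordinate is `a = -ln(1 - u)` and susceptible
#' men fail with probability `c (1 - e^-(a - lambda_m))` (women analogous
#' with `d`, `lambda_w` and the hazard ratio `R`).  Case counts per sex are
#' binomial over the susceptible subgroups; the summary reports the epoch
#' disease probabilities, the F:M case ratios and the implied
#' `C = P(MS)_1 / P(MS)_2`.
#'
#' @param spec a [cohort_spec()]; `exposure_probability_by_epoch` must be
#'   strictly increasing.
#' @param curves a `response_curve_params` object giving (c, d, lambda, R).
#' @return a list with per-epoch counts, `p_ms`, `sex_ratio` and
#'   `implied_C`.
#' @export
simulate_two_epochs <- function(spec, curves = fig_preset_curves()) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(curves, "response_curve_params"))
  u <- spec$exposure_probability_by_epoch
  if (u[1] >= u[2]) {
    stop("epoch exposure probabilities must be strictly increasing", call. = FALSE)
  }
  set.seed(spec$seed)
  n_sf <- round(spec$n_individuals * spec$p_g * spec$p_f_g)
  n_sm <- round(spec$n_individuals * spec$p_g * (1 - spec$p_f_g))
  fail_probs <- function(uu) {
    a <- -log(1 - uu)
    zm <- max(0, curves$c * (1 - exp(-(a - curves$lambda_m))))
    zw <- max(0, curves$d * (1 - exp(-curves$R * (a - curves$lambda_w))))
    c(m = zm, w = zw)
  }
  epochs <- lapply(u, function(uu) {
    z <- fail_probs(uu)
    cases_f <- stats::rbinom(1, n_sf, z[["w"]])
    cases_m <- stats::rbinom(1, n_sm, z[["m"]])
    list(cases_f = cases_f, cases_m = cases_m,
         p_ms = (cases_f + cases_m) / spec$n_individuals,
         sex_ratio = if (cases_m > 0) cases_f / cases_m else Inf,
         expected = z)
  })
  list(epoch1 = epochs[[1]], epoch2 = epochs[[2]],
       implied_C = epochs[[1]]$p_ms / epochs[[2]]$p_ms,
       n_susceptible = c(F = n_sf, M = n_sm))
}
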