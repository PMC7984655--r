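# Shared fixtures and independent oracles for the suite.

# Random penetrance multiset on (0, 1], mixed shapes.
random_penetrances <- function(n, rng_max = 1) {
  x <- runif(n, min = 1e-6, max = rng_max)
  x[x <= 0] <- 1e-6
  x
}

# Independent oracle for the size-biased recurrence: literal proband
# enumeration over a finite population, one individual per penetrance value,
# weighting each genotype by its probability of producing a case.
oracle_size_biased <- function(x) {
  weights <- x / sum(x)         # P(G_i | case)
  sum(weights * x)              # E[penetrance of the case's co-twin genotype]
}

# Brute-force four-cell (G x H) population oracle for the HLA enrichment
# ratio: choose P(G|H-) freely, set P(G|H+) = rho * P(G|H-), equal
# penetrance everywhere, and recover P(H+|MS); returns the rho that
# reproduces a target P(H+|MS) by root finding.
oracle_hla_rho <- function(p_hplus, p_hplus_ms) {
  f <- function(rho) {
    p_g_hminus <- 0.01
    p_g_hplus <- rho * p_g_hminus
    # cases are proportional to susceptible mass in each carrier class
    mass_plus <- p_hplus * p_g_hplus
    mass_minus <- (1 - p_hplus) * p_g_hminus
    mass_plus / (mass_plus + mass_minus) - p_hplus_ms
  }
  uniroot(f, c(1e-6, 1e6), tol = 1e-12)$root
}

# Exhaustive proband enumeration for proband-wise concordance from raw pair
# counts: each concordant pair contributes 1 proband (or 2 if doubly
# ascertained), each discordant pair 1; the co-twin is affected only for
# concordant-pair probands.
oracle_probandwise <- function(C, D, A) {
  probands_affected_cotwin <- C + A
  probands_total <- C + A + D
  probands_affected_cotwin / probands_total
}

default_lower_observed <- function() {
  list(x_prime = 0.134, x1_prime = 0.187, x2_prime = 0.034,
       p_ms = 0.003, p_f_ms = 0.66)
}

small_lower_grids <- list(n_p = 40, n_x1 = 40, n_x2 = 40, n_pg = 100)
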