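# concordance: twin/sibling concordance statistics and the shared-environment
# adjustment that turns observed MZ concordance into the adjusted recurrence x'.

#' Pair-wise twin concordance
#'
#' @param table a [twin_table].
#' @return `C / (C + D)`.
#' @export
pairwise_concordance <- function(table) {
  stopifnot(inherits(table, "twin_table"))
  n <- table$concordant + table$discordant
  if (n <= 0) stop("empty twin table", call. = FALSE)
  table$concordant / n
}

#' Proband-wise twin concordance, ascertainment-aware
#'
#' Counts each doubly-ascertained concordant pair as two probands:
#' `(C + A) / (C + A + D)`.  With `A = C` (every concordant pair ascertained
#' through both members) this reduces to the textbook `2C / (2C + D)`.  The
#' ascertainment-aware form is the default because it reproduces the
#' published Canadian totals-row value 0.25 exactly (37/146 with C=24, D=109,
#' A=13), where the textbook form gives 0.306.
#'
#' @param table a [twin_table]; `doubly_ascertained` must not exceed
#'   `concordant`.
#' @param method `"ascertainment"` (default) or `"textbook"` for `2C/(2C+D)`.
#' @return a probability.
#' @examples
#' probandwise_concordance(twin_table(24, 109, 13))  # 0.2534...
#' @export
probandwise_concordance <- function(table, method = c("ascertainment", "textbook")) {
  stopifnot(inherits(table, "twin_table"))
  method <- match.arg(method)
  C <- table$concordant; D <- table$discordant; A <- table$doubly_ascertained
  if (C + D <= 0) stop("empty twin table", call. = FALSE)
  if (A > C) stop("'doubly_ascertained' cannot exceed 'concordant'", call. = FALSE)
  if (method == "textbook") 2 * C / (2 * C + D) else (C + A) / (C + A + D)
}

#' Concordance summary for a twin table
#'
#' @param table a [twin_table].
#' @param ... passed to [probandwise_concordance()].
#' @return an object of class `concordance_result` with the pair-wise and
#'   proband-wise rates.
#' @export
concordance_result <- function(table, ...) {
  structure(list(pairwise = pairwise_concordance(table),
                 probandwise = probandwise_concordance(table, ...),
                 stratum = table$stratum, label = table$label,
                 counts = table),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance [%s/%s]: pair-wise %.3f, proband-wise %.3f\n",
              x$stratum, x$label, x$pairwise, x$probandwise))
  invisible(x)
}

#' Adjust MZ concordance for the twins' shared early environment
#'
#' MZ co-twins share the intrauterine and early post-natal environment as
#' well as their genotype.  DZ twins and non-twin siblings have the same
#' genetic relationship to the proband but differ in exactly that shared
#' early environment, so the sibling/DZ recurrence ratio estimates the
#' multiplicative inflation that environment contributes, and
#' `(sib / dz) * mz` removes it.  The result is the adjusted MZ recurrence
#' `x'`, the size-biased expected penetrance of the susceptible subset.
#'
#' @param mz MZ proband-wise concordance.
#' @param dz DZ-twin recurrence risk (> 0).
#' @param sib non-twin sibling recurrence risk.
#' @param mode arithmetic mode; `"paper"` rounds the result to 3 decimals as
#'   the source tables print.
#' @return the adjusted recurrence `x'`.
#' @examples
#' adjust_shared_environment(0.25, 0.054, 0.029)  # 0.1343
#' @export
adjust_shared_environment <- function(mz, dz, sib, mode = c("full", "paper")) {
  mode <- match.arg(mode)
  assert_probability(mz, "mz", open_lower = TRUE)
  assert_probability(dz, "dz", open_lower = TRUE)
  assert_probability(sib, "sib", open_lower = TRUE)
  mode_round((sib / dz) * mz, 3, mode)
}

#' Chi-square homogeneity test between two twin-table strata
#'
#' Pearson chi-square without continuity correction on the 2x2 table of
#' concordant/discordant pair counts across two strata (the correction is
#' not applied because pair counts here are large enough that the corrected
#' statistic would understate the published sex difference).
#'
#' @param table_a,table_b [twin_table] objects for the two strata.
#' @return a list with `statistic`, `p_value` and the 2x2 matrix.
#' @examples
#' concordance_chi2(twin_table(22, 66), twin_table(2, 43))  # X2 = 8.51
#' @export
concordance_chi2 <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "twin_table"), inherits(table_b, "twin_table"))
  m <- rbind(c(table_a$concordant, table_a$discordant),
             c(table_b$concordant, table_b$discordant))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal in the 2x2 table", call. = FALSE)
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), table = m)
}
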