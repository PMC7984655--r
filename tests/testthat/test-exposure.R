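test_that("timepoint-2 anchors match the published values and scale", {
  a <- timepoint2_anchors(0.66, 0.003, 0.044, 0.25)
  expect_equal(a[["zw2"]], 0.180, tolerance = 1e-9)
  expect_equal(a[["zm2"]], 0.0309091, tolerance = 1e-6)
  expect_equal(round(a[["zm2"]], 3), 0.031)
  # proportional split: equal shares give equal anchors
  a2 <- timepoint2_anchors(0.25, 0.003, 0.044, 0.25)
  expect_equal(a2[["zw2"]], a2[["zm2"]])
  expect_equal(a2[["zw2"]], 0.003 / 0.044)
  # doubling P(G) halves both anchors
  a3 <- timepoint2_anchors(0.66, 0.003, 0.088, 0.25)
  expect_equal(unname(a3), unname(a) / 2)
  expect_error(timepoint2_anchors(0.99, 0.01, 0.001, 0.5), "infeasible")
})

test_that("the C bound and its reciprocal reproduce both arithmetic modes", {
  expect_equal(c_upper_bound(2.2, 3.2), (1 / 4.2) / (1 / 3.2), tolerance = 1e-12)
  expect_equal(c_upper_bound(2.2, 3.2, mode = "paper"), 0.238 / 0.313,
               tolerance = 1e-12)
  expect_equal(round(c_upper_bound(2.2, 3.2), 2), 0.76)
  expect_equal(c_upper_bound(2, 2 + 1e-12), 1, tolerance = 1e-9)
  expect_error(c_upper_bound(3.2, 2.2), "flips")
  expect_equal(round(prevalence_inflation_factor(2.2, 3.2, mode = "paper"), 2), 1.32)
})

test_that("plateau closed forms reproduce the published limiting values", {
  r <- epoch_case_ratios(2.2, 3.2)
  lim <- limiting_values(0.180, 0.031, r[["ratio_f"]], r[["ratio_m"]], C = 0.6)
  expect_equal(round(lim$c, 3), 0.035)
  lim2 <- limiting_values(0.180, 0.0309091, r[["ratio_f"]], r[["ratio_m"]], C = 0.6)
  expect_equal(lim2$c, 0.0347316, tolerance = 1e-6)
  expect_equal(lim2$d, 0.2280404, tolerance = 1e-6)
  expect_equal(round(lim2$d, 3), 0.228)
  # saturation limit: as C * ratio -> 1 the plateau collapses onto the anchor
  r_sat <- (1 - 1e-9) / 0.9
  lim3 <- limiting_values(0.2, 0.05, ratio_f = r_sat, ratio_m = r_sat, C = 0.9)
  expect_equal(lim3$d, 0.2, tolerance = 1e-8)
})

test_that("threshold difference is positive, bounded over C, and zero at equal saturation", {
  p <- fig_preset_curves()
  expect_gt(p$lambda_diff, 0)
  expect_equal(threshold_difference(0.1, 0.05, 0.1 / 0.4, 0.1 / 0.4 * 2), 0)
  # sweep C over (0.5, 0.76): lambda stays inside the published band
  r <- epoch_case_ratios(2.2, 3.2)
  lams <- vapply(seq(0.501, 0.759, length.out = 100), function(C) {
    lim <- limiting_values(0.180, 0.0309091, r[["ratio_f"]], r[["ratio_m"]], C)
    threshold_difference(0.180, 0.0309091, lim$c, lim$d)
  }, numeric(1))
  expect_true(all(lams > 0.37 & lams < 4.67))
  # and lambda > 0 for all C > 0
  lams_all <- vapply(seq(0.05, 0.74, length.out = 50), function(C) {
    lim <- limiting_values(0.180, 0.0309091, r[["ratio_f"]], r[["ratio_m"]], C)
    threshold_difference(0.180, 0.0309091, lim$c, lim$d)
  }, numeric(1))
  expect_true(all(lams_all > 0))
  expect_error(threshold_difference(0.3, 0.05, 0.1, 0.2), "plateau")
})

test_that("lambda is invariant to the hazard ratio R", {
  p1 <- fig_preset_curves(R = 1)
  for (R in c(0.2, 0.67, 1.5, 5)) {
    pR <- fig_preset_curves(R = R)
    expect_equal(pR$lambda_diff, p1$lambda_diff, tolerance = 1e-12)
    # refit the women's curve from two sampled points at this R and recover
    # the same threshold
    pts <- build_response_curves(pR, a_max = 8, step = 1e-3)
    a_pair <- c(3, 4.5)
    z <- approx(pts$a, pts$p_fail_w, a_pair)$y
    fit <- fit_exponential_limit(R * a_pair[1], z[1], z[2],
                                 delta = R * diff(a_pair))
    expect_equal(fit[["threshold"]] / R, pR$lambda_w, tolerance = 1e-6)
    expect_equal(fit[["limit"]], pR$d, tolerance = 1e-6)
  }
})

test_that("exposure probability bounds match published values and monotonicity", {
  b <- exposure_probability_bound(2.2, 3.2, 0.5)
  expect_equal(round(b[["bound_m"]], 2), 0.83)
  expect_equal(round(b[["bound_w"]], 2), 0.76)
  # closed-form limit as C_min -> 0
  b0 <- exposure_probability_bound(2.2, 3.2, 1e-9)
  expect_equal(unname(b0), rep(1 - exp(-1), 2), tolerance = 1e-6)
  # increasing in C_min
  grid <- seq(0.05, 0.7, length.out = 30)
  vals <- t(vapply(grid, function(C) exposure_probability_bound(2.2, 3.2, C),
                   numeric(2)))
  expect_true(all(diff(vals[, 1]) > 0))
  expect_true(all(diff(vals[, 2]) > 0))
})

test_that("multi-event decomposition takes the k-th root", {
  expect_equal(round(multievent_decomposition(0.83, 3), 2), 0.94)
  expect_equal(multievent_decomposition(0.37, 1), 0.37)
  expect_equal(multievent_decomposition(0.5, 2), sqrt(0.5), tolerance = 1e-12)
})

test_that("curves pass through their anchors, are monotone, and plateau", {
  p <- fig_preset_curves()
  pts <- build_response_curves(p, a_max = 30, step = 0.005)
  expect_true(all(diff(pts$p_fail_m) >= -1e-12))
  expect_true(all(diff(pts$p_fail_w) >= -1e-12))
  expect_true(all(pts$p_fail_m <= p$c + 1e-12))
  expect_true(all(pts$p_fail_w <= p$d + 1e-12))
  # plateau at large exposure
  expect_equal(pts$p_fail_m[nrow(pts)], p$c, tolerance = 1e-9)
  expect_equal(pts$p_fail_w[nrow(pts)], p$d, tolerance = 1e-9)
  # anchor points (evaluated exactly, not off the grid)
  eval_m <- function(a) p$c * (1 - exp(-(a - p$lambda_m)))
  eval_w <- function(a) p$d * (1 - exp(-(a - p$lambda_w)))
  expect_equal(eval_m(p$a1), p$zm1, tolerance = 1e-9)
  expect_equal(eval_m(p$a1 + 1), p$zm2, tolerance = 1e-9)
  expect_equal(eval_w(p$a1), p$zw1, tolerance = 1e-9)
  expect_equal(eval_w(p$a1 + 1), p$zw2, tolerance = 1e-9)
  # two points determine (limit, threshold) uniquely: refit recovers params
  fit_m <- fit_exponential_limit(p$a1, p$zm1, p$zm2)
  expect_equal(fit_m[["limit"]], p$c, tolerance = 1e-9)
  expect_equal(fit_m[["threshold"]], p$lambda_m, tolerance = 1e-9)
  fit_w <- fit_exponential_limit(p$a1, p$zw1, p$zw2)
  expect_equal(fit_w[["limit"]], p$d, tolerance = 1e-9)
  expect_equal(fit_w[["threshold"]], p$lambda_w, tolerance = 1e-9)
})

test_that("R only changes how quickly the women's curve reaches its plateau", {
  near_plateau_at <- function(R) {
    pts <- build_response_curves(fig_preset_curves(R = R), a_max = 40, step = 0.01)
    pts$a[which(pts$p_fail_w >= 0.95 * fig_preset_curves()$d)[1]]
  }
  a_fast <- near_plateau_at(1.5); a_base <- near_plateau_at(1)
  a_slow <- near_plateau_at(0.67)
  expect_lt(a_fast, a_base)
  expect_gt(a_slow, a_base)
})

test_that("non-proportional hazards refuse co-plotting", {
  p <- fig_preset_curves(proportional = FALSE)
  pts <- build_response_curves(p)
  expect_false(attr(pts, "co_plot"))
  expect_true(all(c("a_app", "p_fail_w_app") %in% names(pts)))
})

test_that("the curves cross near the published pure-genetic baseline", {
  p <- fig_preset_curves()
  cross <- curve_intersection(p)
  expect_equal(round(cross[["z"]], 3), 0.018)
  # at the crossing the two curves agree
  zm <- p$c * (1 - exp(-cross[["a"]]))
  zw <- p$d * (1 - exp(-(cross[["a"]] - p$lambda_w)))
  expect_equal(zm, zw, tolerance = 1e-9)
})

test_that("plateaus below the observed MZ concordance are flagged", {
  chk <- limit_consistency_check(0.035, 0.228, c(F = 0.34, M = 0.067))
  expect_false(chk$consistent_m)
  expect_false(chk$consistent_f)
  expect_gt(chk$deficit_m, 0)
  ok <- limit_consistency_check(0.07, 0.35, c(F = 0.34, M = 0.067))
  expect_true(ok$consistent_m && ok$consistent_f)
  eq <- limit_consistency_check(0.067, 0.34, c(F = 0.34, M = 0.067))
  expect_true(eq$consistent_m && eq$consistent_f)
})

test_that("two-epoch simulation recovers the embedded epoch ratio C", {
  cp <- fig_preset_curves(p_f_ms2 = sexratio_to_proportion(3.2))
  u1 <- 1 - exp(-cp$a1); u2 <- 1 - exp(-(cp$a1 + 1))
  spec <- cohort_spec(n_individuals = 2e7, p_g = 0.044, p_f_g = 0.25,
                      exposure_probability_by_epoch = c(u1, u2), seed = 7)
  te <- simulate_two_epochs(spec, cp)
  n1 <- te$epoch1$cases_f + te$epoch1$cases_m
  n2 <- te$epoch2$cases_f + te$epoch2$cases_m
  se_rel <- sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(te$implied_C / cp$C - 1), 3 * se_rel)
  # sex ratio rises between epochs (the direction the data show)
  expect_gt(te$epoch2$sex_ratio, te$epoch1$sex_ratio)
  # equal epochs are rejected; near-equal gives C near 1
  expect_error(simulate_two_epochs(
    cohort_spec(exposure_probability_by_epoch = c(0.5, 0.5)), cp),
    "strictly increasing")
})
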