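# cli_reporting: reproducible pipeline over the analysis stages with a run
# manifest and machine-readable outputs.  The package functions are the
# interface; run_pipeline() chains them in the canonical order.

#' Run the full analysis pipeline
#'
#' Executes the stages `pms` (prevalence-based P(MS) estimates),
#' `concordance` (twin tables and the shared-environment adjustment),
#' `bounds` (upper/lower-branch and partition bounds on P(G)),
#' `curves` (exposure-response parameters and curve points) and
#' `search` (the plateau-reconciling grid search), in order, each stage
#' consuming the previous stage's results.  Every stage writes CSV and/or
#' JSON under `out_dir`; headline quantities are reported in both
#' full-precision and paper-rounded arithmetic side by side.  The run is
#' idempotent for a fixed configuration and seed.
#'
#' @param params an [observed_parameters] object (default:
#'   [default_parameters()]).
#' @param out_dir output directory, created if absent.
#' @param seed integer seed for the stochastic stages.
#' @param stages character vector of stages to run (subset of the five, in
#'   canonical order); skipped stages are noted in the manifest.
#' @param lower_search_grids grid resolutions forwarded to
#'   [search_lower_solution()] in the bounds stage.
#' @param quiet suppress stage messages?
#' @return a list of class `run_manifest`: configuration hash, package
#'   version, seed, timestamps and per-stage output paths (all of which
#'   exist on completion).
#' @export
run_pipeline <- function(params = default_parameters(),
                         out_dir = tempfile("mspenetrance-run-"),
                         seed = 1L,
                         stages = c("pms", "concordance", "bounds", "curves", "search"),
                         lower_search_grids = list(n_p = 40, n_x1 = 40,
                                                   n_x2 = 40, n_pg = 100),
                         quiet = FALSE) {
  stopifnot(inherits(params, "observed_parameters"))
  stages <- match.arg(stages, several.ok = TRUE)
  started <- format(Sys.time(), tz = "UTC")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- list()
  skipped <- setdiff(c("pms", "concordance", "bounds", "curves", "search"), stages)

  config_path <- file.path(out_dir, "config.json")
  write_parameters(params, config_path)
  outputs$config <- config_path

  x_prime <- adjust_shared_environment(params$mz_recurrence, params$dz_recurrence,
                                       params$sib_recurrence)

  if ("pms" %in% stages) {
    say("stage pms: three prevalence-based estimates")
    ests <- list(
      estimate_from_agebands(params$prevalence_overall, params$ageband_weights),
      estimate_from_age_restricted(params$prevalence_45_54),
      estimate_from_death_certificates(params$death_certificate_rate))
    env <- combine_pms_estimates(ests)
    df <- do.call(rbind, lapply(ests, function(e) {
      data.frame(method = e$method, lo = e$interval$lo, hi = e$interval$hi,
                 point = e$point)
    }))
    path <- file.path(out_dir, "pms_estimates.csv")
    utils::write.csv(df, path, row.names = FALSE)
    outputs$pms <- path
    outputs$pms_envelope <- c(env$lo, env$hi)
  }

  if ("concordance" %in% stages) {
    say("stage concordance: twin tables and shared-environment adjustment")
    tabs <- packaged_twin_tables()
    df <- do.call(rbind, lapply(tabs, function(tt) {
      cr <- concordance_result(tt)
      data.frame(stratum = tt$stratum, label = tt$label,
                 concordant = tt$concordant, discordant = tt$discordant,
                 doubly_ascertained = tt$doubly_ascertained,
                 pairwise = cr$pairwise, probandwise = cr$probandwise)
    }))
    df$x_prime_adjusted <- (params$sib_recurrence / params$dz_recurrence) * df$probandwise
    path <- file.path(out_dir, "concordance.csv")
    utils::write.csv(df, path, row.names = FALSE)
    outputs$concordance <- path
  }

  if ("bounds" %in% stages) {
    say("stage bounds: P(G) and partition bounds")
    upper <- pg_upper_solution(params$p_ms, x_prime)
    extreme <- pg_extreme_bound(params$p_ms, params$sib_recurrence)
    gender_full <- gender_bound_chain(params$p_f_ms_t2, params$p_ms, params$p_f,
                                      params$penetrance_range_f,
                                      params$penetrance_range_m, mode = "full")
    gender_paper <- gender_bound_chain(params$p_f_ms_t2, params$p_ms, params$p_f,
                                       params$penetrance_range_f,
                                       params$penetrance_range_m, mode = "paper")
    hla <- hla_enrichment_ratio(params$p_hplus, params$p_hplus_ms)
    lower <- search_lower_solution(
      list(x_prime = x_prime,
           x1_prime = params$penetrance_range_f[2],
           x2_prime = params$penetrance_range_m[2],
           p_ms = params$p_ms, p_f_ms = params$p_f_ms_t2),
      grids = lower_search_grids)
    bounds <- list(
      x_prime = list(full = x_prime,
                     paper = adjust_shared_environment(params$mz_recurrence,
                                                       params$dz_recurrence,
                                                       params$sib_recurrence,
                                                       mode = "paper")),
      p_g_upper_branch = c(upper$lo, upper$hi),
      p_g_extreme = extreme,
      p_f_given_g_max = list(full = gender_full$p_f_given_g_max,
                             paper = gender_paper$p_f_given_g_max),
      hla_enrichment = hla,
      hla_susceptible_fraction = hla_susceptible_fraction(0.073, params$p_hplus),
      lower_branch_p_g = if (!is.null(lower$p_g)) c(lower$p_g$lo, lower$p_g$hi),
      lower_branch_p_g1 = if (!is.null(lower$p_g1)) c(lower$p_g1$lo, lower$p_g1$hi))
    path <- file.path(out_dir, "bounds.json")
    jsonlite::write_json(bounds, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs$bounds <- path
    t4 <- table4_batch(packaged_regional_rows(),
                       sib = params$sib_recurrence, dz = params$dz_recurrence)
    path4 <- file.path(out_dir, "regional_pg.csv")
    utils::write.csv(t4, path4, row.names = FALSE)
    outputs$regional <- path4
  }

  if ("curves" %in% stages) {
    say("stage curves: exposure-response parameters and points")
    cp <- fig_preset_curves(p_ms2 = params$p_ms,
                            sexratio1 = params$sex_ratio_t1,
                            sexratio2 = params$sex_ratio_t2,
                            p_f_ms2 = params$p_f_ms_t2)
    pts <- build_response_curves(cp)
    path <- file.path(out_dir, "curve_points.csv")
    utils::write.csv(pts, path, row.names = FALSE)
    pj <- file.path(out_dir, "curve_params.json")
    jsonlite::write_json(unclass(cp), pj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs$curves <- path
    outputs$curve_params <- pj
  }

  if ("search" %in% stages) {
    say("stage search: reconciling plateaus with observed concordance")
    sr <- run_search(search_spec(p_f_ms2 = params$p_f_ms_t2_variants$orton_recent_epoch,
                                 sexratio1 = params$sex_ratio_t1,
                                 sexratio2 = params$sex_ratio_t2),
                     targets = c(F = params$mz_recurrence_by_sex$F,
                                 M = params$mz_recurrence_by_sex$M))
    path <- file.path(out_dir, "search_matches.csv")
    utils::write.csv(sr$matches, path, row.names = FALSE)
    sj <- file.path(out_dir, "search_summary.json")
    jsonlite::write_json(list(n_matches = sr$n_matches,
                              envelopes = sr$envelopes,
                              message = sr$message),
                         sj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs$search <- path
    outputs$search_summary <- sj
  }

  paths <- unlist(Filter(is.character, outputs))
  if (!all(file.exists(paths))) {
    stop("pipeline completed but output file(s) missing: ",
         paste(paths[!file.exists(paths)], collapse = ", "), call. = FALSE)
  }
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(config_path)),
    package_version = as.character(utils::packageVersion("mspenetrance")),
    seed = seed,
    started = started, finished = format(Sys.time(), tz = "UTC"),
    stages_run = stages, stages_skipped = skipped,
    outputs = outputs),
    class = "run_manifest")
  mj <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest), "outputs")],
                       mj, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat("  package  ", x$package_version, "\n")
  cat("  config   ", x$config_hash, "\n")
  cat("  stages   ", paste(x$stages_run, collapse = ", "), "\n")
  if (length(x$stages_skipped)) {
    cat("  skipped  ", paste(x$stages_skipped, collapse = ", "), "\n")
  }
  for (nm in names(x$outputs)) {
    if (is.character(x$outputs[[nm]])) cat(sprintf("  %-14s %s\n", nm, x$outputs[[nm]]))
  }
  invisible(x)
}
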