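# parameters_io: load, validate and provenance-tag the observed scalar inputs.

.required_keys <- c(
  "prevalence_overall", "prevalence_45_54", "death_certificate_rate",
  "ageband_weights", "mz_recurrence", "dz_recurrence", "sib_recurrence",
  "mz_recurrence_by_sex", "p_ms", "p_f_ms_t1", "p_f_ms_t2",
  "p_f_ms_t2_variants", "sex_ratio_t1", "sex_ratio_t2",
  "p_hplus", "p_hplus_ms", "p_f", "penetrance_range_f", "penetrance_range_m"
)

#' Observed epidemiological parameters
#'
#' Container for every published scalar the analysis consumes: the measured
#' prevalence of MS, the census age-band weights, twin/sibling recurrence
#' risks, the proportion of women among cases at the two observation epochs
#' (equivalently the F:M sex ratios 2.2 and 3.2), HLA carrier frequencies in
#' cases and controls, and the adjusted per-sex penetrance limits.  Each value
#' carries a provenance string naming the study it was taken from; the tags
#' are kept because the analysis deliberately mixes sources (a twin registry,
#' a longitudinal sex-ratio series, a case-control genetics cohort) and the
#' mix must stay auditable.
#'
#' @param values named list of parameter values (see the packaged default
#'   configuration for the full key set).
#' @param provenance named character vector of source tags, parallel to
#'   `values`.
#' @return an object of class `observed_parameters`: the value list with a
#'   `provenance` attribute.
#' @seealso [load_parameters()], [default_parameters()]
#' @export
observed_parameters <- function(values, provenance = character()) {
  missing <- setdiff(.required_keys, names(values))
  if (length(missing)) {
    stop("missing required parameter key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_parameter_values(values)
  structure(values,
            provenance = provenance,
            class = "observed_parameters")
}

validate_parameter_values <- function(v) {
  probs <- c("prevalence_overall", "prevalence_45_54", "death_certificate_rate",
             "mz_recurrence", "dz_recurrence", "sib_recurrence",
             "p_ms", "p_f_ms_t1", "p_f_ms_t2", "p_hplus", "p_hplus_ms", "p_f")
  for (key in probs) assert_probability(v[[key]], key)
  assert_probability(unlist(v$mz_recurrence_by_sex), "mz_recurrence_by_sex")
  assert_probability(unlist(v$p_f_ms_t2_variants), "p_f_ms_t2_variants")
  assert_probability(v$penetrance_range_f, "penetrance_range_f")
  assert_probability(v$penetrance_range_m, "penetrance_range_m")
  w <- v$ageband_weights
  if (length(w) != 3L || any(w < 0)) {
    stop("'ageband_weights' must be three nonnegative proportions", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("'ageband_weights' must sum to 1 (got %.12g)", sum(w)),
         call. = FALSE)
  }
  if (v$sex_ratio_t1 <= 0 || v$sex_ratio_t2 <= 0) {
    stop("sex ratios must be > 0", call. = FALSE)
  }
  if (!(v$mz_recurrence >= v$dz_recurrence && v$dz_recurrence >= v$sib_recurrence)) {
    stop("expected ordering mz_recurrence >= dz_recurrence >= sib_recurrence violated",
         call. = FALSE)
  }
  invisible(v)
}

#' @export
print.observed_parameters <- function(x, ...) {
  cat("Observed epidemiological parameters\n")
  prov <- attr(x, "provenance")
  for (key in names(x)) {
    val <- x[[key]]
    shown <- if (is.list(val)) {
      paste(sprintf("%s=%.4g", names(val), unlist(val)), collapse = ", ")
    } else {
      paste(signif(unlist(val), 4), collapse = ", ")
    }
    cat(sprintf("  %-24s %s\n", key, shown))
    if (!is.null(prov[[key]])) cat(sprintf("  %-24s   [%s]\n", "", prov[[key]]))
  }
  invisible(x)
}

#' Load observed parameters from a JSON configuration
#'
#' Reads a configuration in the packaged format (each key either a bare value
#' or a `{"value": ..., "source": ...}` pair), validates every invariant
#' (probabilities in \[0,1\], age-band weights summing to one, the recurrence
#' ordering MZ >= DZ >= sibling, positive sex ratios) and fills any missing
#' optional key from the packaged Canadian default set.
#'
#' @param config_source path to a JSON file, or a named list already parsed.
#' @return an [observed_parameters] object.
#' @examples
#' p <- default_parameters()
#' p$mz_recurrence
#' @export
load_parameters <- function(config_source) {
  raw <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("configuration file not found: ", config_source, call. = FALSE)
    }
    jsonlite::read_json(config_source, simplifyVector = TRUE)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("'config_source' must be a file path or a named list", call. = FALSE)
  }
  defaults <- .read_default_config()
  merged <- defaults
  for (key in names(raw)) merged[[key]] <- raw[[key]]
  values <- lapply(merged, .config_value)
  provenance <- vapply(merged, .config_source, character(1))
  observed_parameters(values, provenance = provenance)
}

.config_value <- function(entry) {
  if (is.list(entry) && !is.null(entry$value)) entry$value else entry
}

.config_source <- function(entry) {
  if (is.list(entry) && !is.null(entry$source)) entry$source else NA_character_
}

.read_default_config <- function() {
  path <- system.file("extdata", "canada_defaults.json",
                      package = "mspenetrance", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' The packaged Canadian default parameter set
#'
#' @return an [observed_parameters] object holding the default values
#'   (Canadian twin-registry recurrence risks, the 2.2 and 3.2 sex ratios,
#'   WTCCC HLA frequencies, census age-band weights).
#' @export
default_parameters <- function() {
  load_parameters(list())
}

#' Serialize observed parameters back to JSON
#'
#' Writes the `{"value": ..., "source": ...}` form so that a load/write/load
#' round trip is lossless, provenance included.
#'
#' @param params an [observed_parameters] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "observed_parameters"))
  prov <- attr(params, "provenance")
  out <- lapply(names(params), function(key) {
    list(value = params[[key]],
         source = if (is.null(prov[[key]]) || is.na(prov[[key]])) NULL else prov[[key]])
  })
  names(out) <- names(params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert an F-per-M sex ratio to the proportion of women
#'
#' @param ratio F:M ratio among cases; must be positive.
#' @return `ratio / (1 + ratio)`, the implied proportion of women.
#' @examples
#' sexratio_to_proportion(3.2)  # 0.7619
#' @export
sexratio_to_proportion <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("'ratio' must be a positive finite F:M ratio", call. = FALSE)
  }
  ratio / (1 + ratio)
}

#' Inverse of [sexratio_to_proportion()]
#'
#' @param proportion proportion of women among cases, in (0, 1).
#' @return the implied F:M ratio `proportion / (1 - proportion)`.
#' @export
proportion_to_sexratio <- function(proportion) {
  assert_probability(proportion, "proportion", open_lower = TRUE, open_upper = TRUE)
  proportion / (1 - proportion)
}

#' Twin-pair count table
#'
#' @param concordant number of concordant pairs (both affected).
#' @param discordant number of discordant pairs.
#' @param doubly_ascertained number of concordant pairs independently
#'   ascertained through both members; must not exceed `concordant`.
#' @param stratum label (`"overall"`, `"by-sex"`, `"by-HLA"`, ...).
#' @param label sub-stratum label (e.g. `"F"`, `"H+"`).
#' @return an object of class `twin_table`.
#' @export
twin_table <- function(concordant, discordant, doubly_ascertained = 0L,
                       stratum = "overall", label = stratum) {
  if (concordant < 0 || discordant < 0 || doubly_ascertained < 0) {
    stop("twin-pair counts must be nonnegative", call. = FALSE)
  }
  if (doubly_ascertained > concordant) {
    stop("'doubly_ascertained' cannot exceed 'concordant'", call. = FALSE)
  }
  structure(list(concordant = concordant, discordant = discordant,
                 doubly_ascertained = doubly_ascertained,
                 stratum = stratum, label = label),
            class = "twin_table")
}

#' @export
print.twin_table <- function(x, ...) {
  cat(sprintf("Twin table [%s/%s]: C=%d D=%d A=%d\n",
              x$stratum, x$label, x$concordant, x$discordant,
              x$doubly_ascertained))
  invisible(x)
}

#' Packaged MZ-twin concordance tables
#'
#' The Canadian population-based MZ-twin pair counts, overall and broken down
#' by sex and by HLA carrier status.  The registry reports 13 double
#' ascertainments among the 24 concordant pairs overall but not their split
#' across strata; the packaged by-sex rows carry the (12, 1) apportionment
#' for (F, M) and the by-HLA rows apportion at the overall 13/24 rate
#' (5, 6, 11).  Both splits are reconstructions (they reproduce the
#' published per-stratum proband-wise rates), not registry facts.
#'
#' @return a list of [twin_table] objects keyed by `"stratum/label"`.
#' @export
packaged_twin_tables <- function() {
  path <- system.file("extdata", "mz_twin_tables.csv",
                      package = "mspenetrance", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    a <- df$doubly_ascertained[i]
    twin_table(df$concordant[i], df$discordant[i],
               doubly_ascertained = if (is.na(a)) 0L else a,
               stratum = df$stratum[i], label = df$label[i])
  })
  names(out) <- paste(df$stratum, df$label, sep = "/")
  out
}
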