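REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full scale-up analysis pipeline
#'
#' Composes the whole pipeline on files: read and validate the survey (and
#' optional alter table) and configuration, compute the crude and adjusted
#' estimates, Monte Carlo and bootstrap uncertainty intervals, the
#' network-size sensitivity scan, and demographic tabulations, and collect
#' everything into a structured report with provenance (input file hashes,
#' seed, package version, timestamp).
#'
#' @param survey_path Respondent-level CSV (see \code{\link{read_survey}}).
#' @param config_path YAML/JSON configuration (see \code{\link{read_config}});
#'   \code{NULL} uses the package defaults.
#' @param alters_path Optional alter-level CSV.
#' @param seed Integer seed governing both uncertainty methods.
#' @param mc_replicates,boot_replicates Replicate counts for the Monte Carlo
#'   and bootstrap intervals.
#' @param percentiles Interval percentile pair; default \code{c(2.5, 97.5)}.
#' @param sample_factors Sample VF/PF uniformly in the Monte Carlo interval
#'   (default TRUE).
#' @param scales Sensitivity scan multipliers; default \code{c(0.9, 1, 1.1)}.
#' @param per Prevalence scale; default per 1000.
#' @return An object of class \code{nsum_report} with elements
#'   \code{config}, \code{estimates}, \code{intervals}, \code{sensitivity},
#'   \code{demographics}, \code{provenance}.
#' @export
run_full_analysis <- function(survey_path,
                              config_path = NULL,
                              alters_path = NULL,
                              seed = 1L,
                              mc_replicates = 10000,
                              boot_replicates = 10000,
                              percentiles = c(2.5, 97.5),
                              sample_factors = TRUE,
                              scales = c(0.9, 1, 1.1),
                              per = 1000) {
  config <- if (is.null(config_path)) network_config() else read_config(config_path)
  respondents <- read_survey(survey_path)
  alters <- if (!is.null(alters_path)) {
    read_alters(alters_path, respondents = respondents)
  }
  est <- apply_adjustments(suppressWarnings(crude_estimate(respondents, config)),
                           config)
  mc <- monte_carlo_interval(respondents, config, n_replicates = mc_replicates,
                             percentiles = percentiles,
                             sample_factors = sample_factors,
                             seed = seed, keep_draws = FALSE)
  bt <- bootstrap_interval(respondents, config, n_replicates = boot_replicates,
                           percentiles = percentiles,
                           seed = seed, keep_draws = FALSE)
  sens <- sensitivity_scan(respondents, config, scales = scales)
  demo <- list(
    respondents = summarize_demographics(
      respondents, percent_denominator = config$percent_denominator),
    alters = if (!is.null(alters)) {
      summarize_demographics(alters,
                             percent_denominator = config$percent_denominator)
    }
  )
  hashes <- list(survey = unname(tools::md5sum(survey_path)))
  if (!is.null(config_path)) hashes$config <- unname(tools::md5sum(config_path))
  if (!is.null(alters_path)) hashes$alters <- unname(tools::md5sum(alters_path))
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config = config,
    estimates = est,
    prevalence = prevalence(est, config, per = per),
    per = per,
    intervals = list(monte_carlo = mc, bootstrap = bt),
    sensitivity = sens,
    demographics = demo,
    provenance = list(
      input_hashes = hashes,
      seed = as.integer(seed),
      package_version = as.character(utils::packageVersion("nsum")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  class(report) <- "nsum_report"
  report
}

report_as_list <- function(report, include_timestamp = FALSE) {
  est <- report$estimates
  prov <- report$provenance
  if (!include_timestamp) prov$timestamp <- NULL
  list(
    schema_version = report$schema_version,
    config = unclass(report$config),
    estimates = list(
      sum_m = est$sum_m, sum_c = est$sum_c,
      n_male = est$n_male, n_female = est$n_female, t = est$t,
      e_crude = est$e_crude, e_vf = est$e_vf, e_pf = est$e_pf,
      e_adjusted = est$e_adjusted,
      prevalence_per_1000 = est$prevalence_per_1000
    ),
    prevalence = list(per = report$per, value = report$prevalence),
    intervals = lapply(report$intervals, function(u) {
      list(method = u$method, point = u$point, lower = u$lower,
           upper = u$upper, level_low = u$level_low,
           level_high = u$level_high, n_replicates = u$n_replicates,
           seed = u$seed)
    }),
    sensitivity = as.data.frame(report$sensitivity),
    demographics = report$demographics[!vapply(report$demographics, is.null,
                                               logical(1))],
    provenance = prov
  )
}

validate_report_list <- function(x) {
  required <- c("schema_version", "config", "estimates", "prevalence",
                "intervals", "sensitivity", "provenance")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("report is missing section(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num_fields <- c("e_crude", "e_vf", "e_pf", "e_adjusted")
  for (f in num_fields) {
    v <- x$estimates[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("report estimate '%s' is not a finite number", f),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Write a report as machine-readable JSON
#'
#' The JSON schema is versioned and validated on write. By default the
#' provenance timestamp is omitted so that regeneration from the same inputs
#' and seed is byte-identical.
#'
#' @param report An \code{nsum_report}.
#' @param path Destination path.
#' @param include_timestamp Include the wall-clock timestamp (default FALSE
#'   for reproducible output).
#' @return Invisibly, \code{path}.
#' @export
write_report_json <- function(report, path, include_timestamp = FALSE) {
  stopifnot(inherits(report, "nsum_report"))
  x <- report_as_list(report, include_timestamp = include_timestamp)
  validate_report_list(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

fmt_count <- function(x) format(round(x), big.mark = "", scientific = FALSE)

#' Render a report as Markdown
#'
#' Human-readable rendering: headline estimates with both uncertainty
#' intervals laid out as a point-estimate table, the sensitivity scan, and
#' the demographic tabulations. Counts are rounded to the nearest integer
#' and rates to 2 decimals; full precision lives in the JSON output.
#'
#' @param report An \code{nsum_report}.
#' @return A single character string of Markdown.
#' @export
render_report_markdown <- function(report) {
  stopifnot(inherits(report, "nsum_report"))
  est <- report$estimates
  mc <- report$intervals$monte_carlo
  bt <- report$intervals$bootstrap
  lines <- c(
    "# Network scale-up size estimation report",
    "",
    sprintf("Respondents: %d male, %d female; sum m = %d; t = %s.",
            est$n_male, est$n_female, est$sum_m,
            format(est$t, big.mark = ",", scientific = FALSE)),
    "",
    "## Estimates",
    "",
    "| Method of estimation | Crude | Visibility-adjusted | Popularity-adjusted | Fully adjusted |",
    "|---|---|---|---|---|",
    sprintf("| Point estimate | %s | %s | %s | %s |",
            fmt_count(est$e_crude), fmt_count(est$e_vf),
            fmt_count(est$e_pf), fmt_count(est$e_adjusted)),
    sprintf("| Monte Carlo [%g%%, %g%%] | | | | %s - %s |",
            mc$level_low, mc$level_high, fmt_count(mc$lower),
            fmt_count(mc$upper)),
    sprintf("| Bootstrap [%g%%, %g%%] | | | | %s - %s |",
            bt$level_low, bt$level_high, fmt_count(bt$lower),
            fmt_count(bt$upper)),
    "",
    sprintf("Prevalence: %.2f per %s.", report$prevalence,
            format(report$per, big.mark = ",", scientific = FALSE)),
    "",
    "## Sensitivity to personal network size",
    "",
    "| Degree scale | Fully adjusted estimate | Prevalence per 1000 |",
    "|---|---|---|",
    sprintf("| %.2f | %s | %.2f |", report$sensitivity$scale,
            fmt_count(report$sensitivity$e_adjusted),
            report$sensitivity$prevalence_per_1000)
  )
  for (nm in names(report$demographics)) {
    tab <- report$demographics[[nm]]
    if (is.null(tab)) next
    lines <- c(lines, "",
               sprintf("## Demographics: %s", nm), "",
               "| Variable | Category | Count | Percent |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %d | %.1f |", tab$variable, tab$category,
                       tab$count, tab$percent))
  }
  paste(c(lines, ""), collapse = "\n")
}

#' @export
print.nsum_report <- function(x, ...) {
  cat(render_report_markdown(x))
  invisible(x)
}
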