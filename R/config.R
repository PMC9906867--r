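#' Network scale-up configuration
#'
#' Bundles the quantities the scale-up estimator needs beyond the survey
#' itself: per-gender personal network sizes (degrees), the reference
#' population total, and the visibility and popularity correction factors
#' with their plausible ranges.
#'
#' Defaults mirror a street-intercept survey of the adult population of a
#' large Iranian city: men are assumed to know on average 90 adult women and
#' women 120 (degrees borrowed from an external known-population study), the
#' reference population is the 406,916 women aged 18+ recorded in the 2016
#' census, the visibility factor is the reciprocal of a 0.45 midpoint
#' detection probability (range 1/0.55 to 1/0.35) and the popularity factor
#' the reciprocal of a 0.77 midpoint degree ratio (range 1/0.87 to 1/0.67).
#'
#' @param c_male Personal network size (degree) of male respondents.
#' @param c_female Personal network size of female respondents.
#' @param t Reference population total the estimate is scaled to
#'   (here: women aged 18 and over).
#' @param vf_point Visibility-factor point value; the reciprocal of the
#'   probability that a respondent knows an acquaintance's hidden-population
#'   membership.
#' @param vf_range Length-2 numeric, lower and upper plausible visibility
#'   factors (sampled uniformly by the Monte Carlo interval).
#' @param pf_point Popularity-factor point value; the reciprocal of the
#'   ratio of hidden-population degree to general-population degree.
#' @param pf_range Length-2 numeric, plausible popularity-factor range.
#' @param percent_denominator Either \code{"all"} (percentages in demographic
#'   tables use the full record count as denominator) or \code{"nonmissing"}.
#'
#' @return An object of class \code{nsum_config}.
#' @examples
#' cfg <- network_config()
#' cfg$t
#' @export
network_config <- function(c_male = 90,
                           c_female = 120,
                           t = 406916,
                           vf_point = 1 / 0.45,
                           vf_range = c(1 / 0.55, 1 / 0.35),
                           pf_point = 1 / 0.77,
                           pf_range = c(1 / 0.87, 1 / 0.67),
                           percent_denominator = c("all", "nonmissing")) {
  percent_denominator <- match.arg(percent_denominator)
  cfg <- list(
    c_male = as.numeric(c_male),
    c_female = as.numeric(c_female),
    t = as.numeric(t),
    vf_point = as.numeric(vf_point),
    vf_range = as.numeric(vf_range),
    pf_point = as.numeric(pf_point),
    pf_range = as.numeric(pf_range),
    percent_denominator = percent_denominator
  )
  class(cfg) <- "nsum_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "nsum_config"))
  num_fields <- c("c_male", "c_female", "t", "vf_point", "pf_point")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("config field '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  for (f in c("vf_range", "pf_range")) {
    r <- cfg[[f]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        any(r <= 0) || r[1] > r[2]) {
      stop(sprintf("config field '%s' must be an ordered pair of positive numbers", f),
           call. = FALSE)
    }
  }
  if (cfg$vf_point < cfg$vf_range[1] || cfg$vf_point > cfg$vf_range[2]) {
    stop("vf_point must lie within vf_range", call. = FALSE)
  }
  if (cfg$pf_point < cfg$pf_range[1] || cfg$pf_point > cfg$pf_range[2]) {
    stop("pf_point must lie within pf_range", call. = FALSE)
  }
  if (cfg$t != round(cfg$t)) {
    stop("t must be a whole number (a population count)", call. = FALSE)
  }
  cfg
}

#' Read a network configuration from YAML or JSON
#'
#' The file carries any subset of the \code{\link{network_config}} fields;
#' absent fields take the package defaults. Format is chosen by extension
#' (\code{.yaml}/\code{.yml} vs \code{.json}).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return An \code{nsum_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "json" = jsonlite::fromJSON(path, simplifyVector = TRUE),
    "yaml" = ,
    "yml"  = yaml::read_yaml(path),
    stop(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext),
         call. = FALSE)
  )
  known <- names(formals(network_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(network_config, raw)
}

#' Write a network configuration to YAML or JSON
#'
#' @param config An \code{nsum_config} object.
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, \code{path}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nsum_config"))
  x <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    "yaml" = ,
    "yml"  = yaml::write_yaml(x, path),
    stop(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' @export
print.nsum_config <- function(x, ...) {
  cat("Network scale-up configuration\n")
  cat(sprintf("  degrees (c): male %g, female %g\n", x$c_male, x$c_female))
  cat(sprintf("  reference population (t): %s\n",
              format(x$t, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  visibility factor: %.4f (range %.4f-%.4f)\n",
              x$vf_point, x$vf_range[1], x$vf_range[2]))
  cat(sprintf("  popularity factor: %.4f (range %.4f-%.4f)\n",
              x$pf_point, x$pf_range[1], x$pf_range[2]))
  invisible(x)
}
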