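#' Sensitivity of the adjusted estimate to personal network size
#'
#' Personal network sizes are usually borrowed from an external
#' known-population study, so the estimate's dependence on them matters.
#' For each scale factor the estimate is rebuilt with both gender degrees
#' multiplied by that factor. Because the estimator is a ratio, the adjusted
#' estimate obeys an exact reciprocal law:
#' \eqn{e(\mathrm{scale}) = e(1) / \mathrm{scale}}, so a 10\% larger network
#' size shrinks the estimate by the factor 1/1.1.
#'
#' @param respondents An \code{nsum_survey} data frame.
#' @param config An \code{nsum_config}.
#' @param scales Positive multipliers applied to the degrees; default
#'   \code{c(0.9, 1, 1.1)}.
#' @param genders Which genders' degrees to scale: \code{"both"} (default,
#'   the usual wholesale scaling), \code{"male"}, or \code{"female"}.
#' @return A data frame of class \code{nsum_sensitivity} with one row per
#'   scale: \code{scale}, \code{e_adjusted}, \code{prevalence_per_1000},
#'   ordered as given.
#' @examples
#' s <- survey_respondents(id = as.character(1:2),
#'                         gender = c("male", "female"), m = c(1, 2))
#' sensitivity_scan(s, network_config(), scales = c(0.9, 1, 1.1))
#' @export
sensitivity_scan <- function(respondents, config,
                             scales = c(0.9, 1, 1.1),
                             genders = c("both", "male", "female")) {
  stopifnot(inherits(respondents, "nsum_survey"), inherits(config, "nsum_config"))
  genders <- match.arg(genders)
  if (!length(scales) || any(!is.finite(scales)) || any(scales <= 0)) {
    stop("all scales must be positive numbers", call. = FALSE)
  }
  rows <- lapply(scales, function(s) {
    cfg <- config
    if (genders %in% c("both", "male")) cfg$c_male <- config$c_male * s
    if (genders %in% c("both", "female")) cfg$c_female <- config$c_female * s
    est <- apply_adjustments(suppressWarnings(crude_estimate(respondents, cfg)),
                             cfg)
    data.frame(scale = s,
               e_adjusted = est$e_adjusted,
               prevalence_per_1000 = est$prevalence_per_1000)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nsum_sensitivity", "data.frame")
  out
}
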