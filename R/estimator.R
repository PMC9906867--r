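#' Crude network scale-up estimate
#'
#' The basic scale-up estimator of a hidden population's size. Each
#' respondent reports \code{m_i}, the number of hidden-population members in
#' their personal network; with per-respondent degree \code{c_i} (here a
#' gender-specific constant) and reference population total \code{t}, the
#' crude estimate is
#' \deqn{e = \frac{\sum_i m_i}{\sum_i c_i} \times t.}
#' The fraction of a respondent's network that belongs to the hidden
#' population is taken as an estimate of the hidden population's share of
#' the whole reference population.
#'
#' The value is retained at full precision; rounding happens only at report
#' time. A survey in which nobody reports any hidden-population alter yields
#' an estimate of exactly 0 with a warning flag rather than an error.
#'
#' @param respondents An \code{nsum_survey} data frame.
#' @param config An \code{nsum_config} carrying degrees and \code{t}.
#' @return An object of class \code{nsum_estimate} with the crude fields set
#'   (\code{sum_m}, \code{sum_c}, \code{n_male}, \code{n_female}, \code{t},
#'   \code{e_crude}) and the adjusted fields \code{NA} until
#'   \code{\link{apply_adjustments}} is called.
#' @examples
#' s <- survey_respondents(id = as.character(1:2),
#'                         gender = c("male", "female"), m = c(1, 2))
#' crude_estimate(s, network_config())
#' @export
crude_estimate <- function(respondents, config) {
  stopifnot(inherits(respondents, "nsum_survey"), inherits(config, "nsum_config"))
  if (nrow(respondents) == 0L) {
    stop("cannot estimate from an empty survey", call. = FALSE)
  }
  n_male <- sum(respondents$gender == "male")
  n_female <- sum(respondents$gender == "female")
  sum_m <- sum(respondents$m)
  sum_c <- n_male * config$c_male + n_female * config$c_female
  if (sum_c <= 0) stop("total network size must be positive", call. = FALSE)
  zero_m <- sum_m == 0L
  if (zero_m) {
    warning("no hidden-population alters reported (sum of m is 0); the estimate is 0",
            call. = FALSE)
  }
  est <- list(
    sum_m = sum_m,
    sum_c = sum_c,
    n_male = n_male,
    n_female = n_female,
    t = config$t,
    e_crude = sum_m / sum_c * config$t,
    vf_point = NA_real_,
    pf_point = NA_real_,
    e_vf = NA_real_,
    e_pf = NA_real_,
    e_adjusted = NA_real_,
    prevalence_per_1000 = NA_real_,
    zero_m = zero_m
  )
  class(est) <- "nsum_estimate"
  est
}

#' Apply visibility and popularity corrections
#'
#' Two multiplicative corrections address the scale-up method's main
#' assumption violations for stigmatized populations. The visibility factor
#' (VF) corrects the transparency barrier: respondents are unaware of some
#' acquaintances' hidden-population membership, so reported counts are
#' thinned by a detection probability and the estimate is multiplied by its
#' reciprocal. The popularity factor (PF) corrects the barrier effect:
#' hidden-population members tend to have smaller networks than the general
#' population, so the estimate is multiplied by the reciprocal of the degree
#' ratio. Both corrections are pure products and commute.
#'
#' @param estimate An \code{nsum_estimate} from \code{\link{crude_estimate}}.
#' @param config An \code{nsum_config} supplying \code{vf_point} and
#'   \code{pf_point}.
#' @return The estimate with \code{e_vf} (VF only), \code{e_pf} (PF only),
#'   \code{e_adjusted} (both) and \code{prevalence_per_1000} populated.
#' @export
apply_adjustments <- function(estimate, config) {
  stopifnot(inherits(estimate, "nsum_estimate"), inherits(config, "nsum_config"))
  if (is.na(estimate$e_crude)) stop("e_crude is not set", call. = FALSE)
  if (config$vf_point <= 0 || config$pf_point <= 0) {
    stop("correction factors must be positive", call. = FALSE)
  }
  estimate$vf_point <- config$vf_point
  estimate$pf_point <- config$pf_point
  estimate$e_vf <- estimate$e_crude * config$vf_point
  estimate$e_pf <- estimate$e_crude * config$pf_point
  estimate$e_adjusted <- estimate$e_crude * config$vf_point * config$pf_point
  estimate$prevalence_per_1000 <- estimate$e_adjusted / estimate$t * 1000
  estimate
}

#' Hidden-population prevalence in the reference population
#'
#' Expresses the fully adjusted size estimate as a rate per \code{per}
#' members of the reference population (per 1000 by default).
#'
#' @param estimate An adjusted \code{nsum_estimate}.
#' @param config An \code{nsum_config} (supplies \code{t}).
#' @param per Positive integer scale, e.g. 1000 or 100000.
#' @return A single number, \code{e_adjusted / t * per}.
#' @export
prevalence <- function(estimate, config, per = 1000) {
  stopifnot(inherits(estimate, "nsum_estimate"), inherits(config, "nsum_config"))
  if (length(per) != 1L || !is.finite(per) || per <= 0) {
    stop("'per' must be a single positive number", call. = FALSE)
  }
  if (is.na(estimate$e_adjusted)) {
    stop("apply_adjustments() first: e_adjusted is not set", call. = FALSE)
  }
  estimate$e_adjusted / config$t * per
}

#' Sample size for a prevalence survey
#'
#' The usual closed form for estimating a proportion \code{p} to within
#' absolute error \code{d} at a given confidence level,
#' \deqn{n = \lceil z^2 p (1 - p) / d^2 \rceil,}
#' with \code{z} the standard-normal quantile at \code{(1 + confidence)/2},
#' inflated for anticipated nonresponse. Two inflation conventions are in
#' common use: multiplying by \code{1 + nonresponse} (default) or dividing
#' by \code{1 - nonresponse}.
#'
#' @param p Anticipated prevalence, in (0, 1).
#' @param d Absolute sampling error (half-width), > 0.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param nonresponse Anticipated nonresponse proportion in [0, 1).
#' @param convention \code{"multiply"} (n × (1 + nr)) or \code{"divide"}
#'   (n / (1 - nr)).
#' @return The required number of respondents (integer).
#' @examples
#' required_sample_size(p = 0.015, d = 0.008, confidence = 0.95,
#'                      nonresponse = 0.10)
#' @export
required_sample_size <- function(p, d, confidence = 0.95, nonresponse = 0,
                                 convention = c("multiply", "divide")) {
  convention <- match.arg(convention)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (!is.finite(d) || d <= 0) stop("d must be positive", call. = FALSE)
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  if (!is.finite(nonresponse) || nonresponse < 0 || nonresponse >= 1) {
    stop("nonresponse must be in [0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  n0 <- ceiling(z^2 * p * (1 - p) / d^2)
  n <- switch(convention,
    multiply = n0 * (1 + nonresponse),
    divide = n0 / (1 - nonresponse)
  )
  as.integer(ceiling(n))
}

#' @export
print.nsum_estimate <- function(x, ...) {
  cat("Network scale-up estimate\n")
  cat(sprintf("  respondents: %d male, %d female\n", x$n_male, x$n_female))
  cat(sprintf("  sum m = %d, sum c = %g, t = %s\n", x$sum_m, x$sum_c,
              format(x$t, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  crude estimate:          %8.0f\n", x$e_crude))
  if (!is.na(x$e_adjusted)) {
    cat(sprintf("  adjusted for visibility: %8.0f  (VF = %.4f)\n",
                x$e_vf, x$vf_point))
    cat(sprintf("  adjusted for popularity: %8.0f  (PF = %.4f)\n",
                x$e_pf, x$pf_point))
    cat(sprintf("  fully adjusted:          %8.0f\n", x$e_adjusted))
    cat(sprintf("  prevalence per 1000:     %8.2f\n", x$prevalence_per_1000))
  }
  invisible(x)
}
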