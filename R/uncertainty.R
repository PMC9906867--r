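# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

new_uncertainty <- function(method, point, draws, percentiles, seed,
                            keep_draws) {
  qs <- stats::quantile(draws, probs = percentiles / 100, names = FALSE)
  res <- list(
    method = method,
    point = point,
    lower = qs[1],
    upper = qs[2],
    level_low = percentiles[1],
    level_high = percentiles[2],
    n_replicates = length(draws),
    seed = seed,
    draws = if (keep_draws) draws else NULL
  )
  class(res) <- "nsum_uncertainty"
  res
}

check_percentiles <- function(percentiles) {
  if (length(percentiles) != 2L || any(!is.finite(percentiles)) ||
      any(percentiles < 0) || any(percentiles > 100) ||
      percentiles[1] >= percentiles[2]) {
    stop("percentiles must be an increasing pair within [0, 100]", call. = FALSE)
  }
  percentiles
}

#' Monte Carlo uncertainty interval for the adjusted estimate
#'
#' Propagates sampling noise (and optionally correction-factor uncertainty)
#' through the scale-up estimator by parametric simulation. Per replicate:
#' \itemize{
#'   \item the total alter count is drawn as
#'     \eqn{\sum m^* \sim \mathrm{Poisson}(\sum m_{obs})};
#'   \item the total network size is drawn as the sum of two Poisson
#'     variables with means \eqn{n_{male} c_{male}} and
#'     \eqn{n_{female} c_{female}} (equivalent to summing independent
#'     per-respondent Poisson degrees, implemented as aggregate draws);
#'   \item when \code{sample_factors = TRUE}, the visibility and popularity
#'     factors are drawn uniformly over their configured ranges; otherwise
#'     the point factors are used;
#'   \item the replicate estimate is
#'     \eqn{e^* = \sum m^* / \sum c^* \times t \times VF^* \times PF^*}.
#' }
#' The interval is the requested percentile pair of the replicate estimates.
#' Results are reproducible for a fixed seed.
#'
#' @param respondents An \code{nsum_survey} data frame.
#' @param config An \code{nsum_config}.
#' @param n_replicates Number of replicates (at least 100); default 10,000.
#' @param percentiles Increasing pair in [0, 100]; default \code{c(2.5, 97.5)}.
#' @param sample_factors Draw VF and PF uniformly over their ranges (TRUE,
#'   default) or hold them at their point values (FALSE).
#' @param seed Integer seed recorded in the result; the caller's RNG state
#'   is left untouched.
#' @param keep_draws Keep the replicate estimates in the result (default TRUE).
#' @return An object of class \code{nsum_uncertainty} with fields
#'   \code{method, point, lower, upper, level_low, level_high, n_replicates,
#'   seed, draws}.
#' @export
monte_carlo_interval <- function(respondents, config,
                                 n_replicates = 10000,
                                 percentiles = c(2.5, 97.5),
                                 sample_factors = TRUE,
                                 seed = 1L,
                                 keep_draws = TRUE) {
  stopifnot(inherits(respondents, "nsum_survey"), inherits(config, "nsum_config"))
  if (length(n_replicates) != 1L || !is.finite(n_replicates) || n_replicates < 100) {
    stop("n_replicates must be at least 100", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  check_percentiles(percentiles)
  est <- apply_adjustments(suppressWarnings(crude_estimate(respondents, config)),
                           config)
  mean_c_male <- est$n_male * config$c_male
  mean_c_female <- est$n_female * config$c_female
  draws <- with_seed(seed, {
    m_star <- stats::rpois(n_replicates, est$sum_m)
    c_star <- stats::rpois(n_replicates, mean_c_male) +
      stats::rpois(n_replicates, mean_c_female)
    if (sample_factors) {
      vf <- stats::runif(n_replicates, config$vf_range[1], config$vf_range[2])
      pf <- stats::runif(n_replicates, config$pf_range[1], config$pf_range[2])
    } else {
      vf <- config$vf_point
      pf <- config$pf_point
    }
    m_star / c_star * config$t * vf * pf
  })
  new_uncertainty("monte_carlo", est$e_adjusted, draws, percentiles,
                  seed, keep_draws)
}

#' Bootstrap uncertainty interval for the adjusted estimate
#'
#' Nonparametric percentile bootstrap: respondents are resampled with
#' replacement — by default within gender strata, preserving the male/female
#' split because degrees are gender-specific — and the fully adjusted
#' estimate is recomputed per replicate with the point correction factors.
#'
#' @param respondents An \code{nsum_survey} with at least 2 rows.
#' @param config An \code{nsum_config}.
#' @param n_replicates Number of bootstrap replicates; default 10,000.
#' @param percentiles Increasing pair in [0, 100]; default \code{c(2.5, 97.5)}.
#' @param stratify_by_gender Resample within gender (default TRUE); FALSE
#'   resamples the whole table.
#' @param seed Integer seed recorded in the result.
#' @param keep_draws Keep replicate estimates in the result (default TRUE).
#' @return An \code{nsum_uncertainty} object.
#' @export
bootstrap_interval <- function(respondents, config,
                               n_replicates = 10000,
                               percentiles = c(2.5, 97.5),
                               stratify_by_gender = TRUE,
                               seed = 1L,
                               keep_draws = TRUE) {
  stopifnot(inherits(respondents, "nsum_survey"), inherits(config, "nsum_config"))
  if (nrow(respondents) < 2L) {
    stop("bootstrap needs at least 2 respondents", call. = FALSE)
  }
  if (length(n_replicates) != 1L || !is.finite(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be positive", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  check_percentiles(percentiles)
  est <- apply_adjustments(suppressWarnings(crude_estimate(respondents, config)),
                           config)
  factor_prod <- config$vf_point * config$pf_point

  m <- respondents$m
  is_male <- respondents$gender == "male"
  draws <- with_seed(seed, {
    if (stratify_by_gender && any(is_male) && any(!is_male)) {
      m_male <- m[is_male]
      m_female <- m[!is_male]
      n_mal <- length(m_male)
      n_fem <- length(m_female)
      # sum_c is invariant under stratified resampling: strata sizes fixed
      sum_c <- n_mal * config$c_male + n_fem * config$c_female
      vapply(seq_len(n_replicates), function(i) {
        sm <- sum(m_male[sample.int(n_mal, n_mal, replace = TRUE)]) +
          sum(m_female[sample.int(n_fem, n_fem, replace = TRUE)])
        sm / sum_c * config$t * factor_prod
      }, numeric(1))
    } else {
      n <- length(m)
      c_i <- ifelse(is_male, config$c_male, config$c_female)
      vapply(seq_len(n_replicates), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        sum(m[idx]) / sum(c_i[idx]) * config$t * factor_prod
      }, numeric(1))
    }
  })
  new_uncertainty("bootstrap", est$e_adjusted, draws, percentiles,
                  seed, keep_draws)
}

#' @export
print.nsum_uncertainty <- function(x, ...) {
  cat(sprintf("%s uncertainty interval (%d replicates, seed %s)\n",
              switch(x$method, monte_carlo = "Monte Carlo",
                     bootstrap = "Bootstrap", x$method),
              x$n_replicates, format(x$seed)))
  cat(sprintf("  point %.1f, [%g%%, %g%%] interval: %.1f - %.1f\n",
              x$point, x$level_low, x$level_high, x$lower, x$upper))
  invisible(x)
}
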