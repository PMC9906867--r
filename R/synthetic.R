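# Demographic marginals used to dress generated records. Respondent
# marginals emulate a gender-balanced street-intercept sample of adults;
# alter marginals emulate the reported profile of hidden-population
# members (younger, mostly unmarried, mostly educated below diploma).
.resp_marginals <- list(
  age_group = c("18-29" = 315, "30-44" = 387, "45-65" = 299),
  education = c("illiterate" = 62, "elementary" = 91, "guidance" = 191,
                "diploma_plus" = 656),
  marital_status = c("single" = 313, "married" = 669, "divorced_widow" = 18)
)
.alter_marginals <- list(
  age_group = c("18-29" = 259, "30-44" = 155, "45-65" = 20),
  education = c("illiterate" = 11, "elementary" = 46, "guidance" = 206,
                "diploma_plus" = 171),
  marital_status = c("single" = 145, "married" = 121, "divorced" = 132,
                     "widow" = 36),
  n_children = c("0" = 243, "1" = 101, "2" = 71, "3_plus" = 19),
  p_alcohol = 126 / 434,
  p_prison = 22 / 434,
  p_drug = 64 / 434
)

sample_marginal <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Ground truth for a simulated scale-up survey
#'
#' Describes a synthetic population and survey design with the statistical
#' structure the scale-up estimator assumes, plus its two classic
#' violations: a visibility (transparency) barrier — each hidden-population
#' alter's status is known to the respondent only with probability
#' \code{visibility} — and a popularity (barrier) effect — hidden-population
#' members have \code{popularity_ratio} times the general-population degree.
#'
#' Defaults mirror the street-intercept study the package's examples are
#' built around: a reference population of 406,916 adult women, 495 male
#' and 505 female respondents with degrees 90 and 120, visibility 0.45,
#' popularity ratio 0.77, and a true hidden-population size of 4850.
#'
#' @param t Reference population total.
#' @param k_true True hidden-population size (at most \code{t}).
#' @param n_male,n_female Respondent counts by gender.
#' @param c_male,c_female Personal network sizes by gender.
#' @param visibility Probability in (0, 1] that an alter's
#'   hidden-population membership is known to the respondent.
#' @param popularity_ratio Hidden-population degree relative to the general
#'   population (positive; < 1 means smaller networks).
#' @param seed Default integer seed used by \code{\link{generate_survey}}.
#' @return An object of class \code{nsum_truth}.
#' @export
synthetic_truth <- function(t = 406916,
                            k_true = 4850,
                            n_male = 495,
                            n_female = 505,
                            c_male = 90,
                            c_female = 120,
                            visibility = 0.45,
                            popularity_ratio = 0.77,
                            seed = 1L) {
  truth <- list(
    t = as.numeric(t), k_true = as.numeric(k_true),
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    c_male = as.numeric(c_male), c_female = as.numeric(c_female),
    visibility = as.numeric(visibility),
    popularity_ratio = as.numeric(popularity_ratio),
    seed = as.integer(seed)
  )
  if (truth$t <= 0 || truth$k_true < 0 || truth$k_true > truth$t) {
    stop("k_true must lie in [0, t] and t must be positive", call. = FALSE)
  }
  if (truth$n_male < 0 || truth$n_female < 0 ||
      truth$n_male + truth$n_female == 0L) {
    stop("at least one respondent is required", call. = FALSE)
  }
  if (truth$c_male <= 0 || truth$c_female <= 0) {
    stop("degrees must be positive", call. = FALSE)
  }
  if (truth$visibility <= 0 || truth$visibility > 1) {
    stop("visibility must be in (0, 1]", call. = FALSE)
  }
  if (truth$popularity_ratio <= 0) {
    stop("popularity_ratio must be positive", call. = FALSE)
  }
  if (truth$k_true / truth$t * truth$popularity_ratio > 1) {
    stop("alter probability (k_true/t * popularity_ratio) exceeds 1", call. = FALSE)
  }
  class(truth) <- "nsum_truth"
  truth
}

#' Generate a synthetic scale-up survey
#'
#' Simulates the observed data of an aggregated-relational-data survey from
#' a known ground truth. Per respondent of gender \code{g}, the true number
#' of hidden-population alters is
#' \deqn{m_{true} \sim \mathrm{Binomial}(\mathrm{round}(c_g),\;
#'   p = (k_{true}/t)\,\mathrm{popularity\_ratio}),}
#' and the reported count is thinned by the visibility barrier,
#' \eqn{m \sim \mathrm{Binomial}(m_{true}, \mathrm{visibility})}. One alter
#' record is generated per reported alter, with demographics drawn
#' independently from fixed categorical marginals (no joint structure is
#' modelled). Deterministic for a fixed seed.
#'
#' @param truth An \code{nsum_truth} object.
#' @param seed Integer seed; defaults to \code{truth$seed}.
#' @param alters Also generate the alter-level table (default TRUE).
#' @return A list with elements \code{respondents} (an \code{nsum_survey}),
#'   \code{alters} (an \code{nsum_alters}, or NULL when no alters were
#'   reported or \code{alters = FALSE}), and \code{truth}.
#' @examples
#' sim <- generate_survey(synthetic_truth(k_true = 5000, seed = 7))
#' sum(sim$respondents$m)
#' @export
generate_survey <- function(truth, seed = truth$seed, alters = TRUE) {
  stopifnot(inherits(truth, "nsum_truth"))
  p <- truth$k_true / truth$t * truth$popularity_ratio
  n <- truth$n_male + truth$n_female
  gender <- c(rep("male", truth$n_male), rep("female", truth$n_female))
  deg <- ifelse(gender == "male", round(truth$c_male), round(truth$c_female))
  sim <- with_seed(seed, {
    m_true <- stats::rbinom(n, size = deg, prob = p)
    m_obs <- stats::rbinom(n, size = m_true, prob = truth$visibility)
    resp <- survey_respondents(
      id = sprintf("r%04d", seq_len(n)),
      gender = gender,
      m = m_obs,
      age_group = sample_marginal(n, .resp_marginals$age_group),
      education = sample_marginal(n, .resp_marginals$education),
      marital_status = sample_marginal(n, .resp_marginals$marital_status)
    )
    alt <- NULL
    total_alters <- sum(m_obs)
    if (alters && total_alters > 0L) {
      alt <- alter_records(
        respondent_id = rep(resp$id, m_obs),
        age_group = sample_marginal(total_alters, .alter_marginals$age_group),
        education = sample_marginal(total_alters, .alter_marginals$education),
        marital_status = sample_marginal(total_alters,
                                         .alter_marginals$marital_status),
        n_children = sample_marginal(total_alters, .alter_marginals$n_children),
        ever_alcohol = stats::runif(total_alters) < .alter_marginals$p_alcohol,
        ever_prison = stats::runif(total_alters) < .alter_marginals$p_prison,
        ever_drug = stats::runif(total_alters) < .alter_marginals$p_drug,
        respondents = resp
      )
    }
    list(respondents = resp, alters = alt)
  })
  sim$truth <- truth
  sim
}

#' Configuration matching a synthetic ground truth
#'
#' Builds the \code{\link{network_config}} whose correction factors exactly
#' undo the truth's distortions: \code{vf_point = 1/visibility} and
#' \code{pf_point = 1/popularity_ratio} (ranges collapsed to the points).
#'
#' @param truth An \code{nsum_truth} object.
#' @return An \code{nsum_config}.
#' @export
config_from_truth <- function(truth) {
  stopifnot(inherits(truth, "nsum_truth"))
  vf <- 1 / truth$visibility
  pf <- 1 / truth$popularity_ratio
  network_config(
    c_male = truth$c_male, c_female = truth$c_female, t = truth$t,
    vf_point = vf, vf_range = c(vf, vf),
    pf_point = pf, pf_range = c(pf, pf)
  )
}

#' Parameter-recovery experiment for the estimator chain
#'
#' Validation harness: repeatedly simulate a survey from a known truth, run
#' the full estimation chain (crude estimate, then corrections with
#' \code{vf_point = 1/visibility}, \code{pf_point = 1/popularity_ratio}),
#' and compare the fully adjusted estimate to the true hidden-population
#' size. Also records, per simulation, whether the Monte Carlo interval
#' (point factors held fixed) covers the truth.
#'
#' @param truth An \code{nsum_truth} object.
#' @param n_simulations Number of simulated surveys (at least 50).
#' @param seed Integer base seed; simulation \code{i} uses \code{seed + i}.
#' @param mc_replicates Monte Carlo replicates per simulation for the
#'   coverage check; set to 0 to skip interval computation.
#' @param percentiles Interval percentiles; default \code{c(2.5, 97.5)}.
#' @return An object of class \code{nsum_recovery}: \code{k_true},
#'   \code{n_simulations}, \code{mean_estimate}, \code{bias},
#'   \code{relative_bias}, \code{coverage} (NA when skipped), and the
#'   per-simulation \code{estimates}.
#' @export
recover_parameters <- function(truth, n_simulations = 200, seed = 1L,
                               mc_replicates = 1000,
                               percentiles = c(2.5, 97.5)) {
  stopifnot(inherits(truth, "nsum_truth"))
  if (n_simulations < 50) {
    stop("n_simulations must be at least 50", call. = FALSE)
  }
  cfg <- config_from_truth(truth)
  estimates <- numeric(n_simulations)
  covered <- logical(n_simulations)
  for (i in seq_len(n_simulations)) {
    sim_seed <- as.integer(seed) + i
    sim <- generate_survey(truth, seed = sim_seed, alters = FALSE)
    est <- apply_adjustments(
      suppressWarnings(crude_estimate(sim$respondents, cfg)), cfg)
    estimates[i] <- est$e_adjusted
    if (mc_replicates > 0) {
      ui <- monte_carlo_interval(sim$respondents, cfg,
                                 n_replicates = mc_replicates,
                                 percentiles = percentiles,
                                 sample_factors = FALSE,
                                 seed = sim_seed, keep_draws = FALSE)
      covered[i] <- ui$lower <= truth$k_true && truth$k_true <= ui$upper
    }
  }
  res <- list(
    k_true = truth$k_true,
    n_simulations = n_simulations,
    mean_estimate = mean(estimates),
    bias = mean(estimates) - truth$k_true,
    relative_bias = (mean(estimates) - truth$k_true) / truth$k_true,
    coverage = if (mc_replicates > 0) mean(covered) else NA_real_,
    estimates = estimates
  )
  class(res) <- "nsum_recovery"
  res
}

#' @export
print.nsum_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulations (true size %g)\n",
              x$n_simulations, x$k_true))
  cat(sprintf("  mean adjusted estimate: %.1f\n", x$mean_estimate))
  cat(sprintf("  bias: %.1f (relative %.2f%%)\n", x$bias, 100 * x$relative_bias))
  if (!is.na(x$coverage)) {
    cat(sprintf("  Monte Carlo interval coverage of truth: %.1f%%\n",
                100 * x$coverage))
  }
  invisible(x)
}
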