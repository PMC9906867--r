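test_that("Monte Carlo interval is seed-reproducible and leaves the RNG alone", {
  s <- study_survey()
  cfg <- study_config()
  set.seed(999)
  before <- .Random.seed
  a <- monte_carlo_interval(s, cfg, n_replicates = 500, seed = 7)
  expect_identical(before, .Random.seed)
  b <- monte_carlo_interval(s, cfg, n_replicates = 500, seed = 7)
  expect_identical(a, b)
  c_ <- monte_carlo_interval(s, cfg, n_replicates = 500, seed = 8)
  expect_false(identical(a$draws, c_$draws))
  expect_equal(a$seed, 7)
  expect_equal(a$n_replicates, 500L)
  expect_lte(a$lower, a$upper)
})

test_that("fixed-factor Monte Carlo interval matches the delta-method oracle", {
  # e* = m*/c* x const with m* ~ Pois(434), c* ~ Pois(105150):
  # CV^2 = 1/434 + 1/105150, interval ~ point * (1 +/- 1.96 CV)
  s <- study_survey()
  cfg <- study_config()
  ui <- monte_carlo_interval(s, cfg, n_replicates = 20000,
                             sample_factors = FALSE, seed = 31)
  cv <- sqrt(1 / 434 + 1 / 105150)
  expect_equal(ui$lower, ui$point * (1 - 1.96 * cv), tolerance = 0.02)
  expect_equal(ui$upper, ui$point * (1 + 1.96 * cv), tolerance = 0.02)
})

test_that("Monte Carlo replicate mean converges to the point estimate", {
  s <- study_survey()
  cfg <- study_config()
  ui <- monte_carlo_interval(s, cfg, n_replicates = 10000,
                             sample_factors = FALSE, seed = 13)
  se <- sd(ui$draws) / sqrt(ui$n_replicates)
  expect_lt(abs(mean(ui$draws) - ui$point), 3 * se)
})

test_that("interval width collapses in the degenerate-variance limit", {
  # scale sums up by 1e6 with a fixed ratio: Poisson CVs vanish
  n_scale <- 4000L
  big <- survey_respondents(
    id = sprintf("b%05d", 1:n_scale),
    gender = rep(c("male", "female"), n_scale / 2),
    m = rep(109L, n_scale)  # sum m = 436,000
  )
  cfg_small <- network_config()
  small <- survey_respondents(id = c("x", "y"), gender = c("male", "female"),
                              m = c(2L, 2L))
  ui_small <- monte_carlo_interval(small, cfg_small, n_replicates = 2000,
                                   sample_factors = FALSE, seed = 5)
  ui_big <- monte_carlo_interval(big, cfg_small, n_replicates = 2000,
                                 sample_factors = FALSE, seed = 5)
  rel_width <- function(u) (u$upper - u$lower) / u$point
  expect_lt(rel_width(ui_big), 0.02)
  expect_lt(rel_width(ui_big), rel_width(ui_small) / 10)
})

test_that("replicate alter totals are Poisson (chi-square goodness of fit)", {
  # tiny mean: 3 reporters among 1000 respondents; the network-size draw has
  # CV ~0.3% so each replicate's m* is recoverable from e* by rounding
  m <- integer(1000); m[c(1, 2, 500)] <- 1L
  s <- survey_respondents(id = sprintf("g%04d", 1:1000),
                          gender = rep(c("male", "female"), c(495, 505)),
                          m = m)
  cfg <- study_config()
  ui <- monte_carlo_interval(s, cfg, n_replicates = 10000,
                             sample_factors = FALSE, seed = 201)
  unit <- cfg$t * cfg$vf_point * cfg$pf_point / 105150
  m_star <- round(ui$draws / unit)
  kmax <- 9
  obs <- tabulate(pmin(m_star, kmax) + 1L, nbins = kmax + 1L)
  p <- c(dpois(0:(kmax - 1), 3), 1 - ppois(kmax - 1, 3))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("Monte Carlo contract errors fire", {
  s <- study_survey(); cfg <- study_config()
  expect_error(monte_carlo_interval(s, cfg, n_replicates = 10), "at least 100")
  expect_error(monte_carlo_interval(s, cfg, percentiles = c(97.5, 2.5)),
               "increasing pair")
  expect_error(monte_carlo_interval(s, cfg, percentiles = c(-5, 50)),
               "increasing pair")
})

test_that("bootstrap interval is seed-reproducible with zero variance when m is constant", {
  cfg <- study_config()
  s_const <- survey_respondents(id = sprintf("c%03d", 1:100),
                                gender = rep(c("male", "female"), 50),
                                m = rep(2L, 100))
  ui <- bootstrap_interval(s_const, cfg, n_replicates = 300, seed = 3)
  expect_equal(ui$lower, ui$point, tolerance = 1e-12)
  expect_equal(ui$upper, ui$point, tolerance = 1e-12)

  s <- study_survey()
  a <- bootstrap_interval(s, cfg, n_replicates = 300, seed = 5)
  b <- bootstrap_interval(s, cfg, n_replicates = 300, seed = 5)
  expect_identical(a, b)
  expect_error(bootstrap_interval(s[1, ], cfg), "at least 2")
})

test_that("stratified and unstratified bootstrap both centre on the point estimate", {
  s <- study_survey()
  cfg <- study_config()
  strat <- bootstrap_interval(s, cfg, n_replicates = 1000, seed = 17,
                              stratify_by_gender = TRUE)
  unstrat <- bootstrap_interval(s, cfg, n_replicates = 1000, seed = 17,
                                stratify_by_gender = FALSE)
  for (ui in list(strat, unstrat)) {
    expect_lt(ui$lower, ui$point)
    expect_gt(ui$upper, ui$point)
  }
})

test_that("Monte Carlo width shrinks stochastically with survey size at fixed ratio", {
  cfg <- network_config()
  make <- function(n, m_each) {
    survey_respondents(id = sprintf("s%05d", 1:n),
                       gender = rep(c("male", "female"), n / 2),
                       m = rep(m_each, n))
  }
  widths <- sapply(1:3, function(i) {
    n <- c(100L, 1000L, 10000L)[i]
    ui <- monte_carlo_interval(make(n, 1L), cfg, n_replicates = 1000,
                               sample_factors = FALSE, seed = 77)
    (ui$upper - ui$lower) / ui$point
  })
  expect_true(all(diff(widths) < 0))
})
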