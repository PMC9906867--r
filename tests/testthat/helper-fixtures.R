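# Shared fixtures, built in code.

# Survey matching the published aggregates: 495 men / 505 women, 434
# reported hidden-population alters in total. Only the aggregates matter to
# the estimator; the ones are spread across both genders.
study_survey <- function() {
  m <- integer(1000)
  m[c(1:215, 496:714)] <- 1L  # 215 male + 219 female reporters = 434
  survey_respondents(
    id = sprintf("p%04d", 1:1000),
    gender = rep(c("male", "female"), c(495, 505)),
    m = m
  )
}

study_config <- function() network_config()

# Alter table whose marginals equal the published alter demographics
# (434 records; e.g. 145 single, 206 guidance-level education).
study_alters <- function() {
  alter_records(
    respondent_id = sprintf("a%03d", 1:434),
    age_group = rep(c("18-29", "30-44", "45-65"), c(259, 155, 20)),
    education = rep(c("illiterate", "elementary", "guidance", "diploma_plus"),
                    c(11, 46, 206, 171)),
    marital_status = rep(c("single", "married", "divorced", "widow"),
                         c(145, 121, 132, 36)),
    n_children = rep(c("0", "1", "2", "3_plus"), c(243, 101, 71, 19)),
    ever_alcohol = rep(c(TRUE, FALSE), c(126, 308)),
    ever_prison = rep(c(TRUE, FALSE), c(22, 412)),
    ever_drug = rep(c(TRUE, FALSE), c(64, 370))
  )
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Small survey for contract tests.
toy_survey <- function() {
  survey_respondents(
    id = letters[1:6],
    gender = c("male", "male", "male", "female", "female", "female"),
    m = c(0L, 1L, 2L, 0L, 3L, 1L),
    age_group = c("18-29", NA, "30-44", "45-65", "18-29", NA),
    education = c("diploma_plus", "guidance", NA, "elementary", "illiterate", NA),
    marital_status = c("single", "married", NA, "divorced_widow", "single", NA)
  )
}
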