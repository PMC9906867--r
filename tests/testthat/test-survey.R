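test_that("read_survey parses valid rows and totals m", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,gender,age_group,education,marital_status,m",
    "r1,male,18-29,diploma_plus,single,0",
    "r2,Female,30-44,,married,3"
  ), path)
  s <- read_survey(path)
  expect_s3_class(s, "nsum_survey")
  expect_equal(nrow(s), 2L)
  expect_equal(sum(s$m), 3L)
  expect_equal(as.character(s$gender), c("male", "female"))
  expect_true(is.na(s$education[2]))
})

test_that("read_survey rejects bad input with addressed diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,gender,m", "r1,male,2", "r2,female,-1"), path)
  expect_error(read_survey(path), "row 2")

  writeLines(c("id,gender,m", "r1,male,1.5"), path)
  expect_error(read_survey(path), "nonnegative integer")

  writeLines(c("id,gender", "r1,male"), path)
  expect_error(read_survey(path), "missing required column")

  writeLines(c("id,gender,m", "r1,unicorn,1"), path)
  expect_error(read_survey(path), "unrecognized category")

  expect_error(read_survey(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("read_survey honours a column-name schema map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,sex,fsw_count", "r1,M,2"), path)
  s <- read_survey(path, schema = c(id = "pid", gender = "sex", m = "fsw_count"))
  expect_equal(s$id, "r1")
  expect_equal(as.character(s$gender), "male")
  expect_equal(s$m, 2L)
  expect_error(read_survey(path, schema = c(m = "absent_col")), "absent")
})

test_that("survey CSV round-trip is the identity, including missing fields", {
  s <- toy_survey()
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(s, path)
  expect_equal(read_survey(path), s)

  # every optional field empty
  s2 <- survey_respondents(id = "solo", gender = "female", m = 0L)
  write_survey(s2, path)
  expect_equal(read_survey(path), s2)

  sim <- generate_survey(synthetic_truth(seed = 11))
  write_survey(sim$respondents, path)
  expect_equal(read_survey(path), sim$respondents)
  expect_equal(length(readLines(path)), nrow(sim$respondents) + 1L)

  expect_error(write_survey(s[0, ], path), "empty")
})

test_that("alter records validate against the respondent table", {
  s <- toy_survey()
  a <- alter_records(respondent_id = c("b", "c", "c"),
                     marital_status = c("single", "widow", "divorced"),
                     respondents = s)
  expect_s3_class(a, "nsum_alters")
  expect_error(
    alter_records(respondent_id = "zz", respondents = s),
    "unknown respondent"
  )
  # respondent 'a' reported m = 0, so no alter rows are allowed for it
  expect_error(
    alter_records(respondent_id = c("a"), respondents = s),
    "more alter records than reported m"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_alters(a, path)
  expect_equal(read_alters(path, respondents = s), a)
})

test_that("demographic tabulation matches the published alter table cells", {
  tab <- summarize_demographics(study_alters())
  cell <- function(var, cat) tab[tab$variable == var & tab$category == cat, ]
  single <- cell("marital_status", "single")
  expect_equal(single$count, 145L)
  expect_equal(single$percent, 33.4, tolerance = 0.15 / 33.4)
  guidance <- cell("education", "guidance")
  expect_equal(guidance$count, 206L)
  expect_equal(guidance$percent, 47.5, tolerance = 0.15 / 47.5)
  age <- cell("age_group", "18-29")
  expect_equal(age$percent, 59.7, tolerance = 0.15 / 59.7)
})

test_that("demographic tabulation matches the respondent gender split", {
  s <- study_survey()
  tab <- summarize_demographics(s, "gender")
  expect_equal(tab$count[tab$category == "female"], 505L)
  expect_equal(tab$percent[tab$category == "female"], 50.5)
  expect_equal(tab$percent[tab$category == "male"], 49.5)
})

test_that("a single record tabulates at 100 percent", {
  s <- survey_respondents(id = "x", gender = "male", m = 0L)
  tab <- summarize_demographics(s, "gender")
  expect_equal(tab$percent[tab$category == "male"], 100.0)
})

test_that("tabulation errors on unknown variables", {
  expect_error(summarize_demographics(toy_survey(), "shoe_size"),
               "unknown variable")
})

test_that("per-variable counts sum to non-missing totals and percents to ~100", {
  set.seed(401)
  for (i in 1:5) {
    sim <- generate_survey(synthetic_truth(k_true = 5000, seed = 500 + i))
    for (denom in c("all", "nonmissing")) {
      tab <- summarize_demographics(sim$respondents,
                                    percent_denominator = denom)
      for (v in unique(tab$variable)) {
        sub <- tab[tab$variable == v, ]
        expect_equal(sum(sub$count), sum(!is.na(sim$respondents[[v]])))
        if (denom == "nonmissing" || !anyNA(sim$respondents[[v]])) {
          expect_lt(abs(sum(sub$percent) - 100), 0.1 * nrow(sub) + 1e-9)
        }
      }
    }
  }
})

test_that("percent denominator switch changes only tables with missing values", {
  s <- toy_survey()  # education missing for 2 of 6
  all_tab <- summarize_demographics(s, "education", percent_denominator = "all")
  nm_tab <- summarize_demographics(s, "education",
                                   percent_denominator = "nonmissing")
  expect_equal(sum(all_tab$percent), round(100 * 4 / 6, 1), tolerance = 0.01)
  expect_lt(abs(sum(nm_tab$percent) - 100), 0.2)
})
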