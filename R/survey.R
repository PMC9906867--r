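#' @importFrom utils read.csv write.csv
NULL

# Canonical category levels for the two record types. Respondent marital
# status collapses divorced/widow into one category (as interviewed), while
# alter records keep them separate (as reported about network members).
.nsum_levels <- list(
  gender = c("male", "female"),
  age_group = c("18-29", "30-44", "45-65"),
  education = c("illiterate", "elementary", "guidance", "diploma_plus"),
  marital_status = c("single", "married", "divorced_widow"),
  marital_status_alter = c("single", "married", "divorced", "widow"),
  n_children = c("0", "1", "2", "3_plus")
)

# Case-insensitive aliases accepted on input, mapped to canonical levels.
.nsum_aliases <- c(
  "m" = "male", "f" = "female", "man" = "male", "woman" = "female",
  "18–29" = "18-29", "30–44" = "30-44", "45–65" = "45-65",
  "18_29" = "18-29", "30_44" = "30-44", "45_65" = "45-65",
  "diploma+" = "diploma_plus", "diploma & higher" = "diploma_plus",
  "diploma and higher" = "diploma_plus", "diploma" = "diploma_plus",
  "divorced/widow" = "divorced_widow", "divorced or widow" = "divorced_widow",
  "no child" = "0", "none" = "0", "one" = "1", "two" = "2",
  ">=3" = "3_plus", "3+" = "3_plus", "≥ 3" = "3_plus"
)

normalize_category <- function(x, levels) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  hit <- x %in% names(.nsum_aliases)
  x[hit] <- .nsum_aliases[x[hit]]
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("unrecognized category value(s): %s (expected one of %s)",
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

parse_logical_col <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognized logical value(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Construct a respondent-level survey table
#'
#' One row per interviewee, carrying gender (which selects the applicable
#' personal network size), optional demographics, and \code{m}, the number of
#' hidden-population members (here, female sex workers) the respondent
#' reports knowing in their social network.
#'
#' @param id Character vector of unique respondent identifiers.
#' @param gender \code{"male"}/\code{"female"} (case-insensitive; aliases
#'   like \code{"M"} accepted).
#' @param m Nonnegative integer counts of hidden-population alters known.
#' @param age_group Optional: \code{"18-29"}, \code{"30-44"}, \code{"45-65"}.
#' @param education Optional: \code{"illiterate"}, \code{"elementary"},
#'   \code{"guidance"}, \code{"diploma_plus"}.
#' @param marital_status Optional: \code{"single"}, \code{"married"},
#'   \code{"divorced_widow"}.
#' @return A \code{data.frame} of class \code{nsum_survey}.
#' @examples
#' survey_respondents(id = c("a", "b"), gender = c("male", "female"),
#'                    m = c(0, 3))
#' @export
survey_respondents <- function(id, gender, m,
                               age_group = NA, education = NA,
                               marital_status = NA) {
  n <- length(id)
  if (n == 0L) stop("at least one respondent is required", call. = FALSE)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("respondent ids must be unique", call. = FALSE)
  chr <- function(x) rep_len(as.character(x), n)
  df <- data.frame(
    id = id,
    gender = normalize_category(chr(gender), .nsum_levels$gender),
    age_group = normalize_category(chr(age_group), .nsum_levels$age_group),
    education = normalize_category(chr(education), .nsum_levels$education),
    marital_status = normalize_category(chr(marital_status),
                                        .nsum_levels$marital_status),
    m = check_m(rep_len(m, n)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$gender)) {
    stop(sprintf("gender is required for every respondent (missing at row %s)",
                 paste(which(is.na(df$gender)), collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("nsum_survey", "data.frame")
  df
}

check_m <- function(m) {
  m_num <- suppressWarnings(as.numeric(m))
  bad <- is.na(m_num) | m_num < 0 | m_num != round(m_num)
  if (any(bad)) {
    stop(sprintf("m must be a nonnegative integer; invalid at row %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  as.integer(m_num)
}

#' Construct an alter-level table of reported hidden-population members
#'
#' One row per alter (a hidden-population member present in some
#' respondent's network), carrying the demographics the respondent reported
#' about them. The number of alter rows per respondent may not exceed that
#' respondent's \code{m}.
#'
#' @param respondent_id Identifier of the reporting respondent.
#' @param age_group,education Optional categorical demographics (same levels
#'   as the respondent table).
#' @param marital_status Optional: \code{"single"}, \code{"married"},
#'   \code{"divorced"}, \code{"widow"}.
#' @param n_children Optional: \code{"0"}, \code{"1"}, \code{"2"},
#'   \code{"3_plus"}.
#' @param ever_alcohol,ever_prison,ever_drug Optional logicals: lifetime
#'   history of alcohol use, imprisonment, drug use.
#' @param respondents Optional \code{nsum_survey} to validate against: every
#'   \code{respondent_id} must exist there and per-respondent alter counts
#'   must not exceed \code{m}.
#' @return A \code{data.frame} of class \code{nsum_alters}.
#' @export
alter_records <- function(respondent_id,
                          age_group = NA, education = NA,
                          marital_status = NA, n_children = NA,
                          ever_alcohol = NA, ever_prison = NA,
                          ever_drug = NA,
                          respondents = NULL) {
  n <- length(respondent_id)
  if (n == 0L) stop("at least one alter record is required", call. = FALSE)
  chr <- function(x) rep_len(as.character(x), n)
  df <- data.frame(
    respondent_id = as.character(respondent_id),
    age_group = normalize_category(chr(age_group), .nsum_levels$age_group),
    education = normalize_category(chr(education), .nsum_levels$education),
    marital_status = normalize_category(chr(marital_status),
                                        .nsum_levels$marital_status_alter),
    n_children = normalize_category(chr(n_children), .nsum_levels$n_children),
    ever_alcohol = parse_logical_col(chr(ever_alcohol)),
    ever_prison = parse_logical_col(chr(ever_prison)),
    ever_drug = parse_logical_col(chr(ever_drug)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("nsum_alters", "data.frame")
  if (!is.null(respondents)) validate_alters(df, respondents)
  df
}

validate_alters <- function(alters, respondents) {
  missing_ids <- setdiff(alters$respondent_id, respondents$id)
  if (length(missing_ids)) {
    stop(sprintf("alter records reference unknown respondent id(s): %s",
                 paste(utils::head(missing_ids, 5), collapse = ", ")),
         call. = FALSE)
  }
  counts <- table(alters$respondent_id)
  m_by_id <- stats::setNames(respondents$m, respondents$id)
  over <- names(counts)[counts > m_by_id[names(counts)]]
  if (length(over)) {
    stop(sprintf("more alter records than reported m for respondent(s): %s",
                 paste(utils::head(over, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(alters)
}

.survey_cols <- c("id", "gender", "age_group", "education", "marital_status", "m")
.alter_cols <- c("respondent_id", "age_group", "education", "marital_status",
                 "n_children", "ever_alcohol", "ever_prison", "ever_drug")

#' Read a respondent-level survey from CSV
#'
#' Expects a UTF-8, comma-separated file with a header. Required columns:
#' \code{id}, \code{gender}, \code{m}; demographic columns are optional.
#' Column names in the file can be remapped via \code{schema}. Categorical
#' values are normalized case-insensitively; invalid rows raise errors that
#' name the offending row.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   \code{c(m = "fsw_count")}.
#' @return An \code{nsum_survey} data frame.
#' @export
read_survey <- function(path, schema = NULL) {
  raw <- read_mapped_csv(path, schema, required = c("id", "gender", "m"),
                         optional = setdiff(.survey_cols, c("id", "gender", "m")))
  survey_respondents(
    id = raw$id, gender = raw$gender, m = raw$m,
    age_group = raw$age_group %||% NA,
    education = raw$education %||% NA,
    marital_status = raw$marital_status %||% NA
  )
}

#' Write a respondent-level survey to CSV
#'
#' Columns are written in the fixed order \code{id, gender, age_group,
#' education, marital_status, m}; \code{read_survey} of the result returns
#' an identical table.
#'
#' @param respondents An \code{nsum_survey} data frame (nonempty).
#' @param path Destination CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_survey <- function(respondents, path) {
  stopifnot(inherits(respondents, "nsum_survey"))
  if (nrow(respondents) == 0L) stop("cannot write an empty survey", call. = FALSE)
  out <- as.data.frame(respondents)[, .survey_cols]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an alter-level table from CSV
#'
#' @param path CSV file path with columns \code{respondent_id, age_group,
#'   education, marital_status, n_children, ever_alcohol, ever_prison,
#'   ever_drug} (all but \code{respondent_id} optional).
#' @param respondents Optional \code{nsum_survey} to validate ids and
#'   per-respondent counts against.
#' @param schema Optional canonical-to-file column-name map.
#' @return An \code{nsum_alters} data frame.
#' @export
read_alters <- function(path, respondents = NULL, schema = NULL) {
  raw <- read_mapped_csv(path, schema, required = "respondent_id",
                         optional = setdiff(.alter_cols, "respondent_id"))
  alter_records(
    respondent_id = raw$respondent_id,
    age_group = raw$age_group %||% NA,
    education = raw$education %||% NA,
    marital_status = raw$marital_status %||% NA,
    n_children = raw$n_children %||% NA,
    ever_alcohol = raw$ever_alcohol %||% NA,
    ever_prison = raw$ever_prison %||% NA,
    ever_drug = raw$ever_drug %||% NA,
    respondents = respondents
  )
}

#' Write an alter-level table to CSV
#'
#' @param alters An \code{nsum_alters} data frame.
#' @param path Destination CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_alters <- function(alters, path) {
  stopifnot(inherits(alters, "nsum_alters"))
  if (nrow(alters) == 0L) stop("cannot write an empty alter table", call. = FALSE)
  out <- as.data.frame(alters)[, .alter_cols]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_mapped_csv <- function(path, schema, required, optional) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      file_col <- schema[[canonical]]
      if (!file_col %in% names(raw)) {
        stop(sprintf("schema maps '%s' to column '%s', absent from %s",
                     canonical, file_col, path), call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canonical
    }
  }
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req)) {
    stop(sprintf("missing required column(s) in %s: %s",
                 path, paste(missing_req, collapse = ", ")), call. = FALSE)
  }
  raw[intersect(c(required, optional), names(raw))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate demographic frequencies and percentages
#'
#' For each requested variable, counts records per category and expresses
#' each count as a percentage. By default the denominator is the full record
#' count (including records missing that variable), matching how published
#' survey tables are usually laid out; set
#' \code{percent_denominator = "nonmissing"} to use only records with an
#' observed value. Logical variables are tabulated as yes/no.
#'
#' @param records An \code{nsum_survey} or \code{nsum_alters} data frame.
#' @param variables Character vector of column names to tabulate; defaults
#'   to every categorical/logical column of the record type.
#' @param percent_denominator \code{"all"} or \code{"nonmissing"}.
#' @return A data frame with columns \code{variable}, \code{category},
#'   \code{count}, \code{percent} (percent rounded half-even to 1 decimal).
#' @examples
#' s <- survey_respondents(id = letters[1:4],
#'                         gender = c("male", "male", "female", "female"),
#'                         m = 0)
#' summarize_demographics(s, "gender")
#' @export
summarize_demographics <- function(records, variables = NULL,
                                   percent_denominator = c("all", "nonmissing")) {
  percent_denominator <- match.arg(percent_denominator)
  stopifnot(is.data.frame(records))
  if (is.null(variables)) {
    candidates <- setdiff(names(records), c("id", "respondent_id", "m"))
    variables <- candidates[vapply(records[candidates],
                                   function(x) is.factor(x) || is.logical(x),
                                   logical(1))]
  }
  unknown <- setdiff(variables, names(records))
  if (length(unknown)) {
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  n_all <- nrow(records)
  pieces <- lapply(variables, function(v) {
    x <- records[[v]]
    if (is.logical(x)) x <- factor(ifelse(x, "yes", "no"), levels = c("yes", "no"))
    if (!is.factor(x)) x <- factor(x)
    counts <- table(x, useNA = "no")
    denom <- if (percent_denominator == "all") n_all else sum(counts)
    data.frame(
      variable = v,
      category = names(counts),
      count = as.integer(counts),
      percent = round(100 * as.integer(counts) / denom, 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
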