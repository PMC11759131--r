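# Cohort CSV round-trip.

cohort_col_types <- function() {
  readr::cols(
    id = readr::col_integer(),
    gender = readr::col_character(),
    age = readr::col_integer(),
    income = readr::col_double(),
    frequency_answer = readr::col_character(),
    severity_answer = readr::col_character(),
    .default = readr::col_integer(),
    ages_neglect = readr::col_character(),
    ages_physical = readr::col_character(),
    ages_emotional = readr::col_character(),
    ages_sexual = readr::col_character()
  )
}

cohort_columns <- function() {
  c("id", "gender", "age", "income",
    paste0("act_", rep(.subtypes, each = 5), "_", 1:5),
    paste0("ages_", .subtypes),
    "frequency_answer", "severity_answer",
    paste0("dis_", .diseases))
}

#' Write a cohort to CSV
#'
#' One row per respondent; ternary act answers are encoded as 1 (affirm),
#' 0 (deny), `NA` (declined).  The file round-trips losslessly through
#' [read_cohort()].
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "NA")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path Path to a CSV written by [write_cohort()] (or hand-authored
#'   with the same column dictionary).
#' @return A cohort tibble; malformed rows raise an error naming the row and
#'   field.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  x <- readr::read_csv(path, col_types = cohort_col_types(), na = "NA",
                       progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0)
    abort(sprintf("malformed cohort row %d (column %d): expected %s, got %s",
                  prob$row[1], prob$col[1], prob$expected[1], prob$actual[1]))
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  validate_cohort(x)
  x
}

# Structural validation with row-level error messages.
validate_cohort <- function(cohort) {
  need <- cohort_columns()
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    abort(paste("cohort is missing columns:", paste(missing, collapse = ", ")))
  act_cols <- grep("^act_", names(cohort), value = TRUE)
  for (cl in act_cols) {
    bad <- which(!(cohort[[cl]] %in% c(0L, 1L, NA)))
    if (length(bad))
      abort(sprintf("malformed cohort row %d, field `%s`: %s is not 0/1/NA",
                    bad[1], cl, cohort[[cl]][bad[1]]))
  }
  for (s in .subtypes) {
    cl <- paste0("ages_", s)
    ages <- parse_age_string(cohort[[cl]], cl)
    affirmed <- rowSums(
      as.matrix(cohort[paste0("act_", s, "_", 1:5)]) == 1L,
      na.rm = TRUE) > 0
    bad <- which(lengths(ages) > 0 & !affirmed)
    if (length(bad))
      abort(sprintf(
        "malformed cohort row %d, field `%s`: exposure ages without an affirmed %s act",
        bad[1], cl, s))
  }
  bad <- which(!(cohort$gender %in% c("woman", "man")))
  if (length(bad))
    abort(sprintf("malformed cohort row %d, field `gender`: %s",
                  bad[1], cohort$gender[bad[1]]))
  invisible(cohort)
}

# "8;9;10" -> c(8L, 9L, 10L); errors name the offending row
parse_age_string <- function(x, field = "ages") {
  lapply(seq_along(x), function(i) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) return(integer(0))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    a <- suppressWarnings(as.integer(parts))
    if (any(is.na(a)))
      abort(sprintf("malformed cohort row %d, field `%s`: %s", i, field, s))
    if (any(a < 1 | a > 18))
      abort(sprintf(
        "malformed cohort row %d, field `%s`: exposure age outside 1-18", i,
        field))
    a
  })
}
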