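# ICAST-R-style analysis-variable derivation.

.freq_scores <- c("fewer than 10" = 1L, "10-50" = 2L,
                  "too many to count" = 3L)
.sev_scores <- c("not at all" = 0L, "mildly" = 1L, "seriously" = 2L,
                 "a great deal" = 3L)

#' Derive analysis variables from raw cohort records
#'
#' Applies the instrument's coding rules: a subtype is experienced iff at
#' least one of its five acts is affirmed (declined answers count as not
#' affirmed); `multiplicity` is the number of experienced subtypes (0-4);
#' the 18 timing indicators `t_1` ... `t_18` flag exposure to any subtype at
#' that age; `duration` is their sum (0-18); `frequency` and `severity` are
#' the maximum of the inverted follow-up answer codes on a 0-3 scale with 0
#' for unexposed respondents ("not at all" also maps to 0); and
#' `multimorbidity` is the count of affirmed diseases (0-7).
#'
#' @param cohort A cohort tibble ([generate_cohort()] / [read_cohort()]).
#' @return A tibble with one row per respondent: `id`, `gender`, `age`,
#'   `income`, subtype flags `s_neglect` ... `s_sexual`, `multiplicity`,
#'   `t_1` ... `t_18`, `duration`, `frequency`, `severity`,
#'   `multimorbidity`.
#' @examples
#' feats <- derive_features(generate_cohort(sim_config(100, seed = 3)))
#' @export
derive_features <- function(cohort) {
  validate_cohort(cohort)
  n <- nrow(cohort)

  subtype_flags <- vapply(.subtypes, function(s) {
    acts <- as.matrix(cohort[paste0("act_", s, "_", 1:5)])
    as.integer(rowSums(acts == 1L, na.rm = TRUE) > 0)
  }, integer(n))
  if (n == 1) subtype_flags <- matrix(subtype_flags, 1,
                                      dimnames = list(NULL, .subtypes))

  ages <- lapply(.subtypes, function(s)
    parse_age_string(cohort[[paste0("ages_", s)]], paste0("ages_", s)))
  timing <- matrix(0L, n, 18, dimnames = list(NULL, paste0("t_", 1:18)))
  for (j in 1:4) for (i in seq_len(n))
    if (length(ages[[j]][[i]])) timing[i, ages[[j]][[i]]] <- 1L

  multiplicity <- as.integer(rowSums(subtype_flags))
  duration <- as.integer(rowSums(timing))

  no_ages <- which(multiplicity > 0 & duration == 0)
  if (length(no_ages))
    inform(sprintf(
      "%d respondent(s) affirm a subtype but report no exposure ages (multiplicity > 0, duration = 0).",
      length(no_ages)))

  frequency <- unname(.freq_scores[cohort$frequency_answer])
  frequency[is.na(frequency)] <- 0L
  severity <- unname(.sev_scores[cohort$severity_answer])
  severity[is.na(severity)] <- 0L
  # unexposed respondents carry no follow-up information
  frequency[multiplicity == 0] <- 0L
  severity[multiplicity == 0] <- 0L

  dis <- as.matrix(cohort[paste0("dis_", .diseases)])
  multimorbidity <- as.integer(rowSums(dis == 1L, na.rm = TRUE))

  tibble::tibble(
    id = cohort$id,
    gender = cohort$gender,
    age = as.numeric(cohort$age),
    income = as.numeric(cohort$income),
    s_neglect = subtype_flags[, "neglect"],
    s_physical = subtype_flags[, "physical"],
    s_emotional = subtype_flags[, "emotional"],
    s_sexual = subtype_flags[, "sexual"],
    multiplicity = multiplicity,
    !!!tibble::as_tibble(timing),
    duration = duration,
    frequency = frequency,
    severity = severity,
    multimorbidity = multimorbidity
  )
}

#' Feature matrix with column roles
#'
#' Wraps [derive_features()] and tags every analysis column with its role,
#' so downstream stages know which columns are maltreatment types, timing
#' indicators, global scores, covariates, the outcome, or the stratifier.
#'
#' @param cohort A cohort tibble; must have at least one row.
#' @return A `cm_features` tibble (the [derive_features()] output) with a
#'   `roles` attribute; retrieve it with [column_roles()].
#' @export
feature_matrix <- function(cohort) {
  if (nrow(cohort) == 0) abort("cohort is empty; cannot build features.")
  feats <- derive_features(cohort)
  structure(feats, roles = default_roles(),
            class = c("cm_features", class(feats)))
}

default_roles <- function() {
  tibble::tibble(
    column = c("id", "gender", "age", "income",
               paste0("s_", .subtypes), "multiplicity",
               paste0("t_", 1:18), "duration", "frequency", "severity",
               "multimorbidity"),
    role = c("id", "stratifier", "covariate", "covariate",
             rep("type", 4), "global_score",
             rep("timing", 18), rep("global_score", 3),
             "outcome")
  )
}

#' Column-role dictionary of a feature matrix
#'
#' @param features A `cm_features` object (or any feature tibble with the
#'   standard column names).
#' @return A tibble with columns `column` and `role` (`id`, `stratifier`,
#'   `covariate`, `type`, `timing`, `global_score`, `outcome`).
#' @export
column_roles <- function(features) {
  attr(features, "roles") %||% default_roles()
}

# Predictor columns entering the forest model: types, timing, global scores
# and covariates -- never the stratifier or the outcome.
predictor_columns <- function(features) {
  roles <- column_roles(features)
  roles$column[roles$role %in% c("type", "timing", "global_score",
                                 "covariate")]
}

outcome_column <- function(features) {
  roles <- column_roles(features)
  roles$column[roles$role == "outcome"][1]
}

#' Write a feature matrix with its column-role sidecar
#'
#' @param features A `cm_features` tibble.
#' @param path CSV path for the features; the role dictionary is written to
#'   `<path>.roles.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "NA")
  jsonlite::write_json(column_roles(features),
                       paste0(path, ".roles.json"), dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}
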