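# Stratified descriptive statistics and classical tests.

#' Pearson chi-square test for a 2x2 table
#'
#' @param a,b,c,d Cell counts (exposed/unexposed by stratum), or `a` may be
#'   a 2x2 matrix with `b`-`d` missing.
#' @param continuity_correction Apply the Yates correction (default off: the
#'   uncorrected statistic is the one this package's descriptive tables
#'   pin).
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_2x2(41, 1256, 23, 1194)
#' @export
chisq_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                      continuity_correction = FALSE) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(m < 0) || sum(m) == 0)
    abort("counts must be nonnegative with a positive total.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort("a zero marginal row/column gives an expected count of 0.")
  ht <- suppressWarnings(chisq.test(m, correct = continuity_correction))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Two-sample t test
#'
#' Welch's t by default (Welch-Satterthwaite df); set
#' `equal_variance = TRUE` for the pooled-variance Student test.
#'
#' @param x,y Numeric samples (each with >= 2 values).
#' @param equal_variance Pool the variances.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, equal_variance = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    abort("each group needs at least 2 values.")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    abort("zero variance in both groups with equal means.")
  ht <- t.test(x, y, var.equal = equal_variance)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, n >= 3, neither constant.
#' @return A one-row tibble with `r`, `statistic`, `df`, `p_value` (t-based).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("need paired vectors of length >= 3.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input.")
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = unname(ht$p.value))
}

#' Group means with 95% confidence intervals
#'
#' Mean and t-based confidence interval of the outcome per group level and
#' stratum (the dose-response display of multimorbidity by number of
#' experienced subtypes).  Empty groups are absent from the output;
#' single-observation groups are flagged with an undefined (NA) interval.
#'
#' @param features Feature tibble.
#' @param outcome,group,stratifier Column names.
#' @param conf_level Confidence level.
#' @return A `cm_group_means` tibble: `stratum`, `group`, `n`, `mean`,
#'   `ci_lo`, `ci_hi`, `degenerate`.
#' @export
group_means_ci <- function(features, outcome = "multimorbidity",
                           group = "multiplicity", stratifier = "gender",
                           conf_level = 0.95) {
  strata <- split_strata(features, stratifier)
  out <- dplyr::bind_rows(purrr::imap(strata, function(dat, nm) {
    dat |>
      dplyr::group_by(group = .data[[group]]) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data[[outcome]]),
        se = ifelse(dplyr::n() > 1, sd(.data[[outcome]]) / sqrt(dplyr::n()),
                    NA_real_),
        .groups = "drop") |>
      dplyr::mutate(
        stratum = nm,
        tcrit = ifelse(.data$n > 1,
                       qt(1 - (1 - conf_level) / 2, df = .data$n - 1),
                       NA_real_),
        ci_lo = .data$mean - .data$tcrit * .data$se,
        ci_hi = .data$mean + .data$tcrit * .data$se,
        degenerate = .data$n < 2) |>
      dplyr::select("stratum", "group", "n", "mean", "ci_lo", "ci_hi",
                    "degenerate")
  }))
  class(out) <- c("cm_group_means", class(out))
  out
}

# variables summarized as n (%) vs mean (SD) in table1
.table1_binary <- function() c(paste0("s_", .subtypes), paste0("t_", 1:18))
.table1_continuous <- function() {
  c("age", "income", "multiplicity", "duration", "frequency", "severity",
    "multimorbidity")
}

#' Stratified descriptive table
#'
#' Per variable: `n (%)` (binary) or `mean (SD)` (continuous) per stratum,
#' with the between-strata test p-value — Pearson chi-square without
#' continuity correction for binary variables, Welch's t for continuous
#' ones.  Percentage denominators are the stratum sizes; percentages are
#' rounded half-up to one decimal for display (full precision is retained
#' in the `count`/`denom` columns).
#'
#' @param features Feature tibble.
#' @param stratifier Stratifying column (both strata must be nonempty).
#' @return A tibble with `variable`, per-stratum display columns, `count_*`
#'   and `denom_*` for binary rows, `p_value`, `test`.
#' @export
table1 <- function(features, stratifier = "gender") {
  strata <- split_strata(features, stratifier)
  if (length(strata) != 2 || any(vapply(strata, nrow, integer(1)) == 0))
    abort("table1 needs exactly two nonempty strata.")
  s1 <- strata[[1]]
  s2 <- strata[[2]]
  n1 <- nrow(s1)
  n2 <- nrow(s2)
  nm <- names(strata)

  rows <- list()
  for (v in intersect(.table1_continuous(), names(features))) {
    tt <- tryCatch(two_sample_t(s1[[v]], s2[[v]]),  # degenerate: no test
                   error = function(e) tibble::tibble(p_value = NA_real_))
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      summary_1 = fmt_mean_sd(s1[[v]]), summary_2 = fmt_mean_sd(s2[[v]]),
      count_1 = NA_integer_, count_2 = NA_integer_,
      p_value = tt$p_value, test = "welch_t")
  }
  for (v in intersect(.table1_binary(), names(features))) {
    c1 <- sum(s1[[v]] == 1)
    c2 <- sum(s2[[v]] == 1)
    p <- tryCatch(
      chisq_2x2(c1, n1 - c1, c2, n2 - c2)$p_value,
      error = function(e) NA_real_)  # zero marginal: no valid test
    rows[[v]] <- tibble::tibble(
      variable = v, type = "binary",
      summary_1 = sprintf("%d (%s)", c1, fmt_pct(c1, n1)),
      summary_2 = sprintf("%d (%s)", c2, fmt_pct(c2, n2)),
      count_1 = c1, count_2 = c2,
      p_value = p, test = "chisq")
  }
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "summary_1"] <- paste0("summary_", nm[1])
  names(out)[names(out) == "summary_2"] <- paste0("summary_", nm[2])
  names(out)[names(out) == "count_1"] <- paste0("count_", nm[1])
  names(out)[names(out) == "count_2"] <- paste0("count_", nm[2])
  attr(out, "stratum_sizes") <- setNames(c(n1, n2), nm)
  out
}
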