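# Cross-validated importance, outcome-reshuffling null, contrasts.

split_strata <- function(features, stratifier) {
  if (is.null(stratifier)) return(list(all = features))
  if (!stratifier %in% names(features))
    abort(sprintf("stratifier column `%s` not found.", stratifier))
  lv <- sort(unique(as.character(features[[stratifier]])))
  if (setequal(lv, c("woman", "man"))) lv <- c("woman", "man")  # table order
  out <- lapply(lv, function(l) features[features[[stratifier]] == l, ,
                                         drop = FALSE])
  names(out) <- lv
  out
}

#' Cross-validated permutation importance
#'
#' Repeats a k-fold cross-validation: within each stratum and repetition,
#' rows are partitioned into `folds` folds; a forest is fit on each training
#' split and permutation importance is evaluated on the held-out fold.  The
#' per-predictor mean and SD are taken across all `folds * repetitions`
#' fold-fits, and reliability is the SD of the per-repetition means.
#' Estimation validity (out-of-fold MSE and R-squared) is recorded per
#' fold-fit.
#'
#' @param features A feature tibble ([feature_matrix()]).
#' @param config A [forest_config()].
#' @param folds,repetitions Cross-validation shape (default 10 x 10).
#' @param stratifier Column to stratify by (default `"gender"`, i.e.
#'   separate analyses for women and men); `NULL` for a single stratum.
#' @param seed Master seed for fold assignment and forest fits; defaults to
#'   the config seed.
#' @return A `cv_importance` object; [tidy()] gives the per-predictor
#'   summary, [glance()] the estimation validity.
#' @export
cv_importance <- function(features, config = forest_config(), folds = 10,
                          repetitions = 10, stratifier = "gender",
                          seed = NULL) {
  stopifnot(inherits(config, "forest_config"))
  seed <- seed %||% config$seed
  outcome <- outcome_column(features)
  predictors <- predictor_columns(features)
  strata <- split_strata(features, stratifier)

  for (s in names(strata))
    if (nrow(strata[[s]]) < folds * config$min_node_size)
      abort(sprintf(
        "stratum `%s` has %d rows; need at least folds * min_node_size = %d.",
        s, nrow(strata[[s]]), folds * config$min_node_size))

  res <- purrr::imap(strata, function(dat, sname) {
    n <- nrow(dat)
    reps <- purrr::map(seq_len(repetitions), function(r) {
      fold_id <- withr::with_seed(
        child_seed(seed, paste0("cv/", sname, "/rep", r)),
        sample(rep(seq_len(folds), length.out = n)))
      purrr::map(seq_len(folds), function(k) {
        train <- dat[fold_id != k, , drop = FALSE]
        test <- dat[fold_id == k, , drop = FALSE]
        fcfg <- config
        fcfg$seed <- child_seed(seed,
                                paste0("fit/", sname, "/rep", r, "/fold", k))
        fit <- fit_forest(train, outcome, predictors, fcfg)
        imp <- permutation_importance(fit, eval_data = test)
        pred <- predict(fit, test)
        yte <- as.numeric(test[[outcome]])
        mse <- mean((pred - yte)^2)
        mse0 <- mean((yte - mean(as.numeric(train[[outcome]])))^2)
        list(importance = setNames(imp$importance, imp$predictor),
             validity = tibble::tibble(repetition = r, fold = k, mse = mse,
                                       r_squared = 1 - mse / mse0))
      })
    })
    flat <- purrr::flatten(reps)
    impmat <- do.call(rbind, purrr::map(flat, "importance"))
    validity <- dplyr::bind_rows(purrr::map(flat, "validity"))
    rep_means <- rowsum(impmat, rep(seq_len(repetitions), each = folds)) /
      folds
    summary <- tibble::tibble(
      stratum = sname,
      predictor = colnames(impmat),
      importance = colMeans(impmat),
      sd = apply(impmat, 2, sd),
      reliability = apply(rep_means, 2, sd)
    )
    list(summary = summary, replicates = impmat, validity = validity)
  })

  structure(list(
    strata = res, folds = folds, repetitions = repetitions,
    stratifier = stratifier, config = config, seed = seed,
    predictors = predictors, outcome = outcome
  ), class = "cv_importance")
}

#' @export
print.cv_importance <- function(x, ...) {
  cat(sprintf("<cv_importance> %d x %d-fold CV, strata: %s\n", x$repetitions,
              x$folds, paste(names(x$strata), collapse = ", ")))
  print(utils::head(dplyr::arrange(tidy(x), dplyr::desc(.data$importance)),
                    10))
  invisible(x)
}

#' @rdname cv_importance
#' @param x A `cv_importance` object.
#' @param ... Unused.
#' @export
tidy.cv_importance <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$strata, "summary"))
}

#' @rdname cv_importance
#' @export
glance.cv_importance <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$strata, function(s, nm)
    dplyr::summarise(s$validity, stratum = nm, mse = mean(.data$mse),
                     r_squared = mean(.data$r_squared), .groups = "drop")))
}

#' Outcome-reshuffling permutation null for variable importance
#'
#' Builds an empirical chance distribution of importance scores: the outcome
#' column is permuted uniformly at random `n_reshuffles` times and, each
#' time, a forest is refit on the full stratum and permutation importance
#' recomputed.  The observed importance (unpermuted outcome, same
#' procedure) is compared against this null with the add-one empirical
#' p-value `p(v) = (1 + #{null >= observed}) / (n_reshuffles + 1)`.
#'
#' @inheritParams cv_importance
#' @param n_reshuffles Number of outcome permutations (>= 19).
#' @return A `cm_perm_null` object: `tidy()` gives per-predictor observed
#'   importance and empirical p-value per stratum; `$null` holds the full
#'   null draws for diagnostics.
#' @export
permutation_null <- function(features, config = forest_config(),
                             n_reshuffles = 5000, stratifier = "gender",
                             seed = NULL) {
  stopifnot(inherits(config, "forest_config"))
  if (n_reshuffles < 19) abort("`n_reshuffles` must be at least 19.")
  seed <- seed %||% config$seed
  outcome <- outcome_column(features)
  predictors <- predictor_columns(features)
  strata <- split_strata(features, stratifier)

  one_fit <- function(dat, sname, b) {
    fcfg <- config
    fcfg$seed <- child_seed(seed, paste0("null/", sname, "/fit", b))
    fit <- fit_forest(dat, outcome, predictors, fcfg)
    imp <- permutation_importance(fit)
    setNames(imp$importance, imp$predictor)
  }

  res <- purrr::imap(strata, function(dat, sname) {
    observed <- one_fit(dat, sname, 0L)
    null <- withr::with_seed(
      child_seed(seed, paste0("null/", sname, "/shuffles")), {
        vapply(seq_len(n_reshuffles), function(b) {
          perm <- dat
          perm[[outcome]] <- sample(perm[[outcome]])
          one_fit(perm, sname, b)
        }, numeric(length(predictors)))
      })
    null <- t(null)  # n_reshuffles x p
    pvals <- (1 + colSums(sweep(null, 2, observed, ">="))) /
      (n_reshuffles + 1)
    list(observed = observed, null = null, p_value = pvals)
  })

  structure(list(strata = res, n_reshuffles = n_reshuffles,
                 stratifier = stratifier, predictors = predictors,
                 config = config, seed = seed),
            class = "cm_perm_null")
}

#' @rdname permutation_null
#' @param x A `cm_perm_null` object.
#' @param ... Unused.
#' @export
tidy.cm_perm_null <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$strata, function(s, nm)
    tibble::tibble(stratum = nm, predictor = names(s$observed),
                   importance = unname(s$observed),
                   p_value = unname(s$p_value))))
}

#' @export
print.cm_perm_null <- function(x, ...) {
  cat(sprintf("<cm_perm_null> %d outcome reshuffles, strata: %s\n",
              x$n_reshuffles, paste(names(x$strata), collapse = ", ")))
  print(utils::head(dplyr::arrange(tidy(x), .data$p_value), 10))
  invisible(x)
}

#' Contrast the importance of two predictors
#'
#' Paired comparison of per-fold-replicate importances of a focal predictor
#' (typically a maltreatment type or timing indicator) against a reference
#' global score (multiplicity, duration, or severity): a paired t statistic
#' across the `folds * repetitions` replicates of [cv_importance()], with a
#' two-sided p-value.  The statistic is antisymmetric in its arguments.
#'
#' @param result A [cv_importance()] object.
#' @param focal,reference Predictor names present in `result` (distinct).
#' @return A tibble with one row per stratum: `focal`, `reference`,
#'   `statistic`, `df`, `p_value`, `stars` (.05/.01/.001), and
#'   `mean_difference`.
#' @export
contrast_importance <- function(result, focal, reference) {
  stopifnot(inherits(result, "cv_importance"))
  if (identical(focal, reference))
    abort("`focal` and `reference` must differ.")
  dplyr::bind_rows(purrr::imap(result$strata, function(s, nm) {
    if (!all(c(focal, reference) %in% colnames(s$replicates)))
      abort("focal/reference not among the fitted predictors.")
    d <- s$replicates[, focal] - s$replicates[, reference]
    m <- length(d)
    if (m < 2) abort("need at least 2 fold replicates for a contrast.")
    sdd <- sd(d)
    stat <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(m))
    p <- if (sdd == 0 && mean(d) == 0) 1 else 2 * pt(-abs(stat), df = m - 1)
    tibble::tibble(stratum = nm, focal = focal, reference = reference,
                   statistic = stat, df = m - 1, p_value = p,
                   stars = p_stars(p), mean_difference = mean(d))
  }))
}

#' All type/timing-vs-global-score contrasts
#'
#' Convenience wrapper running [contrast_importance()] for every type and
#' timing predictor against each requested global score.
#'
#' @param result A [cv_importance()] object.
#' @param references Global scores to test against.
#' @return A tibble of contrasts.
#' @export
contrast_table <- function(result,
                           references = c("multiplicity", "duration",
                                          "severity")) {
  roles <- default_roles()
  focals <- intersect(
    roles$column[roles$role %in% c("type", "timing", "global_score")],
    result$predictors)
  purrr::map_dfr(references, function(ref)
    purrr::map_dfr(setdiff(focals, ref), function(f)
      contrast_importance(result, f, ref)))
}
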