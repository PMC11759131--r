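cv_small_cfg <- function(seed = 1) {
  forest_config(n_trees = 15, alpha_split = 1, min_node_size = 15,
                seed = seed)
}

test_that("cv_importance validates stratum sizes and returns the full grid", {
  f <- synthetic_features(n = 160, seed = 4)
  expect_error(
    cv_importance(f, forest_config(min_node_size = 20), folds = 10),
    "stratum")
  cv <- cv_importance(f, cv_small_cfg(), folds = 2, repetitions = 3,
                      stratifier = NULL)
  expect_identical(nrow(cv$strata$all$replicates), 6L)  # folds x repetitions
  td <- tidy(cv)
  expect_identical(nrow(td), 28L)
  expect_true(all(is.finite(td$importance)))
  gl <- glance(cv)
  expect_true(all(gl$mse > 0))
})

test_that("cv_importance is deterministic and runs per gender stratum", {
  f <- feature_matrix(generate_cohort(sim_config(n_respondents = 700,
                                                 seed = 5)))
  cv1 <- cv_importance(f, cv_small_cfg(), folds = 2, repetitions = 2)
  cv2 <- cv_importance(f, cv_small_cfg(), folds = 2, repetitions = 2)
  expect_identical(cv1$strata$woman$replicates, cv2$strata$woman$replicates)
  expect_setequal(names(cv1$strata), c("woman", "man"))
  expect_identical(unique(tidy(cv1)$stratum[1:28]), "woman")
})

test_that("null-data cross-validated importances are centred at zero", {
  f <- synthetic_features(n = 100, seed = 8)
  f$multimorbidity <- withr::with_seed(1, rbinom(100, 7, 0.1))  # pure noise
  cv <- cv_importance(f, cv_small_cfg(), folds = 2, repetitions = 1,
                      stratifier = NULL)
  td <- tidy(cv)
  expect_true(all(abs(td$importance) <= 3 * pmax(td$sd, 1e-12)))
})

test_that("empirical null p-values follow the add-one estimator", {
  f <- synthetic_features(n = 120, seed = 3)
  # outcome exactly equal to duration: its importance must beat every
  # reshuffled draw, giving the minimal add-one p of 1/(B+1)
  f$multimorbidity <- f$duration
  pn <- permutation_null(f, cv_small_cfg(), n_reshuffles = 199,
                         stratifier = NULL)
  td <- tidy(pn)
  expect_equal(td$p_value[td$predictor == "duration"], 1 / 200)
  expect_true(all(td$p_value >= 1 / 200 & td$p_value <= 1))
  # a predictor whose observed importance is below all its null draws gets
  # exactly 1 under the add-one rule
  below_all <- vapply(seq_along(pn$predictors), function(j)
    all(pn$strata$all$null[, j] >= pn$strata$all$observed[j]),
    logical(1))
  if (any(below_all))
    expect_true(all(td$p_value[below_all] == 1))
  expect_error(permutation_null(f, cv_small_cfg(), n_reshuffles = 10),
               "at least 19")
})

test_that("reshuffle count changes resolution but not the observed importance", {
  f <- synthetic_features(n = 120, seed = 6)
  pn1 <- permutation_null(f, cv_small_cfg(), n_reshuffles = 19,
                          stratifier = NULL)
  pn2 <- permutation_null(f, cv_small_cfg(), n_reshuffles = 39,
                          stratifier = NULL)
  expect_identical(pn1$strata$all$observed, pn2$strata$all$observed)
  expect_identical(nrow(pn2$strata$all$null), 39L)
})

test_that("importance contrasts are antisymmetric paired t statistics", {
  f <- feature_matrix(generate_cohort(sim_config(n_respondents = 900,
                                                 seed = 13)))
  cv <- cv_importance(f, cv_small_cfg(), folds = 3, repetitions = 2)
  ab <- contrast_importance(cv, "duration", "multiplicity")
  ba <- contrast_importance(cv, "multiplicity", "duration")
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_identical(ab$df, rep(5, 2))
  expect_error(contrast_importance(cv, "duration", "duration"), "differ")
})

test_that("identical importance replicates contrast to zero with p = 1", {
  # hand-built result in which two predictors have identical replicates
  reps <- cbind(a = c(0.1, 0.2, 0.15, 0.12), b = c(0.1, 0.2, 0.15, 0.12))
  fake <- structure(list(strata = list(
    all = list(replicates = reps)), predictors = c("a", "b")),
    class = "cv_importance")
  res <- contrast_importance(fake, "a", "b")
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
})

test_that("contrast_table covers type, timing and global-score focals", {
  f <- feature_matrix(generate_cohort(sim_config(n_respondents = 700,
                                                 seed = 2)))
  cv <- cv_importance(f, cv_small_cfg(), folds = 2, repetitions = 1)
  ct <- contrast_table(cv, references = c("multiplicity", "duration"))
  expect_setequal(unique(ct$reference), c("multiplicity", "duration"))
  # 25 focals vs multiplicity, 25 vs duration, both strata
  expect_identical(nrow(ct), 2L * 2L * 25L)
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
})

test_that("repetition averaging stabilizes the cross-validated mean", {
  # variance of the CV-mean importance of duration across outer seeds
  # shrinks when repetitions increase from 1 to 3
  mean_of <- function(reps, s) {
    f <- synthetic_features(n = 150, seed = 100 + s)
    cv <- cv_importance(f, cv_small_cfg(seed = s), folds = 2,
                        repetitions = reps, stratifier = NULL, seed = s)
    tidy(cv)$importance[tidy(cv)$predictor == "duration"]
  }
  v1 <- var(vapply(1:6, function(s) mean_of(1, s), numeric(1)))
  v3 <- var(vapply(1:6, function(s) mean_of(3, s), numeric(1)))
  expect_lt(v3, v1 * 1.5)  # allows noise but catches gross instability
})
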