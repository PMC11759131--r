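test_that("fully denied records derive all-zero exposure features", {
  rec <- blank_record(dis_diabetes = 1L, dis_stroke = 1L)
  f <- derive_features(rec)
  expect_identical(f$multiplicity, 0L)
  expect_identical(f$duration, 0L)
  expect_identical(f$frequency, 0L)
  expect_identical(f$severity, 0L)
  expect_true(all(as.matrix(f[paste0("t_", 1:18)]) == 0L))
  expect_identical(f$multimorbidity, 2L)
})

test_that("timing indicators union across subtypes and sum to duration", {
  rec <- blank_record(
    act_physical_1 = 1L, ages_physical = "8;9;10;11;12",
    act_emotional_2 = 1L, ages_emotional = "10;11",
    frequency_answer = "fewer than 10", severity_answer = "mildly")
  f <- derive_features(rec)
  expect_identical(f$multiplicity, 2L)
  expect_identical(f$duration, 5L)
  tm <- unlist(f[paste0("t_", 1:18)])
  expect_identical(unname(tm[8:12]), rep(1L, 5))
  expect_identical(sum(tm), 5L)
})

test_that("follow-up answers map to the inverted 0-3 scales", {
  base <- list(act_sexual_1 = 1L, ages_sexual = "14")
  cases <- list(
    list(frequency_answer = "fewer than 10", severity_answer = "not at all",
         frequency = 1L, severity = 0L),
    list(frequency_answer = "10-50", severity_answer = "mildly",
         frequency = 2L, severity = 1L),
    list(frequency_answer = "too many to count",
         severity_answer = "a great deal", frequency = 3L, severity = 3L))
  for (cs in cases) {
    rec <- do.call(blank_record, c(base, cs[c("frequency_answer",
                                              "severity_answer")]))
    f <- derive_features(rec)
    expect_identical(f$frequency, cs$frequency)
    expect_identical(f$severity, cs$severity)
  }
})

test_that("derivation is idempotent, total, and exact on aggregates", {
  ch <- generate_cohort(sim_config(n_respondents = 300, decline_rate = 0.05,
                                   seed = 21))
  f1 <- derive_features(ch)
  f2 <- derive_features(ch)
  expect_identical(f1, f2)
  # aggregation identity, every row, exact
  expect_identical(f1$duration,
                   as.integer(rowSums(f1[paste0("t_", 1:18)])))
  expect_identical(f1$multiplicity,
                   as.integer(f1$s_neglect + f1$s_physical + f1$s_emotional +
                                f1$s_sexual))
  expect_true(all(f1$multimorbidity >= 0 & f1$multimorbidity <= 7))
  # unexposed respondents carry zero follow-up scores
  expect_true(all(f1$frequency[f1$multiplicity == 0] == 0L))
  expect_true(all(f1$severity[f1$multiplicity == 0] == 0L))
})

test_that("adding an exposure age never decreases duration or any t_a", {
  rec <- blank_record(act_neglect_1 = 1L, ages_neglect = "5;6",
                      frequency_answer = "10-50",
                      severity_answer = "seriously")
  f0 <- derive_features(rec)
  rec2 <- rec
  rec2$ages_neglect <- "5;6;9"
  f1 <- derive_features(rec2)
  expect_gt(f1$duration, f0$duration)
  tm0 <- unlist(f0[paste0("t_", 1:18)])
  tm1 <- unlist(f1[paste0("t_", 1:18)])
  expect_true(all(tm1 >= tm0))
})

test_that("out-of-range exposure ages error; affirmation without ages is flagged", {
  rec <- blank_record(act_neglect_1 = 1L, ages_neglect = "19")
  expect_error(derive_features(rec), "outside 1-18")
  rec2 <- blank_record(act_neglect_1 = 1L, frequency_answer = "10-50",
                       severity_answer = "mildly")
  expect_message(f <- derive_features(rec2), "no exposure ages")
  expect_identical(f$multiplicity, 1L)
  expect_identical(f$duration, 0L)
})

test_that("feature_matrix tags the 28 predictors, outcome and stratifier", {
  ch <- generate_cohort(sim_config(n_respondents = 50, seed = 3))
  fm <- feature_matrix(ch)
  roles <- column_roles(fm)
  expect_identical(sum(roles$role == "type"), 4L)
  expect_identical(sum(roles$role == "timing"), 18L)
  expect_identical(sum(roles$role == "global_score"), 4L)
  expect_identical(sum(roles$role == "covariate"), 2L)
  expect_identical(roles$column[roles$role == "outcome"], "multimorbidity")
  expect_identical(roles$column[roles$role == "stratifier"], "gender")
  expect_identical(length(cmforest:::predictor_columns(fm)), 28L)
  expect_error(feature_matrix(ch[0, ]), "empty")
})

test_that("matrix-level means match an independent per-record recomputation", {
  ch <- generate_cohort(sim_config(n_respondents = 150, seed = 44))
  fm <- feature_matrix(ch)
  # independent loop: parse each row's age strings directly
  durs <- mults <- integer(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    ages <- integer(0)
    mult <- 0L
    for (s in subtypes) {
      str <- ch[[paste0("ages_", s)]][i]
      affirmed <- any(unlist(ch[i, paste0("act_", s, "_", 1:5)]) == 1L,
                      na.rm = TRUE)
      mult <- mult + as.integer(affirmed)
      if (nzchar(str))
        ages <- union(ages, as.integer(strsplit(str, ";")[[1]]))
    }
    durs[i] <- length(ages)
    mults[i] <- mult
  }
  expect_equal(mean(fm$duration), mean(durs))
  expect_equal(mean(fm$multiplicity), mean(mults))
  expect_identical(fm$duration, durs)
})

test_that("constant timing columns do not break the forest downstream", {
  ch <- generate_cohort(sim_config(n_respondents = 120, p_any_cm = 0,
                                   subtype_base_rates = rep(0, 4), seed = 6))
  fm <- feature_matrix(ch)
  d <- as.data.frame(fm[, c(cmforest:::predictor_columns(fm),
                            "multimorbidity")])
  fit <- fit_forest(d, "multimorbidity",
                    config = forest_config(n_trees = 5, seed = 1))
  expect_length(predict(fit, d), nrow(d))
})
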