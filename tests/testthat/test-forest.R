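test_that("association test handles degenerate inputs", {
  expect_equal(association_test(rnorm(10), rep(2, 10))$p_value, 1)
  expect_equal(association_test(rep(1, 10), rnorm(10))$p_value, 1)
  expect_error(association_test(1:5, 1:5, case_weights = rep(0, 5)),
               "weights are zero")
  expect_error(association_test(1, 1), "at least 2")
})

test_that("perfect linear association gives a vanishing p-value", {
  x <- rnorm(50)
  res <- association_test(x, x)
  expect_equal(res$statistic, 49, tolerance = 1e-10)  # (n-1) r^2
  expect_lt(res$p_value, 1e-6)
})

test_that("asymptotic p agrees with exhaustive permutation enumeration", {
  withr::local_seed(42)
  # binary x, numeric y, n = 7: full 7! enumeration
  x <- c(0, 0, 0, 1, 1, 1, 1)
  y <- c(0.3, 1.2, -0.5, 2.1, 1.8, 0.9, 2.5)
  expect_lt(abs(association_test(x, y)$p_value - exact_assoc_p(x, y)), 0.05)
  # a second configuration with weaker signal
  y2 <- c(0.3, 1.2, -0.5, 0.1, 1.8, -0.9, 0.5)
  expect_lt(abs(association_test(x, y2)$p_value - exact_assoc_p(x, y2)),
            0.05)
  # categorical x with 3 levels, n = 8; the df = 2 chi-square asymptotic
  # is rougher at this n, so the enumeration bound is wider
  xf <- factor(c("a", "a", "b", "b", "b", "c", "c", "c"))
  y3 <- c(-1.2, -0.8, 0.1, 0.4, 1.0, 1.4, 0.9, 0.2)
  expect_lt(abs(association_test(xf, y3)$p_value - exact_assoc_p(xf, y3)),
            0.1)
})

test_that("case weights subset the test to the active cases", {
  withr::local_seed(9)
  x <- rnorm(30)
  y <- rnorm(30)
  w <- rep(c(1, 0), 15)
  expect_equal(association_test(x, y, case_weights = w),
               association_test(x[w == 1], y[w == 1]))
})

test_that("pure-noise data yields a single root leaf in most trees", {
  leaves <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200),
                      y = rnorm(200))
    })
    fit <- fit_forest(d, "y", config = forest_config(
      n_trees = 1, subsample_fraction = 1, alpha_split = 0.05, seed = s))
    length(fit$trees[[1]]$var) == 1
  }, logical(1))
  expect_gte(mean(leaves), 0.9)
})

test_that("a perfect binary separator yields the depth-1 tree on it", {
  d <- data.frame(x = rep(c(0, 1), each = 30), z = rnorm(60))
  d$y <- ifelse(d$x == 0, 1, 5)
  fit <- fit_forest(d, "y", config = forest_config(
    n_trees = 1, subsample_fraction = 1, min_node_size = 5, mtry = 2,
    seed = 4))
  tr <- fit$trees[[1]]
  expect_length(tr$var, 3)            # root + two leaves
  expect_identical(tr$var[1], 0L)     # split on x (column 0)
  expect_setequal(tr$value[2:3], c(1, 5))
})

test_that("forests on a constant outcome predict that constant", {
  d <- data.frame(a = rnorm(80), b = runif(80), y = 3.25)
  fit <- fit_forest(d, "y", config = forest_config(n_trees = 10, seed = 2))
  expect_true(all(predict(fit, d) == 3.25))
})

test_that("single-tree training predictions equal their leaf means", {
  withr::local_seed(11)
  d <- data.frame(a = rnorm(150), b = rnorm(150))
  d$y <- d$a * 2 + rnorm(150, sd = 0.5)
  fit <- fit_forest(d, "y", config = forest_config(
    n_trees = 1, subsample_fraction = 1, min_node_size = 10, mtry = 2,
    seed = 7))
  pred <- predict(fit, d)
  tr <- fit$trees[[1]]
  oracle <- vapply(seq_len(nrow(d)), function(i)
    r_tree_predict(tr, d[i, c("a", "b")]), numeric(1))
  expect_equal(pred, oracle)
  expect_gt(length(tr$var), 1)
  # predictions bounded by the training outcome range
  expect_true(all(pred >= min(d$y) & pred <= max(d$y)))
})

test_that("the forest beats the mean-only predictor on signal data", {
  withr::local_seed(19)
  n <- 600
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1.5 * d$x1 + rnorm(n)
  train <- d[1:400, ]
  test <- d[401:600, ]
  fit <- fit_forest(train, "y", config = forest_config(
    n_trees = 50, alpha_split = 1, min_node_size = 15, seed = 3))
  mse_forest <- mean((predict(fit, test) - test$y)^2)
  mse_mean <- mean((mean(train$y) - test$y)^2)
  expect_lt(mse_forest, mse_mean)
})

test_that("forests and importances are bit-reproducible under a fixed seed", {
  d <- synthetic_features(n = 200, seed = 5)
  dd <- as.data.frame(d[, c(cmforest:::predictor_columns(d),
                            "multimorbidity")])
  cfg <- forest_config(n_trees = 15, alpha_split = 1, seed = 123)
  f1 <- fit_forest(dd, "multimorbidity", config = cfg)
  f2 <- fit_forest(dd, "multimorbidity", config = cfg)
  expect_identical(f1$trees, f2$trees)
  expect_identical(permutation_importance(f1), permutation_importance(f2))
})

test_that("predictors used in no tree have importance exactly zero", {
  withr::local_seed(2)
  n <- 300
  d <- data.frame(strong = rnorm(n), weak1 = rnorm(n), weak2 = rnorm(n))
  d$y <- 3 * d$strong + rnorm(n, sd = 0.3)
  fit <- fit_forest(d, "y", config = forest_config(
    n_trees = 10, alpha_split = 0.001, mtry = 3, seed = 6))
  used <- sort(unique(unlist(purrr::map(fit$trees, "var"))))
  used <- used[used >= 0] + 1
  imp <- permutation_importance(fit)
  unused <- setdiff(seq_len(3), used)
  for (j in unused) expect_identical(imp$importance[j], 0)
  expect_gt(length(unused), 0)  # the weak predictors are never selected
})

test_that("null-model importance is centred at zero", {
  imps <- vapply(1:30, function(s) {
    withr::with_seed(700 + s,
      d <- data.frame(a = rnorm(150), b = rnorm(150), y = rnorm(150)))
    fit <- fit_forest(d, "y", config = forest_config(
      n_trees = 10, alpha_split = 1, min_node_size = 25, seed = s))
    permutation_importance(fit)$importance[1]
  }, numeric(1))
  expect_lt(abs(mean(imps)), 2 * sd(imps) / sqrt(length(imps)))
})

test_that("a planted effect outranks every noise predictor in most seeds", {
  wins <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      n <- 250
      d <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                      n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
      d$y <- d$signal + rnorm(n, sd = 0.7)
    })
    fit <- fit_forest(d, "y", config = forest_config(
      n_trees = 25, alpha_split = 1, min_node_size = 20, seed = s))
    imp <- permutation_importance(fit)
    which.max(imp$importance) == 1
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("duplicating a predictor neither hurts fit nor doubles importance", {
  withr::local_seed(13)
  n <- 500
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 1.2 * d$x + rnorm(n, sd = 0.6)
  train <- d[1:350, ]
  test <- d[351:500, ]
  cfg <- forest_config(n_trees = 60, alpha_split = 1, min_node_size = 15,
                       importance_mode = "marginal", seed = 8)
  fit1 <- fit_forest(train, "y", config = cfg)
  mse1 <- mean((predict(fit1, test) - test$y)^2)
  imp_single <- permutation_importance(fit1)$importance[1]

  train2 <- train
  test2 <- test
  train2$x_dup <- train2$x
  test2$x_dup <- test2$x
  fit2 <- fit_forest(train2, "y", config = cfg)
  mse2 <- mean((predict(fit2, test2) - test2$y)^2)
  expect_lt(mse2, mse1 * 1.1)  # duplication does not degrade the model

  imp2 <- permutation_importance(fit2, mode = "conditional")
  dup_total <- sum(imp2$importance[imp2$predictor %in% c("x", "x_dup")])
  # conditional importance of the pair splits the credit rather than
  # doubling it
  expect_lt(dup_total, 1.5 * imp_single)
})

test_that("categorical predictors fit, predict, and reject unseen levels", {
  withr::local_seed(3)
  n <- 200
  d <- data.frame(g = factor(sample(letters[1:4], n, TRUE)), z = rnorm(n))
  d$y <- c(a = 0, b = 0, c = 3, d = 3)[as.character(d$g)] + rnorm(n, 0.3)
  fit <- fit_forest(d, "y", config = forest_config(
    n_trees = 20, min_node_size = 15, mtry = 2, seed = 5))
  pred <- predict(fit, d)
  expect_gt(cor(pred, d$y), 0.5)
  bad <- d[1:2, ]
  bad$g <- factor(c("zz", "zz"))
  expect_error(predict(fit, bad), "unseen")
})

test_that("forest JSON serialization names splits and is valid JSON", {
  d <- synthetic_features(n = 150, seed = 2)
  dd <- as.data.frame(d[, c(cmforest:::predictor_columns(d),
                            "multimorbidity")])
  fit <- fit_forest(dd, "multimorbidity", config = forest_config(
    n_trees = 3, alpha_split = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed$trees, 3)
  expect_identical(parsed$outcome, "multimorbidity")
  splitvars <- unlist(purrr::map(parsed$trees, "var"))
  expect_true(all(stats::na.omit(splitvars) %in% fit$predictors))
})
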