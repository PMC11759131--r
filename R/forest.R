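# Conditional-inference regression forest: user-facing API.

#' Configure a conditional-inference forest
#'
#' @param n_trees Number of trees.
#' @param mtry Number of candidate predictors tested at each node; default
#'   `ceiling(sqrt(p))`, resolved at fit time.
#' @param alpha_split Significance level a Bonferroni-adjusted association
#'   p-value must reach for a node to split; `1` disables significance
#'   stopping (splits continue to the node-size limit, as in
#'   unbiased-forest practice).
#' @param subsample_fraction Fraction of rows drawn without replacement for
#'   each tree.
#' @param min_node_size Minimum number of cases in any leaf.
#' @param importance_mode `"conditional"` (permute each predictor within
#'   strata of correlated predictors) or `"marginal"` (permute freely).
#' @param n_importance_permutations Permutations averaged per predictor and
#'   tree when computing importance.
#' @param seed Integer seed; identical config, seed and data give a
#'   bit-identical forest and importance.
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, alpha_split = 0.05,
                          subsample_fraction = 0.632, min_node_size = 20,
                          importance_mode = c("conditional", "marginal"),
                          n_importance_permutations = 1, seed = 1L) {
  importance_mode <- match.arg(importance_mode)
  errs <- character()
  if (!is.numeric(n_trees) || n_trees < 1) errs <- c(errs, "`n_trees` >= 1")
  if (!is.null(mtry) && (!is.numeric(mtry) || mtry < 1))
    errs <- c(errs, "`mtry` >= 1 (or NULL)")
  if (!is.numeric(alpha_split) || alpha_split <= 0 || alpha_split > 1)
    errs <- c(errs, "`alpha_split` in (0, 1]")
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction > 1)
    errs <- c(errs, "`subsample_fraction` in (0, 1]")
  if (!is.numeric(min_node_size) || min_node_size < 1)
    errs <- c(errs, "`min_node_size` >= 1")
  if (!is.numeric(n_importance_permutations) ||
      n_importance_permutations < 1)
    errs <- c(errs, "`n_importance_permutations` >= 1")
  if (length(errs))
    abort(paste0("Invalid forest_config: ", paste(errs, collapse = "; ")))
  structure(list(
    n_trees = as.integer(n_trees), mtry = mtry,
    alpha_split = alpha_split, subsample_fraction = subsample_fraction,
    min_node_size = as.integer(min_node_size),
    importance_mode = importance_mode,
    n_importance_permutations = as.integer(n_importance_permutations),
    seed = as.integer(seed)
  ), class = "forest_config")
}

# Encode a data frame of predictors as a numeric matrix plus per-column
# level counts (0 = numeric, k = categorical with codes 0..k-1).
encode_predictors <- function(data, predictors, xlevels = NULL) {
  n <- nrow(data)
  X <- matrix(0, n, length(predictors),
              dimnames = list(NULL, predictors))
  nlev <- integer(length(predictors))
  xlev <- list()
  for (j in seq_along(predictors)) {
    v <- predictors[j]
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("predictor column `%s` not found.", v))
    if (is.factor(x) || is.character(x)) {
      levs <- if (!is.null(xlevels) && !is.null(xlevels[[v]])) xlevels[[v]]
              else sort(unique(as.character(x)))
      if (length(levs) > 31)
        abort(sprintf("categorical predictor `%s` has > 31 levels.", v))
      code <- match(as.character(x), levs) - 1L
      if (anyNA(code))
        abort(sprintf("predictor `%s` has levels unseen in training.", v))
      X[, j] <- code
      nlev[j] <- length(levs)
      xlev[[v]] <- levs
    } else {
      if (anyNA(x)) abort(sprintf("predictor `%s` contains NA.", v))
      X[, j] <- as.numeric(x)
      nlev[j] <- 0L
    }
  }
  list(X = X, nlev = nlev, xlevels = xlev)
}

#' Association test of the conditional-inference framework
#'
#' Asymptotic permutation test of the standardized linear statistic
#' `T = sum_i g(x_i) y_i` with `g` the identity for numeric `x` and one-hot
#' level indicators for a factor `x`.  `T` is centered and scaled by its
#' conditional permutation mean and covariance and referred to a chi-square
#' distribution (df = rank of the covariance).  This is the test each tree
#' node uses to select its split variable.
#'
#' @param x Predictor: numeric vector or factor.
#' @param y Numeric outcome.
#' @param case_weights Optional 0/1 case inclusion weights (at least two
#'   cases must have positive weight).
#' @return A one-row tibble with `statistic`, `df`, `p_value`.  A constant
#'   `x` or `y` gives `p_value = 1`.
#' @examples
#' association_test(rnorm(30), rnorm(30))
#' @export
association_test <- function(x, y, case_weights = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (!is.null(case_weights)) {
    if (all(case_weights == 0)) abort("all case weights are zero.")
    keep <- case_weights > 0
    x <- x[keep]
    y <- y[keep]
  }
  if (length(y) < 2) abort("need at least 2 cases with positive weight.")
  if (!is.numeric(y)) abort("`y` must be numeric.")
  if (is.factor(x) || is.character(x)) {
    levs <- if (is.factor(x)) levels(x) else sort(unique(x))
    res <- cif_assoc_test_cpp(as.numeric(match(as.character(x), levs) - 1),
                              as.numeric(y), length(levs))
  } else {
    res <- cif_assoc_test_cpp(as.numeric(x), as.numeric(y), 0L)
  }
  tibble::tibble(statistic = res$statistic, df = res$df,
                 p_value = res$p_value)
}

#' Fit a conditional-inference regression forest
#'
#' Grows `n_trees` conditional-inference trees on subsamples drawn without
#' replacement.  At each node, `mtry` randomly chosen candidate predictors
#' are screened with [association_test()]; the node becomes a leaf when the
#' smallest Bonferroni-adjusted p-value exceeds `alpha_split` or the node is
#' smaller than twice `min_node_size`, otherwise it splits on the most
#' significant predictor at the cutpoint maximizing the standardized
#' two-sample statistic of the outcome.
#'
#' @param data A data frame of training rows.
#' @param outcome Name of the numeric outcome column.
#' @param predictors Character vector of predictor columns; default: all
#'   columns except the outcome.
#' @param config A [forest_config()].
#' @return A `cif_forest` object with a [predict][predict.cif_forest]
#'   method.
#' @examples
#' d <- data.frame(x = rnorm(100), z = rnorm(100))
#' d$y <- d$x + rnorm(100, sd = 0.3)
#' f <- fit_forest(d, "y", config = forest_config(n_trees = 20, seed = 1))
#' head(predict(f, d))
#' @export
fit_forest <- function(data, outcome, predictors = NULL,
                       config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  predictors <- predictors %||% setdiff(names(data), outcome)
  if (!outcome %in% names(data))
    abort(sprintf("outcome column `%s` not found.", outcome))
  y <- as.numeric(data[[outcome]])
  if (nrow(data) < config$min_node_size)
    abort("fewer rows than `min_node_size`.")
  enc <- encode_predictors(data, predictors)
  mtry <- config$mtry %||% ceiling(sqrt(length(predictors)))
  mtry <- min(mtry, length(predictors))
  trees <- cif_fit_forest_cpp(
    enc$X, enc$nlev, y, config$n_trees, as.integer(mtry),
    config$alpha_split, config$subsample_fraction, config$min_node_size,
    as.double(config$seed))
  structure(list(
    trees = trees, config = config, outcome = outcome,
    predictors = predictors, nlev = enc$nlev, xlevels = enc$xlevels,
    y_range = range(y), X_train = enc$X, y_train = y
  ), class = "cif_forest")
}

#' @export
print.cif_forest <- function(x, ...) {
  nn <- vapply(x$trees, function(t) length(t$var), integer(1))
  cat(sprintf(
    "<cif_forest> %d trees, %d predictors, outcome `%s`\n", length(x$trees),
    length(x$predictors), x$outcome))
  cat(sprintf("  mean nodes/tree %.1f, alpha_split %.3g, seed %d\n",
              mean(nn), x$config$alpha_split, x$config$seed))
  invisible(x)
}

#' Predict from a conditional-inference forest
#'
#' Predictions are equal-weight means of per-tree leaf means, so they always
#' lie within the training range of the outcome.
#'
#' @param object A `cif_forest`.
#' @param newdata Data frame containing all predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.cif_forest <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing))
    abort(paste("newdata lacks predictor columns:",
                paste(missing, collapse = ", ")))
  enc <- encode_predictors(newdata, object$predictors, object$xlevels)
  cif_predict_cpp(object$trees, enc$X)
}

# Conditioning sets for the conditional importance mode: predictor w
# conditions predictor v when |Pearson r(v, w)| > threshold (on the
# evaluation data, all columns taken numerically).  The permutation strata
# themselves are the partition cells each tree induces on the conditioning
# set with its own cutpoints.
conditioning_sets <- function(X, threshold = 0.2) {
  p <- ncol(X)
  cm <- matrix(FALSE, p, p)
  if (p < 2 || nrow(X) < 8) return(cm)
  sds <- apply(X, 2, sd)
  ok <- which(sds > 0)
  if (length(ok) >= 2) {
    r <- abs(cor(X[, ok, drop = FALSE]))
    cm[ok, ok] <- r > threshold
  }
  diag(cm) <- FALSE
  cm
}

#' Permutation variable importance
#'
#' For each tree, the increase in mean squared error after permuting one
#' predictor over the tree's evaluation cases is recorded; importance is the
#' mean increase across all trees.  With `eval_data = NULL` each tree is
#' evaluated on its out-of-bag rows; otherwise all trees are evaluated on
#' `eval_data` (e.g. a held-out fold).  In `"conditional"` mode the
#' permutation of a predictor is restricted to the cells of the partition
#' each tree itself induces on the predictors correlated with it
#' (|r| > 0.2), so importance reflects a predictor's contribution beyond
#' its correlated companions.  A predictor used by no tree has importance
#' exactly 0.
#'
#' @param forest A fitted `cif_forest`.
#' @param eval_data Optional data frame with predictor and outcome columns.
#' @param mode Override the config's importance mode.
#' @param seed Override the config's seed for the permutation draws.
#' @return A tibble with `predictor` and `importance` (may be negative).
#' @export
permutation_importance <- function(forest, eval_data = NULL, mode = NULL,
                                   seed = NULL) {
  mode <- mode %||% forest$config$importance_mode
  seed <- seed %||% forest$config$seed
  if (is.null(eval_data)) {
    X <- forest$X_train
    y <- forest$y_train
    use_oob <- TRUE
  } else {
    enc <- encode_predictors(eval_data, forest$predictors, forest$xlevels)
    X <- enc$X
    y <- as.numeric(eval_data[[forest$outcome]])
    use_oob <- FALSE
  }
  cond <- if (mode == "conditional")
    conditioning_sets(X)
  else
    matrix(FALSE, ncol(X), ncol(X))
  imp <- cif_importance_cpp(forest$trees, X, y, cond,
                            forest$config$n_importance_permutations,
                            as.double(seed), use_oob)
  tibble::tibble(predictor = forest$predictors, importance = as.numeric(imp))
}

#' Serialize a forest to an inspectable JSON structure
#'
#' Writes every tree's node table (split variable, cutpoint or level mask,
#' adjusted association p-value, node size, node mean) as JSON.
#'
#' @param forest A `cif_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  trees <- lapply(forest$trees, function(t) {
    list(
      var = ifelse(t$var >= 0, forest$predictors[t$var + 1], NA),
      cut = t$cut, level_mask = t$mask, left = t$left, right = t$right,
      node_mean = t$value, p_value = t$pval, n = t$n)
  })
  jsonlite::write_json(
    list(outcome = forest$outcome, predictors = forest$predictors,
         config = unclass(forest$config), trees = trees),
    path, auto_unbox = TRUE, pretty = FALSE, digits = NA, na = "null")
  invisible(path)
}
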