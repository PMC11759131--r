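# Linear sensitivity models: exposure x age-group interactions.

age_group_factor <- function(age, age_grouping) {
  if (is.numeric(age_grouping)) {
    cuts <- sort(unique(c(-Inf, age_grouping, Inf)))
    return(cut(age, cuts, labels = paste0("G", seq_len(length(cuts) - 1)),
               right = TRUE))
  }
  switch(age_grouping,
    tertiles = {
      br <- unique(quantile(age, c(1, 2) / 3, names = FALSE, type = 7))
      cut(age, c(-Inf, br, Inf),
          labels = paste0("G", seq_len(length(br) + 1)), right = TRUE)
    },
    decades = {
      br <- seq(20, 90, by = 10)
      br <- br[br > min(age) & br < max(age)]
      cut(age, c(-Inf, br, Inf),
          labels = paste0("G", seq_len(length(br) + 1)), right = TRUE)
    },
    abort("`age_grouping` must be \"tertiles\", \"decades\", or cut points.")
  )
}

default_sensitivity_covariates <- function(exposure) {
  cov <- c(paste0("s_", .subtypes), "frequency", "severity")
  if (exposure == "severity") cov <- setdiff(cov, "severity")
  if (exposure == "frequency") cov <- setdiff(cov, "frequency")
  # multiplicity is the exact sum of the subtype flags: drop them to keep
  # the design full rank
  if (exposure == "multiplicity") cov <- setdiff(cov, paste0("s_", .subtypes))
  cov
}

#' Linear model of multimorbidity with an exposure-by-age-group interaction
#'
#' Fits, per stratum, the ordinary least squares model
#' `multimorbidity ~ exposure * age_group + covariates`, where `age_group`
#' is a categorical grouping of current age (within-stratum tertiles by
#' default) with the youngest group as reference.  The default covariate
#' set is the four subtype flags plus frequency and severity, pruned of
#' anything collinear with the chosen exposure.  Standardized coefficients
#' are reported as `estimate * sd(x) / sd(outcome)`; the headline
#' interaction beta is the standardized coefficient of
#' `exposure : oldest age group`.
#'
#' @param features Feature tibble.
#' @param exposure One of `"duration"`, `"multiplicity"`, `"severity"`.
#' @param age_grouping `"tertiles"`, `"decades"`, or numeric cut points.
#' @param covariates Covariate columns; `NULL` for the default set.
#' @param stratifier Stratifying column (`NULL` = single stratum).
#' @return A `cm_interaction_fit`; `tidy()` gives coefficients with 95% CIs
#'   and standardized betas, `glance()` gives R-squared, adjusted
#'   R-squared, the headline interaction beta and its p-value.
#' @export
fit_interaction_model <- function(features,
                                  exposure = c("duration", "multiplicity",
                                               "severity"),
                                  age_grouping = "tertiles",
                                  covariates = NULL,
                                  stratifier = "gender") {
  exposure <- match.arg(exposure)
  covariates <- covariates %||% default_sensitivity_covariates(exposure)
  strata <- split_strata(features, stratifier)
  outcome <- "multimorbidity"

  fits <- purrr::imap(strata, function(dat, nm) {
    dat$age_group <- age_group_factor(dat$age, age_grouping)
    kpar <- 2 * nlevels(dat$age_group) + length(covariates)
    if (nrow(dat) < kpar + 2)
      abort(sprintf("stratum `%s` too small for the interaction model.", nm))
    fml <- stats::as.formula(paste(
      outcome, "~", exposure, "* age_group",
      if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
      else ""))
    mm <- model.matrix(fml, dat)
    qrm <- qr(mm)
    if (qrm$rank < ncol(mm)) {
      dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
      abort(sprintf("rank-deficient design in stratum `%s`: collinear %s",
                    nm, paste(dropped, collapse = ", ")))
    }
    fit <- lm(fml, data = dat)
    list(fit = fit, data = dat, stratum = nm)
  })

  structure(list(fits = fits, exposure = exposure,
                 age_grouping = age_grouping, covariates = covariates,
                 outcome = outcome),
            class = "cm_interaction_fit")
}

interaction_terms <- function(fit_obj, stratum_fit) {
  grep(paste0("^", fit_obj$exposure, ":age_group"),
       names(coef(stratum_fit$fit)), value = TRUE)
}

#' @rdname fit_interaction_model
#' @param x A `cm_interaction_fit`.
#' @param ... Unused.
#' @export
tidy.cm_interaction_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$fits, function(s) {
    fit <- s$fit
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    mm <- model.matrix(fit)
    sdy <- sd(fit$model[[1]])
    sdx <- apply(mm, 2, sd)
    tibble::tibble(
      stratum = s$stratum,
      term = rownames(sm),
      estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
      ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2]),
      statistic = unname(sm[, 3]), p_value = unname(sm[, 4]),
      std_beta = unname(sm[, 1] * sdx[rownames(sm)] / sdy))
  }))
}

#' @rdname fit_interaction_model
#' @export
glance.cm_interaction_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$fits, function(s) {
    sm <- summary(s$fit)
    terms <- interaction_terms(x, s)
    headline <- if (length(terms)) terms[length(terms)] else NA_character_
    td <- tidy.cm_interaction_fit(
      structure(list(fits = list(s), exposure = x$exposure),
                class = "cm_interaction_fit"))
    hrow <- td[td$term == headline, ]
    tibble::tibble(
      stratum = s$stratum, n = nrow(s$data),
      r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
      interaction_term = headline,
      interaction_beta = if (nrow(hrow)) hrow$std_beta else NA_real_,
      interaction_p = if (nrow(hrow)) hrow$p_value else NA_real_)
  }))
}

#' @export
print.cm_interaction_fit <- function(x, ...) {
  cat(sprintf("<cm_interaction_fit> exposure `%s` x age groups (%s)\n",
              x$exposure, paste(x$age_grouping, collapse = ",")))
  print(glance(x))
  invisible(x)
}

#' Predicted outcome surface over an exposure grid and age groups
#'
#' Evaluates the fitted linear predictor on a grid of exposure values for
#' each age group, holding covariates at their stratum means.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param exposure_grid Exposure values (clipped to 0-18 with a warning).
#' @return A `cm_surface` tibble: `stratum`, `age_group`, exposure value,
#'   `predicted`.
#' @export
predicted_surface <- function(fit, exposure_grid = 0:18) {
  stopifnot(inherits(fit, "cm_interaction_fit"))
  if (any(exposure_grid < 0 | exposure_grid > 18)) {
    warn("exposure grid clipped to [0, 18].")
    exposure_grid <- pmin(pmax(exposure_grid, 0), 18)
  }
  exposure_grid <- unique(exposure_grid)
  out <- dplyr::bind_rows(purrr::map(fit$fits, function(s) {
    groups <- levels(s$data$age_group)
    grid <- tidyr::expand_grid(exposure = exposure_grid, age_group = groups)
    nd <- tibble::as_tibble(grid)
    names(nd)[1] <- fit$exposure
    nd$age_group <- factor(nd$age_group, levels = groups)
    for (cv in fit$covariates) nd[[cv]] <- mean(s$data[[cv]])
    nd$predicted <- as.numeric(predict(s$fit, newdata = nd))
    nd$stratum <- s$stratum
    nd[, c("stratum", "age_group", fit$exposure, "predicted")]
  }))
  class(out) <- c("cm_surface", class(out))
  attr(out, "exposure") <- fit$exposure
  out
}
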