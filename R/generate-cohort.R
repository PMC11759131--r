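# Synthetic survey cohort generation.

.subtypes <- c("neglect", "physical", "emotional", "sexual")
.diseases <- c("overweight", "diabetes", "cancer", "hypertension",
               "mi", "copd", "stroke")
.freq_levels <- c("fewer than 10", "10-50", "too many to count")
.sev_levels <- c("not at all", "mildly", "seriously", "a great deal")

# Follow-up answer model: cumulative-logit intercepts (slope 0.25 per year of
# exposure duration), chosen so follow-up means match a general-population
# survey profile (see methods vignette).
.freq_cuts <- c(ge2 = -1.6, ge3 = -2.93)
.sev_cuts <- c(ge1 = 1.0, ge2 = -0.1, ge3 = -1.4)

# P(no subtype active) under the shared-liability model with thresholds tau
# and latent correlation rho, by numeric integration over the shared factor.
p_none_given_tau <- function(tau, rho) {
  f <- function(z) {
    out <- stats::dnorm(z)
    for (t in tau)
      out <- out * (1 - stats::pnorm((t - sqrt(rho) * z) / sqrt(1 - rho)))
    out
  }
  stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
}

# Thresholds tau so that, after rejecting all-inactive draws, the conditional
# subtype probabilities hit `target` (fixed point in p_none).
calibrate_thresholds <- function(target, rho) {
  target <- pmin(target, 0.999)
  p_none <- prod(1 - target)
  for (it in 1:40) {
    tau <- stats::qnorm(pmin(0.999, target * (1 - p_none)))
    p_new <- p_none_given_tau(tau, rho)
    if (abs(p_new - p_none) < 1e-10) break
    p_none <- p_new
  }
  tau
}

# truncated-normal draws via inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

ages_to_string <- function(age_list) {
  vapply(age_list, function(a) paste(a, collapse = ";"), character(1))
}

#' Generate a synthetic survey cohort
#'
#' Draws `n_respondents` records with the structure of a retrospective
#' maltreatment survey: demographics, act-level ternary answers (affirmed /
#' denied / declined) for five acts in each of four subtypes, per-age
#' exposure flags for ages 1-18, follow-up frequency and severity answers,
#' and seven binary disease indicators whose probabilities follow a logistic
#' model in exposure duration, timing, age, and income.
#'
#' Subtype co-occurrence uses a single shared Gaussian liability with
#' per-subtype thresholds calibrated (jointly with the all-inactive
#' rejection step) so that marginal subtype prevalences match the configured
#' targets.  Exposure is a contiguous episode with onset drawn from
#' `onset_age_distribution` and geometric length, clipped to ages 1-18 and
#' shared by all active subtypes.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per respondent: `id`, `gender`, `age`,
#'   `income`, 20 act columns `act_<subtype>_<1:5>` coded 1/0/`NA`
#'   (affirm/deny/decline), 4 exposure-age columns `ages_<subtype>`
#'   (semicolon-separated years, `""` if none), `frequency_answer`,
#'   `severity_answer`, and 7 disease columns `dis_<disease>`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_respondents = 100, seed = 7))
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(unclass(config))
  n <- as.integer(config$n_respondents)

  withr::with_seed(child_seed(config$seed, "cohort"), {
    gender <- ifelse(runif(n) < config$prop_women, "woman", "man")
    age <- as.integer(round(rtruncnorm(n, config$age_mean, config$age_sd,
                                       16, 95)))
    income <- rtruncnorm(n, config$income_mean, config$income_sd, 0, Inf)

    exposed <- runif(n) < config$p_any_cm

    # Gender-specific subtype rates: multiplicative adjustment renormalized
    # so pooled prevalences are preserved.
    rates <- matrix(rep(config$subtype_base_rates, each = 2), nrow = 2,
                    dimnames = list(c("woman", "man"), .subtypes))
    for (s in names(config$gender_rate_multipliers)) {
      mult <- config$gender_rate_multipliers[[s]]
      norm <- config$prop_women * mult[["woman"]] +
        (1 - config$prop_women) * mult[["man"]]
      rates[, s] <- rates[, s] * c(mult[["woman"]], mult[["man"]]) / norm
    }

    active <- matrix(FALSE, n, 4, dimnames = list(NULL, .subtypes))
    rho <- config$subtype_latent_cor
    for (g in c("woman", "man")) {
      rows <- which(exposed & gender == g)
      if (!length(rows)) next
      if (config$p_any_cm > 0 && any(rates[g, ] > 0)) {
        target <- pmin(rates[g, ] / config$p_any_cm, 0.999)
        tau <- calibrate_thresholds(target, rho)
        pending <- rows
        for (it in 1:1000) {
          m <- length(pending)
          if (!m) break
          z <- rnorm(m)
          u <- sqrt(rho) * z + sqrt(1 - rho) * matrix(rnorm(m * 4), m, 4)
          act <- sweep(u, 2, tau, "<=")
          ok <- rowSums(act) > 0
          active[pending[ok], ] <- act[ok, , drop = FALSE]
          pending <- pending[!ok]
        }
        if (length(pending))  # vanishing probability; assign a single subtype
          active[pending, which.max(target)] <- TRUE
      }
    }
    exposed <- rowSums(active) > 0  # only realized exposure counts

    # Episode of exposure, shared across the active subtypes.
    exposure_ages <- vector("list", n)
    exposure_ages[] <- list(integer(0))
    draw_episode <- function(m) {
      onset <- sample.int(18, m, replace = TRUE,
                          prob = config$onset_age_distribution)
      len <- 1L + rgeom(m, prob = 1 / config$mean_episode_length)
      Map(function(o, l) seq.int(o, min(o + l - 1L, 18L)), onset, len)
    }
    rows <- which(exposed)
    if (length(rows)) {
      eps <- draw_episode(length(rows))
      if (isTRUE(config$multi_episode)) {
        eps2 <- draw_episode(length(rows))
        eps <- Map(function(a, b) sort(union(a, b)), eps, eps2)
      }
      exposure_ages[rows] <- eps
    }
    duration <- lengths(exposure_ages)

    # Act-level answers: each active subtype affirms >= 1 of its 5 acts.
    acts <- matrix(0L, n, 20)
    colnames(acts) <- paste0("act_", rep(.subtypes, each = 5), "_", 1:5)
    for (j in seq_along(.subtypes)) {
      rows <- which(active[, j])
      if (!length(rows)) next
      a <- matrix(rbinom(length(rows) * 5, 1, 0.35), ncol = 5)
      none <- rowSums(a) == 0
      if (any(none))
        a[cbind(which(none), sample.int(5, sum(none), replace = TRUE))] <- 1L
      acts[rows, (j - 1) * 5 + 1:5] <- a
    }
    if (config$decline_rate > 0) {
      deny <- which(acts == 0L)
      flip <- deny[runif(length(deny)) < config$decline_rate]
      acts[flip] <- NA_integer_
    }

    # Follow-up answers, probability of higher categories increasing in
    # episode length.
    frequency_answer <- rep(NA_character_, n)
    severity_answer <- rep(NA_character_, n)
    rows <- which(exposed)
    if (length(rows)) {
      d <- duration[rows]
      u <- runif(length(rows))
      fr <- 1L + (u < plogis(.freq_cuts[["ge2"]] + 0.25 * d)) +
        (u < plogis(.freq_cuts[["ge3"]] + 0.25 * d))
      frequency_answer[rows] <- .freq_levels[fr]
      u <- runif(length(rows))
      sv <- (u < plogis(.sev_cuts[["ge1"]] + 0.25 * d)) +
        (u < plogis(.sev_cuts[["ge2"]] + 0.25 * d)) +
        (u < plogis(.sev_cuts[["ge3"]] + 0.25 * d))
      severity_answer[rows] <- .sev_levels[sv + 1L]
    }

    # Disease indicators: logistic in duration, timing window, age, income.
    timing_hits <- vapply(seq_len(n), function(i)
      sum(config$beta_timing_window$window %in% exposure_ages[[i]]),
      numeric(1))
    b_dur <- rep(config$beta_duration, n)
    if (config$beta_duration_old_mult != 1) {
      old_cut <- quantile(age, 2 / 3, names = FALSE, type = 7)
      b_dur[age > old_cut] <- config$beta_duration *
        config$beta_duration_old_mult
    }
    eta <- b_dur * duration +
      config$beta_timing_window$coef * timing_hits +
      config$beta_age * (age - 50) +
      config$beta_income * (income - config$income_mean) / config$income_sd

    beta0 <- config$beta0
    if (is.null(beta0)) {
      beta0 <- vapply(config$disease_prevalence, function(target) {
        uniroot(function(b) mean(plogis(b + eta)) - target,
                c(-20, 10), tol = 1e-10)$root
      }, numeric(1))
    }
    diseases <- vapply(seq_len(7), function(d)
      rbinom(n, 1L, plogis(beta0[d] + eta)), integer(n))
    if (n == 1) diseases <- matrix(diseases, nrow = 1)
    colnames(diseases) <- paste0("dis_", .diseases)

    per_subtype_ages <- lapply(seq_along(.subtypes), function(j)
      unname(ifelse(active[, j], ages_to_string(exposure_ages), "")))

    tibble::tibble(
      id = seq_len(n),
      gender = gender,
      age = age,
      income = income,
      !!!tibble::as_tibble(acts),
      ages_neglect = per_subtype_ages[[1]],
      ages_physical = per_subtype_ages[[2]],
      ages_emotional = per_subtype_ages[[3]],
      ages_sexual = per_subtype_ages[[4]],
      frequency_answer = frequency_answer,
      severity_answer = severity_answer,
      !!!tibble::as_tibble(diseases)
    )
  })
}
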