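# Simulation configuration for the synthetic survey generator.

# Default onset-age distribution over ages 1-18.  Obtained by deconvolving
# the per-age exposure prevalence profile of a large German population survey
# against the geometric episode-length survival curve (mean 6 years); see the
# methods vignette.  Normalized at definition time.
.default_onset <- local({
  w <- c(0.0131, 0.0087, 0.0239, 0.0448, 0.0696, 0.1127, 0.0894, 0.1143,
         0.0853, 0.1434, 0.0402, 0.1162, 0.0302, 0.0497, 0.0421, 0.0164,
         0, 0)
  w / sum(w)
})

# Pooled subtype prevalence targets (neglect, physical, emotional, sexual)
.default_subtype_rates <- c(
  neglect = 0.1667, physical = 0.2120, emotional = 0.2291, sexual = 0.0943
)

# Marginal disease prevalence targets used to calibrate per-disease
# intercepts when `beta0` is NULL (overweight, diabetes, cancer,
# hypertension, myocardial infarction, COPD, stroke).
.default_disease_prev <- c(
  overweight = 0.1866, diabetes = 0.0863, cancer = 0.0342,
  hypertension = 0.2466, mi = 0.0326, copd = 0.0179, stroke = 0.0219
)

#' Configure the synthetic survey generator
#'
#' Builds the full parameter set for [generate_cohort()].  The defaults
#' emulate a general-population retrospective maltreatment survey: roughly
#' 36.5% of respondents report at least one maltreatment subtype, subtype
#' prevalences between 6% and 24% with sexual abuse more frequent among
#' women and physical abuse among men, exposure concentrated in contiguous
#' multi-year episodes peaking around ages 8-12, and a 0-7 physical
#' multimorbidity count with mean about 0.6 whose dependence on maltreatment
#' duration and timing is controlled by explicit coefficients.
#'
#' @param n_respondents Number of respondents to generate.
#' @param prop_women Fraction of respondents generated as women.
#' @param age_mean,age_sd Mean and SD (years) of current age, truncated to
#'   16-95 and rounded to whole years.
#' @param income_mean,income_sd Mean and SD of monthly net household income
#'   (currency units), truncated at 0.
#' @param p_any_cm Target prevalence of exposure to at least one subtype.
#' @param subtype_base_rates Named vector of four pooled marginal subtype
#'   prevalences (`neglect`, `physical`, `emotional`, `sexual`).
#' @param gender_rate_multipliers Named list of per-subtype multiplicative
#'   gender adjustments, each `c(woman =, man =)`.  Multipliers are
#'   renormalized against `prop_women` so pooled subtype rates are preserved.
#' @param subtype_latent_cor Latent correlation of the shared Gaussian
#'   liability that induces subtype co-occurrence.
#' @param onset_age_distribution Probability vector over onset ages 1-18;
#'   must sum to 1 (tolerance 1e-9).
#' @param mean_episode_length Mean of the geometric episode length in years.
#' @param multi_episode If `TRUE`, a second independent episode is drawn and
#'   unioned with the first (exposure need not be contiguous).
#' @param decline_rate Probability that a denied act is recorded as a
#'   declined answer (`NA`) instead, to exercise the feature-coding rule.
#' @param beta_duration Log-odds increase per year of exposure duration, on
#'   every disease.
#' @param beta_timing_window List `list(window = <ages>, coef = <number>)`:
#'   an extra log-odds effect for exposure at any age in `window`.
#' @param beta_age Log-odds effect per year of (current age - 50).
#' @param beta_income Log-odds effect per SD of income.
#' @param beta0 Vector of 7 per-disease intercepts, or `NULL` to calibrate
#'   them at generation time so marginal disease prevalences match
#'   `disease_prevalence`.
#' @param disease_prevalence Named vector of 7 marginal disease prevalence
#'   targets used when `beta0` is `NULL`.
#' @param beta_duration_old_mult Multiplier applied to `beta_duration` for
#'   respondents in the oldest within-cohort age tertile (1 = no
#'   modification); used to plant an age-modified duration effect.
#' @param seed Integer seed; identical configuration and seed yield a
#'   byte-identical cohort.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_respondents = 200, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
sim_config <- function(n_respondents = 2500,
                       prop_women = 0.516,
                       age_mean = 50.1, age_sd = 18.0,
                       income_mean = 2782, income_sd = 1603,
                       p_any_cm = 0.365,
                       subtype_base_rates = .default_subtype_rates,
                       gender_rate_multipliers = list(
                         sexual = c(woman = 2, man = 1),
                         physical = c(woman = 1, man = 1.3)
                       ),
                       subtype_latent_cor = 0.4,
                       onset_age_distribution = .default_onset,
                       mean_episode_length = 6,
                       multi_episode = FALSE,
                       decline_rate = 0,
                       beta_duration = 0.13,
                       beta_timing_window = list(window = c(4L, 11L),
                                                 coef = 0.10),
                       beta_age = 0.055,
                       beta_income = -0.15,
                       beta0 = NULL,
                       disease_prevalence = .default_disease_prev,
                       beta_duration_old_mult = 1,
                       seed = 1L) {
  cfg <- list(
    n_respondents = n_respondents, prop_women = prop_women,
    age_mean = age_mean, age_sd = age_sd,
    income_mean = income_mean, income_sd = income_sd,
    p_any_cm = p_any_cm, subtype_base_rates = subtype_base_rates,
    gender_rate_multipliers = gender_rate_multipliers,
    subtype_latent_cor = subtype_latent_cor,
    onset_age_distribution = onset_age_distribution,
    mean_episode_length = mean_episode_length,
    multi_episode = multi_episode, decline_rate = decline_rate,
    beta_duration = beta_duration, beta_timing_window = beta_timing_window,
    beta_age = beta_age, beta_income = beta_income,
    beta0 = beta0, disease_prevalence = disease_prevalence,
    beta_duration_old_mult = beta_duration_old_mult,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  if (!is.numeric(cfg$n_respondents) || length(cfg$n_respondents) != 1 ||
      cfg$n_respondents < 1 || cfg$n_respondents != floor(cfg$n_respondents))
    note("`n_respondents` must be a positive integer.")
  for (f in c("prop_women", "p_any_cm", "decline_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      note(sprintf("`%s` must be a single number in [0, 1].", f))
  }
  if (!is.numeric(cfg$age_sd) || cfg$age_sd <= 0) note("`age_sd` must be > 0.")
  if (!is.numeric(cfg$income_sd) || cfg$income_sd <= 0)
    note("`income_sd` must be > 0.")
  sr <- cfg$subtype_base_rates
  if (!is.numeric(sr) || length(sr) != 4 || any(is.na(sr)) ||
      any(sr < 0) || any(sr > 1))
    note("`subtype_base_rates` must be 4 fractions in [0, 1].")
  else {
    if (is.null(names(sr)))
      names(cfg$subtype_base_rates) <- names(.default_subtype_rates)
    if (cfg$p_any_cm == 0 && any(sr > 0))
      note(paste("`p_any_cm` is 0 but a nonzero subtype rate is requested;",
                 "set `subtype_base_rates` to zero as well."))
    if (cfg$p_any_cm > 0 && any(sr / cfg$p_any_cm > 1))
      note("each subtype rate must be <= `p_any_cm` (subtypes imply exposure).")
  }
  od <- cfg$onset_age_distribution
  if (!is.numeric(od) || length(od) != 18 || any(is.na(od)) || any(od < 0))
    note("`onset_age_distribution` must be 18 nonnegative probabilities.")
  else if (abs(sum(od) - 1) > 1e-9)
    note(sprintf(
      "`onset_age_distribution` must sum to 1 (tolerance 1e-9), got %.12f.",
      sum(od)))
  if (!is.numeric(cfg$mean_episode_length) || cfg$mean_episode_length < 1)
    note("`mean_episode_length` must be >= 1 year.")
  if (!is.numeric(cfg$subtype_latent_cor) || cfg$subtype_latent_cor < 0 ||
      cfg$subtype_latent_cor >= 1)
    note("`subtype_latent_cor` must be in [0, 1).")
  bt <- cfg$beta_timing_window
  if (!is.list(bt) || !all(c("window", "coef") %in% names(bt)) ||
      (length(bt$window) > 0 && !all(bt$window %in% 1:18)))
    note("`beta_timing_window` must be list(window = ages in 1..18, coef = x).")
  if (!is.null(cfg$beta0) && length(cfg$beta0) != 7)
    note("`beta0` must be NULL or a vector of 7 per-disease intercepts.")
  dp <- cfg$disease_prevalence
  if (!is.numeric(dp) || length(dp) != 7 || any(dp <= 0) || any(dp >= 1))
    note("`disease_prevalence` must be 7 fractions in (0, 1).")
  if (!is.numeric(cfg$beta_duration_old_mult) ||
      cfg$beta_duration_old_mult < 0)
    note("`beta_duration_old_mult` must be a nonnegative number.")

  if (length(errs))
    abort(paste0("Invalid sim_config:\n", paste("-", errs, collapse = "\n")))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n = %d, prop_women = %.3f, seed = %d\n",
              x$n_respondents, x$prop_women, x$seed))
  cat(sprintf("  p_any_cm = %.3f; subtype rates: %s\n", x$p_any_cm,
              paste(sprintf("%s %.3f", names(x$subtype_base_rates),
                            x$subtype_base_rates), collapse = ", ")))
  cat(sprintf(
    "  outcome model: beta_duration = %.3f, timing window {%s} coef %.3f\n",
    x$beta_duration, paste(x$beta_timing_window$window, collapse = ","),
    x$beta_timing_window$coef))
  invisible(x)
}
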