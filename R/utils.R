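# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used only to fan one user-facing seed out into per-stage substreams, so
# adding a stage never perturbs the randomness of earlier stages.
str_hash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  m <- 2147480009  # largest prime below 2^31 we care to use
  for (cd in codes) h <- (h * 31 + cd) %% m
  h
}

#' Derive a child seed for a named random substream
#'
#' One global seed fans out to independent per-stage seeds keyed by a stage
#' name, so the randomness consumed by one stage never shifts another's.
#'
#' @param seed Integer master seed.
#' @param stage Character scalar naming the substream.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147480009
  as.integer((abs(seed) %% m * 7919 + str_hash31(stage)) %% m + 1)
}

# round-half-up at `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# "474 of 1297" -> "36.5"
fmt_pct <- function(count, denom, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(100 * count / denom, digits))
}

fmt_mean_sd <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
          round_half_up(mean(x), digits), round_half_up(sd(x), digits))
}

# significance stars at .05 / .01 / .001
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  invisible(x)
}
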