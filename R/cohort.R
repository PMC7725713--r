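# Synthetic cohort generator: participant-level generative model.

#' Cohort specification
#'
#' Defines the generative model of a synthetic case-control cohort: group
#' sizes, per-group age distributions (truncated normals on `age_range`),
#' sex ratios, synthetic standardized-instrument distributions, and the
#' group effects that downstream analyses are meant to recover. Defaults
#' emulate the demographic structure of the reference HDC autism cohort
#' (ASD n = 113, age 11.2 +/- 3.2 years, m/f ratio 96:18; typically
#' developing n = 42, age 16 +/- 4.4, m/f 25:17; ages 5-25).
#'
#' The motor deficit enters through two participant-level parameters: the
#' ASD group's movement amplitude factor `motor_gain` is multiplied by
#' `asd_motor_gain_mult` (< 1: smaller imitative gestures) and its
#' acceleration noise `motor_noise_sd` by `asd_motor_noise_mult`
#' (> 1: higher neuromotor noise). Sociocognitive responses follow logistic
#' models in age whose per-participant intercepts and positive slopes create
#' the developmental trends of the intention and humanness scores.
#'
#' With `null_mode = TRUE` both groups are drawn from the *control*
#' distributions for every generative parameter (group sizes are kept), so
#' any downstream group difference is pure sampling noise.
#'
#' @param n_asd,n_td Group sizes; must be positive.
#' @param age_mean,age_sd Length-2 named vectors (`asd`, `td`) of age
#'   distribution parameters in years.
#' @param age_range Truncation interval for ages, in years.
#' @param male_frac Per-group probability of male sex (converted to fixed
#'   per-group counts to preserve the cohort's sex margins).
#' @param asd_motor_gain_mult,asd_motor_noise_mult Multiplicative group
#'   effects on `motor_gain` and `motor_noise_sd`.
#' @param motor_gain_sdlog,motor_noise_base,motor_noise_sdlog Lognormal
#'   parameters of the individual motor parameters (control group;
#'   `motor_gain` has median 1).
#' @param attribution_slope,humanness_slope Mean per-year increments of the
#'   intention-attribution and humanness logits.
#' @param null_mode Draw both groups from the control distributions.
#' @return An object of class `"hdc_cohort_spec"`.
#' @export
cohort_spec <- function(n_asd = 113, n_td = 42,
                        age_mean = c(asd = 11.2, td = 16),
                        age_sd = c(asd = 3.2, td = 4.4),
                        age_range = c(5, 25),
                        male_frac = c(asd = 96 / 114, td = 25 / 42),
                        asd_motor_gain_mult = 0.8,
                        asd_motor_noise_mult = 1.5,
                        motor_gain_sdlog = 0.15,
                        motor_noise_base = 2,
                        motor_noise_sdlog = 0.3,
                        attribution_slope = 0.12,
                        humanness_slope = 0.08,
                        null_mode = FALSE) {
  if (n_asd < 1 || n_td < 1) stop_hdc("group sizes must be positive")
  structure(
    list(n_asd = n_asd, n_td = n_td, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, male_frac = male_frac,
         asd_motor_gain_mult = asd_motor_gain_mult,
         asd_motor_noise_mult = asd_motor_noise_mult,
         motor_gain_sdlog = motor_gain_sdlog,
         motor_noise_base = motor_noise_base,
         motor_noise_sdlog = motor_noise_sdlog,
         attribution_slope = attribution_slope,
         humanness_slope = humanness_slope,
         null_mode = isTRUE(null_mode)),
    class = "hdc_cohort_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

# Exact-count categorical assignment: round(p * n) of one level, permuted.
sample_counts <- function(n, frac, levels) {
  k <- round(frac * n)
  sample(rep(levels, c(k, n - k)))
}

#' Sample a synthetic cohort
#'
#' Draws one participant table from a [cohort_spec()] generative model. All
#' synthetic standardized-instrument scores (IQ, SRS-2 t, NEPSY-II theory of
#' mind and affect recognition, Purdue Pegboard z) are simple group-shifted
#' normals: they exist to exercise the correlation machinery, not to model
#' the instruments.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: demographics
#'   (`participant_id`, `group`, `sex`, `age`, `handedness`), synthetic
#'   instruments (`iq`, `srs_t`, `nepsy_tom`, `nepsy_af`, `purdue_z`), and
#'   generative motor/sociocognitive parameters (`motor_gain`,
#'   `motor_noise_sd`, `compliance`, `attribution_intercept`,
#'   `attribution_age_slope`, `humanness_intercept`, `humanness_age_slope`).
#' @examples
#' cohort <- sample_cohort(cohort_spec(), seed = 1)
#' dplyr::count(cohort, group)
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "hdc_cohort_spec"))
  with_seed_if(seed, {
    groups <- c(rep("ASD", spec$n_asd), rep("TD", spec$n_td))
    n <- length(groups)
    # under null_mode every generative distribution is the control one
    g <- if (spec$null_mode) rep("td", n) else c("asd", "td")[match(groups, c("ASD", "TD"))]
    gain_mult <- ifelse(g == "asd", spec$asd_motor_gain_mult, 1)
    noise_mult <- ifelse(g == "asd", spec$asd_motor_noise_mult, 1)

    age <- rnorm_trunc(n, spec$age_mean[g], spec$age_sd[g], spec$age_range)
    sex <- character(n)
    for (grp in c("ASD", "TD")) {
      idx <- which(groups == grp)
      sex[idx] <- sample_counts(length(idx), spec$male_frac[[tolower(grp)]],
                                c("m", "f"))
    }
    # handedness emulated but not validated (right-handed ~82%)
    hand <- sample(c("right", "left"), n, replace = TRUE, prob = c(0.82, 0.18))

    shift <- function(mean_asd, mean_td, sd_asd, sd_td) {
      rnorm(n, ifelse(g == "asd", mean_asd, mean_td),
            ifelse(g == "asd", sd_asd, sd_td))
    }
    tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = groups,
      sex = sex,
      age = age,
      handedness = hand,
      iq = shift(101.2, 107.4, 18.5, 13.2),
      srs_t = shift(74.2, 45, 12, 5.4),
      nepsy_tom = shift(18, 22, 4, 4),
      nepsy_af = shift(20, 24, 4, 4),
      purdue_z = shift(-0.8, 0, 1, 1),
      motor_gain = gain_mult * stats::rlnorm(n, 0, spec$motor_gain_sdlog),
      motor_noise_sd = noise_mult *
        stats::rlnorm(n, log(spec$motor_noise_base), spec$motor_noise_sdlog),
      compliance = pmin(2, pmax(0, rnorm(n, 1, 0.25))),
      attribution_intercept = rnorm(n, -0.8, 0.4),
      attribution_age_slope = pmax(0, rnorm(n, spec$attribution_slope, 0.03)),
      humanness_intercept = rnorm(n, -1.2, 0.5),
      humanness_age_slope = pmax(0, rnorm(n, spec$humanness_slope, 0.02))
    )
  })
}
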