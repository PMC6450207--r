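#' @title Behavioural parameter sets
#' @description Cover-class-specific movement, energetics and predation
#'   parameters. Empirically anchored constants: 15-min time steps, 96
#'   per day over a 60-day season (5760 steps); mean 9.1 h (SD 0.7) of
#'   active dispersal per day; perceptual range 100 m; free crossing
#'   between forested classes but only 1% probability of crossing into
#'   unforested ones; female:male ratios of 0.9 for mean step length
#'   (MSL) and 0.97 for mean vector length (MVL); initial energy reserve
#'   5491 kJ and expenditure 10.5 kJ per time step; starvation at 0 kJ.
#'   The per-class multiplier, capture, gain and hazard tables are
#'   package defaults (documented, configurable): the underlying field
#'   estimates were never published as tables.
#' @name params
NULL

#' Movement parameters
#'
#' @param class_table cover-class table the per-class vectors align to.
#' @param msl_multiplier per-class tortuosity multiplier on step length.
#' @param mvl_male per-class male mean vector length in \[0, 1\].
#' @param crossing_prob per-class probability of crossing *into* that
#'   class; defaults to 1 for forested and 0.01 for unforested classes.
#' @param perceptual_range metres (default 100).
#' @param fm_msl,fm_mvl female:male ratios (0.9, 0.97).
#' @param bound_length metres per bound; only the 1:2:3 ratio across the
#'   10/20/30 bounds-per-minute levels matters for inverse modelling on
#'   synthetic landscapes.
#' @return list of class `movement_params`.
#' @export
movement_params <- function(class_table = default_cover_classes(),
                            msl_multiplier = NULL, mvl_male = NULL,
                            crossing_prob = NULL,
                            perceptual_range = 100,
                            fm_msl = 0.9, fm_mvl = 0.97,
                            bound_length = 1.0) {
  k <- nrow(class_table)
  msl_multiplier <- msl_multiplier %||%
    stats::setNames(rep(1, k), class_table$name)
  mvl_male <- mvl_male %||% ifelse(class_table$forested, 0.72, 0.65)
  crossing_prob <- crossing_prob %||%
    ifelse(class_table$forested, 1.0, 0.01)
  stopifnot(all(mvl_male >= 0 & mvl_male <= 1),
            all(msl_multiplier > 0),
            all(crossing_prob >= 0 & crossing_prob <= 1))
  structure(list(class_table = class_table,
                 msl_multiplier = unname(msl_multiplier),
                 mvl_male = unname(mvl_male),
                 crossing_prob = unname(crossing_prob),
                 perceptual_range = perceptual_range,
                 fm_msl = fm_msl, fm_mvl = fm_mvl,
                 bound_length = bound_length),
            class = "movement_params")
}

#' Energetics parameters
#'
#' @param class_table cover-class table.
#' @param initial_reserve starting reserve, kJ (5491).
#' @param cost_per_step expenditure per 15-min step, kJ (10.5).
#' @param reserve_cap storage ceiling, kJ (defaults to the initial
#'   reserve).
#' @param capture_prob per-class probability of a successful prey
#'   capture per *active* step.
#' @param gain_mean,gain_sd per-class energy gain per capture, kJ.
#' @export
energy_params <- function(class_table = default_cover_classes(),
                          initial_reserve = 5491,
                          cost_per_step = 10.5,
                          reserve_cap = initial_reserve,
                          capture_prob = NULL,
                          gain_mean = NULL, gain_sd = NULL) {
  k <- nrow(class_table)
  capture_prob <- capture_prob %||%
    ifelse(class_table$forested, 0.09, 0.01) *
      ifelse(class_table$name == "open_water", 0, 1)
  gain_mean <- gain_mean %||% ifelse(class_table$forested, 420, 150)
  gain_sd <- gain_sd %||% ifelse(class_table$forested, 150, 60)
  stopifnot(all(capture_prob >= 0 & capture_prob <= 1),
            initial_reserve > 0, cost_per_step >= 0,
            reserve_cap >= initial_reserve * 0)
  structure(list(class_table = class_table,
                 initial_reserve = initial_reserve,
                 cost_per_step = cost_per_step,
                 reserve_cap = reserve_cap,
                 capture_prob = unname(capture_prob),
                 gain_mean = unname(gain_mean),
                 gain_sd = unname(gain_sd)),
            class = "energy_params")
}

#' Predation-risk parameters
#'
#' @param class_table cover-class table.
#' @param hazard per-class probability of death by predation per 15-min
#'   step, in \[0, 1). Defaults give a season-long forest mortality near
#'   the empirical 0.17.
#' @export
risk_params <- function(class_table = default_cover_classes(),
                        hazard = NULL) {
  hazard <- hazard %||%
    ifelse(class_table$forested, 2.6e-5, 4e-4)
  stopifnot(all(hazard >= 0 & hazard < 1))
  structure(list(class_table = class_table, hazard = unname(hazard)),
            class = "risk_params")
}

#' Mean step length for a cover class, sex and bound rate
#'
#' Base length = bound rate (bounds/min) x 15 min x bound length (m),
#' scaled by the class tortuosity multiplier; females move 0.9x the male
#' length.
#'
#' @param params a `movement_params`.
#' @param cover cover-class id.
#' @param sex `"M"` or `"F"`.
#' @param bound_rate bounds per minute (10, 20 or 30).
#' @return metres per 15-min step.
#' @export
step_length <- function(params, cover, sex, bound_rate) {
  i <- match(cover, params$class_table$id)
  if (is.na(i)) stop("unknown cover class id: ", cover)
  base <- bound_rate * 15 * params$bound_length * params$msl_multiplier[i]
  if (sex == "F") base * params$fm_msl else base
}
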