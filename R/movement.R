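#' @title Single-step behavioural primitives
#' @description The correlated random walk and survival machinery applied
#'   at every 15-min time step: daily activity scheduling, wrapped-Cauchy
#'   turning, cover-dependent step acceptance, foraging/metabolism and
#'   per-step predation hazard. [run_replicate()] applies the same rules
#'   in its optimised inner loop; these entry points expose them one step
#'   at a time.
#' @name movement
NULL

#' Daily activity schedule
#'
#' Draws the day's active-dispersal duration from Normal(`mean_hours`,
#' `sd_hours`) truncated to \[0, 24\] h, converts it to
#' `ceiling(hours * 4)` 15-min steps, and places them as one contiguous
#' block starting at a uniform random step of the day.
#'
#' @param mean_hours mean active hours per day (9.1).
#' @param sd_hours SD of active hours (0.7).
#' @param steps_per_day steps per day (96).
#' @param seed optional integer seed.
#' @return Integer vector of active step-of-day indices (possibly
#'   empty).
#' @export
daily_activity_schedule <- function(mean_hours = 9.1, sd_hours = 0.7,
                                    steps_per_day = 96L, seed = NULL) {
  stopifnot(mean_hours >= 0, sd_hours >= 0)
  with_seed_(seed, {
    h <- min(24, max(0, stats::rnorm(1, mean_hours, sd_hours)))
    n <- min(steps_per_day, as.integer(ceiling(h * 4)))
    if (n == 0L) return(integer(0))
    start <- sample.int(steps_per_day - n + 1L, 1L)
    seq.int(start, start + n - 1L)
  })
}

# Wrapped-Cauchy turning angles with concentration rho (= mean vector
# length), centred on zero; closed-form inverse-CDF sampler.
rwrapped_cauchy <- function(n, rho) {
  if (rho >= 1) return(rep(0, n))
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  u <- stats::runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

#' Draw a new heading from a wrapped-Cauchy turn
#'
#' The turn is wrapped-Cauchy distributed with concentration equal to
#' the mean vector length (MVL): `mvl = 1` moves dead straight, `mvl =
#' 0` turns uniformly.
#'
#' @param previous_heading radians.
#' @param mvl mean vector length in \[0, 1\].
#' @param n number of draws.
#' @param seed optional seed.
#' @return headings in \[0, 2*pi).
#' @export
draw_heading <- function(previous_heading, mvl, n = 1L, seed = NULL) {
  if (mvl < 0 || mvl > 1) stop("mvl must lie in [0, 1]")
  with_seed_(seed,
             (previous_heading + rwrapped_cauchy(n, mvl)) %% (2 * pi))
}

#' Propose and resolve one movement step
#'
#' Uses the *current* cell's cover class for step length and turning
#' concentration. A proposed destination in a forested class is accepted
#' outright; one in an unforested class is accepted with that class's
#' crossing probability (1% by default); a destination outside the
#' extent is never accepted (the boundary behaves as an uncrossable
#' unforested class). On rejection the heading is redrawn, up to
#' `max_retries` times, after which the agent stays put.
#'
#' @param x,y position in metres.
#' @param heading radians.
#' @param grid a `cover_grid`.
#' @param params a `movement_params`.
#' @param sex `"M"` or `"F"`.
#' @param bound_rate bounds per minute.
#' @param max_retries heading redraws before staying put.
#' @param seed optional seed.
#' @return list `x`, `y`, `heading`, `moved`.
#' @export
attempt_move <- function(x, y, heading, grid, params, sex = "M",
                         bound_rate = 30, max_retries = 20L,
                         seed = NULL) {
  nx <- nrow(grid$cells); ny <- ncol(grid$cells)
  cs <- grid$cell_size
  cls_tab <- params$class_table
  forested <- class_lookup(cls_tab, "forested")
  cross <- rep(NA_real_, max(cls_tab$id))
  cross[cls_tab$id] <- params$crossing_prob
  cix <- coord_to_cell(x, cs); ciy <- coord_to_cell(y, cs)
  cover <- grid$cells[cix, ciy]
  len <- step_length(params, cover, sex, bound_rate)
  mvl <- params$mvl_male[match(cover, cls_tab$id)]
  if (sex == "F") mvl <- mvl * params$fm_mvl
  with_seed_(seed, {
    h <- heading
    for (tr in seq_len(max_retries)) {
      h <- (h + rwrapped_cauchy(1, mvl)) %% (2 * pi)
      px <- x + len * cos(h); py <- y + len * sin(h)
      dx <- coord_to_cell(px, cs); dy <- coord_to_cell(py, cs)
      if (dx < 1 || dx > nx || dy < 1 || dy > ny) next
      dest <- grid$cells[dx, dy]
      if (forested[dest] == 1 || stats::runif(1) < cross[dest])
        return(list(x = px, y = py, heading = h, moved = TRUE))
    }
    list(x = x, y = y, heading = h, moved = FALSE)
  })
}

#' Forage and metabolise for one time step
#'
#' Every step costs `cost_per_step` kJ (active or resting). During an
#' active step the agent additionally attempts a prey capture with the
#' current cover's capture probability; on success it gains a
#' Normal(gain mean, gain SD) amount truncated at zero, capped at the
#' reserve ceiling. A reserve at or below 0 kJ is starvation.
#'
#' @param energy current reserve (kJ).
#' @param cover cover-class id.
#' @param energy_params an `energy_params`.
#' @param active is this an active step?
#' @param seed optional seed.
#' @return list `energy`, `starved`, `gain`.
#' @export
forage_and_metabolize <- function(energy, cover, energy_params,
                                  active = TRUE, seed = NULL) {
  i <- match(cover, energy_params$class_table$id)
  if (is.na(i)) stop("unknown cover class id: ", cover)
  with_seed_(seed, {
    e <- energy - energy_params$cost_per_step
    gain <- 0
    if (active && stats::runif(1) < energy_params$capture_prob[i]) {
      gain <- max(0, stats::rnorm(1, energy_params$gain_mean[i],
                                  energy_params$gain_sd[i]))
      e <- min(energy_params$reserve_cap, e + gain)
    }
    list(energy = max(e, 0), starved = e <= 0, gain = gain)
  })
}

#' Apply one step of predation hazard
#'
#' @param cover cover-class id.
#' @param risk_params a `risk_params`.
#' @param seed optional seed.
#' @return `TRUE` when the agent dies of predation this step.
#' @export
apply_predation <- function(cover, risk_params, seed = NULL) {
  i <- match(cover, risk_params$class_table$id)
  if (is.na(i)) stop("unknown cover class id: ", cover)
  with_seed_(seed, stats::runif(1) < risk_params$hazard[i])
}
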