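#' @title The dispersal simulator
#' @description Simulates each translocated disperser through the 60-day
#'   season at 15-min resolution: correlated random-walk movement with
#'   cover-specific parameters, foraging and starvation, per-step
#'   predation hazard, candidate-site memory within a 100-m perceptual
#'   range, and territorial home-range establishment under the
#'   scenario's selectivity schedule and exploration rule. Agents are
#'   updated step by step; within a step, settlements claim occupancy in
#'   release order.
#' @name dispersal_sim
NULL

#' Scenario configuration
#'
#' One row of the factorial study design: a selectivity rule (static
#' single threshold or dynamic descending thresholds with immediate or
#' delayed map swapping), an optional required 2-week exploration phase,
#' and a bound rate.
#'
#' @param name scenario label.
#' @param thresholds percent-rule threshold(s), descending.
#' @param exploration require a 14-day exploration phase before
#'   settlement attempts?
#' @param timing `"immediate"` or `"delayed"` dynamic map swapping.
#' @param bound_rate bounds per minute (10, 20 or 30).
#' @param season_days,steps_per_day season structure (60 d x 96 steps).
#' @param exploration_days exploration-phase length (14).
#' @param replicates replicates per combination (5).
#' @export
scenario_config <- function(name, thresholds, exploration = FALSE,
                            timing = c("immediate", "delayed"),
                            bound_rate = 30, season_days = 60L,
                            steps_per_day = 96L, exploration_days = 14L,
                            replicates = 5L) {
  timing <- match.arg(timing)
  stopifnot(bound_rate %in% c(10, 20, 30))
  structure(list(name = name, thresholds = thresholds,
                 exploration = exploration, timing = timing,
                 bound_rate = bound_rate,
                 season_days = as.integer(season_days),
                 steps_per_day = as.integer(steps_per_day),
                 exploration_days = as.integer(exploration_days),
                 replicates = as.integer(replicates)),
            class = "scenario_config")
}

#' Total time steps in a season
#'
#' @param config a `scenario_config`.
#' @return e.g. 5760 for the default 60-day, 96-step season.
#' @export
season_steps <- function(config) {
  config$season_days * config$steps_per_day
}

empty_memory <- function() {
  data.frame(x = numeric(0), y = numeric(0), anchor_ix = integer(0),
             anchor_iy = integer(0), patch = integer(0),
             map_index = integer(0), area = numeric(0),
             food = numeric(0), risk = numeric(0), step = integer(0))
}

#' Scan the perceptual range and remember candidate sites
#'
#' Scans all cells whose centres lie within the perceptual range of the
#' position. Any suitable cell belonging to a contiguous suitable patch
#' of at least `min_patch_area` (10% of the minimum home-range size)
#' whose patch is not already in memory for the active map is appended
#' as a candidate site, scored by the patch means of food value and
#' predation hazard.
#'
#' @param x,y position (m).
#' @param patches a [label_patches()] result for the active map.
#' @param cell_size metres.
#' @param memory candidate-site `data.frame` (or `NULL`).
#' @param min_patch_area m^2.
#' @param perceptual_range metres (100).
#' @param map_index index of the active map in its stack.
#' @param step discovery step counter.
#' @param patch_food,patch_risk optional per-patch score vectors.
#' @return updated memory `data.frame`.
#' @export
perceive_and_remember <- function(x, y, patches, cell_size,
                                  memory = NULL, min_patch_area,
                                  perceptual_range = 100,
                                  map_index = 1L, step = 0L,
                                  patch_food = NULL, patch_risk = NULL) {
  if (is.null(memory)) memory <- empty_memory()
  L <- patches$labels
  nx <- nrow(L); ny <- ncol(L)
  r <- ceiling(perceptual_range / cell_size)
  cx <- coord_to_cell(x, cell_size); cy <- coord_to_cell(y, cell_size)
  mxs <- rep(cx + (-r:r), times = 2 * r + 1)
  mys <- rep(cy + (-r:r), each = 2 * r + 1)
  ok <- mxs >= 1 & mxs <= nx & mys >= 1 & mys <= ny
  mxs <- mxs[ok]; mys <- mys[ok]
  d2 <- (cell_center(mxs, cell_size) - x)^2 +
        (cell_center(mys, cell_size) - y)^2
  ok <- d2 <= perceptual_range^2
  mxs <- mxs[ok]; mys <- mys[ok]
  labs <- L[cbind(mxs, mys)]
  for (j in seq_along(labs)) {
    p <- labs[j]
    if (p == 0L) next
    if (patches$areas[p] < min_patch_area) next
    if (any(memory$patch == p & memory$map_index == map_index)) next
    memory <- rbind(memory, data.frame(
      x = cell_center(mxs[j], cell_size),
      y = cell_center(mys[j], cell_size),
      anchor_ix = mxs[j], anchor_iy = mys[j],
      patch = p, map_index = map_index,
      area = patches$areas[p],
      food = if (is.null(patch_food)) 0 else patch_food[p],
      risk = if (is.null(patch_risk)) 0 else patch_risk[p],
      step = as.integer(step)))
  }
  memory
}

#' Rank remembered candidate sites
#'
#' Score = `w_food * z(food) - w_risk * z(risk) - w_dist * z(distance)`
#' with min-max normalisation over the memory; descending score, ties
#' broken by earlier discovery step.
#'
#' @param memory candidate-site `data.frame`.
#' @param x,y current position (m).
#' @param weights numeric `c(food, risk, distance)`.
#' @return memory reordered best-first.
#' @export
rank_sites <- function(memory, x, y, weights = c(1, 1, 1)) {
  if (is.null(memory) || nrow(memory) == 0) stop("memory is empty")
  z <- function(v) {
    rng <- range(v)
    if (rng[2] == rng[1]) return(rep(0, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  d <- sqrt((memory$x - x)^2 + (memory$y - y)^2)
  score <- weights[1] * z(memory$food) - weights[2] * z(memory$risk) -
    weights[3] * z(d)
  memory[order(-score, memory$step), , drop = FALSE]
}

# Is settlement permitted on `day` under this scenario's exploration rule?
settlement_permitted <- function(config, day) {
  !config$exploration || day > config$exploration_days
}

#' Phase transitions of the settlement state machine
#'
#' Applies one decision point of the settlement logic to an agent-state
#' list: an exploring agent with a non-empty memory (and settlement
#' permitted on `day`) orients toward its top-ranked site; an orienting
#' agent that has arrived within perceptual range of its target attempts
#' to grow a home range of the sex-specific minimum area on the current
#' active map, settling on success and otherwise dropping the site and
#' re-ranking.
#'
#' @param agent list with `x`, `y`, `sex`, `phase` (`"exploring"`,
#'   `"orienting"`, `"settled"`), `memory`, and optionally `target`
#'   (a one-row memory slice).
#' @param stack a `suitability_stack`.
#' @param occupancy an `occupancy_field` (or list with `M`/`F`
#'   matrices).
#' @param config a `scenario_config`.
#' @param day current day.
#' @param min_homerange_area named `c(F = ..., M = ...)` m^2.
#' @param perceptual_range metres.
#' @param weights site-ranking weights.
#' @param territory_id id stamped into occupancy on success.
#' @return list `agent`, `occupancy`, `settled` (logical),
#'   `territory` (or `NULL`).
#' @export
settlement_controller <- function(agent, stack, occupancy, config, day,
                                  min_homerange_area = c(F = 3e6, M = 5e6),
                                  perceptual_range = 100,
                                  weights = c(1, 1, 1),
                                  territory_id = 1L) {
  out <- list(agent = agent, occupancy = occupancy, settled = FALSE,
              territory = NULL)
  if (!settlement_permitted(config, day)) return(out)
  if (agent$phase == "exploring") {
    if (!is.null(agent$memory) && nrow(agent$memory) > 0) {
      agent$memory <- rank_sites(agent$memory, agent$x, agent$y, weights)
      agent$target <- agent$memory[1, , drop = FALSE]
      agent$phase <- "orienting"
    }
    out$agent <- agent
    return(out)
  }
  if (agent$phase != "orienting") return(out)
  d2 <- (agent$target$x - agent$x)^2 + (agent$target$y - agent$y)^2
  if (d2 > perceptual_range^2) {
    out$agent <- agent
    return(out)
  }
  map <- active_map(stack, day)
  occ <- occupancy[[agent$sex]]
  seedc <- c(agent$target$anchor_ix, agent$target$anchor_iy)
  terr <- NULL
  if (map$suitable[seedc[1], seedc[2]] && occ[seedc[1], seedc[2]] == 0L)
    terr <- grow_territory(seedc, map, occ,
                           unname(min_homerange_area[agent$sex]))
  if (!is.null(terr)) {
    occ[terr$cells] <- territory_id
    occupancy[[agent$sex]] <- occ
    agent$phase <- "settled"
    agent$centroid <- terr$centroid
    out <- list(agent = agent, occupancy = occupancy, settled = TRUE,
                territory = terr)
    return(out)
  }
  # failed attempt: drop the site, try the next or resume exploring
  keep <- !(agent$memory$patch == agent$target$patch &
            agent$memory$map_index == agent$target$map_index)
  agent$memory <- agent$memory[keep, , drop = FALSE]
  if (nrow(agent$memory) > 0) {
    agent$memory <- rank_sites(agent$memory, agent$x, agent$y, weights)
    agent$target <- agent$memory[1, , drop = FALSE]
  } else {
    agent$phase <- "exploring"
    agent$target <- NULL
  }
  out$agent <- agent
  out
}
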