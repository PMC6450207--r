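#' Simulate one replicate of the dispersal season
#'
#' Runs every released agent step by step through the full season
#' (default 60 days x 96 fifteen-minute steps = 5760 steps). Each step,
#' resting agents pay metabolic cost and predation hazard; active agents
#' additionally move (correlated random walk, or directed travel while
#' orienting to a remembered site), forage, scan their perceptual range
#' for candidate home-range sites, and attempt settlement when the
#' scenario permits it. Agents are processed in release order, so
#' same-step settlement conflicts resolve in favour of the
#' earlier-released individual. Terminal fates: `settled`, `predation`,
#' `starvation`, or `season_end` for unsettled survivors.
#'
#' @param releases release set `data.frame` (`id`, `x`, `y`, `sex`).
#' @param grid a `cover_grid`.
#' @param stack a `suitability_stack` built for the scenario.
#' @param occupancy an `occupancy_field` of resident territories (not
#'   modified; the replicate works on a copy).
#' @param config a `scenario_config`.
#' @param move_par,energy_par,risk_par parameter sets; defaults derive
#'   from the grid's class table.
#' @param min_homerange_area named `c(F = ..., M = ...)` m^2.
#' @param site_weights food/risk/distance ranking weights.
#' @param seed integer seed; runs are fully reproducible.
#' @param record_trajectories keep per-step positions (memory-heavy;
#'   intended for small runs).
#' @return `data.frame` with one row per agent: `id`, `sex`, release
#'   coordinates, `fate`, `settle_day`, home-range centroid, final
#'   energy. Attributes: `steps` (season step count), `n_settled`,
#'   `occupancy` (the post-settlement per-sex occupancy matrices),
#'   `attempts` (per-agent settlement-attempt diagnostics), and
#'   `trajectories` (when recorded).
#' @export
run_replicate <- function(releases, grid, stack, occupancy, config,
                          move_par = NULL, energy_par = NULL,
                          risk_par = NULL,
                          min_homerange_area = c(F = 3e6, M = 5e6),
                          site_weights = c(1, 1, 1), seed = NULL,
                          record_trajectories = FALSE) {
  move_par <- move_par %||% movement_params(grid$classes)
  energy_par <- energy_par %||% energy_params(grid$classes)
  risk_par <- risk_par %||% risk_params(grid$classes)
  nx <- nrow(grid$cells); ny <- ncol(grid$cells)
  if (!identical(dim(grid$cells), dim(stack$maps[[1]]$suitable)))
    stop("grid and suitability stack extents differ")
  cs <- grid$cell_size
  n <- nrow(releases)
  empty <- data.frame(id = integer(0), sex = character(0),
                      x_release = numeric(0), y_release = numeric(0),
                      fate = character(0), settle_day = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      energy = numeric(0))
  if (n == 0L) {
    attr(empty, "steps") <- season_steps(config)
    return(empty)
  }

  ids <- grid$classes$id
  mk <- function(v) { out <- rep(NA_real_, max(ids)); out[ids] <- v; out }
  forested_v <- mk(as.numeric(grid$classes$forested))
  cross_v <- mk(move_par$crossing_prob)
  capture_v <- mk(energy_par$capture_prob)
  gmean_v <- mk(energy_par$gain_mean)
  gsd_v <- mk(energy_par$gain_sd)
  hazard_v <- mk(risk_par$hazard)
  base_len <- config$bound_rate * 15 * move_par$bound_length
  msl <- list(M = mk(base_len * move_par$msl_multiplier),
              F = mk(base_len * move_par$msl_multiplier * move_par$fm_msl))
  mvl <- list(M = mk(move_par$mvl_male),
              F = mk(pmin(1, move_par$mvl_male * move_par$fm_mvl)))
  p_range <- move_par$perceptual_range
  cost <- energy_par$cost_per_step
  cap <- energy_par$reserve_cap
  cells_flat <- as.integer(grid$cells)

  n_maps <- length(stack$maps)
  labs_flat <- lapply(stack$patches, function(p) as.integer(p$labels))
  areas_l <- lapply(stack$patches, function(p) p$areas)
  food_cell <- capture_v[cells_flat] * gmean_v[cells_flat]
  risk_cell <- hazard_v[cells_flat]
  patch_food <- vector("list", n_maps)
  patch_risk <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    lf <- labs_flat[[m]]
    sel <- lf > 0L
    if (any(sel)) {
      patch_food[[m]] <- as.numeric(
        tapply(food_cell[sel], lf[sel], mean))
      patch_risk[[m]] <- as.numeric(
        tapply(risk_cell[sel], lf[sel], mean))
    } else {
      patch_food[[m]] <- patch_risk[[m]] <- numeric(0)
    }
  }
  day_map <- integer(config$season_days)
  for (d in seq_len(config$season_days))
    day_map[d] <- active_map(stack, d, index = TRUE)

  occ <- list(M = occupancy$M, F = occupancy$F)
  terr_id0 <- length(occupancy$territories %||% list())

  # perceptual offsets (block bounded by the range in cells)
  pr <- ceiling(p_range / cs)
  off_dx <- rep(-pr:pr, times = 2 * pr + 1)
  off_dy <- rep(-pr:pr, each = 2 * pr + 1)

  spd <- config$steps_per_day
  expl_ok_day <- if (config$exploration) config$exploration_days + 1L else 1L
  min_hr <- c(M = unname(min_homerange_area["M"]),
              F = unname(min_homerange_area["F"]))
  min_patch <- min_hr * 0.1

  with_seed_(seed, {
    x <- releases$x; y <- releases$y
    sex <- releases$sex
    heading <- stats::runif(n, 0, 2 * pi)
    cix <- coord_to_cell(x, cs); ciy <- coord_to_cell(y, cs)
    energy <- rep(energy_par$initial_reserve, n)
    phase <- rep(0L, n)  # 0 exploring, 1 orienting, 2 settled, 3 dead
    fate <- rep(NA_character_, n)
    settle_day <- rep(NA_integer_, n)
    cent_x <- rep(NA_real_, n); cent_y <- rep(NA_real_, n)
    tgt_x <- rep(NA_real_, n); tgt_y <- rep(NA_real_, n)
    tgt_ix <- rep(NA_integer_, n); tgt_iy <- rep(NA_integer_, n)
    tgt_patch <- rep(NA_integer_, n); tgt_map <- rep(NA_integer_, n)
    mem <- replicate(n, list(x = numeric(0), y = numeric(0),
                             aix = integer(0), aiy = integer(0),
                             patch = integer(0), map = integer(0),
                             food = numeric(0), risk = numeric(0),
                             step = integer(0)), simplify = FALSE)
    seen <- replicate(n, lapply(seq_len(n_maps), function(m)
      logical(length(areas_l[[m]]))), simplify = FALSE)
    act_start <- integer(n); act_len <- integer(n)
    n_attempts <- integer(n); n_fail_small <- integer(n)
    n_fail_blocked <- integer(n)
    traj <- if (record_trajectories)
      replicate(n, matrix(NA_real_, 0, 4,
                          dimnames = list(NULL, c("x", "y", "energy",
                                                  "phase"))),
                simplify = FALSE) else NULL

    wf <- site_weights[1]; wr <- site_weights[2]; wd <- site_weights[3]
    zmm <- function(v) {
      rng <- range(v)
      if (rng[2] == rng[1]) rep(0, length(v))
      else (v - rng[1]) / (rng[2] - rng[1])
    }
    retarget <- function(i) {
      M <- mem[[i]]
      d <- sqrt((M$x - x[i])^2 + (M$y - y[i])^2)
      sc <- wf * zmm(M$food) - wr * zmm(M$risk) - wd * zmm(d)
      b <- order(-sc, M$step)[1]
      tgt_x[i] <<- M$x[b]; tgt_y[i] <<- M$y[b]
      tgt_ix[i] <<- M$aix[b]; tgt_iy[i] <<- M$aiy[b]
      tgt_patch[i] <<- M$patch[b]; tgt_map[i] <<- M$map[b]
      phase[i] <<- 1L
    }
    drop_target <- function(i) {
      M <- mem[[i]]
      keep <- !(M$patch == tgt_patch[i] & M$map == tgt_map[i])
      mem[[i]] <<- lapply(M, function(v) v[keep])
    }

    step_global <- 0L
    for (day in seq_len(config$season_days)) {
      m_idx <- day_map[day]
      L <- labs_flat[[m_idx]]
      areas_m <- areas_l[[m_idx]]
      pf_m <- patch_food[[m_idx]]
      prk_m <- patch_risk[[m_idx]]
      suit_m <- stack$maps[[m_idx]]$suitable
      any_patch <- length(areas_m) > 0L
      permitted <- day >= expl_ok_day

      live <- which(phase < 2L)
      if (!length(live)) break
      hrs <- pmin(24, pmax(0, stats::rnorm(length(live), 9.1, 0.7)))
      nact <- pmin(spd, as.integer(ceiling(hrs * 4)))
      act_len[live] <- nact
      act_start[live] <- 1L +
        as.integer(floor(stats::runif(length(live)) * (spd - nact + 1L)))

      for (s in seq_len(spd)) {
        step_global <- step_global + 1L
        live <- which(phase < 2L)
        if (!length(live)) break
        is_act <- s >= act_start[live] & s < act_start[live] + act_len[live]
        resting <- live[!is_act]
        active <- live[is_act]

        if (length(resting)) {
          energy[resting] <- energy[resting] - cost
          starv <- resting[energy[resting] <= 0]
          if (length(starv)) {
            phase[starv] <- 3L; fate[starv] <- "starvation"
            energy[starv] <- 0
            resting <- setdiff(resting, starv)
          }
          if (length(resting)) {
            cls <- cells_flat[cix[resting] + (ciy[resting] - 1L) * nx]
            dead <- resting[stats::runif(length(resting)) < hazard_v[cls]]
            if (length(dead)) {
              phase[dead] <- 3L; fate[dead] <- "predation"
            }
          }
        }

        for (i in active) {
          ccell <- cix[i] + (ciy[i] - 1L) * nx
          cls <- cells_flat[ccell]
          sxi <- sex[i]
          len <- msl[[sxi]][cls]
          rho <- mvl[[sxi]][cls]
          orienting <- phase[i] == 1L
          h <- heading[i]
          if (orienting) {
            h <- atan2(tgt_y[i] - y[i], tgt_x[i] - x[i])
            # travel no farther than the target: a fixed-length step
            # would orbit the arrival ring without ever entering it
            dt <- sqrt((tgt_x[i] - x[i])^2 + (tgt_y[i] - y[i])^2)
            if (dt < len) len <- dt
          }
          moved <- FALSE
          for (retry in 1:10) {
            if (!(orienting && retry == 1L)) {
              u <- stats::runif(1)
              h <- (h + 2 * atan(((1 - rho) / (1 + rho)) *
                                 tan(pi * (u - 0.5)))) %% (2 * pi)
            }
            px <- x[i] + len * cos(h)
            py <- y[i] + len * sin(h)
            dxc <- floor(px / cs) + 1
            dyc <- floor(py / cs) + 1
            if (dxc < 1 || dxc > nx || dyc < 1 || dyc > ny) next
            dcls <- cells_flat[dxc + (dyc - 1) * nx]
            if (forested_v[dcls] == 1 || stats::runif(1) < cross_v[dcls]) {
              x[i] <- px; y[i] <- py
              cix[i] <- as.integer(dxc); ciy[i] <- as.integer(dyc)
              moved <- TRUE
              break
            }
          }
          heading[i] <- h
          if (record_trajectories)  # energy is the pre-foraging reserve
            traj[[i]] <- rbind(traj[[i]], c(x[i], y[i], energy[i],
                                            phase[i]))

          ccell <- cix[i] + (ciy[i] - 1L) * nx
          cls <- cells_flat[ccell]
          e <- energy[i] - cost
          if (stats::runif(1) < capture_v[cls]) {
            g <- stats::rnorm(1, gmean_v[cls], gsd_v[cls])
            if (g > 0) e <- min(cap, e + g)
          }
          if (e <= 0) {
            energy[i] <- 0; phase[i] <- 3L; fate[i] <- "starvation"
            next
          }
          energy[i] <- e
          if (stats::runif(1) < hazard_v[cls]) {
            phase[i] <- 3L; fate[i] <- "predation"
            next
          }

          if (any_patch) {
            mxs <- cix[i] + off_dx
            mys <- ciy[i] + off_dy
            ok <- mxs >= 1L & mxs <= nx & mys >= 1L & mys <= ny
            if (!all(ok)) { mxs <- mxs[ok]; mys <- mys[ok] }
            d2 <- ((mxs - 0.5) * cs - x[i])^2 + ((mys - 0.5) * cs - y[i])^2
            inr <- d2 <= p_range^2
            vx <- mxs[inr]; vy <- mys[inr]
            labs_all <- L[vx + (vy - 1L) * nx]
            labs <- labs_all[labs_all > 0L]
            if (length(labs)) {
              sv <- seen[[i]][[m_idx]]
              for (p in unique(labs)) {
                if (sv[p]) next
                sv[p] <- TRUE
                if (areas_m[p] >= min_patch[[sxi]]) {
                  j <- which(labs_all == p)[1]
                  axi <- vx[j]; ayi <- vy[j]
                  M <- mem[[i]]
                  M$x <- c(M$x, (axi - 0.5) * cs)
                  M$y <- c(M$y, (ayi - 0.5) * cs)
                  M$aix <- c(M$aix, axi); M$aiy <- c(M$aiy, ayi)
                  M$patch <- c(M$patch, p); M$map <- c(M$map, m_idx)
                  M$food <- c(M$food, pf_m[p])
                  M$risk <- c(M$risk, prk_m[p])
                  M$step <- c(M$step, step_global)
                  mem[[i]] <- M
                }
              }
              seen[[i]][[m_idx]] <- sv
            }
          }

          if (!permitted) next
          if (phase[i] == 0L && length(mem[[i]]$x)) retarget(i)
          if (phase[i] == 1L) {
            if ((tgt_x[i] - x[i])^2 + (tgt_y[i] - y[i])^2 <= p_range^2) {
              sxm <- occ[[sxi]]
              terr <- NULL
              n_attempts[i] <- n_attempts[i] + 1L
              blocked <- !(suit_m[tgt_ix[i], tgt_iy[i]] &&
                           sxm[tgt_ix[i], tgt_iy[i]] == 0L)
              if (blocked) n_fail_blocked[i] <- n_fail_blocked[i] + 1L
              else {
                terr <- grow_territory(c(tgt_ix[i], tgt_iy[i]),
                                       suit_m, sxm, min_hr[[sxi]],
                                       cell_size = cs)
                if (is.null(terr))
                  n_fail_small[i] <- n_fail_small[i] + 1L
              }
              if (!is.null(terr)) {
                sxm[terr$cells] <- terr_id0 + i
                occ[[sxi]] <- sxm
                phase[i] <- 2L
                fate[i] <- "settled"
                settle_day[i] <- day
                cent_x[i] <- terr$centroid[1]
                cent_y[i] <- terr$centroid[2]
              } else {
                drop_target(i)
                if (length(mem[[i]]$x)) retarget(i)
                else { phase[i] <- 0L }
              }
            }
          }
        }
      }
    }

    unsettled <- which(phase < 2L)
    fate[unsettled] <- "season_end"
    out <- data.frame(id = releases$id, sex = sex,
                      x_release = releases$x, y_release = releases$y,
                      fate = fate, settle_day = settle_day,
                      centroid_x = cent_x, centroid_y = cent_y,
                      energy = energy, stringsAsFactors = FALSE)
    attr(out, "steps") <- season_steps(config)
    attr(out, "n_settled") <- sum(fate == "settled")
    attr(out, "attempts") <- data.frame(
      id = releases$id, attempts = n_attempts,
      fail_blocked = n_fail_blocked, fail_small = n_fail_small,
      memory_size = vapply(mem, function(m) length(m$x), integer(1)),
      end_phase = phase)
    attr(out, "occupancy") <- occ
    if (record_trajectories) attr(out, "trajectories") <- traj
    out
  })
}
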