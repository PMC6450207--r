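# Hand-built one-map stack with two square suitable patches.
two_patch_world <- function(nx = 20, ny = 20) {
  suit <- matrix(FALSE, nx, ny)
  suit[2:5, 2:5] <- TRUE     # patch A (16 cells)
  suit[14:17, 14:17] <- TRUE # patch B (16 cells)
  map <- structure(list(suitable = suit, threshold = 0.7,
                        window_area = 1e6, cell_size = 100),
                   class = "suitability_map")
  structure(list(maps = list(map), thresholds = 0.7,
                 schedule = data.frame(first_day = 1L, last_day = 60L,
                                       map_index = 1L),
                 timing_mode = "immediate", season_days = 60L,
                 patches = list(label_patches(map))),
            class = "suitability_stack")
}

test_that("perception remembers qualifying patches exactly once", {
  stack <- two_patch_world()
  patches <- stack$patches[[1]]
  # far from both patches: nothing remembered
  mem <- perceive_and_remember(1000, 1000, patches, 100,
                               min_patch_area = 1.6e5)
  expect_equal(nrow(mem), 0)
  # within range of patch A
  mem <- perceive_and_remember(350, 520, patches, 100,
                               min_patch_area = 1.6e5)
  expect_equal(nrow(mem), 1)
  # revisiting adds no duplicate
  mem2 <- perceive_and_remember(400, 450, patches, 100, memory = mem,
                                min_patch_area = 1.6e5)
  expect_equal(nrow(mem2), 1)
  # 16-cell patch fails a 17-cell requirement
  none <- perceive_and_remember(350, 520, patches, 100,
                                min_patch_area = 1.7e5)
  expect_equal(nrow(none), 0)
})

test_that("site ranking prefers food, safety and proximity", {
  m1 <- data.frame(x = 100, y = 0, anchor_ix = 2L, anchor_iy = 1L,
                   patch = 1L, map_index = 1L, area = 1e6, food = 1,
                   risk = 0, step = 1L)
  expect_equal(rank_sites(m1, 0, 0)$patch, 1L)

  two <- rbind(m1, data.frame(x = 5000, y = 0, anchor_ix = 51L,
                              anchor_iy = 1L, patch = 2L,
                              map_index = 1L, area = 1e6, food = 1,
                              risk = 0, step = 2L))
  expect_equal(rank_sites(two, 0, 0)$patch, c(1L, 2L))

  # brute-force score oracle on random memories
  withr::with_seed(11, {
    for (rep in 1:20) {
      mm <- data.frame(x = runif(10, 0, 1e4), y = runif(10, 0, 1e4),
                       anchor_ix = 1:10, anchor_iy = 1:10,
                       patch = 1:10, map_index = 1L,
                       area = runif(10, 1e5, 1e6),
                       food = runif(10), risk = runif(10), step = 1:10)
      px <- runif(1, 0, 1e4); py <- runif(1, 0, 1e4)
      got <- rank_sites(mm, px, py)$patch
      z <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
           else (v - min(v)) / diff(range(v))
      d <- sqrt((mm$x - px)^2 + (mm$y - py)^2)
      sc <- z(mm$food) - z(mm$risk) - z(d)
      expect_equal(got, mm$patch[order(-sc, mm$step)])
    }
  })
  expect_error(rank_sites(NULL, 0, 0), "empty")
})

test_that("exploration phase blocks settlement until day 15", {
  stack <- two_patch_world()
  cfg <- scenario_config("delay", 0.7, exploration = TRUE)
  occ <- list(M = matrix(0L, 20, 20), F = matrix(0L, 20, 20))
  mem <- perceive_and_remember(350, 520, stack$patches[[1]], 100,
                               min_patch_area = 1.6e5)
  agent <- list(x = 350, y = 520, sex = "M", phase = "exploring",
                memory = mem)
  r3 <- settlement_controller(agent, stack, occ, cfg, day = 3,
                              min_homerange_area = c(F = 1.6e5, M = 1.6e5))
  expect_equal(r3$agent$phase, "exploring")
  r15 <- settlement_controller(agent, stack, occ, cfg, day = 15,
                               min_homerange_area = c(F = 1.6e5, M = 1.6e5))
  expect_equal(r15$agent$phase, "orienting")
})

test_that("a blocked top site fails over to the next candidate", {
  stack <- two_patch_world()
  patches <- stack$patches[[1]]
  cfg <- scenario_config("static", 0.7, exploration = FALSE)
  occ <- list(M = matrix(0L, 20, 20), F = matrix(0L, 20, 20))
  labA <- patches$labels[3, 3]
  occ$M[patches$labels == labA] <- 99L  # same-sex resident owns patch A
  mem <- perceive_and_remember(350, 520, patches, 100,
                               min_patch_area = 1.6e5)
  mem <- perceive_and_remember(1450, 1520, patches, 100, memory = mem,
                               min_patch_area = 1.6e5)
  expect_equal(nrow(mem), 2)
  agent <- list(x = 350, y = 450, sex = "M", phase = "exploring",
                memory = mem)
  st1 <- settlement_controller(agent, stack, occ, cfg, day = 1,
                               min_homerange_area = c(F = 1.6e5,
                                                      M = 1.6e5))
  expect_equal(st1$agent$phase, "orienting")
  expect_equal(st1$agent$target$patch, labA)  # nearest first
  # at the blocked target: attempt fails, reorients to patch B
  st2 <- settlement_controller(st1$agent, stack, occ, cfg, day = 1,
                               min_homerange_area = c(F = 1.6e5,
                                                      M = 1.6e5))
  expect_false(st2$settled)
  expect_equal(st2$agent$phase, "orienting")
  expect_false(st2$agent$target$patch == labA)
  # arriving at patch B: establishment succeeds for the male,
  # and a female is unaffected by the male resident on A
  agB <- st2$agent
  agB$x <- 1450; agB$y <- 1520
  st3 <- settlement_controller(agB, stack, occ, cfg, day = 1,
                               min_homerange_area = c(F = 1.6e5,
                                                      M = 1.6e5),
                               territory_id = 7L)
  expect_true(st3$settled)
  expect_equal(st3$agent$phase, "settled")
  expect_equal(sum(st3$occupancy$M == 7L), 16)
  # patch A still belongs to the resident
  expect_true(all(occ$M[patches$labels == labA] == 99L))
})

test_that("an empty release set yields an empty outcome", {
  g <- uniform_grid(10, 10, frac = 1)
  stack <- build_stack(g, 0.7)
  cfg <- scenario_config("s", 0.7)
  occ <- list(M = matrix(0L, 10, 10), F = matrix(0L, 10, 10))
  out <- run_replicate(data.frame(id = integer(0), x = numeric(0),
                                  y = numeric(0), sex = character(0)),
                       g, stack, occ, cfg, seed = 1)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "steps"), 5760)
})

test_that("a benign world settles every agent", {
  g <- uniform_grid(60, 60, frac = 1)
  stack <- build_stack(g, 0.7)
  cfg <- scenario_config("benign", 0.7, exploration = FALSE)
  occ <- list(M = matrix(0L, 60, 60), F = matrix(0L, 60, 60))
  rel <- data.frame(id = 1:3, x = c(1000, 3000, 5000),
                    y = c(1000, 3000, 5000), sex = c("M", "F", "M"))
  ep <- energy_params(g$classes, capture_prob = 1, gain_mean = 60,
                      gain_sd = 0)
  rp <- risk_params(g$classes, hazard = 0)
  out <- run_replicate(rel, g, stack, occ, cfg, energy_par = ep,
                       risk_par = rp, seed = 2)
  expect_true(all(out$fate == "settled"))
  expect_true(all(out$settle_day == 1))
  # same-sex exclusivity after settlement
  occ2 <- attr(out, "occupancy")
  ids_m <- setdiff(unique(as.vector(occ2$M)), 0L)
  expect_length(ids_m, 2)  # both males own disjoint stamps
  expect_length(setdiff(unique(as.vector(occ2$F)), 0L), 1)
})

test_that("with no food everywhere agents starve on schedule", {
  g <- uniform_grid(40, 40, frac = 0)  # nothing suitable either
  stack <- build_stack(g, 0.7)
  cfg <- scenario_config("starve", 0.7)
  occ <- list(M = matrix(0L, 40, 40), F = matrix(0L, 40, 40))
  rel <- data.frame(id = 1:4, x = rep(2000, 4), y = rep(2000, 4),
                    sex = c("M", "F", "M", "F"))
  ep <- energy_params(g$classes, capture_prob = 0)
  rp <- risk_params(g$classes, hazard = 0)
  out <- run_replicate(rel, g, stack, occ, cfg, energy_par = ep,
                       risk_par = rp, seed = 3)
  expect_true(all(out$fate == "starvation"))
  expect_true(all(out$energy == 0))
})

test_that("replicates are deterministic under a fixed seed", {
  g <- generate_cover_grid(c(60, 60), seed = 4)
  stack <- build_stack(g, c(0.6, 0.5), season_days = 10)
  cfg <- scenario_config("det", c(0.6, 0.5), season_days = 10)
  occ <- list(M = matrix(0L, 60, 60), F = matrix(0L, 60, 60))
  rel <- generate_release_set(g, n = 5, seed = 5)
  a <- run_replicate(rel, g, stack, occ, cfg, seed = 7)
  b <- run_replicate(rel, g, stack, occ, cfg, seed = 7)
  expect_identical(a, b)
})

test_that("relaxing the threshold only enlarges the establishable set", {
  g <- generate_cover_grid(c(60, 60), seed = 6)
  m_hi <- suitability_map(g, 0.7)
  m_lo <- suitability_map(g, 0.5)
  occ0 <- matrix(0L, 60, 60)
  withr::with_seed(8, {
    cells <- sample(which(m_hi$suitable), min(30, sum(m_hi$suitable)))
    for (cell in cells) {
      sc <- c((cell - 1) %% 60 + 1, (cell - 1) %/% 60 + 1)
      hi <- grow_territory(sc, m_hi, occ0, 1e6)
      lo <- grow_territory(sc, m_lo, occ0, 1e6)
      if (!is.null(hi)) expect_false(is.null(lo))
    }
  })
})

test_that("trajectories can be recorded and serialised", {
  g <- uniform_grid(30, 30, frac = 0.4)  # nothing suitable: keep moving
  stack <- build_stack(g, 0.7)
  cfg <- scenario_config("traj", 0.7, season_days = 2)
  occ <- list(M = matrix(0L, 30, 30), F = matrix(0L, 30, 30))
  rel <- data.frame(id = 1:2, x = c(500, 2500), y = c(500, 2500),
                    sex = c("M", "F"))
  out <- run_replicate(rel, g, stack, occ, cfg, seed = 4,
                       min_homerange_area = c(F = 1e5, M = 1e5),
                       record_trajectories = TRUE)
  traj <- attr(out, "trajectories")
  expect_length(traj, 2)
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(out, pcsv)
  df <- read.csv(pcsv)
  expect_named(df, c("agent", "step", "x", "y", "energy", "phase"))
  expect_true(all(df$x >= 0 & df$x <= 3000))
  pgj <- withr::local_tempfile(fileext = ".geojson")
  write_trajectories(out, pgj, format = "geojson")
  gj <- jsonlite::read_json(pgj)
  expect_equal(gj$features[[1]]$geometry$type, "LineString")
})
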