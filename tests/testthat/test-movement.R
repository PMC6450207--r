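test_that("daily activity schedule converts hours to contiguous steps", {
  # SD 0: ceiling(9.1 * 4) = 37 active steps, every day
  for (s in 1:5) {
    sch <- daily_activity_schedule(9.1, 0, seed = s)
    expect_length(sch, 37)
    expect_equal(sch, seq(min(sch), max(sch)))
    expect_gte(min(sch), 1)
    expect_lte(max(sch), 96)
  }
  expect_length(daily_activity_schedule(24, 0, seed = 1), 96)
  expect_length(daily_activity_schedule(0, 0, seed = 1), 0)
})

test_that("mean daily activity recovers the configured hours", {
  hrs <- withr::with_seed(21, {
    vapply(1:4000, function(i)
      length(daily_activity_schedule(9.1, 0.7)) / 4, numeric(1))
  })
  # active steps = ceiling(h * 4), so expected steps/4 is within one
  # quarter-hour above the raw mean; 3 SE Monte-Carlo band around that
  se <- 0.7 / sqrt(4000)
  expect_lte(abs(mean(hrs) - (9.1 + 0.125)), 3 * se + 0.125)
})

test_that("wrapped-Cauchy turning reproduces the mean vector length", {
  expect_equal(draw_heading(1.2, 1, n = 50, seed = 1), rep(1.2, 50))

  turns0 <- withr::with_seed(2, martensim:::rwrapped_cauchy(1e5, 0))
  R0 <- sqrt(mean(cos(turns0))^2 + mean(sin(turns0))^2)
  expect_lt(R0, 0.01)

  turns <- withr::with_seed(3, martensim:::rwrapped_cauchy(1e5, 0.8))
  R <- sqrt(mean(cos(turns))^2 + mean(sin(turns))^2)
  # var(cos) = (1 + rho^2)/2 - rho^2 for a wrapped Cauchy
  se <- sqrt(((1 + 0.8^2) / 2 - 0.8^2) / 1e5)
  expect_lte(abs(R - 0.8), 3 * se + 1e-3)
  expect_error(draw_heading(0, 1.2), "mvl")
})

test_that("step lengths follow bound rate, cover and sex", {
  cl <- two_class_table()
  mp <- movement_params(cl, msl_multiplier = c(1, 1), bound_length = 1)
  expect_equal(step_length(mp, 1, "M", 30), 450)
  expect_equal(step_length(mp, 1, "F", 30), 405)
  expect_equal(step_length(mp, 1, "M", 30) / step_length(mp, 1, "M", 10),
               3)
  expect_error(step_length(mp, 99, "M", 30), "unknown cover")
})

test_that("moves into forest are free; into open land rare", {
  g <- uniform_grid(30, 30, frac = 1, forested = TRUE)
  mp <- movement_params(g$classes)
  res <- withr::with_seed(5, {
    replicate(200, attempt_move(1500, 1500, runif(1, 0, 2 * pi), g, mp,
                                bound_rate = 10)$moved)
  })
  expect_true(all(res))

  # forest island: every destination cell is unforested
  cl <- two_class_table()
  cells <- matrix(2L, 21, 21)
  cells[11, 11] <- 1L
  gi <- grid_from_matrix(cells, cl)
  mp <- movement_params(cl, msl_multiplier = c(1, 1))
  acc <- withr::with_seed(6, {
    vapply(1:10000, function(i)
      attempt_move(1050, 1050, runif(1, 0, 2 * pi), gi, mp,
                   bound_rate = 10, max_retries = 1)$moved, logical(1))
  })
  b <- binom_bounds(10000, 0.01)
  expect_gte(mean(acc), b[1])
  expect_lte(mean(acc), b[2])
})

test_that("agents never leave the extent", {
  g <- uniform_grid(5, 5, frac = 1)
  mp <- movement_params(g$classes)
  pos <- c(50, 450)
  withr::with_seed(8, {
    for (i in 1:300) {
      mv <- attempt_move(pos[1], pos[2], runif(1, 0, 2 * pi), g, mp,
                         bound_rate = 30)
      pos <- c(mv$x, mv$y)
      expect_true(pos[1] >= 0 && pos[1] <= 500 &&
                  pos[2] >= 0 && pos[2] <= 500)
    }
  })
})

test_that("starvation arrives at the closed-form step count", {
  cl <- two_class_table()
  ep <- energy_params(cl, capture_prob = c(0, 0))
  e <- 5491
  steps <- 0
  repeat {
    steps <- steps + 1
    r <- forage_and_metabolize(e, 1, ep, active = TRUE)
    e <- r$energy
    if (r$starved) break
  }
  expect_equal(steps, ceiling(5491 / 10.5))  # 523
})

test_that("certain capture with ample gain prevents starvation", {
  cl <- two_class_table()
  ep <- energy_params(cl, capture_prob = c(1, 1),
                      gain_mean = c(50, 50), gain_sd = c(0, 0))
  e <- 5491
  withr::with_seed(3, {
    for (i in 1:5760) {
      r <- forage_and_metabolize(e, 1, ep, active = TRUE)
      e <- r$energy
      expect_false(r$starved)
    }
  })
  expect_lte(e, ep$reserve_cap)
})

test_that("energy balances at zero expected net gain", {
  cl <- two_class_table()
  ep <- energy_params(cl, capture_prob = c(0.5, 0.5),
                      gain_mean = c(21, 21), gain_sd = c(0, 0),
                      reserve_cap = 1e9, initial_reserve = 1e6)
  nets <- withr::with_seed(9, {
    vapply(1:10000, function(i) {
      r <- forage_and_metabolize(5e5, 1, ep, active = TRUE)
      r$energy - 5e5
    }, numeric(1))
  })
  se <- 10.5 / sqrt(10000)  # sd of net = 21 * sqrt(0.25)
  expect_lte(abs(mean(nets)), 3 * se)
})

test_that("predation hazard compounds geometrically", {
  cl <- two_class_table()
  expect_false(apply_predation(1, risk_params(cl, hazard = c(0, 0)),
                               seed = 1))
  expect_true(apply_predation(1, risk_params(cl, hazard = c(1 - 1e-12,
                                                            0)),
                              seed = 1))
  rp <- risk_params(cl, hazard = c(0.002, 0.002))
  n_agents <- 2000; n_steps <- 100
  dead <- withr::with_seed(4, {
    vapply(seq_len(n_agents), function(a) {
      for (s in seq_len(n_steps))
        if (apply_predation(1, rp)) return(TRUE)
      FALSE
    }, logical(1))
  })
  p_exp <- 1 - (1 - 0.002)^n_steps
  se <- sqrt(p_exp * (1 - p_exp) / n_agents)
  expect_lte(abs(mean(dead) - p_exp), 3 * se)
})
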