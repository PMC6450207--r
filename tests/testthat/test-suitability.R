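test_that("cell values follow the stand-data / class-fraction rule", {
  cl <- data.frame(id = 1L, name = "aspen", forested = TRUE,
                   has_stand_data = TRUE, nonavoided_fraction = 0.17,
                   weight = 1)
  g <- generate_cover_grid(c(10, 10), 100, cl, clustering_scale = 0,
                           stand_data_fraction = 0.5, seed = 3)
  v <- cell_values(g)
  # no stand record: the class-level fraction
  expect_true(all(v[!g$stand_data] == 0.17))
  # stand record: binary per-cell flag
  expect_setequal(unique(v[g$stand_data]), c(0, 1))
  expect_equal(v[g$stand_data], as.numeric(g$nonavoided[g$stand_data]))

  g0 <- uniform_grid(frac = 0)
  expect_equal(cell_value(g0, 3, 4), 0)
  expect_error(cell_value(g0, 0, 1), "extent")
})

test_that("uniform value grids threshold as a block", {
  g <- uniform_grid(frac = 0.65)
  expect_true(all(suitability_map(g, 0.6)$suitable))
  expect_false(any(suitability_map(g, 0.7)$suitable))
})

test_that("focal mean equals the brute-force window loop", {
  withr::local_seed(42)
  v <- matrix(runif(50 * 50), 50, 50)
  cs <- 100
  for (wa in c(1e4, 2.5e5, 1e6)) {
    got <- focal_mean(v, cs, wa)
    r <- sqrt(wa / pi)
    brute <- matrix(NA_real_, 50, 50)
    for (i in 1:50) for (j in 1:50) {
      acc <- 0; cnt <- 0
      R <- floor(r / cs)
      for (di in -R:R) for (dj in -R:R) {
        if (sqrt(di^2 + dj^2) * cs > r) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > 50 || jj < 1 || jj > 50) next
        acc <- acc + v[ii, jj]; cnt <- cnt + 1
      }
      brute[i, j] <- acc / cnt
    }
    expect_equal(got, brute, tolerance = 1e-12)
  }
  expect_error(focal_mean(v, 100, 100), "window smaller")
})

test_that("suitable sets are nested across descending thresholds", {
  for (seed in 1:3) {
    g <- generate_cover_grid(c(60, 60), seed = seed)
    v <- cell_values(g)
    prev <- NULL
    for (th in c(0.8, 0.7, 0.6, 0.5, 0.4)) {
      s <- suitability_map(g, th, values = v)$suitable
      if (!is.null(prev)) expect_true(all(s[prev]))  # prev subset of s
      prev <- s
    }
  }
})

test_that("patch labelling agrees with an igraph components oracle", {
  withr::local_seed(7)
  suit <- matrix(runif(30 * 25) < 0.45, 30, 25)
  lp <- label_patches(suit, cell_size = 100)
  idx <- which(suit)
  nx <- nrow(suit)
  coords <- cbind((idx - 1) %% nx + 1, (idx - 1) %/% nx + 1)
  edges <- NULL
  for (k in seq_along(idx)) {
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- coords[k, ] + d
      if (nb[1] > nrow(suit) || nb[2] > ncol(suit)) next
      j <- match(nb[1] + (nb[2] - 1) * nx, idx)
      if (!is.na(j)) edges <- rbind(edges, c(k, j))
    }
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, length(idx) - igraph::vcount(gr))
  comp <- igraph::components(gr)
  expect_equal(max(lp$labels), comp$no)
  # identical partitions up to label renaming
  got <- lp$labels[idx]
  expect_equal(length(unique(paste(got, comp$membership))),
               comp$no)
  expect_equal(sort(lp$areas / 100^2), sort(as.numeric(comp$csize)))
})

test_that("schedules partition the season correctly", {
  g <- uniform_grid(frac = 0.8)
  st <- build_stack(g, c(0.8, 0.7, 0.6), 60, "immediate")
  expect_equal(st$schedule$first_day, c(1L, 21L, 41L))
  expect_equal(st$schedule$last_day, c(20L, 40L, 60L))

  one <- build_stack(g, 0.7, 60)
  expect_equal(one$schedule$first_day, 1L)
  expect_equal(one$schedule$last_day, 60L)

  del <- build_stack(g, c(0.8, 0.7, 0.6), 60, "delayed",
                     exploration_days = 14)
  lens <- del$schedule$last_day - del$schedule$first_day + 1L
  expect_equal(sum(lens), 60L)
  # first map holds through exploration plus its equal share of the rest
  a <- lens[1] - 14L
  expect_equal(a + lens[2] + lens[3], 46L)
  expect_lte(abs(lens[2] - lens[3]), 1L)
  expect_lte(abs(a - lens[2]), 1L)

  # remainder handling: lengths always sum to the season
  for (k in 1:4) for (days in c(17L, 30L, 61L)) {
    thr <- seq(0.9, 0.9 - 0.1 * (k - 1), by = -0.1)
    s <- build_stack(g, thr, days)
    expect_equal(sum(s$schedule$last_day - s$schedule$first_day + 1L),
                 days)
  }
  expect_error(build_stack(g, c(0.6, 0.7), 60), "descending")
})

test_that("active_map returns the scheduled map", {
  g <- uniform_grid(frac = 0.8)
  st <- build_stack(g, c(0.8, 0.7, 0.6), 60, "immediate")
  expect_equal(active_map(st, 1, index = TRUE), 1L)
  expect_equal(active_map(st, 21, index = TRUE), 2L)
  expect_equal(active_map(st, 60, index = TRUE), 3L)
  expect_identical(active_map(st, 60), st$maps[[3]])
  expect_error(active_map(st, 0), "out of range")
  expect_error(active_map(st, 61), "out of range")
})

test_that("suitability stacks serialise to ASCII maps plus JSON", {
  g <- uniform_grid(12, 12, frac = 0.65)
  st <- build_stack(g, c(0.6, 0.5), season_days = 10)
  base <- file.path(withr::local_tempdir(), "stack")
  write_stack(st, base)
  m1 <- read_asc(paste0(base, "_map1.asc"))
  expect_true(all(m1$m == 1))
  sched <- jsonlite::read_json(paste0(base, "_schedule.json"),
                               simplifyVector = TRUE)
  expect_equal(sched$thresholds, c(0.6, 0.5))
  expect_equal(sum(sched$schedule$last_day -
                   sched$schedule$first_day + 1), 10)
})
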