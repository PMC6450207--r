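# Shared fixtures: tiny grids and scenario shorthands built in code.

# Single-class grid whose every cell has the given class-level value.
uniform_grid <- function(nx = 20, ny = 20, frac = 0.65, cell_size = 100,
                         forested = TRUE, seed = 1) {
  cl <- data.frame(id = 1L, name = "only", forested = forested,
                   has_stand_data = FALSE, nonavoided_fraction = frac,
                   weight = 1)
  generate_cover_grid(c(nx, ny), cell_size, cl, clustering_scale = 0,
                      stand_data_fraction = 0, seed = seed)
}

# Two-class grid: class 1 forested/suitable-prone, class 2 a barrier.
barrier_grid <- function(nx = 20, ny = 20, w_barrier = 0.5, seed = 1,
                         cell_size = 100) {
  cl <- data.frame(id = c(1L, 2L), name = c("forest", "open"),
                   forested = c(TRUE, FALSE), has_stand_data = FALSE,
                   nonavoided_fraction = c(1, 0),
                   weight = c(1 - w_barrier, w_barrier))
  generate_cover_grid(c(nx, ny), cell_size, cl, clustering_scale = 0,
                      stand_data_fraction = 0, seed = seed)
}

# Hand-build a cover grid from an explicit class-id matrix.
grid_from_matrix <- function(cells, class_table, cell_size = 100) {
  nx <- nrow(cells); ny <- ncol(cells)
  martensim:::new_cover_grid(class_table, cells,
                             matrix(FALSE, nx, ny),
                             matrix(NA, nx, ny), cell_size)
}

two_class_table <- function() {
  data.frame(id = c(1L, 2L), name = c("forest", "open"),
             forested = c(TRUE, FALSE), has_stand_data = FALSE,
             nonavoided_fraction = c(1, 0), weight = c(0.5, 0.5))
}

# Minimal pattern_set stand-in for ranking tests.
make_ps <- function(values, n = 15, n_settled = 12) {
  ps <- c(values, list(n = n, n_settled = n_settled,
                       n_dead = n - n_settled, n_unsettled = 0,
                       records = NULL))
  class(ps) <- "pattern_set"
  ps
}

# Exact binomial bounds at the given two-sided level.
binom_bounds <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
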