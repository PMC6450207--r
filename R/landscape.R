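#' @title Synthetic cover-type landscapes
#' @description Generators for the categorical cover grid and disperser
#'   release sets on which the simulation runs. The landscape generator
#'   produces a spatially autocorrelated categorical mosaic (a
#'   Gaussian-smoothed random field thresholded at class-weight quantiles)
#'   with a configurable fraction of cells carrying stand-level records,
#'   standing in for a classified forest-inventory / land-cover raster.
#' @name landscape
NULL

new_cover_grid <- function(classes, cells, stand_data, nonavoided,
                           cell_size, origin = c(0, 0)) {
  structure(
    list(classes = classes, cells = cells, stand_data = stand_data,
         nonavoided = nonavoided, cell_size = cell_size, origin = origin),
    class = "cover_grid"
  )
}

#' @export
print.cover_grid <- function(x, ...) {
  cat(sprintf("<cover_grid> %d x %d cells @ %g m (%g x %g km), %d classes\n",
              nrow(x$cells), ncol(x$cells), x$cell_size,
              nrow(x$cells) * x$cell_size / 1000,
              ncol(x$cells) * x$cell_size / 1000, nrow(x$classes)))
  cat(sprintf("  stand-level data on %.1f%% of cells\n",
              100 * mean(x$stand_data)))
  invisible(x)
}

# Separable Gaussian smoothing with truncated-kernel renormalisation at the
# edges, so the smoothed field has no systematic edge bias.
gauss_smooth <- function(m, sigma) {
  R <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-R, R), sd = sigma)
  smooth_dim1 <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    cnt <- numeric(n)
    for (j in seq_along(w)) {
      off <- j - R - 1L
      src <- seq_len(n) - off
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + w[j] * m[src[ok], , drop = FALSE]
      cnt[ok] <- cnt[ok] + w[j]
    }
    acc / cnt
  }
  t(smooth_dim1(t(smooth_dim1(m))))
}

#' Generate a synthetic categorical cover grid
#'
#' Draws an i.i.d. standard-normal field, optionally smooths it with an
#' isotropic Gaussian kernel of standard deviation `clustering_scale`
#' (in cells) to induce patchiness, and slices it at the normal quantiles
#' of the cumulative class weights, so that expected class frequencies
#' match the weights. A seeded Bernoulli mask flags cells that carry
#' stand-level records; those cells get a per-cell binary nonavoided flag
#' drawn with their class's `nonavoided_fraction`, while cells without
#' records fall back to the class-level fraction when suitability is
#' evaluated.
#'
#' @param extent integer vector `c(ncols, nrows)` of cells (x then y).
#' @param cell_size cell edge length in metres (> 0).
#' @param class_table a cover-class table, see [default_cover_classes()].
#' @param clustering_scale Gaussian smoothing SD in cells; 0 gives an
#'   i.i.d. (unclustered) mosaic.
#' @param stand_data_fraction target fraction of cells carrying
#'   stand-level records (the study landscape lacked them on 48.8% of the
#'   area, i.e. carried them on 51.2%).
#' @param seed integer seed; identical seeds give bit-identical grids.
#' @return A `cover_grid` object.
#' @export
generate_cover_grid <- function(extent = c(200L, 200L), cell_size = 100,
                                class_table = default_cover_classes(),
                                clustering_scale = 10,
                                stand_data_fraction = 0.512,
                                seed = NULL) {
  validate_class_table(class_table)
  if (cell_size <= 0) stop("cell_size must be positive")
  if (clustering_scale < 0) stop("clustering_scale must be >= 0")
  if (stand_data_fraction < 0 || stand_data_fraction > 1)
    stop("stand_data_fraction must lie in [0, 1]")
  nx <- as.integer(extent[1]); ny <- as.integer(extent[2])
  with_seed_(seed, {
    field <- matrix(stats::rnorm(nx * ny), nx, ny)
    if (clustering_scale > 0) {
      field <- gauss_smooth(field, clustering_scale)
      field <- (field - mean(field)) / stats::sd(field)
    }
    w <- class_table$weight / sum(class_table$weight)
    k <- length(w)
    if (k == 1L) {
      idx <- matrix(1L, nx, ny)
    } else {
      breaks <- stats::qnorm(cumsum(w)[-k])
      idx <- matrix(findInterval(field, breaks) + 1L, nx, ny)
    }
    cells <- matrix(class_table$id[idx], nx, ny)
    can_stand <- matrix(class_table$has_stand_data[idx], nx, ny)
    stand <- matrix(stats::runif(nx * ny) < stand_data_fraction, nx, ny) &
      can_stand
    frac <- matrix(class_table$nonavoided_fraction[idx], nx, ny)
    nonav <- matrix(NA, nx, ny)
    nonav[stand] <- stats::runif(sum(stand)) < frac[stand]
    new_cover_grid(class_table, cells, stand, nonav, cell_size)
  })
}

grid_extent_m <- function(grid) {
  c(nrow(grid$cells), ncol(grid$cells)) * grid$cell_size
}

# Lookup vector indexed by class id (ids must be small positive integers).
class_lookup <- function(class_table, column) {
  out <- rep(NA_real_, max(class_table$id))
  out[class_table$id] <- class_table[[column]]
  out
}

#' Generate release locations for translocated dispersers
#'
#' Places `n` release points uniformly within forested cells, optionally
#' enforcing a minimum pairwise spacing by rejection sampling. Sexes are
#' assigned so that `round(n * sex_ratio)` individuals are male, in a
#' seeded random order.
#'
#' @param grid a `cover_grid`.
#' @param n number of dispersers (the study released 15).
#' @param sex_ratio male fraction in (0, 1).
#' @param min_spacing minimum pairwise distance in metres.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per point.
#' @return A `data.frame` with columns `id`, `x`, `y`, `sex`.
#' @export
generate_release_set <- function(grid, n = 15L, sex_ratio = 0.5,
                                 min_spacing = 0, seed = NULL,
                                 max_tries = 1000L) {
  stopifnot(n >= 1, min_spacing >= 0)
  forested <- class_lookup(grid$classes, "forested")
  ok_cells <- which(forested[grid$cells] == 1)
  if (!length(ok_cells)) stop("grid contains no forested cells")
  nx <- nrow(grid$cells)
  with_seed_(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (tr in seq_len(max_tries)) {
        cell <- sample(ok_cells, 1L)
        ix <- (cell - 1L) %% nx + 1L
        iy <- (cell - 1L) %/% nx + 1L
        px <- (ix - 1L + stats::runif(1)) * grid$cell_size
        py <- (iy - 1L + stats::runif(1)) * grid$cell_size
        if (!length(xs) ||
            min(sqrt((xs - px)^2 + (ys - py)^2)) >= min_spacing) {
          xs <- c(xs, px); ys <- c(ys, py); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n, " release points with min_spacing = ",
             min_spacing, " m")
    }
    n_male <- round(n * sex_ratio)
    sexes <- rep("F", n)
    sexes[sample.int(n, n_male)] <- "M"
    data.frame(id = seq_len(n), x = xs, y = ys, sex = sexes,
               stringsAsFactors = FALSE)
  })
}
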