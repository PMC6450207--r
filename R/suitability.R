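#' @title Habitat suitability under percent-rule focal thresholds
#' @description A cell's suitability value is 1/0 where a stand-level
#'   record classifies it as nonavoided/avoided, and the class-level
#'   nonavoided fraction elsewhere. A cell is *suitable* when the mean
#'   suitability value over a circular focal window (default area 1 km^2)
#'   centred on it meets a percent-rule threshold (e.g. 70%). Lowering
#'   the threshold monotonically enlarges the suitable set, which is the
#'   mechanism behind temporally declining habitat selectivity: a stack
#'   of maps with descending thresholds is scheduled across the 60-day
#'   dispersal season.
#' @name suitability
NULL

#' Per-cell suitability values
#'
#' @param grid a `cover_grid`.
#' @return numeric matrix in \[0, 1\]: binary for cells with stand-level
#'   records, the class nonavoided fraction otherwise.
#' @export
cell_values <- function(grid) {
  frac <- class_lookup(grid$classes, "nonavoided_fraction")
  if (anyNA(frac[unique(as.vector(grid$cells))]))
    stop("grid contains unknown class ids")
  v <- matrix(frac[grid$cells], nrow(grid$cells))
  v[grid$stand_data] <- as.numeric(grid$nonavoided[grid$stand_data])
  v
}

#' @rdname cell_values
#' @param ix,iy 1-based cell indices.
#' @export
cell_value <- function(grid, ix, iy) {
  if (ix < 1 || ix > nrow(grid$cells) || iy < 1 || iy > ncol(grid$cells))
    stop("cell outside extent")
  cell_values(grid)[ix, iy]
}

# Cell-offset list for a circular window of `window_area` m^2;
# membership by cell-centre distance.
disc_offsets <- function(cell_size, window_area) {
  if (window_area < cell_size^2)
    stop("window smaller than one cell")
  r <- sqrt(window_area / pi)
  R <- floor(r / cell_size)
  g <- expand.grid(dx = -R:R, dy = -R:R)
  g[sqrt(g$dx^2 + g$dy^2) * cell_size <= r, , drop = FALSE]
}

#' Focal (moving-window) mean with edge truncation
#'
#' Mean of `v` over the circular window centred on each cell; windows are
#' truncated to the grid extent at the edges.
#'
#' @param v numeric matrix of cell values.
#' @param cell_size cell size in metres.
#' @param window_area window area in m^2 (default 1 km^2).
#' @export
focal_mean <- function(v, cell_size, window_area = 1e6) {
  off <- disc_offsets(cell_size, window_area)
  nx <- nrow(v); ny <- ncol(v)
  acc <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (k in seq_len(nrow(off))) {
    dx <- off$dx[k]; dy <- off$dy[k]
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    acc[xs, ys] <- acc[xs, ys] + v[xs + dx, ys + dy, drop = FALSE]
    cnt[xs, ys] <- cnt[xs, ys] + 1
  }
  acc / cnt
}

#' Binary suitability map from a percent-rule focal threshold
#'
#' @param grid a `cover_grid` (or a plain value matrix via `values`).
#' @param threshold percent rule as a proportion in (0, 1\].
#' @param window_area focal window area in m^2.
#' @param values optional precomputed value matrix (bypasses
#'   [cell_values()]).
#' @return A `suitability_map`: logical matrix plus provenance fields.
#' @export
suitability_map <- function(grid, threshold, window_area = 1e6,
                            values = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  v <- values %||% cell_values(grid)
  fm <- focal_mean(v, grid$cell_size, window_area)
  structure(
    list(suitable = fm >= threshold, threshold = threshold,
         window_area = window_area, cell_size = grid$cell_size),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf(
    "<suitability_map> threshold %.0f%%, window %.2f km^2, %.1f%% suitable\n",
    100 * x$threshold, x$window_area / 1e6, 100 * mean(x$suitable)))
  invisible(x)
}

#' Label contiguous suitable patches
#'
#' Connected-component labelling of the suitable cells (rook or queen
#' connectivity). Patch areas are returned in m^2.
#'
#' @param map a `suitability_map` (or logical matrix).
#' @param connectivity 4 (rook, default) or 8 (queen).
#' @param cell_size required when `map` is a bare matrix.
#' @return list with `labels` (integer matrix, 0 = unsuitable) and
#'   `areas` (m^2 per patch id).
#' @export
label_patches <- function(map, connectivity = 4, cell_size = NULL) {
  if (inherits(map, "suitability_map")) {
    suit <- map$suitable; cs <- map$cell_size
  } else {
    suit <- map; cs <- cell_size %||% stop("cell_size required")
  }
  nx <- nrow(suit); ny <- ncol(suit)
  labels <- matrix(0L, nx, ny)
  dxs <- c(-1L, 1L, 0L, 0L); dys <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dxs <- c(dxs, -1L, -1L, 1L, 1L); dys <- c(dys, -1L, 1L, -1L, 1L)
  }
  stack <- integer(nx * ny)
  nid <- 0L
  for (start in which(suit)) {
    if (labels[start] != 0L) next
    nid <- nid + 1L
    labels[start] <- nid
    sp <- 1L; stack[1L] <- start
    while (sp > 0L) {
      cur <- stack[sp]; sp <- sp - 1L
      cx <- (cur - 1L) %% nx + 1L
      cy <- (cur - 1L) %/% nx + 1L
      for (d in seq_along(dxs)) {
        mx <- cx + dxs[d]; my <- cy + dys[d]
        if (mx < 1L || mx > nx || my < 1L || my > ny) next
        nb <- mx + (my - 1L) * nx
        if (suit[nb] && labels[nb] == 0L) {
          labels[nb] <- nid
          sp <- sp + 1L; stack[sp] <- nb
        }
      }
    }
  }
  list(labels = labels,
       areas = if (nid) tabulate(labels[labels > 0L], nid) * cs^2
               else numeric(0))
}

#' Build a (possibly dynamic) suitability schedule
#'
#' With `timing_mode = "immediate"` the season is split into as many
#' equal periods as there are thresholds (remainder days appended to the
#' final period). With `"delayed"` the post-exploration days are split
#' equally across all thresholds and the first period additionally spans
#' the exploration phase, so map swapping only starts once exploration
#' ends.
#'
#' @param grid a `cover_grid`.
#' @param thresholds strictly descending percent rules (one value gives a
#'   static schedule).
#' @param season_days dispersal season length in days (default 60).
#' @param timing_mode `"immediate"` or `"delayed"`.
#' @param exploration_days exploration-phase length used by the delayed
#'   mode (default 14).
#' @param window_area focal window area (m^2).
#' @param values optional precomputed cell-value matrix.
#' @return A `suitability_stack`: maps, patch labellings, and a
#'   day-indexed schedule.
#' @export
build_stack <- function(grid, thresholds, season_days = 60L,
                        timing_mode = c("immediate", "delayed"),
                        exploration_days = 14L, window_area = 1e6,
                        values = NULL) {
  timing_mode <- match.arg(timing_mode)
  k <- length(thresholds)
  stopifnot(k >= 1, season_days >= k)
  if (k > 1 && any(diff(thresholds) >= 0))
    stop("thresholds must be strictly descending")
  v <- values %||% cell_values(grid)
  maps <- lapply(thresholds, function(t)
    suitability_map(grid, t, window_area, values = v))
  if (timing_mode == "immediate" || k == 1) {
    lens <- split_days(season_days, k)
  } else {
    stopifnot(season_days > exploration_days)
    lens <- split_days(season_days - exploration_days, k)
    lens[1] <- lens[1] + exploration_days
  }
  last <- cumsum(lens)
  schedule <- data.frame(first_day = c(1L, head(last, -1) + 1L),
                         last_day = last, map_index = seq_len(k))
  structure(
    list(maps = maps, thresholds = thresholds, schedule = schedule,
         timing_mode = timing_mode, season_days = season_days,
         patches = lapply(maps, label_patches)),
    class = "suitability_stack"
  )
}

#' Serialise a suitability stack: maps as ASCII grids, schedule as JSON
#'
#' Writes `<base>_map<i>.asc` for each threshold's binary map and
#' `<base>_schedule.json` with the thresholds, timing mode and
#' day-indexed schedule.
#'
#' @param stack a `suitability_stack`.
#' @param base path prefix.
#' @export
write_stack <- function(stack, base) {
  for (i in seq_along(stack$maps))
    write_asc(stack$maps[[i]]$suitable,
              sprintf("%s_map%d.asc", base, i),
              stack$maps[[i]]$cell_size)
  jsonlite::write_json(
    list(thresholds = stack$thresholds,
         timing_mode = stack$timing_mode,
         season_days = stack$season_days,
         schedule = stack$schedule),
    paste0(base, "_schedule.json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Map scheduled for a given day
#'
#' @param stack a `suitability_stack`.
#' @param day day of season, 1-based.
#' @param index return the map index instead of the map.
#' @export
active_map <- function(stack, day, index = FALSE) {
  if (day < 1 || day > stack$season_days) stop("day out of range")
  i <- stack$schedule$map_index[
    day >= stack$schedule$first_day & day <= stack$schedule$last_day]
  if (index) i else stack$maps[[i]]
}
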