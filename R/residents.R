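#' @title Resident territories and occupancy
#' @description Martens are territorial: a disperser can only establish a
#'   home range on contiguous suitable habitat unoccupied by a resident
#'   of the same sex. The package builds that territorial backdrop by
#'   stamping a set of "known" territories and then simulating the
#'   release and immediate home-range establishment of additional
#'   residents until a target population size is reached (the study used
#'   22 known home ranges plus 78 simulated residents for a population
#'   estimate of 100). Occupancy is tracked per sex; opposite-sex
#'   territories may overlap.
#' @name residents
NULL

new_occupancy <- function(nx, ny) {
  list(M = matrix(0L, nx, ny), F = matrix(0L, nx, ny))
}

#' Number of residents to simulate on top of known territories
#'
#' @param pop_estimate pre-translocation population estimate (default 100).
#' @param n_known number of known territories (default 22).
#' @export
n_simulated_residents <- function(pop_estimate = 100L, n_known = 22L) {
  stopifnot(pop_estimate >= n_known)
  as.integer(pop_estimate - n_known)
}

#' Grow a territory by breadth-first region growth
#'
#' Starting from a suitable, same-sex-unoccupied seed cell, accretes
#' contiguous suitable unoccupied cells breadth-first (layer by layer,
#' cells within a layer taken in ascending linear-index order) until the
#' target area is covered. Fails (returns `NULL`) when the reachable
#' region is smaller than the target.
#'
#' @param seed_cell `c(ix, iy)` cell indices.
#' @param map a `suitability_map` (or logical matrix with `cell_size`).
#' @param occupancy integer occupancy matrix for the relevant sex
#'   (0 = unoccupied).
#' @param target_area home-range area in m^2.
#' @param connectivity 4 (default) or 8.
#' @param cell_size needed when `map` is a bare matrix.
#' @return A `territory` (list: `cells` linear indices, `centroid` m,
#'   `area` m^2) or `NULL` on failure.
#' @export
grow_territory <- function(seed_cell, map, occupancy, target_area,
                           connectivity = 4, cell_size = NULL) {
  if (inherits(map, "suitability_map")) {
    suit <- map$suitable; cs <- map$cell_size
  } else {
    suit <- map; cs <- cell_size %||% stop("cell_size required")
  }
  nx <- nrow(suit); ny <- ncol(suit)
  seed <- seed_cell[1] + (seed_cell[2] - 1L) * nx
  avail <- suit & occupancy == 0L
  if (!avail[seed]) stop("seed cell unsuitable or occupied")
  need <- as.integer(ceiling(target_area / cs^2))
  dxs <- c(-1L, 1L, 0L, 0L); dys <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dxs <- c(dxs, -1L, -1L, 1L, 1L); dys <- c(dys, -1L, 1L, -1L, 1L)
  }
  visited <- matrix(FALSE, nx, ny)
  visited[seed] <- TRUE
  layer <- seed
  taken <- integer(0)
  while (length(layer) && length(taken) < need) {
    layer <- sort(layer)
    room <- need - length(taken)
    taken <- c(taken, layer[seq_len(min(room, length(layer)))])
    if (length(taken) >= need) break
    nxt <- integer(0)
    for (cur in layer) {
      cx <- (cur - 1L) %% nx + 1L
      cy <- (cur - 1L) %/% nx + 1L
      for (d in seq_along(dxs)) {
        mx <- cx + dxs[d]; my <- cy + dys[d]
        if (mx < 1L || mx > nx || my < 1L || my > ny) next
        nb <- mx + (my - 1L) * nx
        if (avail[nb] && !visited[nb]) {
          visited[nb] <- TRUE
          nxt <- c(nxt, nb)
        }
      }
    }
    layer <- nxt
  }
  if (length(taken) < need) return(NULL)
  ix <- (taken - 1L) %% nx + 1L
  iy <- (taken - 1L) %/% nx + 1L
  structure(list(cells = taken,
                 centroid = c(mean(cell_center(ix, cs)),
                              mean(cell_center(iy, cs))),
                 area = length(taken) * cs^2),
            class = "territory")
}

#' Populate the landscape with resident territories
#'
#' Stamps `n_known` generated "known" territories first, then simulates
#' the release of `n_additional` residents (default: up to
#' `pop_estimate`) at points drawn uniformly from suitable unoccupied
#' cells, each establishing immediately via [grow_territory()].
#' Individuals that fail after `max_tries` seed draws are recorded as
#' unplaced. Same-sex territories never overlap; opposite-sex ones may.
#'
#' @param map a `suitability_map`.
#' @param n_known number of known territories to stamp (default 22).
#' @param n_additional simulated residents; default
#'   `pop_estimate - n_known`.
#' @param pop_estimate target population size (default 100).
#' @param sex_ratio male fraction.
#' @param min_homerange_area named vector `c(F = ..., M = ...)` in m^2.
#' @param seed integer seed.
#' @param max_tries seed draws per individual before it is unplaced.
#' @return An `occupancy_field`: per-sex id matrices, territory list,
#'   and placement diagnostics.
#' @export
populate_residents <- function(map, n_known = 22L, n_additional = NULL,
                               pop_estimate = 100L, sex_ratio = 0.5,
                               min_homerange_area = c(F = 3e6, M = 5e6),
                               seed = NULL, max_tries = 30L) {
  stopifnot(n_known >= 0)
  n_additional <- n_additional %||%
    n_simulated_residents(pop_estimate, n_known)
  stopifnot(n_additional >= 0)
  nx <- nrow(map$suitable); ny <- ncol(map$suitable)
  occ <- new_occupancy(nx, ny)
  if (!any(map$suitable) && (n_known + n_additional) > 0)
    stop("no suitable cells to place residents on")
  terrs <- list()
  unplaced <- 0L
  with_seed_(seed, {
    n_tot <- n_known + n_additional
    sexes <- ifelse(stats::runif(n_tot) < sex_ratio, "M", "F")
    for (i in seq_len(n_tot)) {
      sex <- sexes[i]
      area <- unname(min_homerange_area[sex])
      placed <- FALSE
      free <- which(map$suitable & occ[[sex]] == 0L)
      for (tr in seq_len(max_tries)) {
        if (!length(free)) break
        seed_cell_idx <- free[sample.int(length(free), 1L)]
        sc <- c((seed_cell_idx - 1L) %% nx + 1L,
                (seed_cell_idx - 1L) %/% nx + 1L)
        terr <- grow_territory(sc, map, occ[[sex]], area)
        if (!is.null(terr)) {
          terr$id <- length(terrs) + 1L
          terr$sex <- sex
          terr$known <- i <= n_known
          occ[[sex]][terr$cells] <- terr$id
          terrs[[terr$id]] <- terr
          placed <- TRUE
          break
        }
      }
      if (!placed) unplaced <- unplaced + 1L
    }
  })
  structure(list(M = occ$M, F = occ$F, territories = terrs,
                 n_known = as.integer(n_known),
                 n_simulated = as.integer(n_additional),
                 unplaced = unplaced, cell_size = map$cell_size),
            class = "occupancy_field")
}

#' @export
print.occupancy_field <- function(x, ...) {
  cat(sprintf(
    "<occupancy_field> %d territories (%d known + %d simulated, %d unplaced)\n",
    length(x$territories), x$n_known,
    x$n_simulated - x$unplaced, x$unplaced))
  invisible(x)
}

# Trace the boundary rings of a rook-connected cell set by edge
# cancellation: interior edges appear twice in opposite directions and
# drop out; the surviving directed edges chain into closed rings.
cells_to_rings <- function(cells, nx, cell_size) {
  ix <- (cells - 1L) %% nx + 1L
  iy <- (cells - 1L) %/% nx + 1L
  vkey <- function(vx, vy) paste(vx, vy)
  from <- c(vkey(ix - 1, iy - 1), vkey(ix, iy - 1),
            vkey(ix, iy), vkey(ix - 1, iy))
  to <- c(vkey(ix, iy - 1), vkey(ix, iy),
          vkey(ix - 1, iy), vkey(ix - 1, iy - 1))
  ekey <- paste(from, to)
  rkey <- paste(to, from)
  keep <- !(ekey %in% rkey)
  from <- from[keep]; to <- to[keep]
  # multi-map from-vertex -> outgoing edge indices (pinch vertices can
  # have two outgoing boundary edges)
  out_edges <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  take_edge <- function(v) {
    idx <- out_edges[[v]]
    idx <- idx[!used[idx]]
    if (!length(idx)) return(NA_integer_)
    idx[1]
  }
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      ring <- c(ring, to[e])
      if (to[e] == from[e0]) break
      e <- take_edge(to[e])
      if (is.na(e)) break  # defensive; cancelled edges always close
    }
    coords <- do.call(rbind, lapply(strsplit(ring, " "), as.numeric))
    rings[[length(rings) + 1L]] <- coords * cell_size
  }
  rings
}

#' Export territories as GeoJSON polygons
#'
#' @param field an `occupancy_field`.
#' @param path output .geojson path.
#' @param nx grid x-dimension override (taken from the field's matrices
#'   by default).
#' @export
territories_to_geojson <- function(field, path, nx = nrow(field$M)) {
  feats <- lapply(field$territories, function(t) {
    rings <- cells_to_rings(t$cells, nx, field$cell_size)
    list(
      type = "Feature",
      properties = list(id = t$id, sex = t$sex, known = t$known,
                        area_m2 = t$area,
                        centroid_x = t$centroid[1],
                        centroid_y = t$centroid[2]),
      geometry = list(type = "Polygon",
                      coordinates = lapply(rings, function(r)
                        lapply(seq_len(nrow(r)), function(i)
                          unname(r[i, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
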