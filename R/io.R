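#' @title File formats
#' @description Esri ASCII grid read/write for raster layers, JSON
#'   sidecars for class tables and schedules, and provenance-stamped CSV
#'   for tabular outputs. The grid convention throughout the package is a
#'   matrix `m[ix, iy]` with `ix` increasing eastward and `iy` increasing
#'   northward; ASCII grids are written north-up as the format requires.
#' @name io
NULL

#' Write a matrix as an Esri ASCII grid
#'
#' @param m numeric/integer/logical matrix `m[ix, iy]`.
#' @param path output file path (.asc).
#' @param cell_size cell size in metres.
#' @param origin planar coordinates of the lower-left corner.
#' @param nodata value substituted for `NA`.
#' @export
write_asc <- function(m, path, cell_size, origin = c(0, 0),
                      nodata = -9999) {
  if (is.logical(m)) m[] <- as.integer(m)
  nx <- nrow(m); ny <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nx),
    paste("nrows", ny),
    paste("xllcorner", origin[1]),
    paste("yllcorner", origin[2]),
    paste("cellsize", cell_size),
    paste("NODATA_value", nodata)
  ), con)
  vals <- t(m)[ny:1, , drop = FALSE]  # north-up rows
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path input .asc path.
#' @return list with `m` (matrix `m[ix, iy]`), `cell_size`, `origin`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  stopifnot(length(vals) == nx * ny)
  rows <- matrix(vals, nrow = ny, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) rows[rows == hdr$nodata_value] <- NA
  m <- t(rows[ny:1, , drop = FALSE])
  list(m = m, cell_size = hdr$cellsize,
       origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}

#' Save / load a cover grid as ASCII grids plus a JSON sidecar
#'
#' Writes `<base>.asc` (class ids), `<base>_stand.asc`,
#' `<base>_nonavoided.asc` and `<base>.json` (class table, cell size,
#' origin).
#'
#' @param grid a `cover_grid`.
#' @param base path prefix (no extension).
#' @export
write_cover_grid <- function(grid, base) {
  write_asc(grid$cells, paste0(base, ".asc"), grid$cell_size, grid$origin)
  write_asc(grid$stand_data * 1L, paste0(base, "_stand.asc"),
            grid$cell_size, grid$origin)
  write_asc(ifelse(is.na(grid$nonavoided), NA, grid$nonavoided * 1L),
            paste0(base, "_nonavoided.asc"), grid$cell_size, grid$origin)
  jsonlite::write_json(
    list(classes = grid$classes, cell_size = grid$cell_size,
         origin = grid$origin),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_cover_grid
#' @export
read_cover_grid <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  cells <- read_asc(paste0(base, ".asc"))
  stand <- read_asc(paste0(base, "_stand.asc"))
  nonav <- read_asc(paste0(base, "_nonavoided.asc"))
  new_cover_grid(as.data.frame(side$classes),
                 matrix(as.integer(cells$m), nrow(cells$m)),
                 stand$m == 1,
                 ifelse(is.na(nonav$m), NA, nonav$m == 1),
                 side$cell_size, side$origin)
}

#' Export recorded trajectories
#'
#' Writes the active-step positions recorded by
#' `run_replicate(..., record_trajectories = TRUE)` as a long CSV
#' (`agent`, `step`, `x`, `y`, `energy`, `phase`) or as GeoJSON
#' LineStrings (one feature per agent).
#'
#' @param outcomes a [run_replicate()] result carrying the
#'   `trajectories` attribute.
#' @param path output path (.csv or .geojson).
#' @param format `"csv"` or `"geojson"`.
#' @export
write_trajectories <- function(outcomes, path,
                               format = c("csv", "geojson")) {
  format <- match.arg(format)
  traj <- attr(outcomes, "trajectories")
  if (is.null(traj)) stop("outcomes carry no recorded trajectories")
  if (format == "csv") {
    df <- do.call(rbind, lapply(seq_along(traj), function(i) {
      m <- traj[[i]]
      if (!nrow(m)) return(NULL)
      data.frame(agent = outcomes$id[i], step = seq_len(nrow(m)),
                 x = m[, "x"], y = m[, "y"], energy = m[, "energy"],
                 phase = m[, "phase"])
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    feats <- Filter(Negate(is.null),
                    lapply(seq_along(traj), function(i) {
      m <- traj[[i]]
      if (nrow(m) < 2) return(NULL)
      list(type = "Feature",
           properties = list(agent = outcomes$id[i],
                             fate = outcomes$fate[i]),
           geometry = list(
             type = "LineString",
             coordinates = lapply(seq_len(nrow(m)), function(r)
               c(m[r, "x"], m[r, "y"]))))
    }))
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# CSV with a provenance comment header (seed, scenario labels, ...).
write_csv_prov <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
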