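#' Default configuration
#'
#' Every tunable default of every module, as one nested list suitable
#' for YAML round-tripping (see [write_config()] / [read_config()] and
#' the command-line driver in `inst/cli/martensim.R`).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    landscape = list(extent = c(200L, 200L), cell_size = 100,
                     clustering_scale = 10, stand_data_fraction = 0.512),
    releases = list(n = 15L, sex_ratio = 0.5, min_spacing = 0),
    reference = list(n = 15L, include_outlier = TRUE, tol = 0.10),
    season = list(days = 60L, steps_per_day = 96L,
                  exploration_days = 14L),
    residents = list(n_known = 22L, pop_estimate = 100L),
    homerange = list(min_area_f = 3e6, min_area_m = 5e6,
                     window_area = 1e6),
    movement = list(perceptual_range = 100, fm_msl = 0.9,
                    fm_mvl = 0.97, bound_length = 1.0,
                    bound_rates = c(10, 20, 30)),
    energy = list(initial_reserve = 5491, cost_per_step = 10.5),
    design = list(replicates = 5L)
  )
}

#' Write / read a configuration as YAML
#'
#' @param config nested list (see [default_config()]).
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && !is.null(cfg[[sec]]))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

#' Minimum home-range areas from a configuration
#'
#' @param config nested list (see [default_config()]).
#' @return named vector `c(F = ..., M = ...)` in m^2.
#' @export
config_homerange <- function(config = default_config()) {
  c(F = config$homerange$min_area_f, M = config$homerange$min_area_m)
}
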