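#' @title The factorial simulation experiment
#' @description Orchestrates the full study design: 9 home-range
#'   establishment scenarios (three static thresholds without and with a
#'   required exploration phase, a 70-60-50 dynamic progression, and an
#'   80-70-60 progression with immediate or delayed map swapping)
#'   crossed with 3 candidate bound rates (10/20/30 bounds per minute,
#'   the inversely-modelled movement speed), 5 replicates each: 27
#'   combinations, 135 runs. Pattern sets feed the six-method ranking
#'   and the consensus-best combination is validated with the kernel
#'   fit.
#' @name experiment
NULL

#' The nine study scenarios
#'
#' @param season_days,steps_per_day,exploration_days,replicates season
#'   structure shared by all scenarios.
#' @return named list of `scenario_config`s (bound rate unset, filled in
#'   by [build_design()]).
#' @export
default_scenarios <- function(season_days = 60L, steps_per_day = 96L,
                              exploration_days = 14L, replicates = 5L) {
  sc <- function(name, thresholds, exploration, timing = "immediate")
    scenario_config(name, thresholds, exploration, timing,
                    bound_rate = 30, season_days = season_days,
                    steps_per_day = steps_per_day,
                    exploration_days = exploration_days,
                    replicates = replicates)
  list(
    static50 = sc("static50", 0.5, FALSE),
    static60 = sc("static60", 0.6, FALSE),
    static70 = sc("static70", 0.7, FALSE),
    delay50 = sc("delay50", 0.5, TRUE),
    delay60 = sc("delay60", 0.6, TRUE),
    delay70 = sc("delay70", 0.7, TRUE),
    dynamic70 = sc("dynamic70", c(0.7, 0.6, 0.5), TRUE),
    dynamic80i = sc("dynamic80i", c(0.8, 0.7, 0.6), TRUE),
    dynamic80d = sc("dynamic80d", c(0.8, 0.7, 0.6), TRUE, "delayed")
  )
}

#' Enumerate the factorial design
#'
#' @param scenarios list of `scenario_config`s (default: the nine study
#'   scenarios).
#' @param bound_rates bounds-per-minute levels (10, 20, 30).
#' @param replicates replicates per combination (5).
#' @param master_seed seed from which every run's seed is derived.
#' @return A `design` object: data.frame of runs (scenario, bound_rate,
#'   replicate, seed) plus the scenario list.
#' @export
build_design <- function(scenarios = default_scenarios(),
                         bound_rates = c(10, 20, 30),
                         replicates = 5L, master_seed = 1L) {
  stopifnot(length(scenarios) >= 1, length(bound_rates) >= 1)
  combos <- expand.grid(scenario = names(scenarios),
                        bound_rate = bound_rates,
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$scenario, combos$bound_rate), ]
  runs <- merge(combos, data.frame(replicate = seq_len(replicates)))
  runs <- runs[order(runs$scenario, runs$bound_rate, runs$replicate), ]
  rownames(runs) <- NULL
  runs$seed <- mapply(function(s, b, r) derive_seed(master_seed, s, b, r),
                      runs$scenario, runs$bound_rate, runs$replicate,
                      USE.NAMES = FALSE)
  structure(list(runs = runs, scenarios = scenarios,
                 bound_rates = bound_rates, replicates = replicates,
                 n_combinations = nrow(combos), n_runs = nrow(runs),
                 master_seed = master_seed),
            class = "design")
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf("<design> %d scenarios x %d bound rates = %d combinations; %d runs\n",
              length(x$scenarios), length(x$bound_rates),
              x$n_combinations, x$n_runs))
  invisible(x)
}

#' Prepare the landscape bundle for a design
#'
#' Builds (and caches per distinct threshold rule) the suitability
#' stacks and resident occupancy fields every scenario needs. Residents
#' are re-established once per suitability rule, on the rule's
#' first-period map.
#'
#' @param grid a `cover_grid`.
#' @param design a `design`.
#' @param n_known,pop_estimate resident construction (22 known, 100
#'   total).
#' @param min_homerange_area named `c(F = ..., M = ...)` m^2.
#' @param window_area focal window (m^2).
#' @param seed integer seed.
#' @return list keyed like `design$scenarios` with `stack` and
#'   `occupancy` per scenario.
#' @export
prepare_landscape <- function(grid, design, n_known = 22L,
                              pop_estimate = 100L,
                              min_homerange_area = c(F = 3e6, M = 5e6),
                              window_area = 1e6, seed = 1L) {
  values <- cell_values(grid)
  cache <- list()
  out <- list()
  for (nm in names(design$scenarios)) {
    sc <- design$scenarios[[nm]]
    key <- paste(c(sc$thresholds, sc$timing), collapse = "_")
    if (is.null(cache[[key]])) {
      stack <- build_stack(grid, sc$thresholds, sc$season_days,
                           sc$timing, sc$exploration_days,
                           window_area, values = values)
      occ <- populate_residents(
        stack$maps[[1]], n_known = n_known, pop_estimate = pop_estimate,
        min_homerange_area = min_homerange_area,
        seed = derive_seed(seed, "residents", key))
      cache[[key]] <- list(stack = stack, occupancy = occ)
    }
    out[[nm]] <- cache[[key]]
  }
  out
}

#' Run the full factorial experiment
#'
#' Executes every run of the design, writes outcome and pattern CSVs,
#' ranks all combinations with the six pattern-matching methods, and
#' fits the dispersal kernel of the consensus-best combination. Runs
#' that error are logged and excluded from ranking, never silently
#' dropped.
#'
#' @param design a `design`.
#' @param grid a `cover_grid`.
#' @param landscape result of [prepare_landscape()] (built on the fly
#'   when `NULL`).
#' @param releases release set shared by all runs (generated from the
#'   grid when `NULL`).
#' @param reference an `empirical_reference` (generated with default
#'   targets when `NULL`).
#' @param out_dir output directory (created).
#' @param dry_run enumerate runs without simulating.
#' @param n_agents agents per run when `releases` is `NULL` (15).
#' @param min_homerange_area named `c(F = ..., M = ...)` m^2.
#' @param verbose log per-run progress to stderr.
#' @return list: `design`, `outcomes`, `patterns` (long CSV form),
#'   `ranking` (a `ranking_table`), `kernel` (best-combination fit),
#'   `failed` (failed run labels), `out_dir`.
#' @export
run_experiment <- function(design, grid, landscape = NULL,
                           releases = NULL, reference = NULL,
                           out_dir = tempfile("experiment"),
                           dry_run = FALSE, n_agents = 15L,
                           min_homerange_area = c(F = 3e6, M = 5e6),
                           verbose = FALSE) {
  if (dry_run) return(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  landscape <- landscape %||%
    prepare_landscape(grid, design,
                      min_homerange_area = min_homerange_area,
                      seed = design$master_seed)
  releases <- releases %||%
    generate_release_set(grid, n = n_agents,
                         seed = derive_seed(design$master_seed,
                                            "releases"))
  reference <- reference %||%
    generate_empirical_reference(seed = derive_seed(design$master_seed,
                                                    "reference"))
  runs <- design$runs
  all_out <- list()
  summaries <- list()
  failed <- character(0)
  for (r in seq_len(nrow(runs))) {
    nm <- runs$scenario[r]
    sc <- design$scenarios[[nm]]
    sc$bound_rate <- runs$bound_rate[r]
    combo <- paste(nm, runs$bound_rate[r], sep = "_")
    label <- paste(combo, runs$replicate[r], sep = "_r")
    res <- tryCatch(
      run_replicate(releases, grid, landscape[[nm]]$stack,
                    landscape[[nm]]$occupancy, sc,
                    min_homerange_area = min_homerange_area,
                    seed = runs$seed[r]),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, label)
      message("run ", label, " failed: ", conditionMessage(res))
      next
    }
    if (verbose)
      message(sprintf("%s: %d settled / %d", label,
                      attr(res, "n_settled"), nrow(res)))
    res$scenario <- nm
    res$bound_rate <- runs$bound_rate[r]
    res$replicate <- runs$replicate[r]
    all_out[[label]] <- res
    summaries[[combo]] <- c(summaries[[combo]],
                            list(compute_pattern_set(res)))
  }
  outcomes <- do.call(rbind, all_out)
  rownames(outcomes) <- NULL
  write_csv_prov(outcomes, file.path(out_dir, "outcomes.csv"),
                 c(master_seed = design$master_seed))
  pat_df <- do.call(rbind, lapply(names(summaries), function(cb) {
    pattern_sets_to_df(summaries[[cb]], scenario = cb)
  }))
  write_csv_prov(pat_df, file.path(out_dir, "patterns.csv"),
                 c(master_seed = design$master_seed))
  ranking <- NULL
  kernel <- NULL
  if (length(summaries) >= 2) {
    ref_pat <- reference_patterns(reference,
                                  seed = derive_seed(design$master_seed,
                                                     "ci"))
    ranking <- rank_combinations(summaries, ref_pat)
    write_csv_prov(as.data.frame(ranking),
                   file.path(out_dir, "ranking.csv"),
                   c(master_seed = design$master_seed))
    jsonlite::write_json(as.data.frame(ranking),
                         file.path(out_dir, "ranking.json"),
                         auto_unbox = TRUE, digits = NA)
    best <- ranking$id[1]
    dists <- unlist(lapply(summaries[[best]], function(ps)
      ps$records$dispersal_km))
    if (length(dists) >= 5) {
      kernel <- tryCatch(
        fit_kernel(dists, seed = derive_seed(design$master_seed,
                                             "kernel")),
        error = function(e) NULL)
      if (!is.null(kernel))
        jsonlite::write_json(unclass(kernel),
                             file.path(out_dir, "kernel.json"),
                             auto_unbox = TRUE, digits = NA)
    }
  }
  list(design = design, outcomes = outcomes, patterns = pat_df,
       summaries = summaries, ranking = ranking, kernel = kernel,
       failed = failed, out_dir = out_dir)
}

#' Which bound rate does each method select?
#'
#' Inverse modelling: for each of the six pattern-matching methods, the
#' bound rate(s) of its top-ranked combination; ties credit every tied
#' rate.
#'
#' @param ranking a `ranking_table` whose ids end in `_<bound_rate>`.
#' @return named list: per method, the winning bound rate(s); plus a
#'   `tally` table over all methods.
#' @export
inverse_model_report <- function(ranking) {
  if (is.null(ranking) || nrow(ranking) == 0) stop("empty ranking table")
  methods <- c("pass_fail", "weighted_pass_fail", "rank_sum",
               "weighted_rank_sum", "mahalanobis_d2", "total_indicator")
  rate_of <- function(id) as.numeric(sub(".*_", "", id))
  winners <- lapply(methods, function(m) {
    r <- ranking[[paste0("rank_", m)]]
    sort(unique(rate_of(ranking$id[which(r == min(r, na.rm = TRUE))])))
  })
  names(winners) <- methods
  tally <- table(unlist(winners))
  c(winners, list(tally = tally))
}
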