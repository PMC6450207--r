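# martensim

Spatially explicit individual-based simulation of post-release dispersal
in translocated American martens (*Martes americana*), built to ask a
behavioural question: does a time-limited disperser relax its
habitat-selectivity criterion as the season runs out?

Martens translocated into unfamiliar forest must find and defend a home
range before winter. `martensim` simulates each disperser through a
60-day season of 5760 fifteen-minute steps: a correlated random walk
with cover- and sex-specific step lengths (mean step length, MSL) and
turning concentrations (mean vector length, MVL), an energy budget
(5491 kJ initial reserve, 10.5 kJ per step, cover-specific prey
capture), per-step predation hazard, a 100-m perceptual range feeding a
memory of candidate home-range sites, and territorial establishment on
contiguous suitable habitat unoccupied by a same-sex conspecific.
Habitat suitability is a percent rule: a cell is suitable when at least
*t*% of the surrounding 1 km² is nonavoided cover. Scenarios hold *t*
static (50/60/70%), impose a 2-week exploration phase, or let *t*
decline through the season (70→60→50% or 80→70→60%) — the declining
schedules implement the hypothesis under test.

Model evaluation is pattern-oriented: nine empirical dispersal patterns
(distance mean/SD, days-to-establishment mean/SD, average and nearest
neighbour distance, mortality rate, and two male>female contrasts) are
confronted with simulations under six pattern-matching methods —
pass/fail and weighted pass/fail (1.96·SE and bootstrap-CI criteria),
rank-sum and weighted rank-sum, Total Indicator (summed RMSD ratios),
and mean Mahalanobis D² with a pooled covariance — plus a consensus
rank-sum across methods. The movement speed (10, 20 or 30 bounds per
minute) is estimated by inverse modelling. Dispersal kernels of the
best model are validated by a profile-likelihood Weibull fit with an
Anderson–Darling parametric-bootstrap goodness-of-fit test.

Everything runs on synthetic inputs generated by the package itself: a
patchy categorical cover mosaic (with 48.8% of cells lacking
stand-level data, as in the study landscape), release sets, resident
territories, and a synthetic "observed marten" reference whose summary
statistics match the published pattern values.

## Worked example

```r
library(martensim)

grid <- generate_cover_grid(seed = 42)      # 20 x 20 km synthetic mosaic
stack <- build_stack(grid, c(0.7, 0.6, 0.5))   # declining selectivity
pop <- scaled_resident_population(grid)        # density-scaled residents
occ <- populate_residents(stack$maps[[1]], n_known = pop$n_known,
                          pop_estimate = pop$pop_estimate, seed = 7)
rel <- generate_release_set(grid, n = 15, seed = 3)
cfg <- scenario_config("dynamic70", c(0.7, 0.6, 0.5),
                       exploration = TRUE, bound_rate = 30)
out <- run_replicate(rel, grid, stack, occ, cfg, seed = 11)
table(out$fate)
#> predation   settled
#>         2        13
compute_pattern_set(out)
#> <pattern_set> n = 15 (settled 13, dead 2, unsettled 0)
#>   distance 9.29 +/- 4.96 km; days 20.8 +/- 3.1; mortality 0.13
```

Thirteen of the 15 released martens settled, after a mean of 20.8 days
(settlement cannot start before day 15 under the exploration rule) and
9.3 km from their release points; two died of predation. The pattern
set holds the nine calibration statistics for this replicate; feeding
replicate pattern sets from several scenarios to `rank_combinations()`
together with `reference_patterns(generate_empirical_reference(...))`
produces the six-method ranking table and consensus order, and
`fit_kernel()` validates the best combination's distance kernel.

The full factorial study (9 scenarios × 3 bound rates × 5 replicates)
runs through `build_design()` / `run_experiment()`, or from a shell via
the thin driver `inst/cli/martensim.R` (`make-landscape`,
`make-reference`, `simulate`, `rank`, `fit-kernel`, `report`).

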