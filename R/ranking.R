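#' @title Pattern-oriented ranking of scenario combinations
#' @description Scores every scenario x bound-rate combination against
#'   the observed patterns with six pattern-matching methods - pass/fail
#'   and weighted pass/fail (1.96 SE / bootstrap-CI matching criteria),
#'   rank-sum and weighted rank-sum (ranked absolute deviations), the
#'   Total Indicator (summed RMSD ratios to the per-pattern best), and
#'   the mean Mahalanobis distance D^2 over replicates with a pooled
#'   covariance matrix - then aggregates the per-method ranks into a
#'   consensus ordering.
#' @name pom_ranking
NULL

NUMERIC_PATTERNS <- c("distance_mean", "distance_sd", "days_mean",
                      "days_sd", "avg_neighbor_mean",
                      "nearest_neighbor_mean", "mortality")
BINARY_PATTERNS <- c("mf_distance", "mf_days")
D2_PATTERNS <- c("distance_mean", "days_mean", "avg_neighbor_mean",
                 "nearest_neighbor_mean")

#' Percentile bootstrap confidence interval
#'
#' @param records numeric vector of individual-level values.
#' @param statistic function of a numeric vector.
#' @param B bootstrap resamples (>= 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return `c(lower, upper)`.
#' @export
bootstrap_ci <- function(records, statistic = mean, B = 2000L,
                         level = 0.95, seed = NULL) {
  stopifnot(length(records) >= 2, B >= 1000)
  with_seed_(seed, {
    n <- length(records)
    stats_b <- vapply(seq_len(B), function(b)
      statistic(records[sample.int(n, n, replace = TRUE)]), numeric(1))
    a <- (1 - level) / 2
    unname(stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE))
  })
}

#' Assemble the reference-pattern table for calibration
#'
#' Combines the nine observed pattern values with the matching machinery
#' each needs: 1.96 SE bands for individual-level numerics, bootstrap
#' 95% CIs for population-level numerics (SDs cannot be given an
#' analytic SE from 15 animals), and the all-replicates rule for the two
#' binary sex contrasts. The underlying records are retained for D^2.
#'
#' @param reference an `empirical_reference`.
#' @param B bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @return A `reference_patterns` object (data.frame + records
#'   attribute).
#' @export
reference_patterns <- function(reference, B = 2000L, seed = 1L) {
  tab <- default_pattern_targets()
  s <- reference$summary
  rec <- reference$records
  st <- rec[rec$fate == "settled", , drop = FALSE]
  tab$value <- vapply(tab$pattern, function(p) {
    v <- s[[p]]
    if (is.logical(v)) as.numeric(v) else v
  }, numeric(1))
  tab$se <- NA_real_
  tab$ci_lo <- NA_real_
  tab$ci_hi <- NA_real_
  ind_src <- list(distance_mean = st$dispersal_km, days_mean = st$days,
                  avg_neighbor_mean = st$avg_neighbor_km,
                  nearest_neighbor_mean = st$nearest_neighbor_km)
  for (p in names(ind_src)) {
    i <- match(p, tab$pattern)
    v <- ind_src[[p]]
    tab$se[i] <- stats::sd(v) / sqrt(length(v))
  }
  pop_src <- list(distance_sd = list(v = st$dispersal_km, f = stats::sd),
                  days_sd = list(v = st$days, f = stats::sd),
                  mortality = list(v = as.numeric(rec$fate == "dead"),
                                   f = mean))
  for (p in names(pop_src)) {
    i <- match(p, tab$pattern)
    ci <- bootstrap_ci(pop_src[[p]]$v, pop_src[[p]]$f, B = B,
                       seed = derive_seed(seed, p))
    tab$ci_lo[i] <- ci[1]; tab$ci_hi[i] <- ci[2]
  }
  structure(tab, records = rec, class = c("reference_patterns",
                                          "data.frame"))
}

# replicate-mean of a numeric pattern over a combination's pattern sets
rep_mean <- function(pattern_sets, pattern) {
  mean(vapply(pattern_sets, function(ps)
    as.numeric(ps[[pattern]]), numeric(1)), na.rm = TRUE)
}

rep_values <- function(pattern_sets, pattern) {
  vapply(pattern_sets, function(ps) as.numeric(ps[[pattern]]), numeric(1))
}

#' Pass/fail score of one combination
#'
#' An individual-level numeric pattern passes when the replicate mean
#' lies within 1.96 SE of the observed mean (boundary inclusive); a
#' population-level numeric when it lies inside the bootstrap 95% CI; a
#' binary sex contrast when *all* replicates reproduce the male-biased
#' direction. Unweighted score: passes out of 9; weighted: sum of the
#' passed patterns' importance weights (max 17).
#'
#' @param pattern_sets list of `pattern_set`s (the combination's
#'   replicates).
#' @param reference a `reference_patterns`.
#' @param weighted use importance weights?
#' @return points scored (attribute `passed`: named logical).
#' @export
passfail_score <- function(pattern_sets, reference, weighted = FALSE) {
  passed <- stats::setNames(logical(nrow(reference)), reference$pattern)
  for (i in seq_len(nrow(reference))) {
    p <- reference$pattern[i]
    if (reference$mode[i] == "binary") {
      v <- rep_values(pattern_sets, p)
      passed[p] <- length(v) > 0 && !anyNA(v) && all(v == 1)
    } else {
      m <- rep_mean(pattern_sets, p)
      if (is.na(m)) { passed[p] <- FALSE; next }
      if (reference$level[i] == "individual") {
        passed[p] <- abs(m - reference$value[i]) <=
          1.96 * reference$se[i]
      } else {
        passed[p] <- m >= reference$ci_lo[i] & m <= reference$ci_hi[i]
      }
    }
  }
  score <- if (weighted) sum(reference$weight[passed[reference$pattern]])
           else sum(passed)
  structure(score, passed = passed)
}

#' Rank-sum score across combinations
#'
#' For each of the 7 numeric patterns, combinations are ranked ascending
#' by the absolute deviation of their replicate mean from the observed
#' value (minimum-rank ties); the rank-sum is the sum over patterns,
#' optionally weighting each pattern's rank by its importance. Lower is
#' better.
#'
#' @param summaries named list: per combination, its list of
#'   `pattern_set`s.
#' @param reference a `reference_patterns`.
#' @param weighted multiply ranks by pattern weights?
#' @return named numeric vector of rank-sums.
#' @export
rank_patterns <- function(summaries, reference, weighted = FALSE) {
  stopifnot(length(summaries) >= 2)
  total <- stats::setNames(numeric(length(summaries)), names(summaries))
  for (p in NUMERIC_PATTERNS) {
    i <- match(p, reference$pattern)
    dev <- vapply(summaries, function(ss)
      abs(rep_mean(ss, p) - reference$value[i]), numeric(1))
    r <- rank(dev, ties.method = "min", na.last = "keep")
    r[is.na(r)] <- length(summaries)  # unavailable pattern ranks last
    w <- if (weighted) reference$weight[i] else 1
    total <- total + w * r
  }
  total
}

#' Root mean square deviation of one pattern
#'
#' `sqrt(sum((Obs - Sim_r)^2) / N_rep)` over a combination's replicates.
#'
#' @param pattern_sets the combination's replicates.
#' @param reference a `reference_patterns`.
#' @param pattern pattern name.
#' @export
rmsd <- function(pattern_sets, reference, pattern) {
  obs <- reference$value[match(pattern, reference$pattern)]
  sim <- rep_values(pattern_sets, pattern)
  if (anyNA(sim)) stop("missing replicate value for pattern ", pattern)
  sqrt(sum((obs - sim)^2) / length(sim))
}

#' Total Indicator
#'
#' For each numeric pattern, each combination's RMSD is divided by the
#' smallest RMSD achieved by any combination for that pattern; the TI is
#' the sum of those ratios (>= the number of patterns, with equality iff
#' best everywhere). A zero best-RMSD is handled by an epsilon shift on
#' both numerator and denominator.
#'
#' @param summaries named list of combinations' replicate pattern sets.
#' @param reference a `reference_patterns`.
#' @param eps epsilon for the zero-RMSD rule.
#' @return named numeric vector of TI values (lower is better).
#' @export
total_indicator <- function(summaries, reference, eps = 1e-12) {
  stopifnot(length(summaries) >= 2)
  ti <- stats::setNames(numeric(length(summaries)), names(summaries))
  for (p in NUMERIC_PATTERNS) {
    obs <- reference$value[match(p, reference$pattern)]
    r <- vapply(summaries, function(ss) {
      sim <- rep_values(ss, p)
      if (anyNA(sim)) NA_real_ else sqrt(sum((obs - sim)^2) / length(sim))
    }, numeric(1))
    if (all(is.na(r))) next
    best <- min(r, na.rm = TRUE)
    ti <- ti + if (best == 0) (r + eps) / (best + eps) else r / best
  }
  ti  # NA for combinations with incomplete patterns; ranked last
}

# Pooled covariance of replicate-level D2 pattern vectors across all
# combinations, each combination centred on its own mean.
pooled_covariance <- function(summaries, ridge = 1e-8) {
  X <- lapply(summaries, function(ss) {
    m <- t(vapply(ss, function(ps)
      vapply(D2_PATTERNS, function(p) as.numeric(ps[[p]]), numeric(1)),
      numeric(length(D2_PATTERNS))))
    m[stats::complete.cases(m), , drop = FALSE]
  })
  k <- length(D2_PATTERNS)
  SS <- matrix(0, k, k)
  df <- 0
  for (m in X) {
    if (nrow(m) < 2) next
    cm <- scale(m, center = TRUE, scale = FALSE)
    SS <- SS + crossprod(cm)
    df <- df + nrow(m) - 1
  }
  if (df == 0) stop("need >= 2 complete replicates in some combination")
  S <- SS / df
  # ridge-regularise if ill-conditioned
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12)
    S <- S + ridge * sum(diag(S)) / k * diag(k)
  S
}

#' Mean Mahalanobis distance of a combination from the observed data
#'
#' For each replicate, the squared Mahalanobis distance between the
#' 4-vector of individual-level patterns (distance mean, days mean,
#' average and nearest neighbour distance) and the observed vector,
#' using the pooled covariance `S`; returns the mean over replicates.
#'
#' @param pattern_sets the combination's replicates.
#' @param reference a `reference_patterns`.
#' @param pooled_cov pooled covariance matrix (see
#'   [total_indicator()]'s `summaries` for the pooling set); computed
#'   internally by [rank_combinations()].
#' @return mean D^2 (lower is better).
#' @export
mahalanobis_d2 <- function(pattern_sets, reference, pooled_cov) {
  obs <- reference$value[match(D2_PATTERNS, reference$pattern)]
  m <- t(vapply(pattern_sets, function(ps)
    vapply(D2_PATTERNS, function(p) as.numeric(ps[[p]]), numeric(1)),
    numeric(length(D2_PATTERNS))))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) return(NA_real_)
  mean(stats::mahalanobis(m, center = obs, cov = pooled_cov))
}

#' Score and rank all combinations with the six methods
#'
#' @param summaries named list: one element per scenario x bound-rate
#'   combination, each a list of replicate `pattern_set`s. Names encode
#'   the combination id.
#' @param reference a `reference_patterns`.
#' @return A `ranking_table` data.frame: method scores, per-method ranks
#'   and the consensus `Sum`, ordered by the consensus.
#' @export
rank_combinations <- function(summaries, reference) {
  stopifnot(length(summaries) >= 2)
  ids <- names(summaries)
  pf <- vapply(summaries, function(ss)
    as.numeric(passfail_score(ss, reference, weighted = FALSE)),
    numeric(1))
  wpf <- vapply(summaries, function(ss)
    as.numeric(passfail_score(ss, reference, weighted = TRUE)),
    numeric(1))
  rs <- rank_patterns(summaries, reference, weighted = FALSE)
  wrs <- rank_patterns(summaries, reference, weighted = TRUE)
  ti <- total_indicator(summaries, reference)
  S <- pooled_covariance(summaries)
  d2 <- vapply(summaries, function(ss)
    mahalanobis_d2(ss, reference, S), numeric(1))
  tab <- data.frame(id = ids, pass_fail = pf, weighted_pass_fail = wpf,
                    rank_sum = rs, weighted_rank_sum = wrs,
                    mahalanobis_d2 = d2, total_indicator = ti,
                    stringsAsFactors = FALSE, row.names = NULL)
  consensus(tab)
}

#' Consensus ranking across the six methods
#'
#' Each method's scores are converted to ranks (pass/fail methods:
#' higher is better; all others: lower is better; minimum-rank ties);
#' the consensus `Sum` adds the six ranks and orders ascending, ties
#' broken by the rank-sum method's rank and then by id.
#'
#' @param tab data.frame with the six method-score columns and `id`.
#' @return the table with `rank_*` columns and `Sum`, reordered.
#' @export
consensus <- function(tab) {
  need <- c("pass_fail", "weighted_pass_fail", "rank_sum",
            "weighted_rank_sum", "mahalanobis_d2", "total_indicator")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing method columns: ",
                         paste(miss, collapse = ", "))
  rk <- function(v, desc = FALSE) {
    r <- rank(if (desc) -v else v, ties.method = "min",
              na.last = "keep")
    r[is.na(r)] <- nrow(tab)  # incomplete combinations rank last
    r
  }
  tab$rank_pass_fail <- rk(tab$pass_fail, desc = TRUE)
  tab$rank_weighted_pass_fail <- rk(tab$weighted_pass_fail, desc = TRUE)
  tab$rank_rank_sum <- rk(tab$rank_sum)
  tab$rank_weighted_rank_sum <- rk(tab$weighted_rank_sum)
  tab$rank_mahalanobis_d2 <- rk(tab$mahalanobis_d2)
  tab$rank_total_indicator <- rk(tab$total_indicator)
  rcols <- paste0("rank_", need)
  tab$Sum <- rowSums(tab[rcols])
  tab <- tab[order(tab$Sum, tab$rank_rank_sum, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ranking_table", "data.frame")
  tab
}
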