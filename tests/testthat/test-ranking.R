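# A reference and a helper that fabricates replicate pattern sets with
# controlled deviations from it.
ref_fixture <- function(seed = 3) {
  reference_patterns(generate_empirical_reference(seed = seed),
                     B = 1000, seed = 5)
}

ps_at <- function(ref, shift = 0, jitter = 0, seed = 1, mf = TRUE) {
  vals <- as.list(setNames(ref$value, ref$pattern))
  withr::with_seed(seed, {
    for (p in setdiff(names(vals), c("mf_distance", "mf_days"))) {
      vals[[p]] <- vals[[p]] + shift + rnorm(1, 0, jitter)
    }
  })
  vals$mf_distance <- as.logical(mf)
  vals$mf_days <- as.logical(mf)
  make_ps(vals)
}

test_that("bootstrap CIs behave as percentile intervals", {
  expect_equal(bootstrap_ci(rep(4.2, 10), mean, B = 1000, seed = 1),
               c(4.2, 4.2))
  withr::with_seed(2, x <- rnorm(100))
  ci <- bootstrap_ci(x, mean, B = 10000, seed = 3)
  half <- diff(ci) / 2
  analytic <- 1.96 * sd(x) / sqrt(100)
  expect_lte(abs(half - analytic), 0.1 * analytic)
  expect_identical(ci, bootstrap_ci(x, mean, B = 10000, seed = 3))
})

test_that("reference patterns carry SEs and bootstrap CIs", {
  ref <- ref_fixture()
  ind <- ref$level == "individual" & ref$mode == "numeric"
  expect_true(all(!is.na(ref$se[ind])))
  pop <- ref$level == "population" & ref$mode == "numeric"
  expect_true(all(ref$ci_lo[pop] <= ref$ci_hi[pop]))
})

test_that("a perfect match scores 9 unweighted and 17 weighted", {
  ref <- ref_fixture()
  reps <- lapply(1:5, function(r) ps_at(ref))
  expect_equal(as.numeric(passfail_score(reps, ref)), 9)
  expect_equal(as.numeric(passfail_score(reps, ref, weighted = TRUE)),
               sum(default_pattern_targets()$weight))  # 17
})

test_that("one contrary replicate fails a binary pattern", {
  ref <- ref_fixture()
  reps <- lapply(1:5, function(r) ps_at(ref))
  reps[[3]] <- ps_at(ref, mf = FALSE)
  sc <- passfail_score(reps, ref)
  expect_false(attr(sc, "passed")["mf_distance"])
  expect_false(attr(sc, "passed")["mf_days"])
})

test_that("the 1.96 SE pass boundary is inclusive", {
  ref <- ref_fixture()
  i <- match("distance_mean", ref$pattern)
  exact <- lapply(1:5, function(r) {
    ps <- ps_at(ref)
    ps$distance_mean <- ref$value[i] + 1.96 * ref$se[i]
    ps
  })
  expect_true(attr(passfail_score(exact, ref), "passed")["distance_mean"])
  over <- lapply(exact, function(ps) {
    ps$distance_mean <- ps$distance_mean + 1e-6
    ps
  })
  expect_false(attr(passfail_score(over, ref), "passed")["distance_mean"])
})

test_that("rank-sums order combinations by deviation", {
  ref <- ref_fixture()
  summaries <- list(A = lapply(1:5, function(r) ps_at(ref, shift = 0.01)),
                    B = lapply(1:5, function(r) ps_at(ref, shift = 5)))
  rs <- rank_patterns(summaries, ref)
  expect_equal(unname(rs), c(7, 14))
  tied <- list(A = summaries$A, B = summaries$A)
  expect_equal(unname(rank_patterns(tied, ref)), c(7, 7))
  ref1 <- ref
  ref1$weight[] <- 1
  expect_equal(rank_patterns(summaries, ref1, weighted = TRUE),
               rank_patterns(summaries, ref1))
})

test_that("RMSD follows the replicate-wise formula", {
  ref <- ref_fixture()
  i <- match("days_mean", ref$pattern)
  obs <- ref$value[i]
  reps <- lapply(c(-2, 2), function(d) {
    ps <- ps_at(ref); ps$days_mean <- obs + d; ps
  })
  expect_equal(rmsd(reps, ref, "days_mean"), 2)
  expect_equal(rmsd(lapply(1:3, function(r) ps_at(ref)), ref,
                    "days_mean"), 0)
  one <- list(ps_at(ref))
  one[[1]]$days_mean <- obs + 3.5
  expect_equal(rmsd(one, ref, "days_mean"), 3.5)
})

test_that("Total Indicator is floored at the pattern count", {
  ref <- ref_fixture()
  summaries <- list(best = lapply(1:5, function(r) ps_at(ref)),
                    worse = lapply(1:5, function(r) ps_at(ref, shift = 3)))
  ti <- total_indicator(summaries, ref)
  expect_equal(unname(ti["best"]), 7)  # perfect ties resolved by epsilon
  expect_gte(ti["worse"], 7)
  # symmetric two-pattern example: each combination best on one pattern
  sym <- list(
    A = lapply(1:2, function(r) {
      ps <- ps_at(ref)
      ps$distance_mean <- ref$value[match("distance_mean", ref$pattern)] + 1
      ps$days_mean <- ref$value[match("days_mean", ref$pattern)] + 2
      ps
    }),
    B = lapply(1:2, function(r) {
      ps <- ps_at(ref)
      ps$distance_mean <- ref$value[match("distance_mean", ref$pattern)] + 2
      ps$days_mean <- ref$value[match("days_mean", ref$pattern)] + 1
      ps
    }))
  ti2 <- total_indicator(sym, ref)
  expect_equal(unname(ti2["A"]), unname(ti2["B"]))
  expect_equal(unname(ti2["A"]), 5 + 1 + 2)  # 5 tied + ratios 1 and 2
})

test_that("D^2 reduces to squared Euclidean under identity covariance", {
  ref <- ref_fixture()
  obs <- ref$value[match(martensim:::D2_PATTERNS, ref$pattern)]
  reps <- lapply(1:4, function(r) ps_at(ref, jitter = 1, seed = r))
  d2 <- mahalanobis_d2(reps, ref, diag(4))
  direct <- mean(vapply(reps, function(ps) {
    v <- vapply(martensim:::D2_PATTERNS, function(p) ps[[p]], numeric(1))
    sum((v - obs)^2)
  }, numeric(1)))
  expect_equal(d2, direct)
  expect_equal(mahalanobis_d2(lapply(1:3, function(r) ps_at(ref)), ref,
                              diag(4)), 0)
})

test_that("D^2 is invariant to a unit change applied consistently", {
  ref <- ref_fixture()
  summaries <- list(A = lapply(1:5, function(r) ps_at(ref, jitter = 2,
                                                      seed = r)),
                    B = lapply(1:5, function(r) ps_at(ref, shift = 4,
                                                      jitter = 2,
                                                      seed = 10 + r)))
  S <- martensim:::pooled_covariance(summaries)
  base <- mahalanobis_d2(summaries$B, ref, S)
  # rescale one pattern by 1000 in sims, reference and covariance
  k <- match("distance_mean", martensim:::D2_PATTERNS)
  scale_ps <- function(ps) { ps$distance_mean <- ps$distance_mean * 1000; ps }
  summaries2 <- lapply(summaries, function(ss) lapply(ss, scale_ps))
  ref2 <- ref
  ref2$value[match("distance_mean", ref2$pattern)] <-
    ref2$value[match("distance_mean", ref2$pattern)] * 1000
  S2 <- martensim:::pooled_covariance(summaries2)
  expect_equal(mahalanobis_d2(summaries2$B, ref2, S2), base,
               tolerance = 1e-8)
})

test_that("a dominant combination is ranked first by all six methods", {
  ref <- ref_fixture()
  summaries <- list(
    perfect_10 = lapply(1:5, function(r) ps_at(ref, jitter = 1e-4,
                                               seed = r)),
    near_20 = lapply(1:5, function(r) ps_at(ref, shift = 2, jitter = 1,
                                            seed = 10 + r)),
    far_30 = lapply(1:5, function(r) ps_at(ref, shift = 8, jitter = 1,
                                           seed = 20 + r, mf = FALSE)))
  tab <- rank_combinations(summaries, ref)
  expect_equal(tab$id[1], "perfect_10")
  for (m in c("pass_fail", "weighted_pass_fail", "rank_sum",
              "weighted_rank_sum", "mahalanobis_d2", "total_indicator"))
    expect_equal(tab[[paste0("rank_", m)]][tab$id == "perfect_10"], 1)
  expect_equal(tab$Sum[1], 6)
})

test_that("consensus ranking is invariant to row order", {
  withr::with_seed(9, {
    tab <- data.frame(id = paste0("c", 1:6, "_", c(10, 20, 30)),
                      pass_fail = sample(0:9, 6, TRUE),
                      weighted_pass_fail = sample(0:17, 6, TRUE),
                      rank_sum = runif(6, 7, 100),
                      weighted_rank_sum = runif(6, 10, 200),
                      mahalanobis_d2 = runif(6, 0, 50),
                      total_indicator = runif(6, 7, 40))
  })
  a <- consensus(tab)
  b <- consensus(tab[sample(6), ])
  expect_equal(a, b)
  expect_error(consensus(tab[, -2]), "missing method")
})

test_that("adding a worse combination never hurts existing scores", {
  ref <- ref_fixture()
  base <- list(A = lapply(1:5, function(r) ps_at(ref, shift = 1,
                                                 jitter = 0.5, seed = r)),
               B = lapply(1:5, function(r) ps_at(ref, shift = 3,
                                                 jitter = 0.5,
                                                 seed = 10 + r)))
  pf_before <- as.numeric(passfail_score(base$A, ref))
  ti_before <- total_indicator(base, ref)["A"]
  worse <- c(base, list(C = lapply(1:5, function(r)
    ps_at(ref, shift = 10, jitter = 0.5, seed = 20 + r))))
  expect_equal(as.numeric(passfail_score(worse$A, ref)), pf_before)
  expect_lte(total_indicator(worse, ref)["A"], ti_before + 1e-12)
  for (p in martensim:::NUMERIC_PATTERNS)
    expect_equal(rmsd(worse$A, ref, p), rmsd(base$A, ref, p))
})
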