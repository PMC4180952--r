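test_that("periodogram recovers a known period and handles edge cases", {
  times <- seq(0, 300, by = 20)
  y <- cos(2 * pi * times / 60)
  P <- periodogram_power(y, times, seq(40, 240, 10))
  expect_equal(as.numeric(names(P)[which.max(P)]), 60)
  # constant series -> zero power everywhere
  expect_true(all(periodogram_power(rep(3, 16), times) <= 1e-10))
  # time reversal leaves the spectrum unchanged (even sampling)
  y2 <- cos(2 * pi * times / 80) + 0.1 * sin(2 * pi * times / 120)
  expect_equal(periodogram_power(rev(y2), times),
               periodogram_power(y2, times), tolerance = 1e-9)
  # missing values handled without imputation
  y3 <- y; y3[c(4, 9)] <- NA
  P3 <- periodogram_power(y3, times, seq(40, 240, 10))
  expect_equal(as.numeric(names(P3)[which.max(P3)]), 60)
  expect_error(periodogram_power(y[1:6], times[1:6], 60),
               "insufficient-data")
  expect_error(periodogram_power(y, times, c(10, 60)), "period_grid")
})

test_that("autocorrelation score: period lag, antiphase, degenerate", {
  times <- seq(0, 300, by = 20)
  y <- cos(2 * pi * times / 80)   # period = 4 sample steps
  expect_equal(autocorr_score(y, 4), 1, tolerance = 1e-9)
  expect_equal(autocorr_score(y, 2), -1, tolerance = 1e-9)
  expect_equal(autocorr_score(c(1, 1, 1, 1, 2), 1), 0)  # zero-variance head
  expect_error(autocorr_score(y, 16), "lag")
  # white noise scores scatter around 0
  set.seed(1)
  r <- replicate(200, autocorr_score(rnorm(16), 4))
  expect_lt(abs(mean(r)), 0.1)
  expect_true(all(abs(r) < 1))
})

test_that("template rank score: perfect match, antiphase, tau arithmetic", {
  times <- seq(0, 300, by = 20)
  # period 72 shares no rational alignment with the 20-min grid, so all
  # sampled values are distinct (no floating-point rank ties)
  tpl <- cos(2 * pi * (times / 72 - 0.1))
  grid2 <- c(0.1, 0.6)   # the phase and its antiphase
  expect_equal(template_rank_score(tpl, times, 72, grid2), 1)
  # negated template matches the antiphase entry of the phase grid
  expect_equal(template_rank_score(-tpl, times, 72, grid2), 1)
  # monotone distortion leaves the rank score unchanged
  expect_equal(template_rank_score(exp(3 * tpl), times, 72, grid2), 1)
  expect_equal(template_rank_score(rep(1, 16), times, 72, grid2), 0)
  # tau value against an enumeration of discordant pairs
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  tm <- matrix(1:8, ncol = 1)
  pairs <- utils::combn(8, 2)
  conc <- sum(apply(pairs, 2, function(ij)
    sign(y[ij[2]] - y[ij[1]]) * sign(ij[2] - ij[1])))
  expect_equal(drop(oscarrest:::kendall_tau_multi(matrix(y, ncol = 1), tm)),
               conc / ncol(pairs))
})

test_that("permutation p-values: constant series, exact enumeration, floor", {
  times <- seq(0, 300, by = 20)
  stat <- function(s, t) max(periodogram_power(s, t, seq(40, 240, 10)))
  # constant series: all permutations identical -> p = 1
  expect_equal(permutation_pvalue(stat, rep(2, 16), times, n_perm = 99,
                                  seed = 1), 1)
  # add-one floor
  y <- cos(2 * pi * times / 100)
  p <- permutation_pvalue(stat, y, times, n_perm = 99, seed = 1)
  expect_gte(p, 1 / 100)
  # exact enumeration on 5 points matches an independent oracle
  stat5 <- function(s, t) sum(s * seq_along(s))   # cheap deterministic stat
  y5 <- c(0.3, 1.2, 0.1, 2.4, 0.8)
  t5 <- 0:4
  p_exact <- permutation_pvalue(stat5, y5, t5, exact = TRUE)
  obs <- stat5(y5, t5)
  all_p <- vapply(perms_oracle(seq_along(y5)),
                  function(idx) stat5(y5[idx], t5), numeric(1))
  expect_equal(p_exact, mean(all_p >= obs - 1e-12))
  # determinism given seed
  expect_identical(permutation_pvalue(stat, y, times, 99, seed = 7),
                   permutation_pvalue(stat, y, times, 99, seed = 7))
})

test_that("bh_fdr matches the step-up oracle and spec examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("consensus calling: intersection logic and recovery", {
  # trivial set algebra via the constructor
  cs <- consensus_set(list(a = c("A", "B", "C"), b = c("B", "C"),
                           c = "C"), alpha = 0.05)
  expect_equal(cs$gene_ids, "C")
  # small simulated panel: consensus within each per-algorithm set,
  # dropping an algorithm never shrinks the consensus
  models <- c(lapply(1:15, function(i)
    periodic_model(sprintf("p%02d", i), phi = (i * 0.07) %% 1)),
    lapply(1:25, function(i) flat_model(sprintf("f%02d", i))))
  m <- simulate_experiment(models, default_sync(),
                           experiment_design("WT", seed = 21))
  res <- call_periodic(m, n_perm = 199, seed = 5)
  per <- res$consensus$per_algorithm
  for (s in per) expect_true(all(res$consensus$gene_ids %in% s))
  for (drop in seq_along(per)) {
    sub <- Reduce(intersect, per[-drop])
    expect_true(all(res$consensus$gene_ids %in% sub))
  }
  # most truly periodic genes are found, flat genes mostly are not
  truth <- vapply(models, function(x) x$amplitude > 0, logical(1))
  ids <- vapply(models, function(x) x$gene_id, character(1))
  hit <- ids[truth] %in% res$consensus$gene_ids
  expect_gte(mean(hit), 0.8)
  fp <- ids[!truth] %in% res$consensus$gene_ids
  expect_lte(mean(fp), 0.1)
  # alpha = 0 empties the consensus
  res0 <- call_periodic(m, alpha = 0, n_perm = 99, seed = 5)
  expect_length(res0$consensus$gene_ids, 0)
})

test_that("period and phase estimation", {
  times <- seq(0, 360, by = 20)
  # off-grid period recovered within +/- 5 min
  y70 <- 2 + cos(2 * pi * times / 70)
  e <- estimate_period_phase(y70, times)
  expect_lt(abs(e$period - 70), 5)
  expect_false(e$boundary)
  # on-grid period recovered essentially exactly, peak time at 0
  y80 <- 2 + cos(2 * pi * times / 80)
  e80 <- estimate_period_phase(y80, times)
  expect_lt(abs(e80$period - 80), 0.5)
  expect_lt(min(e80$peak_time, 80 - e80$peak_time), 1)
  # phase recovery: peak shifted to 25 min
  ysh <- 2 + cos(2 * pi * (times - 25) / 80)
  esh <- estimate_period_phase(ysh, times)
  expect_lt(abs(esh$peak_time - 25), 2)
  # identical series -> identical estimates
  expect_identical(estimate_period_phase(y70, times),
                   estimate_period_phase(y70, times))
  # argmax on the grid boundary is flagged
  yfast <- cos(2 * pi * times / 40)
  expect_true(estimate_period_phase(yfast, times, seq(40, 240, 10))$boundary)
})
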