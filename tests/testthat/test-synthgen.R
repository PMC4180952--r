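test_that("mean_profile degenerate cases", {
  sync <- default_sync()
  # amplitude zero -> exactly the baseline everywhere
  m0 <- flat_model(b = 3)
  expect_equal(mean_profile(m0, sync, c(0, 50, 333)), rep(3, 3))
  # concentration zero -> flat at b + a
  mk0 <- gene_model("g", 1, 2, 0.3, 0, programs = list(WT = "continue"))
  expect_equal(mean_profile(mk0, sync, c(0, 77, 200)), rep(3, 3))
})

test_that("perfect synchrony peaks at phi * period and matches single cell", {
  p <- 120
  sync <- perfect_sync(period = p)
  m <- periodic_model(phi = 0.5, kappa = 30)
  tt <- seq(0, p, by = 0.25)
  tr <- mean_profile(m, sync, tt)
  expect_lt(abs(tt[which.max(tr)] - 0.5 * p), 0.26)
  # bulk trace equals the single-cell profile at the deterministic phase
  theta <- sync$initial_phase + tt / p
  sc <- oscarrest:::cell_profile(theta, m$baseline, m$amplitude,
                                 m$concentration, m$peak_phase)
  expect_lt(max(abs(tr - sc)), 1e-8)
})

test_that("quadrature matches adaptive-integration oracle", {
  sync <- synchrony_model(initial_sd = 0.05, dispersion_rate = 0.08,
                          period = 100)
  m <- periodic_model(phi = 0.3, kappa = 3)
  tt <- c(0, 30, 110, 250)
  tr <- mean_profile(m, sync, tt, nodes = 4096L)
  oracle <- vapply(tt, function(t1) {
    mu <- t1 / 100
    sd <- phase_sd(sync, t1)
    m$baseline + m$amplitude * stats::integrate(function(th)
      stats::dnorm(th, mu, sd) *
        exp(m$concentration * (cos(2 * pi * (th - m$peak_phase)) - 1)),
      mu - 8 * sd, mu + 8 * sd, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_lt(max(abs(tr - oracle)), 1e-6)
})

test_that("desynchronization strictly damps successive bulk cycle peaks", {
  p <- 100
  sync <- synchrony_model(initial_sd = 0.02, dispersion_rate = 0.1,
                          period = p)
  m <- gene_model("g", 0, 1, 0.3, 4,
                  programs = list(WT = "continue"))
  tt <- seq(0, 3 * p, by = 0.5)
  tr <- mean_profile(m, sync, tt)
  peaks <- vapply(0:2, function(k)
    max(tr[tt >= k * p & tt < (k + 1) * p]), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("invalid models are rejected", {
  expect_error(gene_model("g", -1, 1, 0, 1), "baseline")
  expect_error(gene_model("g", 1, 1, 1.2, 1), "peak_phase")
  expect_error(gene_model("g", 1, NaN, 0, 1), "finite")
  expect_error(gene_model("g", 1, 1, 0, 1, programs = list(WT = "explode")),
               "unknown program")
  expect_error(synchrony_model(period = -5), "period")
  expect_error(synchrony_model(bud_phase = 1), "bud_phase")
})

test_that("arrest programs produce the specified trajectories", {
  p <- 120
  sync <- perfect_sync(period = p)
  thr <- list(WT = "continue", CDK_ON = "repress_after_first_peak",
              X_OFF = "off", X_HI = "persistent_high",
              X_ONE = "one_cycle_then_repress")
  m <- gene_model("g", 0.5, 4, 0.5, 6, programs = thr)
  tt <- seq(0, 360, by = 1)
  expect_equal(apply_arrest_program(m, "X_OFF", sync, tt),
               rep(0.5, length(tt)))
  # persistent_high plateaus at b + a after the first peak
  hi <- apply_arrest_program(m, "X_HI", sync, tt)
  expect_equal(hi[tt > 0.5 * p], rep(4.5, sum(tt > 0.5 * p)))
  # repress_after_first_peak departs from continue only past
  # t1 = (phi - theta0 + 0.25) * p = 90 and decays toward b
  cont <- apply_arrest_program(m, "WT", sync, tt)
  rep1 <- apply_arrest_program(m, "CDK_ON", sync, tt)
  div <- tt[which(abs(cont - rep1) > 1e-9)[1]]
  expect_gt(div, 90)
  expect_lt(div, 95)
  expect_lt(abs(rep1[length(tt)] - 0.5), 0.05)
  # one_cycle_then_repress diverges one full period later
  one <- apply_arrest_program(m, "X_ONE", sync, tt)
  div2 <- tt[which(abs(cont - one) > 1e-9)[1]]
  expect_gt(div2, 90 + p)
  expect_error(apply_arrest_program(m, "NOPE", sync, tt), "no program")
})

test_that("simulate_experiment: determinism, noiseless limit, noise CV", {
  sync <- default_sync()
  des0 <- experiment_design("CDK_ON", noise_cv = 0, seed = 11)
  models <- list(periodic_model("g1", program = "off"), flat_model("g2"))
  m <- simulate_experiment(models, sync, des0)
  # noiseless off/flat rows are constant at baseline
  expect_equal(unname(m$values["g1", ]), rep(0.5, 19))
  expect_equal(unname(m$values["g2", ]), rep(2, 19))
  # same seed twice -> identical matrices
  des1 <- experiment_design("WT", noise_cv = 0.1, seed = 42)
  a <- simulate_experiment(models, sync, des1)
  b <- simulate_experiment(models, sync, des1)
  expect_identical(a$values, b$values)
  # different seed differs
  des2 <- experiment_design("WT", noise_cv = 0.1, seed = 43)
  expect_false(identical(a$values,
                         simulate_experiment(models, sync, des2)$values))
  # duplicate ids rejected
  expect_error(simulate_experiment(list(flat_model("x"), flat_model("x")),
                                   sync, des1), "duplicate")
})

test_that("lognormal noise has the configured CV", {
  sync <- default_sync()
  models <- lapply(1:300, function(i) flat_model(sprintf("g%03d", i), b = 5))
  des <- experiment_design("WT", noise_cv = 0.1, seed = 9)
  m <- simulate_experiment(models, sync, des)
  row_cv <- apply(m$values, 1, function(r) sd(r) / mean(r))
  expect_lt(abs(median(row_cv) - 0.1) / 0.1, 0.2)
  expect_true(all(m$values >= 0))
})

test_that("budding curves: degenerate step, start, symmetry, monotonicity", {
  # sigma -> 0: step at t = theta_bud * p = 30, interpolated t50 exact
  sync <- perfect_sync(period = 120, bud = 0.25)
  des <- experiment_design("CDK_ON", dt = 20, total_time = 300)
  b <- simulate_budding(sync, des)
  expect_equal(t50_budded(b), 30)
  expect_equal(b$fraction_budded[1], 0)           # t=0, theta0 < theta_bud
  expect_true(all(diff(b$fraction_budded) >= 0))  # arrest: monotone
  # smooth case: 0.5 crossing where theta0 + t/p = theta_bud (Phi symmetry)
  sync2 <- synchrony_model(initial_sd = 0.05, dispersion_rate = 0.2,
                           period = 120, bud_phase = 0.25)
  des2 <- experiment_design("CDK_ON", dt = 1, total_time = 300)
  b2 <- simulate_budding(sync2, des2)
  expect_lt(abs(t50_budded(b2) - 30), 1)
  # WT curve comes back down after division
  desw <- experiment_design("WT", dt = 5, total_time = 300)
  bw <- simulate_budding(synchrony_model(period = 100), desw)
  expect_lt(min(bw$fraction_budded[bw$times > 100 & bw$times < 140]), 0.5)
})

test_that("scenario generator draws the configured panel", {
  models <- scenario_gene_models(100, seed = 5)
  regs <- vapply(models, function(m) m$regulon, character(1))
  expect_equal(unname(table(regs)[c("SBF", "MBF", "SFF", "SWI5_ACE2",
                                    "OTHER")]),
               table(regs)[c("SBF", "MBF", "SFF", "SWI5_ACE2", "OTHER")],
               ignore_attr = TRUE)
  expect_equal(sum(regs == "OTHER"), 30)
  expect_true(all(vapply(models, function(m)
    m$regulon != "OTHER" || m$amplitude == 0, logical(1))))
  # deterministic given seed
  again <- scenario_gene_models(100, seed = 5)
  expect_identical(models, again)
})
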