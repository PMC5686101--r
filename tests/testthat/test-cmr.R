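test_that("sweep grids ascend through the decades", {
  g <- coarse_grid()
  expect_equal(g[1], 1e-8)
  expect_equal(g[length(g)], 1e-2)
  expect_true(all(diff(g) > 0))
  expect_length(g, 9 * 6 + 1) # d x 10^-e up to the 1e-2 cap
  f <- fine_grid(4)
  expect_equal(f[1], 1e-4)
  expect_equal(f[length(f)], 9.9e-4)
  expect_equal(diff(f)[1], 1e-5, tolerance = 1e-9)
  expect_equal(decade_of(c(3e-4, 1e-4, 9.9e-4, 1e-8)), c(4L, 4L, 4L, 8L))
})

test_that("early advance can never flip the accept decision at a rate", {
  for (n in c(7, 19, 20, 99, 100, 2000)) {
    keeper <- floor(0.05 * n) + 1
    loss <- ceiling(0.95 * n)
    # once `keeper` runs keep peak 0, at most n - keeper can lose it
    expect_lt(n - keeper, loss)
    # one keeper fewer still allows the rate to pass
    expect_gte(n - (keeper - 1), loss)
  }
})

test_that("run_batch counts losses and advances early at sub-CMR rates", {
  land <- make_landscape(L = 30, seed = 1)
  cfg <- run_config(land, 10, max_generations = 150, seed = 5)
  one <- run_batch(0.5, cfg, n_runs = 1)
  expect_true(one$runs_lost %in% 0:1)

  # far above the CMR: every run loses
  b_hi <- run_batch(0.5, cfg, n_runs = 20)
  expect_equal(b_hi$runs_lost, 20)
  expect_true(b_hi$reached_cmr)
  expect_false(b_hi$early_advanced)

  # no mutation: the batch is abandoned after floor(0.05*20)+1 = 2 keepers
  b_lo <- run_batch(0, cfg, n_runs = 20)
  expect_true(b_lo$early_advanced)
  expect_equal(b_lo$runs_kept, 2)
  expect_equal(b_lo$runs_total, 2)
  expect_false(b_lo$reached_cmr)
})

test_that("disabling early advance does not change the decision", {
  land <- make_landscape(L = 30, seed = 2)
  cfg <- run_config(land, 10, max_generations = 300, seed = 9)
  seeds <- derive_seeds(7, 1, 20)[1, ]
  for (rate in c(2e-3, 4e-3)) { # transition region at this scale
    with_ea <- run_batch(rate, cfg, 20, seeds)
    without <- run_batch(rate, cfg, 20, seeds, keeper_threshold = 21)
    expect_equal(with_ea$reached_cmr, without$reached_cmr)
  }
})

test_that("coarse_sweep brackets the decade of a step-function stub", {
  cs <- coarse_sweep(fake_cfg, n_runs = 100, runner = step_stub(3e-4))
  expect_true(cs$found)
  expect_equal(cs$rate, 3e-4)
  expect_equal(cs$decade, 4L)

  cs0 <- coarse_sweep(fake_cfg, n_runs = 100, runner = step_stub(0))
  expect_equal(cs0$rate, 1e-8)
  expect_equal(cs0$decade, 8L)

  cs_never <- coarse_sweep(fake_cfg, n_runs = 100, runner = step_stub(Inf))
  expect_false(cs_never$found)
  expect_true(is.na(cs_never$rate))
  expect_equal(nrow(cs_never$results), length(coarse_grid()))
})

test_that("fine_sweep pinpoints a deterministic threshold exactly", {
  thr <- fine_grid(4)[14] # 2.3e-4
  est <- fine_sweep(fake_cfg, decade = 4L, n_batches = 20,
                    batch_size = 100, runner = step_stub(thr))
  expect_s3_class(est, "cmr_estimate")
  expect_equal(est$batch_cmrs, rep(thr, 20))
  expect_equal(est$mean, thr)
  expect_equal(est$sd, 0)
  expect_equal(unname(est$ci95), c(thr, thr))
})

test_that("fine_sweep escalates decades and censors unreachable batches", {
  thr <- fine_grid(3)[25] # above decade 4: forces escalation
  est <- fine_sweep(fake_cfg, decade = 4L, n_batches = 5,
                    batch_size = 100, runner = step_stub(thr))
  expect_equal(est$batch_cmrs, rep(thr, 5))
  est_never <- fine_sweep(fake_cfg, decade = 4L, n_batches = 3,
                          batch_size = 100, runner = step_stub(Inf))
  expect_equal(est_never$n_censored, 3)
  expect_true(all(is.na(cmr_values(est_never))))
  expect_equal(cmr_values(est_never, "grid_top"), rep(1e-2, 3))
})

test_that("fine_sweep recovers the 95%-loss rate of a logistic stub", {
  slope <- 8
  mid <- -3.2
  target <- 10^(mid + stats::qlogis(0.95) / slope) # rate with p = 0.95
  set.seed(77)
  est <- fine_sweep(fake_cfg, decade = decade_of(target), n_batches = 20,
                    batch_size = 100, runner = logistic_stub(mid, slope))
  expect_equal(est$n_censored, 0)
  # batch CMRs concentrate near the 95% point of the loss curve
  expect_lt(abs(log10(est$mean) - log10(target)), 0.15)
})

test_that("confidence intervals match the closed-form t-interval", {
  set.seed(4)
  vals <- round(stats::rnorm(20, 3e-4, 4e-5), 8)
  est <- cmrsim:::new_cmr_estimate(vals, batch_size = 100,
                                   protocol = "fine")
  tt <- stats::t.test(vals)
  expect_equal(unname(est$ci95), unname(tt$conf.int[1:2]),
               tolerance = 1e-12)
  expect_equal(est$mean, mean(vals))
  g <- glance(est)
  expect_equal(g$ci_low, est$ci95[["low"]])
  td <- tidy(est)
  expect_equal(nrow(td), 20)
  expect_false(any(td$censored))
})

test_that("the batch CMR shifts with the loss curve", {
  est_hi <- estimate_cmr(fake_cfg, n_batches = 5, batch_size = 100,
                         protocol = "coarse", runner = step_stub(3e-4))
  est_lo <- estimate_cmr(fake_cfg, n_batches = 5, batch_size = 100,
                         protocol = "coarse", runner = step_stub(1e-5))
  expect_gt(est_hi$mean, est_lo$mean)
  set.seed(12)
  est_s_hi <- estimate_cmr(fake_cfg, 5, 100, protocol = "coarse",
                           runner = logistic_stub(-3.2, 8))
  est_s_lo <- estimate_cmr(fake_cfg, 5, 100, protocol = "coarse",
                           runner = logistic_stub(-4.2, 8))
  expect_gt(est_s_hi$mean, est_s_lo$mean)
})

test_that("the full protocol chains the coarse and fine sweeps", {
  thr <- fine_grid(4)[14]
  est <- estimate_cmr(fake_cfg, n_batches = 6, batch_size = 100,
                      protocol = "fine", runner = step_stub(thr))
  expect_equal(est$batch_cmrs, rep(thr, 6))
  est_nf <- estimate_cmr(fake_cfg, n_batches = 4, batch_size = 100,
                         protocol = "fine", runner = step_stub(Inf))
  expect_equal(est_nf$n_censored, 4)
})

test_that("derived seeds are reproducible and distinct", {
  s1 <- derive_seeds(42, 4, 10)
  s2 <- derive_seeds(42, 4, 10)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0)
  expect_false(identical(derive_seeds(43, 4, 10), s1))
})
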