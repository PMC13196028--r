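make_manual_dataset <- function(times, od_mean, sd) {
  # dataset with exactly the requested per-time mean and SD (the SD is set
  # directly so extreme weight cases can be exercised at positive OD)
  d <- growth_dataset("100WT", 1, 0, od_mean[1], times,
                      cbind(od_mean, od_mean))
  d$od_sd <- sd
  d
}

test_that("weighted log residuals follow the floored-SD definition", {
  p <- default_model_params()
  tr <- simulate_lysis(p, initial_state(0.01, 0, 0.49), t_end = 10)
  # dataset equal to the model curve -> all residuals zero
  od <- approx(tr$time, tr$od, xout = 0:8)$y
  ds <- growth_dataset("100WT", 1, 0, 0.01, 0:8, cbind(od, od))
  expect_equal(weighted_log_residuals(ds, tr), rep(0, 9))

  # direct evaluation: ln(0.02/0.01) / 0.1
  ds2 <- make_manual_dataset(c(0, 1), c(0.02, 0.02), c(0.1, 0.1))
  tr2 <- structure(tibble::tibble(time = c(0, 1), od = c(0.01, 0.01)),
                   class = c("lysis_trajectory", class(tibble::tibble())))
  r <- weighted_log_residuals(ds2, tr2)
  expect_equal(r, rep(log(2) / 0.1, 2), tolerance = 1e-12)

  # SD below the floor is replaced by the floor
  ds3 <- make_manual_dataset(c(0, 1), c(0.02, 0.02), c(1e-4, 1e-4))
  r3 <- weighted_log_residuals(ds3, tr2)
  expect_equal(r3, rep(log(2) / 1e-3, 2), tolerance = 1e-12)

  expect_error(weighted_log_residuals(
    growth_dataset("100WT", 1, 0, 0.01, c(0, 20), cbind(c(1, 1), c(1, 1))),
    tr2), "span")
})

test_that("halving all SDs doubles residuals and quadruples RSS", {
  times <- 0:5
  od_mean <- 0.01 * exp(0.5 * times)
  tr <- structure(tibble::tibble(time = times, od = od_mean * 1.1),
                  class = c("lysis_trajectory", class(tibble::tibble())))
  sd1 <- rep(0.08, 6)
  d1 <- make_manual_dataset(times, od_mean, sd1)
  d2 <- make_manual_dataset(times, od_mean, sd1 / 2)
  r1 <- weighted_log_residuals(d1, tr)
  r2 <- weighted_log_residuals(d2, tr)
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
  expect_equal(sum(r2^2), 4 * sum(r1^2), tolerance = 1e-10)
})

test_that("fit diagnostics use the known-variance penalized forms", {
  f <- structure(list(stage = 1L, estimates = c(a = 1, b = 2),
                      residuals = rep(0, 10), n_obs = 10L, n_params = 2L),
                 class = "lysis_fit")
  d <- fit_diagnostics(f)
  expect_equal(unname(d), c(0, 4, 2 * log(10)))
  # an extra parameter that leaves RSS unchanged costs exactly 2 AIC units
  f3 <- f; f3$n_params <- 3L
  expect_equal(fit_diagnostics(f3)[["aic"]] - d[["aic"]], 2)
  # BIC penalty exceeds AIC's once n > e^2
  expect_gt(fit_diagnostics(f3)[["bic"]] - d[["bic"]], 2)
})

test_that("stage 1 recovers glucose kinetics from noiseless data", {
  p <- model_params(0.7, 0.01, 1, 0.08, delta = 0.6, k = 10, epsilon = 0.3)
  ds <- generate_batch_dataset(p, "100WT", 1, 0, 0.01,
                               batch_noise_model(od_cv = 0, t_end = 12),
                               seed = 1)
  s1 <- fit_stage1(ds, fast_cfg())
  expect_lt(rel_err_pct(s1$estimates[["mu_g_max"]], 0.7), 1)
  expect_lt(rel_err_pct(s1$estimates[["K_S_g"]], 0.01), 1)

  # determinism: identical data -> identical estimates
  s1b <- fit_stage1(ds, fast_cfg())
  expect_identical(s1$estimates, s1b$estimates)

  # flat OD series: growth rate pinned at (effectively) zero
  flat <- growth_dataset("100WT", 1, 0, 0.01, 0:8,
                         matrix(0.01, 9, 3))
  sf <- fit_stage1(flat, fast_cfg())
  expect_lt(sf$estimates[["mu_g_max"]], 0.01)

  mixed <- generate_batch_dataset(p, "19WT-81TS", 0.19, 0.81, 0.01,
                                  batch_noise_model(od_cv = 0), seed = 1)
  expect_error(fit_stage1(mixed), "WT-only")
})

test_that("stage 2 recovers lysis rate and chain length", {
  p <- model_params(0.6, 0.01, 1, 0.08, delta = 0.9, k = 6, epsilon = 0.3)
  noise0 <- batch_noise_model(od_cv = 0)
  wt <- generate_batch_dataset(p, "100WT", 1, 0, 0.01, noise0, seed = 1)
  ts <- generate_batch_dataset(p, "100TS", 0, 1, 0.01, noise0, seed = 2)
  cfg <- fast_cfg()
  s1 <- fit_stage1(wt, cfg)
  s2 <- fit_stage2(ts, s1, cfg = cfg)
  expect_equal(s2$estimates[["k"]], 6)
  expect_lt(rel_err_pct(s2$estimates[["delta"]], 0.9), 5)

  # the returned k attains the grid-minimal weighted RSS: independent
  # re-scan through the public residual interface
  C_g0 <- s1$fixed[["C_g0"]]
  early <- 1:4
  ts_early <- growth_dataset("100TS", 0, 1, 0.01, ts$times[early],
                             ts$replicates[early, ])
  rss_k <- vapply(1:15, function(k) {
    optimize(function(ld) {
      pk <- model_params(s1$estimates[["mu_g_max"]],
                         s1$estimates[["K_S_g"]], 0, 1,
                         delta = exp(ld), k = k, epsilon = 0)
      tr <- simulate_lysis(pk, initial_state(0, 0.01, C_g0),
                           times = seq(0, 3, by = 0.05))
      sum(weighted_log_residuals(ts_early, tr)^2)
    }, lower = log(1e-3), upper = log(10), tol = 1e-6)$objective
  }, numeric(1))
  expect_equal(which.min(rss_k), 6)

  # pure growth (no lysis in the data): delta pinned at its lower bound
  p0 <- model_params(0.6, 0.01, 0, 1, delta = 0, k = 1, epsilon = 0)
  ts0 <- generate_batch_dataset(p0, "100TS", 0, 1, 0.01, noise0, seed = 3)
  s20 <- fit_stage2(ts0, s1, cfg = cfg)
  expect_lt(s20$estimates[["delta"]], 2e-3)

  short <- growth_dataset("100TS", 0, 1, 0.01, 0:2,
                          ts$replicates[1:3, ])
  expect_error(fit_stage2(short, s1, cfg = cfg), "at least 4")
  expect_error(fit_stage2(wt, s1, cfg = cfg), "TS-only")
})

test_that("stage 3 recovers lysate parameters from mixed cultures", {
  p <- model_params(0.6, 0.01, 0.8, 0.05, delta = 0.6, k = 10,
                    epsilon = 0.4)
  suite <- generate_growth_curve_suite(p, batch_noise_model(od_cv = 0),
                                       seed = 5)
  cfg <- fast_cfg()
  s1 <- fit_stage1(suite[["100WT"]], cfg)
  s2 <- fit_stage2(suite[["100TS"]], s1, cfg = cfg)
  s3 <- fit_stage3(suite[c("73WT-27TS", "19WT-81TS")], s1, s2, cfg)
  expect_lt(rel_err_pct(s3$estimates[["mu_l_max"]], 0.8), 10)
  expect_lt(rel_err_pct(s3$estimates[["K_S_l"]], 0.05), 10)
  expect_lt(rel_err_pct(s3$estimates[["epsilon"]], 0.4), 10)

  # pooled residual bookkeeping: one residual per (mix, time) point
  expect_equal(s3$n_obs, length(suite[["73WT-27TS"]]$times) +
                 length(suite[["19WT-81TS"]]$times))

  # estimates respect the configured bounds
  td <- tidy(s3)
  expect_true(all(td$estimate >= td$lower_bound - 1e-12 &
                    td$estimate <= td$upper_bound + 1e-12))

  expect_error(fit_stage3(suite["100WT"], s1, s2, cfg), "mixed")
})

test_that("recycling-free data drive epsilon to its lower bound", {
  p0 <- model_params(0.6, 0.01, 1, 0.08, delta = 0.6, k = 10, epsilon = 0)
  suite <- generate_growth_curve_suite(p0, batch_noise_model(od_cv = 0),
                                       seed = 8)
  cfg <- fast_cfg()
  s1 <- fit_stage1(suite[["100WT"]], cfg)
  s2 <- fit_stage2(suite[["100TS"]], s1, cfg = cfg)
  s3 <- fit_stage3(suite[c("73WT-27TS", "19WT-81TS")], s1, s2, cfg)
  expect_lt(s3$estimates[["epsilon"]], 0.01)
})

test_that("the three-stage pipeline is ordered, deterministic and validated", {
  ds <- fit_suite(od_cv = 0.05, seed = 3)
  cfg <- fast_cfg()
  fit1 <- run_three_stage_fit(ds, cfg)
  fit2 <- run_three_stage_fit(ds, cfg)
  expect_identical(fit1$table, fit2$table)

  # frozen-parameter contract: stage 3 carries stage-1/2 values unchanged
  expect_identical(fit1$stage3$fixed[["delta"]],
                   fit1$stage2$estimates[["delta"]])
  expect_identical(fit1$stage3$fixed[["mu_g_max"]],
                   fit1$stage1$estimates[["mu_g_max"]])

  expect_error(run_three_stage_fit(ds[c("100WT", "73WT-27TS")], cfg),
               "stage 2")
  expect_error(run_three_stage_fit(ds[c("100TS", "73WT-27TS")], cfg),
               "stage 1")
  expect_error(run_three_stage_fit(ds[c("100WT", "100TS")], cfg),
               "stage 3")
})

test_that("normalized delta biomass implements the compensation metric", {
  s <- tibble::tibble(time = 0:5, od = c(1, 2, 3, 4, 5, 6))
  expect_equal(normalized_delta_biomass(s, s)$delta_biomass, rep(0, 6))
  s2 <- dplyr::mutate(s, od = 2 * od)
  expect_equal(normalized_delta_biomass(s2, s)$delta_biomass, rep(1, 6))
  # 19% inoculum against the full-inoculum control
  s3 <- dplyr::mutate(s, od = 0.19 * od)
  expect_equal(normalized_delta_biomass(s3, s)$delta_biomass[1], -0.81)
  expect_error(normalized_delta_biomass(
    s, tibble::tibble(time = 0:5, od = c(0, 1, 2, 3, 4, 5))), "nonzero")
})

test_that("bootstrap CIs are seeded, degenerate-safe and level-monotone", {
  cfg <- fast_cfg()
  # identical replicates: resampling changes nothing -> zero-width CIs
  ds0 <- fit_suite(od_cv = 0, seed = 1)
  bs0 <- bootstrap_cis(ds0, cfg, n_boot = 4, seed = 42)
  point <- setNames(bs0$point$table$estimate, bs0$point$table$parameter)
  for (i in seq_len(nrow(bs0$ci95))) {
    pr <- bs0$ci95$parameter[i]
    expect_equal(bs0$ci95$lower[i], bs0$ci95$upper[i], tolerance = 1e-10)
    expect_equal(bs0$ci95$lower[i], unname(point[pr]), tolerance = 1e-8)
  }

  ds <- fit_suite(od_cv = 0.05, seed = 13)
  bs1 <- bootstrap_cis(ds, cfg, n_boot = 8, seed = 7)
  bs2 <- bootstrap_cis(ds, cfg, n_boot = 8, seed = 7)
  expect_identical(bs1$ci95, bs2$ci95)

  ci90 <- boot_ci(bs1, 0.90)
  ci95 <- boot_ci(bs1, 0.95)
  m <- dplyr::left_join(ci90, ci95, by = "parameter",
                        suffix = c("_90", "_95"))
  expect_true(all(m$lower_90 >= m$lower_95 - 1e-12))
  expect_true(all(m$upper_90 <= m$upper_95 + 1e-12))

  expect_error(bootstrap_cis(ds, cfg, n_boot = 0), "n_boot")
})
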