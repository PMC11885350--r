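boot_fixture <- function(seed = 61, tau = 0.5, N = 15, n = 6, H = 24) {
  truth <- small_truth(N = N, n_range = c(n, n), H = H, seed = seed)
  sim <- simulate_dataset(truth)
  cfg <- small_config(tau = tau, L = 5, D = 4, elf_lam = 0.05)
  sm <- c(alpha = 0.5, beta_s = 5, beta_t = 5, u = 1)
  fit <- fq_fit(sim$clean, cfg, smoothing = sm)
  tt <- seq(min(sim$clean$t), max(sim$clean$t), length.out = 5)
  tgt <- target_spec("quantile_curve", X_A = colMeans(sim$clean$curves),
                     t_eval = tt)
  list(data = sim$clean, cfg = cfg, fit = fit, target = tgt, truth = sim$truth)
}

test_that("block bootstrap: definition, degeneracy, reproducibility", {
  fx <- boot_fixture()
  bb <- block_bootstrap(fx$data, fx$cfg, fx$target, B = 12, seed = 5,
                        fit = fx$fit)
  # sd_boot is the textbook column SD of the stored replicates
  expect_equal(bb$sd_boot, apply(bb$replicates, 2, sd))
  expect_true(all(bb$sd_boot >= 0))
  expect_identical(nrow(bb$replicates) + bb$n_failed, 12L)

  # identical seed + inputs -> bit-identical replicate matrix
  bb2 <- block_bootstrap(fx$data, fx$cfg, fx$target, B = 12, seed = 5,
                         fit = fx$fit)
  expect_identical(bb$replicates, bb2$replicates)
  bb3 <- block_bootstrap(fx$data, fx$cfg, fx$target, B = 12, seed = 6,
                         fit = fx$fit)
  expect_false(identical(bb$replicates, bb3$replicates))

  # constant responses: the refit is the same whatever the resample
  dcst <- fq_dataset(fx$data$subject_id, fx$data$t,
                     rep(1.7, fx$data$M), fx$data$curves, fx$data$grid)
  fcst <- fq_fit(dcst, fx$cfg, smoothing = c(alpha = 1, beta_s = 1,
                                             beta_t = 1, u = 1))
  bcst <- block_bootstrap(dcst, fx$cfg, fx$target, B = 8, seed = 2,
                          fit = fcst)
  expect_lt(max(bcst$sd_boot), 1e-6)
})

test_that("block resamples carry each selected subject's rows verbatim", {
  fx <- boot_fixture()
  rows_by_subj <- split(seq_len(fx$data$M), fx$data$subject)
  subjects <- c(3L, 3L, 9L, 1L)
  rs <- funqr:::resample_rows(rows_by_subj, subjects)
  expect_identical(rs$rows,
                   c(rows_by_subj[[3]], rows_by_subj[[3]],
                     rows_by_subj[[9]], rows_by_subj[[1]]))
  expect_identical(rs$subject, rep(1:4, each = length(rows_by_subj[[1]])))
})

test_that("wild weights have a zero conditional tau-quantile", {
  for (tau in c(0.1, 0.25, 0.5)) {
    set.seed(71)
    w <- funqr:::wild_weights(1e5, tau)
    expect_true(all(w %in% c(-2 * tau, 2 * (1 - tau))))
    expect_lt(abs(mean(w < 0) - tau), 3 * sqrt(tau * (1 - tau) / 1e5))
    # applied to any positive residual magnitude the error stays calibrated
    r <- abs(rnorm(1e5))
    expect_lt(abs(mean(w * r < 0) - tau), 3 * sqrt(tau * (1 - tau) / 1e5))
  }
})

test_that("wild bootstrap: bias formula, fixed covariates, reproducibility", {
  fx <- boot_fixture()
  curves_before <- fx$data$curves + 0
  wb <- wild_bootstrap(fx$data, fx$fit, fx$target, B = 12, seed = 9)
  est <- predict_quantile(fx$fit, fx$target$X_A, fx$target$t_eval)$estimate
  expect_equal(wb$bias_boot, colMeans(wb$replicates) - est)
  expect_identical(fx$data$curves, curves_before)
  wb2 <- wild_bootstrap(fx$data, fx$fit, fx$target, B = 12, seed = 9)
  expect_identical(wb$replicates, wb2$replicates)

  # all replicate targets equal to the estimate -> zero bias (constant y)
  dcst <- fq_dataset(fx$data$subject_id, fx$data$t,
                     rep(0.4, fx$data$M), fx$data$curves, fx$data$grid)
  fcst <- fq_fit(dcst, fx$cfg, smoothing = c(alpha = 1, beta_s = 1,
                                             beta_t = 1, u = 1))
  wcst <- wild_bootstrap(dcst, fcst, fx$target, B = 6, seed = 3)
  expect_lt(max(abs(wcst$bias_boot)), 1e-5)
})

test_that("confidence interval arithmetic follows the normal form", {
  ci <- confidence_interval(1.0, 0, 1, alpha = 0.05)
  expect_equal(ci$lo, 1 - 1.959964, tolerance = 1e-6)
  expect_equal(ci$hi, 1 + 1.959964, tolerance = 1e-6)
  ci_b <- confidence_interval(1.0, 0.3, 1, alpha = 0.05)
  expect_equal(ci_b$lo, ci$lo - 0.3)
  expect_equal(ci_b$hi, ci$hi - 0.3)
  ci0 <- confidence_interval(c(2, 3), c(0.1, 0.2), c(0, 0))
  expect_equal(ci0$lo, c(1.9, 2.8))
  expect_equal(ci0$hi, c(1.9, 2.8))
  expect_error(confidence_interval(1, 0, -1), "non-negative")
  expect_error(confidence_interval(1, 0, 1, alpha = 2), "alpha")
})

test_that("pipeline produces finite intervals and honours a null direction", {
  fx <- boot_fixture(N = 12, n = 5, H = 16)
  rep <- run_inference_pipeline(fx$data, fx$cfg, B = 8, seed = 3,
                                pve = 0.99)
  expect_true(all(is.finite(rep$table$lo)))
  expect_true(all(is.finite(rep$table$hi)))
  expect_true(all(rep$table$lo <= rep$table$hi))

  # delta-X = 0: the difference target is identically zero, CI contains 0
  tt <- sort(unique(fx$data$t))
  X <- colMeans(fx$data$curves)
  tgt0 <- target_spec("quantile_difference", X_A = X, X_B = X, t_eval = tt)
  rep0 <- run_inference_pipeline(fx$data, fx$cfg, target = tgt0, B = 6,
                                 seed = 4, pve = NULL, smoothing =
                                   c(alpha = 0.5, beta_s = 5, beta_t = 5,
                                     u = 1))
  expect_true(all(rep0$table$lo <= 1e-10 & rep0$table$hi >= -1e-10))
})
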