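test_that("design assembly: integral column, incidence, nested-loop oracle", {
  truth <- small_truth(N = 6, n_range = c(5, 5), H = 24, seed = 13)
  sim <- simulate_dataset(truth)
  d <- sim$clean

  # scalar variant with X == 1 over a 24-hour domain: column of 24s
  d1 <- fq_dataset(d$subject_id, d$t, d$y,
                   matrix(1, d$M, 24), d$grid)
  des1 <- assemble_design(d1, small_config(variant = "scalar", L = 4))
  expect_equal(des1$Zs[, 5], rep(24, d$M), tolerance = 1e-10)

  # subject incidence: row sums 1, column sums n_i; the centered block is
  # the incidence matrix times the contrast
  des <- assemble_design(d, small_config(L = 5, D = 4))
  inc <- outer(d$subject, seq_len(d$N), `==`) * 1
  expect_equal(rowSums(inc), rep(1, d$M))
  expect_equal(colSums(inc), as.numeric(d$n_i))
  expect_equal(des$Zu, inc %*% des$C, ignore_attr = TRUE)

  # full-variant linear predictor equals explicit nested loops
  cfg <- small_config(L = 5, D = 4)
  set.seed(8)
  a <- rnorm(5); delta <- matrix(rnorm(4 * 5), 4, 5); z <- rnorm(d$N - 1)
  eta <- as.numeric(des$Zs %*% c(a, as.vector(delta)) + des$Zu %*% z)
  u <- as.numeric(des$C %*% z)
  expect_equal(eta, nested_loop_eta(d, cfg, a, delta, u),
               tolerance = 1e-10)
})

test_that("intercept-only fit recovers the empirical quantile", {
  set.seed(31)
  y <- rexp(201) - 0.3
  d <- fq_dataset(rep(1, 201), seq_len(201), y, matrix(0, 201, 12),
                  seq(0, 22, 2))
  for (tau in c(0.25, 0.5, 0.8)) {
    cfg <- fq_config(tau, variant = "scalar", L = 1,
                     elf_lam = 1e-4 * sd(y), s_domain = c(0, 24))
    f <- suppressWarnings(fq_fit(d, cfg, smoothing = c()))
    expect_true(f$converged)
    expect_lt(abs(f$a - as.numeric(quantile(y, tau))), 1e-3 * sd(y))
  }
})

test_that("constant responses give a flat fit with no subject effects", {
  truth <- small_truth(N = 8, n_range = c(5, 5), H = 24, seed = 3)
  sim <- simulate_dataset(truth)
  d <- fq_dataset(sim$clean$subject_id, sim$clean$t,
                  rep(2.5, sim$clean$M), sim$clean$curves, sim$clean$grid)
  cfg <- small_config(L = 5, D = 4, elf_lam = 1e-3)
  f <- fq_fit(d, cfg, smoothing = c(alpha = 1, beta_s = 1, beta_t = 1,
                                    u = 1))
  tt <- seq(min(d$t), max(d$t), length.out = 20)
  expect_equal(alpha_curve(f, tt), rep(2.5, 20), tolerance = 1e-4)
  expect_lt(max(abs(f$delta)), 1e-4)
  expect_lt(max(abs(f$u)), 1e-4)
  expect_lt(abs(mean(f$u)), 1e-8)
})

test_that("fits are equivariant under a constant shift of the response", {
  truth <- small_truth(N = 12, n_range = c(6, 6), H = 24, seed = 17)
  sim <- simulate_dataset(truth)
  d <- sim$clean
  cfg <- small_config(tau = 0.3, L = 5, D = 4, elf_lam = 0.05)
  sm <- c(alpha = 0.5, beta_s = 5, beta_t = 5, u = 1)
  f1 <- fq_fit(d, cfg, smoothing = sm)
  d2 <- fq_dataset(d$subject_id, d$t, d$y + 10, d$curves, d$grid)
  f2 <- fq_fit(d2, cfg, smoothing = sm)
  tt <- seq(min(d$t), max(d$t), length.out = 15)
  expect_equal(alpha_curve(f2, tt), alpha_curve(f1, tt) + 10,
               tolerance = 1e-4)
  expect_equal(f2$delta, f1$delta, tolerance = 1e-4)
  expect_equal(f2$u, f1$u, tolerance = 1e-4)
})

test_that("residual signs are calibrated on unpenalized-intercept fits", {
  set.seed(5)
  n <- 400
  t <- runif(n, 1, 20)
  y <- sin(t / 3) + rnorm(n) * 0.6
  d <- fq_dataset(rep(1, n), t, y, matrix(0, n, 12), seq(0, 22, 2))
  for (tau in c(0.2, 0.5)) {
    cfg <- fq_config(tau, variant = "scalar", L = 6, elf_lam = 0.01,
                     s_domain = c(0, 24))
    f <- fq_fit(d, cfg, smoothing = c(alpha = 0.01))
    band <- max(0.02, 3 * sqrt(tau * (1 - tau) / n))
    expect_lt(abs(mean(f$residuals < 0) - tau), band)
  }
})

test_that("coefficients stabilize as the ELF smoothing shrinks", {
  set.seed(19)
  n <- 300
  x <- runif(n, -1, 1)
  y <- 1 + x + rnorm(n) * (1 + 0.5 * x)
  d <- fq_dataset(rep(1, n), seq_len(n), y, matrix(x, n, 12),
                  seq(0, 22, 2))
  lams <- 0.2 / 2^(0:3)
  coefs <- sapply(lams, function(lam) {
    cfg <- fq_config(0.3, variant = "scalar", L = 1, elf_lam = lam,
                     s_domain = c(0, 24))
    f <- fq_fit(d, cfg, smoothing = c())
    c(f$a, f$delta)
  })
  moves <- sqrt(colSums((coefs[, -1] - coefs[, -ncol(coefs)])^2))
  expect_lt(moves[3], moves[1])
})
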