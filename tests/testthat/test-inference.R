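fit_fixture <- function(seed = 37, tau = 0.5) {
  truth <- small_truth(N = 12, n_range = c(6, 6), H = 24, seed = seed)
  sim <- simulate_dataset(truth)
  cfg <- small_config(tau = tau, L = 5, D = 4, elf_lam = 0.05)
  list(fit = fq_fit(sim$clean, cfg,
                    smoothing = c(alpha = 0.5, beta_s = 5, beta_t = 5,
                                  u = 1)),
       data = sim$clean, truth = sim$truth)
}

test_that("predicted quantile curve is the linear functional of the fit", {
  fx <- fit_fixture()
  f <- fx$fit
  tt <- seq(min(fx$data$t), max(fx$data$t), length.out = 11)
  H <- length(fx$data$grid)

  # X == 0: prediction reduces to the smooth intercept
  p0 <- predict_quantile(f, rep(0, H), tt)
  expect_equal(p0$estimate, alpha_curve(f, tt), tolerance = 1e-12)
  expect_true(all(p0$model_se >= 0))

  # linearity: alpha counted once
  XA <- fx$data$curves[3, ]; XB <- fx$data$curves[20, ]
  pA <- predict_quantile(f, XA, tt)$estimate
  pB <- predict_quantile(f, XB, tt)$estimate
  pAB <- predict_quantile(f, XA + XB, tt)$estimate
  expect_equal(pAB, pA + pB - alpha_curve(f, tt), tolerance = 1e-10)

  # nested-loop evaluation of the double basis sum
  xi <- as.numeric(functional_scores(matrix(XA, 1), fx$data$grid,
                                     f$config$beta_s_basis)$xi)
  psi_a <- build_basis(f$config$alpha_basis, tt)$values
  psi_b <- build_basis(f$config$beta_t_basis, tt)$values
  direct <- numeric(length(tt))
  for (k in seq_along(tt)) {
    v <- sum(psi_a[k, ] * f$a)
    for (l in seq_len(ncol(psi_b))) for (d in seq_along(xi))
      v <- v + f$delta[d, l] * psi_b[k, l] * xi[d]
    direct[k] <- v
  }
  expect_equal(predict_quantile(f, XA, tt)$estimate, direct,
               tolerance = 1e-10)

  expect_error(predict_quantile(f, rep(0, H + 1), tt), "grid")
  expect_error(predict_quantile(f, rep(0, H), max(fx$data$t) + 5),
               "t_eval")
})

test_that("quantile difference cancels the intercept and subject level", {
  fx <- fit_fixture()
  f <- fx$fit
  tt <- seq(min(fx$data$t), max(fx$data$t), length.out = 9)
  XA <- fx$data$curves[1, ]; XB <- fx$data$curves[10, ]

  expect_equal(quantile_difference(f, XA, XA, tt)$estimate,
               rep(0, length(tt)))
  dAB <- quantile_difference(f, XA, XB, tt)
  expect_equal(dAB$estimate,
               predict_quantile(f, XA, tt)$estimate -
                 predict_quantile(f, XB, tt)$estimate,
               tolerance = 1e-12)
  # antisymmetry and invariance to a common shift curve
  expect_equal(quantile_difference(f, XB, XA, tt)$estimate,
               -dAB$estimate, tolerance = 1e-12)
  g <- sin(fx$data$grid / 3)
  expect_equal(quantile_difference(f, XA + g, XB + g, tt)$estimate,
               dAB$estimate, tolerance = 1e-10)

  # constructed constant surface beta == c: difference for delta-X == 1
  # equals c times the domain length
  f2 <- f
  cdelta <- matrix(0.2, nrow(f$delta), ncol(f$delta))
  f2$delta <- cdelta
  f2$theta[f2$design$blocks$beta] <- as.vector(cdelta)
  d1 <- quantile_difference(f2, rep(1, length(fx$data$grid)),
                            rep(0, length(fx$data$grid)), tt)
  expect_equal(d1$estimate, rep(0.2 * 24, length(tt)), tolerance = 1e-8)
})

test_that("pointwise quantile curves match order statistics", {
  set.seed(51)
  curves <- matrix(rnorm(9 * 5), 9, 5)
  med <- pointwise_quantile_curves(curves, level = 0.5)
  expect_equal(med, apply(curves, 2, function(col) sort(col)[5]))

  one <- matrix(rep(c(1, 2, 3, 4, 5), each = 7), 7, 5)
  expect_equal(pointwise_quantile_curves(one, level = 0.23), c(1, 2, 3, 4, 5))

  big <- matrix(rnorm(1000 * 4), 1000, 4)
  q20 <- pointwise_quantile_curves(big, level = 0.2)
  expect_true(all(abs(q20 - qnorm(0.2)) < 0.1))

  expect_error(pointwise_quantile_curves(matrix(0, 0, 3), level = 0.5),
               "empty")
  expect_error(pointwise_quantile_curves(big, level = 1.5), "level")
})
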