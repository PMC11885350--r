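error_family <- function(name, scale) {
  switch(name,
    normal = list(r = function(n) stats::rnorm(n, sd = scale),
                  q = function(tau) stats::qnorm(tau, sd = scale)),
    t3 = list(r = function(n) scale * stats::rt(n, df = 3),
              q = function(tau) scale * stats::qt(tau, df = 3)),
    # shifted, standardized chi-square(3): mean zero, unit-ish scale, skewed
    chisq = list(r = function(n)
                   scale * (stats::rchisq(n, df = 3) - 3) / sqrt(6),
                 q = function(tau)
                   scale * (stats::qchisq(tau, df = 3) - 3) / sqrt(6)),
    stop("unknown error family: ", name))
}

default_covariate_model <- function(s_domain = c(0, 24)) {
  per <- diff(s_domain)
  nrm <- sqrt(per / 2)  # int cos^2(2 pi k s / per) ds = per / 2
  list(
    mean_fn = function(s) 20 + 3 * cos(2 * pi * (s - 15) / per),
    comp_fns = list(
      function(s) cos(2 * pi * s / per) / nrm,
      function(s) sin(2 * pi * s / per) / nrm,
      function(s) cos(4 * pi * s / per) / nrm),
    eigenvalues = c(4, 1, 0.25),
    noise_sd = 0.25)
}

#' Define a synthetic longitudinal functional truth
#'
#' Fixes every ingredient of the data-generating process: the smooth
#' intercept `alpha(t)`, the coefficient surface `beta(s, t)`, the subject
#' level distribution, the error family (with closed-form quantile
#' function, so the true conditional quantile is available as an oracle),
#' and the covariate process (cyclic mean curve plus Fourier-type principal
#' components with a given eigenvalue spectrum, observed with iid
#' measurement noise).
#'
#' Defaults emulate the structure of a sow lactation study: N = 225
#' subjects observed on 7 to 21 consecutive integer days, daily covariate
#' curves on a 24-hour grid sampled every five minutes (H = 288), an
#' intercept rising steeply over the first days before flattening, and a
#' negative covariate effect that strengthens over the observation period.
#'
#' @param N Number of subjects.
#' @param n_range Integer range of repeated measures per subject (each
#'   subject's count drawn uniformly).
#' @param H Grid points per curve.
#' @param t_domain,s_domain Longitudinal and within-day domains.
#' @param alpha_fn Function `t -> alpha(t)`.
#' @param beta_fn Function `(s, t) -> beta(s, t)` (vectorized in `s`).
#' @param sigma_u Standard deviation of the normal subject levels.
#' @param error Error family: `"normal"`, `"t3"` or `"chisq"` (skewed).
#' @param error_scale Scale of the error family.
#' @param covariate_model List with `mean_fn`, `comp_fns` (list of
#'   functions), `eigenvalues`, `noise_sd`; see
#'   `funqr:::default_covariate_model`.
#' @param seed Integer seed.
#' @return An object of class `"fq_truth"`.
#' @export
sim_truth <- function(N = 225L, n_range = c(7L, 21L), H = 288L,
                      t_domain = c(1, 21), s_domain = c(0, 24),
                      alpha_fn = function(t) 4 + 2 * tanh((t - 5) / 3),
                      beta_fn = function(s, t)
                        -0.04 * (t / 21) * (1 + cos(2 * pi * (s - 16) / 24)),
                      sigma_u = 0.5,
                      error = c("normal", "t3", "chisq"),
                      error_scale = 0.6,
                      covariate_model = NULL, seed = 1L) {
  error <- match.arg(error)
  stopifnot(N >= 1L, n_range[1] >= 1L, n_range[2] >= n_range[1], H >= 4L)
  structure(list(N = as.integer(N), n_range = as.integer(n_range),
                 H = as.integer(H), t_domain = t_domain,
                 s_domain = s_domain, alpha_fn = alpha_fn,
                 beta_fn = beta_fn, sigma_u = sigma_u, error = error,
                 error_scale = error_scale,
                 covariate_model = covariate_model %||%
                   default_covariate_model(s_domain),
                 seed = as.integer(seed)),
            class = "fq_truth")
}

# int beta(s, t) X(s) ds on a fine grid (10x the observation grid), one
# value per observation row. X_scores: observations x K component scores.
fine_integral <- function(truth, t_obs, X_scores, fine_mult = 10L) {
  Hf <- truth$H * fine_mult
  per <- diff(truth$s_domain)
  sf <- truth$s_domain[1] + per * (seq_len(Hf) - 1) / Hf
  wf <- per / Hf
  cm <- truth$covariate_model
  Xf <- matrix(cm$mean_fn(sf), nrow(X_scores), Hf, byrow = TRUE)
  for (k in seq_along(cm$comp_fns))
    Xf <- Xf + X_scores[, k] %o% cm$comp_fns[[k]](sf)
  vapply(seq_along(t_obs), function(i)
    sum(truth$beta_fn(sf, t_obs[i]) * Xf[i, ]) * wf, numeric(1))
}

#' Generate a synthetic longitudinal functional dataset
#'
#' Draws subject levels, covariate curves and responses according to the
#' truth object:
#' `Y_ij = alpha(t_ij) + int beta(s, t_ij) X_ij(s) ds + u_i + e_ij`, with
#' the integral computed by fine-grid quadrature (10x the observation
#' grid), and noisy covariate observations
#' `W_ij(s_h) = X_ij(s_h) + eps_ij,h`. Longitudinal times are consecutive
#' integer days starting at the left end of the t-domain.
#'
#' @param truth An [sim_truth()] object.
#' @param seed Optional seed overriding `truth$seed`.
#' @return A list with `noisy` (an [fq_dataset()] carrying the W curves),
#'   `clean` (the same dataset with the true X curves), and `truth` (with
#'   the realized subject levels in `$u`).
#' @export
simulate_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "fq_truth"))
  seed <- seed %||% truth$seed
  with_preserved_seed(seed, {
    N <- truth$N
    n_i <- if (truth$n_range[1] == truth$n_range[2])
      rep(truth$n_range[1], N) else
      sample(seq(truth$n_range[1], truth$n_range[2]), N, replace = TRUE)
    M <- sum(n_i)
    subj <- rep(seq_len(N), n_i)
    t_obs <- unlist(lapply(n_i, function(n)
      truth$t_domain[1] + seq_len(n) - 1), use.names = FALSE)
    u <- stats::rnorm(N, sd = truth$sigma_u)

    cm <- truth$covariate_model
    K <- length(cm$comp_fns)
    scores <- matrix(stats::rnorm(M * K), M, K) *
      rep(sqrt(cm$eigenvalues), each = M)
    per <- diff(truth$s_domain)
    grid <- truth$s_domain[1] + per * (seq_len(truth$H) - 1) / truth$H
    X <- matrix(cm$mean_fn(grid), M, truth$H, byrow = TRUE)
    for (k in seq_len(K)) X <- X + scores[, k] %o% cm$comp_fns[[k]](grid)
    W <- X + matrix(stats::rnorm(M * truth$H, sd = cm$noise_sd), M,
                    truth$H)

    fam <- error_family(truth$error, truth$error_scale)
    e <- fam$r(M)
    y <- truth$alpha_fn(t_obs) + fine_integral(truth, t_obs, scores) +
      u[subj] + e
    truth$u <- u
    list(noisy = fq_dataset(subj, t_obs, y, W, grid),
         clean = fq_dataset(subj, t_obs, y, X, grid),
         truth = truth)
  })
}

#' True conditional quantile under a synthetic truth
#'
#' The oracle for recovery tests:
#' `alpha(t) + int beta(s, t) X(s) ds + u + q_e(tau)`, with `q_e` the error
#' family's closed-form quantile function and the integral computed by
#' fine-grid quadrature.
#'
#' @param truth An [sim_truth()] object.
#' @param X Covariate curve: a function of `s`, or a numeric vector on the
#'   truth's observation grid (periodically interpolated to the fine grid).
#' @param t Evaluation time(s).
#' @param tau Quantile level.
#' @param u Subject level (default 0, the typical subject).
#' @return Numeric vector over `t`.
#' @export
true_quantile <- function(truth, X, t, tau, u = 0) {
  stopifnot(inherits(truth, "fq_truth"))
  check_tau(tau)
  per <- diff(truth$s_domain)
  Hf <- truth$H * 10L
  sf <- truth$s_domain[1] + per * (seq_len(Hf) - 1) / Hf
  wf <- per / Hf
  Xf <- if (is.function(X)) X(sf) else {
    grid <- truth$s_domain[1] + per * (seq_len(truth$H) - 1) / truth$H
    stats::spline(c(grid, grid[1] + per), c(X, X[1]), xout = sf,
                  method = "periodic")$y
  }
  fam <- error_family(truth$error, truth$error_scale)
  ints <- vapply(t, function(ti) sum(truth$beta_fn(sf, ti) * Xf) * wf,
                 numeric(1))
  truth$alpha_fn(t) + ints + u + fam$q(tau)
}
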