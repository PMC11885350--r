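# Two-point wild weights with P(w < 0) = tau, so the conditional
# tau-quantile of w * |r| is zero.
wild_weights <- function(n, tau) {
  ifelse(stats::runif(n) < tau, -2 * tau, 2 * (1 - tau))
}

# Row indices of a subject-block resample: all rows of each selected
# subject, kept verbatim and in order, with the relabelled subject index.
resample_rows <- function(rows_by_subj, subjects) {
  rows <- unlist(rows_by_subj[subjects], use.names = FALSE)
  list(rows = rows,
       subject = rep(seq_along(subjects), lengths(rows_by_subj[subjects])))
}

drop_failed <- function(reps, ok, B, scheme) {
  n_failed <- sum(!ok)
  if (n_failed == B) stop("all ", scheme, " bootstrap replicates failed")
  if (n_failed > 0.1 * B)
    stop(n_failed, " of ", B, " ", scheme,
         " bootstrap refits failed to converge (more than 10%)")
  if (n_failed > 0L)
    warning(n_failed, " of ", B, " ", scheme,
            " bootstrap refits dropped (non-convergence)")
  reps[ok, , drop = FALSE]
}

#' Subject-block bootstrap standard errors
#'
#' Resamples complete subjects with replacement: each replicate draws N
#' subjects, carries all their (response, covariate, time) rows verbatim
#' (relabelled to unique subject ids), refits the model and evaluates the
#' target. The per-time-point sample standard deviation over replicates
#' estimates the sampling variability of the target estimate under
#' within-subject dependence.
#'
#' Smoothing parameters are held fixed at the baseline fit's values by
#' default; `fix_smoothing = FALSE` re-selects them in every replicate
#' (considerably slower).
#'
#' @param data An [fq_dataset()] (already pre-smoothed if FPCA is used).
#' @param config An [fq_config()].
#' @param target A [target_spec()].
#' @param B Number of bootstrap replicates (at least 2).
#' @param seed Integer seed; identical seed and inputs give bit-identical
#'   replicate matrices.
#' @param fit Optional baseline [fq_fit()] (refitted here when `NULL`).
#' @param fix_smoothing Keep the baseline smoothing parameters (default
#'   TRUE).
#' @return A list of class `"fq_boot"` with `scheme = "block"`, the
#'   replicate matrix (successful replicates x length(t_eval)), `sd_boot`,
#'   `n_failed` and `seed`.
#' @export
block_bootstrap <- function(data, config, target, B, seed = 1L, fit = NULL,
                            fix_smoothing = TRUE) {
  B <- as.integer(B)
  stopifnot(B >= 2L, inherits(target, "fq_target"))
  if (is.null(fit)) fit <- fq_fit(data, config)
  design <- fit$design
  y <- data$y
  tau <- fit$config$tau
  ps <- ncol(design$Zs)
  G <- if (target$kind == "quantile_curve")
    target_design(fit, target$X_A, target$t_eval, include_alpha = TRUE)
  else
    target_design(fit, target$X_A - target$X_B, target$t_eval,
                  include_alpha = FALSE)
  rows_by_subj <- split(seq_len(data$M), data$subject)
  P <- make_penalty(design, as.list(fit$smoothing_params))
  reps <- matrix(NA_real_, B, length(target$t_eval))
  ok <- logical(B)
  with_preserved_seed(seed, {
    for (b in seq_len(B)) {
      subjects <- sample.int(data$N, data$N, replace = TRUE)
      rs <- resample_rows(rows_by_subj, subjects)
      rows <- rs$rows; newsubj <- rs$subject
      Zb <- make_zop(design$Zs[rows, , drop = FALSE], newsubj, design$C)
      Pb <- P
      if (!fix_smoothing) {
        db <- fq_dataset(newsubj, data$t[rows], y[rows],
                         data$curves[rows, , drop = FALSE], data$grid)
        lam_b <- select_smoothing(db, fit$config)
        des_b <- assemble_design(db, fit$config)
        Pb <- make_penalty(des_b, as.list(lam_b))
      }
      ft <- fit_inner(Zb, y[rows], Pb, tau, fit$elf_lam,
                      theta0 = fit$theta, maxit = fit$config$maxit,
                      tol = fit$config$tol)
      ok[b] <- ft$converged && all(is.finite(ft$theta))
      if (ok[b]) reps[b, ] <- as.numeric(G %*% ft$theta[seq_len(ps)])
    }
  })
  reps <- drop_failed(reps, ok, B, "block")
  structure(list(scheme = "block", replicates = reps,
                 sd_boot = apply(reps, 2L, stats::sd),
                 n_failed = B - nrow(reps), seed = seed,
                 t_eval = target$t_eval),
            class = "fq_boot")
}

#' Residual-term bootstrap bias estimate with resampled random effects
#'
#' Generates bootstrap responses under a distribution whose true target
#' value equals the baseline estimate, so the refitting bias can be
#' measured: for each replicate, subject levels `u*` are drawn with
#' replacement from the centered, reflated estimated intercepts, residual
#' terms with conditional tau-quantile zero are added, the model is refit
#' (covariates and times held exactly fixed, so the design is reused), and
#' the bias estimate is `mean_b(target_b) - target_hat`.
#'
#' Two error-regeneration schemes are offered; both guarantee the defining
#' property that the regenerated error's tau-quantile is zero:
#' * `"resample"` (default): errors are drawn with replacement from the
#'   fitted residuals centered at their empirical tau-quantile. This
#'   preserves the shape of the error distribution near the quantile, which
#'   is what the refitting bias depends on; it assumes the error
#'   distribution is exchangeable across observations.
#' * `"wild"`: errors are `w * |r|` with two-point weights
#'   `w in \{2(1 - tau), -2 tau\}`, `P(w = -2 tau) = tau`, the classical
#'   wild form that is robust to covariate-dependent error scale but
#'   replaces the error distribution by a two-atom one.
#'
#' @param data An [fq_dataset()] (the one the fit was computed on).
#' @param fit A converged baseline [fq_fit()].
#' @param target A [target_spec()].
#' @param B Number of replicates (at least 2).
#' @param seed Integer seed (bit-reproducible).
#' @param errors `"resample"` or `"wild"` (see Details).
#' @return A list of class `"fq_boot"` with `scheme = "wild"`, the
#'   replicate matrix, `bias_boot`, `n_failed` and `seed`.
#' @export
wild_bootstrap <- function(data, fit, target, B, seed = 1L,
                           errors = c("resample", "wild")) {
  B <- as.integer(B)
  errors <- match.arg(errors)
  stopifnot(B >= 2L, inherits(fit, "fq_fit"), inherits(target, "fq_target"))
  design <- fit$design
  tau <- fit$config$tau
  ps <- ncol(design$Zs)
  G <- if (target$kind == "quantile_curve")
    target_design(fit, target$X_A, target$t_eval, include_alpha = TRUE)
  else
    target_design(fit, target$X_A - target$X_B, target$t_eval,
                  include_alpha = FALSE)
  theta_hat <- as.numeric(G %*% fit$theta[seq_len(ps)])
  eta_s <- as.numeric(design$Zs %*% fit$theta[seq_len(ps)])
  # reflate the centered intercepts before resampling: penalized estimates
  # are shrunk, and under the EBLUP analogy E[u_hat^2] = (EDF_u/N) sigma_u^2,
  # so drawing from the raw u_hat would understate subject-level variance
  # and with it the penalization bias the scheme exists to estimate
  u_c <- fit$u - mean(fit$u)
  shrink <- max(fit$edf_u, 1) / data$N
  u_c <- u_c / sqrt(min(shrink, 1))
  absr <- abs(fit$residuals)
  r_c <- fit$residuals -
    as.numeric(stats::quantile(fit$residuals, tau, names = FALSE))
  Z <- make_zop(design$Zs, data$subject, design$C)
  P <- make_penalty(design, as.list(fit$smoothing_params))
  reps <- matrix(NA_real_, B, length(target$t_eval))
  ok <- logical(B)
  with_preserved_seed(seed, {
    for (b in seq_len(B)) {
      ustar <- sample(u_c, data$N, replace = TRUE)
      estar <- if (errors == "resample")
        sample(r_c, data$M, replace = TRUE)
      else
        wild_weights(data$M, tau) * absr
      yb <- eta_s + ustar[data$subject] + estar
      ft <- fit_inner(Z, yb, P, tau, fit$elf_lam, theta0 = fit$theta,
                      maxit = fit$config$maxit, tol = fit$config$tol)
      ok[b] <- ft$converged && all(is.finite(ft$theta))
      if (ok[b]) reps[b, ] <- as.numeric(G %*% ft$theta[seq_len(ps)])
    }
  })
  reps <- drop_failed(reps, ok, B, "wild")
  structure(list(scheme = "wild", replicates = reps,
                 bias_boot = colMeans(reps) - theta_hat,
                 n_failed = B - nrow(reps), seed = seed,
                 t_eval = target$t_eval),
            class = "fq_boot")
}

#' Bias-adjusted normal confidence interval
#'
#' `estimate - bias_boot +/- z_(1 - alpha/2) * sd_boot`, combining the
#' wild-bootstrap bias estimate with the block-bootstrap standard error.
#'
#' @param estimate,bias_boot,sd_boot Numeric vectors of equal length
#'   (`bias_boot` may be 0).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A list with `lo`, `hi` and the adjusted `center`.
#' @export
confidence_interval <- function(estimate, bias_boot, sd_boot,
                                alpha = 0.05) {
  n <- length(estimate)
  if (length(bias_boot) == 1L) bias_boot <- rep(bias_boot, n)
  if (length(sd_boot) == 1L) sd_boot <- rep(sd_boot, n)
  if (length(bias_boot) != n || length(sd_boot) != n)
    stop("estimate, bias_boot and sd_boot must have matching lengths")
  if (any(sd_boot < 0)) stop("sd_boot must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  center <- estimate - bias_boot
  hw <- stats::qnorm(1 - alpha / 2) * sd_boot
  list(lo = center - hw, hi = center + hw, center = center)
}

#' Run the full estimation and inference pipeline
#'
#' FPCA pre-smoothing of the covariate curves, model fit, target estimation,
#' subject-block bootstrap (standard errors), wild bootstrap (bias
#' adjustment), and the combined bias-adjusted confidence interval.
#'
#' @param data An [fq_dataset()] with possibly noisy curves.
#' @param config An [fq_config()].
#' @param target A [target_spec()]; default: the quantile difference
#'   between the pointwise 20% and 80% covariate curves over the observed
#'   time range, mirroring the low-vs-high daily temperature contrast the
#'   method was designed for.
#' @param B Bootstrap replicates for each scheme (default 100).
#' @param alpha Confidence level complement (default 0.05).
#' @param seed Integer seed driving all randomness (smoothing folds and the
#'   two bootstrap schemes use sub-seeds derived from it).
#' @param pve FPCA percentage of variance explained (default 0.9999);
#'   `NULL` skips pre-smoothing.
#' @param smoothing Passed to [fq_fit()] (default `"auto"`).
#' @param fix_smoothing Hold smoothing fixed during block-bootstrap refits.
#' @param verbose Print stage timings.
#' @return A list of class `"fq_report"` with the FPCA fit, the model fit,
#'   both bootstrap results, the interval, and a per-time-point summary
#'   table (`t`, `estimate`, `adjusted`, `model_se`, `sd_boot`, `lo`, `hi`).
#' @export
run_inference_pipeline <- function(data, config, target = NULL, B = 100L,
                                   alpha = 0.05, seed = 1L, pve = 0.9999,
                                   smoothing = "auto", fix_smoothing = TRUE,
                                   verbose = FALSE) {
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- force(expr)
    if (verbose)
      message(sprintf("[%s] %.1fs", name, proc.time()[3] - t0))
    out
  }
  config$seed <- as.integer(seed)
  fpca <- NULL
  if (!is.null(pve)) {
    fpca <- stage("fpca", fit_fpca(data$curves, data$grid, pve = pve))
    data <- fq_dataset(data$subject_id, data$t, data$y,
                       fpca_reconstruct(fpca), data$grid)
  }
  if (is.null(target)) {
    tt <- sort(unique(data$t))
    t_eval <- if (length(tt) <= 50L) tt else
      seq(min(tt), max(tt), length.out = 41L)
    target <- target_spec("quantile_difference",
                          X_A = pointwise_quantile_curves(data$curves,
                                                          data$grid, 0.2),
                          X_B = pointwise_quantile_curves(data$curves,
                                                          data$grid, 0.8),
                          t_eval = t_eval)
  }
  fit <- stage("fit", fq_fit(data, config, smoothing = smoothing))
  est <- eval_target(fit, target)
  block <- stage("block bootstrap",
                 block_bootstrap(data, config, target, B,
                                 seed = seed + 1000L, fit = fit,
                                 fix_smoothing = fix_smoothing))
  wild <- stage("wild bootstrap",
                wild_bootstrap(data, fit, target, B, seed = seed + 2000L))
  ci <- confidence_interval(est$estimate, wild$bias_boot, block$sd_boot,
                            alpha)
  table <- data.frame(t = target$t_eval, estimate = est$estimate,
                      adjusted = ci$center, model_se = est$model_se,
                      sd_boot = block$sd_boot, bias_boot = wild$bias_boot,
                      lo = ci$lo, hi = ci$hi)
  structure(list(fpca = fpca, fit = fit, target = target, estimate = est,
                 block = block, wild = wild, ci = ci, table = table,
                 B = B, alpha = alpha, seed = seed),
            class = "fq_report")
}

#' @export
print.fq_report <- function(x, ...) {
  cat("Inference report (", x$target$kind, ", tau = ", x$fit$config$tau,
      ", B = ", x$B, ")\n", sep = "")
  print(utils::head(x$table, 10L), digits = 4)
  if (nrow(x$table) > 10L) cat("  ...", nrow(x$table), "evaluation times\n")
  invisible(x)
}
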