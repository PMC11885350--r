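#' Specify an inference target
#'
#' A target is either the typical-subject quantile curve
#' `Q(t) = alpha(t) + int beta(s, t) X(s) ds` (subject level `u = 0`) or the
#' fixed-subject quantile difference
#' `D(t) = int beta(s, t) (X_A(s) - X_B(s)) ds`, in which both `alpha` and
#' the subject level cancel exactly.
#'
#' @param kind `"quantile_curve"` or `"quantile_difference"`.
#' @param X_A Numeric curve on the model's s-grid.
#' @param X_B Second curve (required for `"quantile_difference"`).
#' @param t_eval Numeric vector of evaluation times.
#' @return An object of class `"fq_target"`.
#' @export
target_spec <- function(kind = c("quantile_curve", "quantile_difference"),
                        X_A, X_B = NULL, t_eval) {
  kind <- match.arg(kind)
  if (kind == "quantile_difference" && is.null(X_B))
    stop("quantile_difference requires X_B")
  structure(list(kind = kind, X_A = as.numeric(X_A),
                 X_B = if (!is.null(X_B)) as.numeric(X_B),
                 t_eval = as.numeric(t_eval)),
            class = "fq_target")
}

# Design rows of a target over the smooth coefficients (alpha block zeroed
# for difference targets). Evaluation uses the same quadrature as training.
target_design <- function(fit, X, t_eval, include_alpha = TRUE) {
  design <- fit$design
  config <- design$config
  if (length(X) != length(fit$data$grid))
    stop("X must be a curve on the fit's s-grid")
  if (any(t_eval < config$t_domain[1] - 1e-10 |
          t_eval > config$t_domain[2] + 1e-10))
    stop("t_eval outside the fitted t-domain")
  L <- config$alpha_basis$num_basis
  Tn <- length(t_eval)
  Ga <- if (include_alpha) build_basis(config$alpha_basis, t_eval)$values
        else matrix(0, Tn, L)
  variant <- config$variant
  if (variant %in% c("full", "s_only")) {
    xi <- as.numeric(functional_scores(matrix(X, 1L), fit$data$grid,
                                       config$beta_s_basis)$xi)
    D <- length(xi)
  }
  intX <- sum(design$quad_weights * X)
  Gb <- switch(variant,
    full = {
      Lb <- config$beta_t_basis$num_basis
      Psi <- build_basis(config$beta_t_basis, t_eval)$values
      Psi[, rep(seq_len(Lb), each = D), drop = FALSE] *
        matrix(xi[rep(seq_len(D), times = Lb)], Tn, D * Lb, byrow = TRUE)
    },
    s_only = matrix(xi, Tn, D, byrow = TRUE),
    t_only = build_basis(config$beta_t_basis, t_eval)$values * intX,
    scalar = matrix(intX, Tn, 1L))
  cbind(Ga, Gb)
}

target_value <- function(fit, G, t_eval, kind) {
  ps <- ncol(fit$design$Zs)
  est <- as.numeric(G %*% fit$theta[seq_len(ps)])
  se <- sqrt(pmax(rowSums((G %*% fit$coef_cov) * G), 0))
  structure(list(kind = kind, t_eval = t_eval, estimate = est,
                 model_se = se),
            class = "fq_target_value")
}

#' Predict the typical-subject quantile curve
#'
#' Evaluates `alpha(t) + int beta(s, t) X(s) ds` at the requested times with
#' the subject level set to zero, using the training quadrature rule for the
#' integral. Model-based standard errors come from the coefficient
#' covariance by the delta method (the target is linear in the
#' coefficients).
#'
#' @param fit An [fq_fit()] result.
#' @param X Numeric curve on the fit's s-grid.
#' @param t_eval Numeric vector of evaluation times within the t-domain.
#' @return A list of class `"fq_target_value"` with `estimate` and
#'   `model_se` over `t_eval`.
#' @export
predict_quantile <- function(fit, X, t_eval) {
  stopifnot(inherits(fit, "fq_fit"))
  G <- target_design(fit, X, t_eval, include_alpha = TRUE)
  target_value(fit, G, t_eval, "quantile_curve")
}

#' Quantile difference between two covariate curves
#'
#' Evaluates `D(t) = int beta(s, t) (X_A(s) - X_B(s)) ds`, the change in the
#' conditional quantile for a fixed subject when the covariate moves from
#' `X_B` to `X_A`; the smooth intercept and the subject level cancel
#' exactly, so the standard error involves only the `beta` coefficient
#' block. Antisymmetric in `(X_A, X_B)` and invariant to adding the same
#' curve to both arguments.
#'
#' @param fit An [fq_fit()] result.
#' @param X_A,X_B Numeric curves on the fit's s-grid.
#' @param t_eval Numeric vector of evaluation times.
#' @return A list of class `"fq_target_value"`.
#' @export
quantile_difference <- function(fit, X_A, X_B, t_eval) {
  stopifnot(inherits(fit, "fq_fit"))
  if (length(X_A) != length(X_B)) stop("X_A and X_B must share the grid")
  G <- target_design(fit, X_A - X_B, t_eval, include_alpha = FALSE)
  target_value(fit, G, t_eval, "quantile_difference")
}

# Evaluate a stored target spec on a fit (shared by the bootstrap schemes).
eval_target <- function(fit, target) {
  stopifnot(inherits(target, "fq_target"))
  if (target$kind == "quantile_curve")
    predict_quantile(fit, target$X_A, target$t_eval)
  else
    quantile_difference(fit, target$X_A, target$X_B, target$t_eval)
}

#' Pointwise empirical quantile curve of a sample of curves
#'
#' Per-grid-point empirical quantile across observations; used to build
#' reference covariate profiles such as the pointwise 20% and 80% curves of
#' a set of daily temperature trajectories.
#'
#' @param curves Numeric matrix, observations x H.
#' @param grid Optional grid (attached to the result as an attribute).
#' @param level Quantile level in (0, 1).
#' @return Numeric vector of length H.
#' @export
pointwise_quantile_curves <- function(curves, grid = NULL, level) {
  curves <- as.matrix(curves)
  if (nrow(curves) == 0L) stop("empty curve matrix")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  out <- apply(curves, 2L, stats::quantile, probs = level, names = FALSE,
               type = 7)
  if (!is.null(grid)) attr(out, "grid") <- grid
  out
}

#' Evaluate the fitted smooth intercept
#'
#' @param fit An [fq_fit()] result.
#' @param t_eval Evaluation times.
#' @return Numeric vector `alpha(t_eval)`.
#' @export
alpha_curve <- function(fit, t_eval) {
  as.numeric(build_basis(fit$config$alpha_basis, t_eval)$values %*% fit$a)
}

#' Evaluate the fitted coefficient surface
#'
#' Returns `beta(s, t)` on the grid `s x t` for the fitted variant (constant
#' in `t` for `"s_only"`, `beta(t) / |S|`-style average effect spread over
#' the day for `"t_only"` and `"scalar"` is not defined pointwise, so those
#' variants return the coefficient of `int X ds` replicated over `s` divided
#' by the domain length).
#'
#' @param fit An [fq_fit()] result.
#' @param s,t Numeric evaluation grids.
#' @return Numeric matrix, `length(s)` x `length(t)`.
#' @export
beta_surface <- function(fit, s, t) {
  config <- fit$config
  Phi <- build_basis(config$beta_s_basis, s)$values
  switch(config$variant,
    full = {
      Psi <- build_basis(config$beta_t_basis, t)$values
      Phi %*% fit$delta %*% t(Psi)
    },
    s_only = matrix(Phi %*% fit$delta, length(s), length(t)),
    t_only = {
      Psi <- build_basis(config$beta_t_basis, t)$values
      matrix(1 / diff(config$s_domain), length(s), 1L) %*%
        t(Psi %*% fit$delta)
    },
    scalar = matrix(fit$delta / diff(config$s_domain), length(s),
                    length(t)))
}
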