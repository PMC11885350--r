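#' Check (pinball) loss
#'
#' The quantile-regression loss `v * (tau - 1\{v < 0\})`; its minimizer over
#' a constant is the empirical tau-quantile.
#'
#' @param v Numeric scalar or vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Loss values, same shape as `v`.
#' @export
pinball_loss <- function(v, tau) {
  check_tau(tau)
  v * (tau - (v < 0))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1)
    stop("tau must be a single number strictly inside (0, 1)")
  invisible(tau)
}

# log(1 + exp(z)) without overflow
log1pexp <- function(z) {
  out <- z
  small <- z <= 30
  out[small] <- log1p(exp(z[small]))
  out[!small] <- z[!small] + log1p(exp(-z[!small]))
  out
}

#' Extended log-F (ELF) smoothed check loss
#'
#' A convex, twice-differentiable smoothing of the check loss,
#' `rho(v) = (tau - 1) v + lam * log(1 + exp(v / lam))`.
#' Its derivative lies strictly between `tau - 1` and `tau`, and
#' `0 <= rho(v) - pinball_loss(v, tau) <= lam * log(2)` for all `v`, so the
#' smooth loss converges uniformly to the check loss as `lam -> 0`.
#'
#' @param v Numeric scalar or vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @param lam Positive smoothness parameter (same units as `v`).
#' @return A list with elements `value`, `grad` and `hess`, each the same
#'   shape as `v` (derivatives are with respect to `v`).
#' @export
elf_loss <- function(v, tau, lam) {
  check_tau(tau)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("lam must be a single positive number")
  z <- v / lam
  p <- stats::plogis(z)
  list(value = (tau - 1) * v + lam * log1pexp(z),
       grad  = (tau - 1) + p,
       hess  = p * (1 - p) / lam)
}

# value-only path for line searches
elf_value <- function(v, tau, lam) {
  (tau - 1) * v + lam * log1pexp(v / lam)
}

# Log-likelihood of the ELF density f(v) = exp(-rho(v)/sigma) / Z with
# Z = lam * Beta(lam (1 - tau) / sigma, lam tau / sigma). Used by the AIC.
elf_loglik_value <- function(v, tau, lam, sigma) {
  rho <- elf_loss(v, tau, lam)$value
  logZ <- log(lam) + lbeta(lam * (1 - tau) / sigma, lam * tau / sigma)
  -sum(rho) / sigma - length(v) * logZ
}
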