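#' Specify a marginal spline basis
#'
#' Defines a univariate penalized spline basis used either for the
#' longitudinal direction (time in days, ordinary cubic B-splines) or for the
#' within-day direction (hour of day, cyclic cubic B-splines so that the
#' fitted coefficient surface wraps smoothly at midnight).
#'
#' Knots are equally spaced over the domain. The roughness penalty is the
#' standard P-spline difference penalty on the basis coefficients
#' (circular differences for the cyclic basis), of order `penalty_order`.
#'
#' @param kind `"cubic"` for an ordinary cubic B-spline basis or `"cyclic"`
#'   for a periodic cubic B-spline basis.
#' @param num_basis Number of basis functions. For `"cubic"` this must be at
#'   least 4 (or exactly 1, which denotes the constant basis used by
#'   intercept-only models); for `"cyclic"` at least 3.
#' @param domain Numeric length-2 interval. For a cyclic basis the domain
#'   length is the period.
#' @param penalty_order Order of the difference penalty (default 2, so the
#'   penalty vanishes on linear functions of the coefficients).
#' @return An object of class `"fq_basis_spec"`.
#' @seealso [build_basis()], [functional_scores()]
#' @export
basis_spec <- function(kind = c("cubic", "cyclic"), num_basis, domain,
                       penalty_order = 2L) {
  kind <- match.arg(kind)
  num_basis <- as.integer(num_basis)
  penalty_order <- as.integer(penalty_order)
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[2] > domain[1],
            penalty_order >= 0L)
  if (kind == "cubic" && num_basis == 1L) {
    penalty_order <- 0L  # constant basis, unpenalized
  } else {
    if (num_basis < penalty_order + 1L)
      stop("num_basis must be at least penalty_order + 1")
    if (kind == "cubic" && num_basis < 4L)
      stop("cubic basis requires num_basis >= 4 (or 1 for the constant basis)")
  }
  if (kind == "cyclic" && num_basis < 4L)
    stop("cyclic cubic basis requires num_basis >= 4")
  structure(list(kind = kind, num_basis = num_basis,
                 domain = as.numeric(domain), penalty_order = penalty_order),
            class = "fq_basis_spec")
}

# Difference penalty matrix; circular = TRUE composes circulant first
# differences so constants (order 1) and, on equally spaced knots, linear
# trends (order 2) are unpenalized.
difference_penalty <- function(num_basis, order, circular = FALSE) {
  if (order == 0L) return(diag(num_basis))
  if (!circular) {
    D <- diff(diag(num_basis), differences = order)
  } else {
    D1 <- diag(num_basis)
    D1 <- D1[c(2:num_basis, 1L), ] - diag(num_basis)
    D <- diag(num_basis)
    for (k in seq_len(order)) D <- D1 %*% D
  }
  crossprod(D)
}

#' Evaluate a spline basis and its roughness penalty
#'
#' Returns the basis matrix at the requested points together with the
#' penalty matrix of the spec. Ordinary cubic B-splines satisfy the partition
#' of unity on the domain; cyclic evaluation points are wrapped modulo the
#' period, so the basis and its first two derivatives agree at the two
#' endpoints of the domain.
#'
#' @param spec An [basis_spec()] object.
#' @param eval_points Numeric vector of evaluation points. Points outside the
#'   domain are an error for the non-cyclic basis.
#' @return A list of class `"fq_basis"` with elements `eval_points`, `values`
#'   (points x num_basis matrix), `penalty` (symmetric positive semidefinite)
#'   and `spec`.
#' @export
build_basis <- function(spec, eval_points) {
  stopifnot(inherits(spec, "fq_basis_spec"), is.numeric(eval_points))
  x <- as.numeric(eval_points)
  if (anyNA(x) || any(!is.finite(x))) stop("eval_points must be finite")
  a <- spec$domain[1]; b <- spec$domain[2]
  nb <- spec$num_basis
  if (spec$kind == "cubic") {
    if (any(x < a - 1e-10 | x > b + 1e-10))
      stop("evaluation point outside the domain of a non-cyclic basis")
    x <- pmin(pmax(x, a), b)
    if (nb == 1L) {
      V <- matrix(1, length(x), 1L)
      S <- matrix(0, 1L, 1L)
    } else {
      h <- (b - a) / (nb - 3L)
      knots <- a + h * seq(-3L, nb, by = 1L)
      V <- splines::splineDesign(knots, x, ord = 4L)
      S <- difference_penalty(nb, spec$penalty_order, circular = FALSE)
    }
  } else {
    period <- b - a
    xw <- a + (x - a) %% period
    knots <- seq(a, b, length.out = nb + 1L)
    V <- mgcv::cSplineDes(xw, knots, ord = 4L)
    S <- difference_penalty(nb, spec$penalty_order, circular = TRUE)
  }
  structure(list(eval_points = x, values = V, penalty = S, spec = spec),
            class = "fq_basis")
}

# Quadrature weights on a grid. Cyclic grids use the circular trapezoid rule
# (uniform grids reduce to width * rep(1, H)); weights always sum to the
# length of the s-domain.
quadrature_weights <- function(grid, cyclic = FALSE, period = NULL,
                               rule = c("trapezoid", "left")) {
  rule <- match.arg(rule)
  H <- length(grid)
  if (H < 2L) stop("grid must have at least two points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (cyclic) {
    if (is.null(period)) period <- H * (grid[2] - grid[1])
    gaps <- c(diff(grid), period - (grid[H] - grid[1]))
    if (gaps[H] <= 0) stop("grid exceeds the stated period")
    if (rule == "left") return(gaps)
    prev <- c(gaps[H], gaps[-H])
    return((gaps + prev) / 2)
  }
  if (rule == "left") {
    c(diff(grid), 0)
  } else {
    h <- diff(grid)
    c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  }
}

#' Functional covariate scores by numerical quadrature
#'
#' Projects each observed curve onto the basis functions of `spec`,
#' approximating the integrals `xi[i, d] = int phi_d(s) X_i(s) ds` with a
#' Riemann-type quadrature rule on the observed grid (trapezoidal by
#' default; circular trapezoid for a cyclic basis, whose weights are uniform
#' on an equally spaced grid).
#'
#' @param curves Numeric matrix, observations x H, no missing values
#'   (reconstruct with [fpca_reconstruct()] first if the raw curves are
#'   noisy or incomplete).
#' @param grid Strictly increasing numeric vector of length H.
#' @param spec [basis_spec()] for the s-direction.
#' @param rule `"trapezoid"` (default) or `"left"`.
#' @return A list of class `"fq_scores"` with elements `xi`
#'   (observations x num_basis), `grid` and `quadrature_weights`.
#' @export
functional_scores <- function(curves, grid, spec,
                              rule = c("trapezoid", "left")) {
  rule <- match.arg(rule)
  curves <- as.matrix(curves)
  if (ncol(curves) != length(grid))
    stop("number of curve columns must match the grid length")
  if (anyNA(curves)) stop("curves contain missing values")
  cyc <- spec$kind == "cyclic"
  w <- quadrature_weights(grid, cyclic = cyc,
                          period = if (cyc) diff(spec$domain) else NULL,
                          rule = rule)
  Phi <- build_basis(spec, grid)$values
  xi <- curves %*% (w * Phi)
  structure(list(xi = xi, grid = grid, quadrature_weights = w),
            class = "fq_scores")
}

#' Tensor-product design row
#'
#' Builds the design row pairing the functional scores `xi` of one
#' observation with the longitudinal spline values `psi_t` evaluated at its
#' observation time, so that the inner product of the row with `vec(delta)`
#' (a D x L coefficient matrix stacked column by column) equals the double
#' sum `sum_l sum_d delta[d, l] * psi_t[l] * xi[d]`. Bilinear in both
#' arguments.
#'
#' @param xi_row Numeric vector of length D (scores).
#' @param psi_t Numeric vector of length L (t-basis values).
#' @return Numeric vector of length `L * D`.
#' @export
tensor_design_row <- function(xi_row, psi_t) {
  as.vector(outer(as.numeric(xi_row), as.numeric(psi_t)))
}
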