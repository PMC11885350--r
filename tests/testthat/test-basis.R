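test_that("cubic B-spline basis: partition of unity, domain checks, penalty", {
  sp <- basis_spec("cubic", 10, c(0, 21))
  b <- build_basis(sp, seq(0.3, 20.7, length.out = 50))
  expect_equal(rowSums(b$values), rep(1, 50), tolerance = 1e-10)
  expect_true(isSymmetric(b$penalty))
  expect_true(all(eigen(b$penalty, only.values = TRUE)$values > -1e-10))

  # second-order penalty annihilates linear functions: the coefficient
  # vector reproducing f(t) = t is the Greville abscissae
  h <- 21 / 7
  knots <- 0 + h * (-3:10)
  grev <- (knots[2:11] + knots[3:12] + knots[4:13]) / 3
  expect_lt(abs(t(grev) %*% b$penalty %*% grev), 1e-8)
  fitted_line <- b$values %*% grev
  expect_equal(as.numeric(fitted_line), b$eval_points, tolerance = 1e-10)

  expect_error(build_basis(sp, c(-1, 5)), "outside the domain")
  expect_error(basis_spec("cubic", 3, c(0, 1)), "num_basis")
  expect_error(basis_spec("cubic", 2, c(0, 1), penalty_order = 2), "num_basis")
})

test_that("cyclic basis is periodic with matching values at the endpoints", {
  sp <- basis_spec("cyclic", 8, c(0, 24))
  b <- build_basis(sp, c(0, 24, 3.7, 27.7))
  expect_equal(b$values[1, ], b$values[2, ])          # 0 vs 24
  expect_equal(b$values[3, ], b$values[4, ])          # wrap by one period
  # partition of unity also holds for the periodic basis
  bb <- build_basis(sp, seq(0, 23.9, by = 0.37))
  expect_equal(rowSums(bb$values), rep(1, nrow(bb$values)),
               tolerance = 1e-10)
  # first two derivatives agree across the seam (finite differences)
  eps <- 1e-5
  v <- function(x) build_basis(sp, x)$values
  d_left <- (v(24 - eps) - v(24 - 2 * eps)) / eps
  d_right <- (v(eps * 2) - v(eps)) / eps
  expect_equal(d_left, d_right, tolerance = 1e-3)
  # circular difference penalty annihilates constants
  expect_lt(max(abs(b$penalty %*% rep(1, 8))), 1e-12)
})

test_that("functional scores approximate the basis-projection integrals", {
  g <- seq(0, 24 - 1 / 12, by = 1 / 12)   # H = 288
  spc <- basis_spec("cyclic", 7, c(0, 24))

  # zero curve -> zero scores
  fs0 <- functional_scores(matrix(0, 3, length(g)), g, spc)
  expect_equal(fs0$xi, matrix(0, 3, 7))
  expect_equal(sum(fs0$quadrature_weights), 24)

  # partition of unity + linearity: row sums of xi equal the quadrature
  # approximation of int X ds (non-cyclic basis so the property is exact)
  gnc <- seq(0, 24, length.out = 100)
  spnc <- basis_spec("cubic", 9, c(0, 24))
  X <- matrix(runif(3 * 100), 3)
  fs <- functional_scores(X, gnc, spnc)
  w <- fs$quadrature_weights
  expect_equal(rowSums(fs$xi), as.numeric(X %*% w), tolerance = 1e-10)

  # smooth curve: H = 288 scores match a 10x-finer-grid oracle
  X1 <- matrix(sin(2 * pi * g / 24), 1)
  xi_coarse <- functional_scores(X1, g, spc)$xi
  gf <- seq(0, 24 - 24 / 28800, length.out = 28800)
  xi_fine <- functional_scores(matrix(sin(2 * pi * gf / 24), 1), gf, spc)$xi
  expect_lt(max(abs(xi_coarse - xi_fine)) / max(abs(xi_fine)), 1e-3)

  expect_error(functional_scores(matrix(0, 2, 5), g, spc), "match the grid")
})

test_that("quadrature error decreases as the grid is refined", {
  spc <- basis_spec("cyclic", 5, c(0, 24))
  f <- function(s) exp(sin(2 * pi * s / 24))
  ref <- functional_scores(matrix(f(seq(0, 24 - 24 / 46080,
                                        length.out = 46080)), 1),
                           seq(0, 24 - 24 / 46080, length.out = 46080),
                           spc)$xi
  errs <- sapply(c(36, 72, 144, 288), function(H) {
    g <- seq(0, 24 - 24 / H, length.out = H)
    max(abs(functional_scores(matrix(f(g), 1), g, spc)$xi - ref))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("tensor design rows reproduce the nested double sum", {
  set.seed(4)
  D <- 7L; L <- 10L
  xi <- rnorm(D); psi <- rnorm(L); delta <- matrix(rnorm(D * L), D, L)
  row <- tensor_design_row(xi, psi)
  direct <- 0
  for (l in seq_len(L)) for (d in seq_len(D))
    direct <- direct + delta[d, l] * psi[l] * xi[d]
  expect_equal(sum(row * as.vector(delta)), direct, tolerance = 1e-12)

  # unit t-vector places xi in block l
  e3 <- replace(numeric(L), 3, 1)
  r3 <- tensor_design_row(xi, e3)
  expect_equal(r3[(2 * D + 1):(3 * D)], xi)
  expect_equal(r3[-((2 * D + 1):(3 * D))], numeric(D * (L - 1)))

  # bilinearity
  expect_equal(tensor_design_row(2 * xi, psi), 2 * row)
  expect_equal(tensor_design_row(xi, 3 * psi), 3 * row)
})
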