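# Shared fixtures: everything generated in code, sized for fast tests.

# Small longitudinal functional dataset with known structure.
small_truth <- function(N = 30L, n_range = c(6L, 6L), H = 48L,
                        sigma_u = 0.5, error = "normal",
                        error_scale = 0.5, seed = 1L, ...) {
  sim_truth(N = N, n_range = n_range, H = H, sigma_u = sigma_u,
            error = error, error_scale = error_scale, seed = seed, ...)
}

small_config <- function(tau = 0.5, variant = "full", L = 5L, D = 4L,
                         seed = 1L, ...) {
  fq_config(tau, variant = variant, L = L, D = D, seed = seed, ...)
}

# Linear quantile regression oracle: statsmodels' interior-point/IRLS
# QuantReg via the system python. x may have several columns.
qr_oracle <- function(y, x, tau) {
  x <- as.matrix(x)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  df <- data.frame(y = y, x)
  names(df) <- c("y", paste0("x", seq_len(ncol(x))))
  utils::write.csv(df, tf, row.names = FALSE)
  script <- sprintf(paste0(
    "import pandas as pd, statsmodels.api as sm\n",
    "df = pd.read_csv('%s')\n",
    "X = sm.add_constant(df.drop(columns=['y']))\n",
    "r = sm.QuantReg(df['y'], X).fit(q=%.10f)\n",
    "print(' '.join(str(float(v)) for v in r.params.values))\n"), tf, tau)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = FALSE)
  as.numeric(strsplit(out[length(out)], " ")[[1]])
}

# Evaluate the model's linear predictor by explicit nested loops over the
# double basis sum (the independent oracle for design/predict checks).
nested_loop_eta <- function(data, config, a, delta, u) {
  config <- funqr:::resolve_config(config, data)
  psi_a <- build_basis(config$alpha_basis, data$t)$values
  psi_b <- build_basis(config$beta_t_basis, data$t)$values
  xi <- functional_scores(data$curves, data$grid,
                          config$beta_s_basis)$xi
  L <- ncol(psi_a); Lb <- ncol(psi_b); D <- ncol(xi)
  eta <- numeric(data$M)
  for (m in seq_len(data$M)) {
    v <- 0
    for (l in seq_len(L)) v <- v + a[l] * psi_a[m, l]
    for (l in seq_len(Lb)) for (d in seq_len(D))
      v <- v + delta[d, l] * psi_b[m, l] * xi[m, d]
    eta[m] <- v + u[data$subject[m]]
  }
  eta
}
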