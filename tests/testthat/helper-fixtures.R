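# Shared fixtures: everything is generated in code, no stored data.

tiny_panel <- function(K = 4, markers_per_type = 10, n_background = 40,
                       seed = 11) {
  make_reference_panel(K = K, markers_per_type = markers_per_type,
                       n_background = n_background, seed = seed)
}

blood_panel <- function(markers_per_type = 20, n_background = 100,
                        seed = 11) {
  make_reference_panel(K = 12, markers_per_type = markers_per_type,
                       n_background = n_background, seed = seed)
}

tiny_beta <- function(values = matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 3, 2),
                      cpgs = paste0("cg", 1:3), samples = c("s1", "s2")) {
  dimnames(values) <- list(cpgs, samples)
  beta_matrix(values)
}

# independent OLS oracle via explicit normal equations
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# independent meta-analysis oracle: direct transcription of the
# inverse-variance / DerSimonian-Laird formulas
meta_oracle <- function(e, s) {
  w <- 1 / s^2
  mu <- sum(w * e) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (e - mu)^2)
  df <- length(e) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (s^2 + tau2)
  mur <- sum(wr * e) / sum(wr)
  ser <- sqrt(1 / sum(wr))
  list(fixed = mu, fixed_se = se, Q = Q, df = df, tau2 = tau2,
       random = mur, random_se = ser,
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}
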