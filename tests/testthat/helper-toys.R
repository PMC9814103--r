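# Shared fixtures built in code: toy spaces and an independent dense-algebra
# GP oracle (explicit kernel formula + solve(), no Cholesky caching) used to
# cross-check the package's cached-solve implementation.

toy_space_2cat <- function() {
  parameter_space(list(
    categorical_param("mixer", c("a", "b", "c")),
    continuous_param("temp", 20, 60, "degC", precision = 5),
    continuous_param("conc", 0.01, 0.1, "M", precision = 0.001)
  ))
}

# 1-D space whose lab grid is exactly the 12 integers 0..11.
toy_space_grid12 <- function() {
  parameter_space(list(
    continuous_param("x", 0, 11, "", precision = 1)
  ))
}

# Matern-5/2 value from the closed-form expression, scalar inputs.
oracle_k <- function(x1, x2, ls, sf2) {
  r <- sqrt(sum(((x1 - x2) / ls)^2))
  sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

oracle_K <- function(X1, X2, ls, sf2) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1)))
    for (j in seq_len(nrow(X2)))
      K[i, j] <- oracle_k(X1[i, ], X2[j, ], ls, sf2)
  K
}

# Full GP posterior + evidence by direct dense inversion, standardized frame.
oracle_gp <- function(X, y, Xs, ls, sf2, sn2, y_mean = mean(y),
                      y_sd = stats::sd(y)) {
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  n <- nrow(X)
  K <- oracle_K(X, X, ls, sf2) + diag(sn2, n)
  Kinv <- solve(K)
  Ks <- oracle_K(X, Xs, ls, sf2)
  mean_s <- drop(t(Ks) %*% Kinv %*% ys)
  var_s <- pmax(sf2 - diag(t(Ks) %*% Kinv %*% Ks), 0)
  lml <- as.numeric(-0.5 * t(ys) %*% Kinv %*% ys -
                      0.5 * determinant(K, logarithm = TRUE)$modulus -
                      n / 2 * log(2 * pi))
  list(mean = mean_s * y_sd + y_mean, sd = sqrt(var_s) * y_sd, lml = lml,
       mean_std = mean_s, sd_std = sqrt(var_s))
}

# Small deterministic training set on the 12-point toy grid.
toy_grid_records <- function() {
  data.frame(x = c(0, 3, 5, 9), yield_pct = c(20, 60, 40, 55))
}
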