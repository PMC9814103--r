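test_that("two-point posterior matches the hand-computed closed form", {
  # n = 2 toy problem solved by explicit 2x2 inversion in the oracle helper
  X <- matrix(c(0.2, 0.8), ncol = 1)
  y <- c(10, 30)
  ls <- 0.5; sf2 <- 2; sn2 <- 0.1
  m <- gp_model(X, y, ls, sf2, sn2)
  Xs <- matrix(c(0.2, 0.5, 0.95), ncol = 1)
  p <- gp_predict(m, Xs)
  o <- oracle_gp(X, y, Xs, ls, sf2, sn2)
  expect_equal(p$mean, o$mean, tolerance = 1e-10)
  expect_equal(p$sd, o$sd, tolerance = 1e-10)
  expect_equal(gp_log_marginal_likelihood(m), o$lml, tolerance = 1e-10)
})

test_that("posterior and evidence agree with the dense oracle up to n = 25", {
  set.seed(101)
  for (n in c(5, 12, 25)) {
    d <- 4
    X <- matrix(stats::runif(n * d), n, d)
    y <- 40 + 30 * sin(4 * X[, 1]) + 10 * X[, 2] + stats::rnorm(n, 0, 2)
    ls <- c(0.3, 0.8, 1.5, 0.5); sf2 <- 1.7; sn2 <- 0.05
    m <- gp_model(X, y, ls, sf2, sn2)
    Xs <- matrix(stats::runif(8 * d), 8, d)
    p <- gp_predict(m, Xs)
    o <- oracle_gp(X, y, Xs, ls, sf2, sn2)
    # tolerance in standardized units
    expect_lt(max(abs(p$mean - o$mean)) / m$y_sd, 1e-6)
    expect_lt(max(abs(p$sd - o$sd)) / m$y_sd, 1e-6)
    expect_lt(abs(m$lml - o$lml), 1e-6)
  }
})

test_that("fitting on the six initial screening experiments succeeds", {
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:6, ]
  X <- encode_conditions(sp, conditions_from_records(sp, t1))
  m <- gp_fit(X, t1$yield_pct, seed = 1)
  k <- m$kernel
  expect_true(all(is.finite(k$lengthscales)) && all(k$lengthscales > 0))
  expect_true(is.finite(k$signal_var) && k$signal_var > 0)
  expect_gte(k$noise_var, 1e-6)
  expect_true(is.finite(m$lml))
})

test_that("fitted evidence beats 20 random hyperparameter draws", {
  set.seed(7)
  n <- 12; d <- 3
  X <- matrix(stats::runif(n * d), n, d)
  y <- 50 + 25 * cos(5 * X[, 1]) * X[, 3] + stats::rnorm(n, 0, 1)
  m <- gp_fit(X, y, seed = 5)
  draws <- replicate(20, {
    ls <- exp(stats::runif(d, log(1e-2), log(10)))
    sf2 <- exp(stats::runif(1, log(1e-2), log(1e2)))
    sn2 <- exp(stats::runif(1, log(1e-6), log(1)))
    gp_model(X, y, ls, sf2, sn2,
             y_stats = list(mean = m$y_mean, sd = m$y_sd))$lml
  })
  expect_true(all(m$lml >= draws))
})

test_that("constant responses give a constant posterior with small sd", {
  X <- matrix(stats::runif(10), ncol = 2)
  y <- rep(42, 5)
  m <- gp_fit(X, y, seed = 2)
  p <- gp_predict(m, matrix(stats::runif(6), ncol = 2))
  expect_equal(p$mean, rep(42, 3), tolerance = 1e-6)
  expect_true(all(p$sd < 1))
})

test_that("near-noiseless model interpolates its training data", {
  set.seed(11)
  X <- matrix(stats::runif(12), ncol = 2)
  y <- c(10, 50, 30, 80, 60, 20)
  m <- gp_model(X, y, lengthscales = c(0.5, 0.5), signal_var = 1,
                noise_var = 1e-6)
  p <- gp_predict(m, X)
  expect_lt(max(abs(p$mean - y)) / m$y_sd, 1e-4)
})

test_that("far from all data the posterior reverts to the prior", {
  X <- matrix(stats::runif(10, 0, 0.05), ncol = 2)
  y <- c(60, 70, 65, 75, 68)
  ls <- c(0.05, 0.05)
  m <- gp_model(X, y, lengthscales = ls, signal_var = 1, noise_var = 0.01)
  # >= 10 lengthscales away from every training point
  p <- gp_predict(m, matrix(c(1, 1), ncol = 2))
  expect_equal(p$mean, m$y_mean, tolerance = 1e-3)
  expect_equal(p$sd, sqrt(1) * m$y_sd, tolerance = 1e-3)
})

test_that("posterior sd never exceeds the prior sd and is never negative", {
  set.seed(3)
  X <- matrix(stats::runif(30), ncol = 3)
  y <- stats::runif(10, 0, 100)
  m <- gp_model(X, y, c(0.4, 0.6, 0.8), 1.5, 0.02)
  p <- gp_predict(m, rbind(X, matrix(stats::runif(30), ncol = 3)))
  expect_true(all(p$sd >= 0))
  expect_true(all(p$sd <= sqrt(1.5) * m$y_sd + 1e-9))
})

test_that("predictions are invariant to permuting the training rows", {
  set.seed(13)
  X <- matrix(stats::runif(24), ncol = 2)
  y <- stats::runif(12, 20, 90)
  perm <- sample(12)
  m1 <- gp_model(X, y, c(0.5, 0.7), 1, 0.05)
  m2 <- gp_model(X[perm, ], y[perm], c(0.5, 0.7), 1, 0.05)
  Xs <- matrix(stats::runif(10), ncol = 2)
  p1 <- gp_predict(m1, Xs); p2 <- gp_predict(m2, Xs)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-8)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-8)
})

test_that("evidence drops when noise is inflated on well-fit data", {
  set.seed(17)
  X <- matrix(seq(0, 1, length.out = 10), ncol = 1)
  y <- 50 + 30 * sin(3 * X[, 1])
  m <- gp_fit(X, y, seed = 4)
  k <- m$kernel
  inflated <- gp_model(X, y, k$lengthscales, k$signal_var,
                       min(k$noise_var * 100, 1),
                       y_stats = list(mean = m$y_mean, sd = m$y_sd))
  expect_lt(inflated$lml, m$lml)
})

test_that("duplicated observations change the evidence deterministically", {
  set.seed(19)
  X <- matrix(stats::runif(8), ncol = 2)
  y <- c(30, 60, 45, 70)
  m <- gp_model(X, y, c(0.5, 0.5), 1, 0.05)
  l1 <- gp_log_marginal_likelihood(m, rbind(X, X[1, , drop = FALSE]),
                                   c(y, y[1]))
  l2 <- gp_log_marginal_likelihood(m, rbind(X, X[1, , drop = FALSE]),
                                   c(y, y[1]))
  expect_identical(l1, l2)
  expect_false(isTRUE(all.equal(l1, m$lml)))
})

test_that("fitting is deterministic given data and seed", {
  set.seed(23)
  X <- matrix(stats::runif(16), ncol = 2)
  y <- stats::runif(8, 0, 100)
  m1 <- gp_fit(X, y, seed = 9)
  m2 <- gp_fit(X, y, seed = 9)
  expect_identical(m1$kernel, m2$kernel)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(gp_fit(matrix(1, 1, 2), 5), "at least 2")
  expect_error(gp_fit(matrix(1:4, 2, 2), c(1, NA)), "finite")
  expect_error(gp_predict(gp_model(matrix(stats::runif(4), 2, 2), c(1, 2),
                                   c(0.5, 0.5), 1, 0.1),
                          matrix(1, 1, 3)), "columns")
})

test_that("a saved model reloads with identical predictions", {
  set.seed(29)
  X <- matrix(stats::runif(12), ncol = 2)
  y <- stats::runif(6, 10, 90)
  m <- gp_fit(X, y, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  gp_save(m, f)
  m2 <- gp_load(f)
  Xs <- matrix(stats::runif(8), ncol = 2)
  expect_equal(gp_predict(m, Xs), gp_predict(m2, Xs), tolerance = 1e-10)
})
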