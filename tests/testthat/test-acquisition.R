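test_that("confidence-bound acquisition follows mean + beta * sd", {
  expect_equal(acq_lcb(50, 10, beta = 0), 50)
  expect_equal(acq_lcb(50, 0, beta = 7), 50)
  expect_equal(acq_lcb(50, 10, beta = 2), 70)
  expect_equal(acq_lcb(c(10, 20), c(1, 2), beta = 1), c(11, 22))
  expect_error(acq_lcb(10, -1), "non-negative")
  # monotone in beta at fixed (mean, sd)
  betas <- seq(0, 5, by = 0.5)
  vals <- vapply(betas, function(b) acq_lcb(42, 3, b), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("expected improvement matches its closed form", {
  expect_equal(acq_ei(40, 0, best_observed = 50, xi = 0), 0)
  expect_equal(acq_ei(60, 0, best_observed = 50, xi = 5), 5)
  # zero mean-gap: EI = sigma / sqrt(2 pi)
  sigma <- 7
  expect_equal(acq_ei(50, sigma, best_observed = 50, xi = 0),
               sigma / sqrt(2 * pi), tolerance = 1e-12)
  # Monte-Carlo cross-check of the Gaussian expectation
  set.seed(31)
  draws <- stats::rnorm(1e6, mean = 55, sd = 4)
  mc <- mean(pmax(draws - 52, 0))
  expect_equal(acq_ei(55, 4, best_observed = 52, xi = 0), mc, tolerance = 0.02)
  expect_error(acq_ei(10, -1, 5), "non-negative")
})

test_that("with beta = 0 and q = 1 the batch is the posterior-mean maximizer", {
  sp <- toy_space_grid12()
  rec <- toy_grid_records()
  cfg <- acq_config(kind = "parallel_lcb", beta = 0, batch_size = 1, seed = 5)
  st <- new_campaign(sp, rec, cfg)
  m <- gp_model(encode_conditions(sp, conditions_from_records(sp, st$history)),
                st$history$yield_pct, lengthscales = 0.15, signal_var = 1,
                noise_var = 0.01)
  prop <- propose_batch(st, m)
  # brute force over the 12 grid points, excluding already-run ones
  grid <- setdiff(0:11, rec$x)
  mu <- gp_predict(m, encode_conditions(sp, data.frame(x = grid)))$mean
  expect_equal(prop$conditions[[1]]$x, grid[which.max(mu)])
})

test_that("batches equal the exhaustive sequential-hallucination argmax", {
  sp <- toy_space_grid12()
  rec <- toy_grid_records()
  for (seed in c(2, 27)) {
    cfg <- acq_config(kind = "parallel_lcb", beta = 2, batch_size = 3,
                      seed = seed)
    st <- new_campaign(sp, rec, cfg)
    X0 <- encode_conditions(sp, conditions_from_records(sp, st$history))
    m <- gp_model(X0, st$history$yield_pct, lengthscales = 0.2,
                  signal_var = 1, noise_var = 0.01)
    prop <- propose_batch(st, m)

    # oracle: enumerate all 12 vertices; at each step take the acquisition
    # argmax among unused points, then condition a fresh model on the
    # posterior-mean value there (same standardization frame, no gp_augment)
    Xa <- X0; ya <- st$history$yield_pct
    used <- rec$x
    picks <- numeric(3)
    for (s in 1:3) {
      mm <- gp_model(Xa, ya, lengthscales = 0.2, signal_var = 1,
                     noise_var = 0.01,
                     y_stats = list(mean = m$y_mean, sd = m$y_sd))
      avail <- setdiff(0:11, used)
      Xg <- encode_conditions(sp, data.frame(x = avail))
      p <- gp_predict(mm, Xg)
      a <- p$mean + 2 * p$sd
      best <- avail[which.max(a)]
      picks[s] <- best
      xb <- encode_conditions(sp, data.frame(x = best))
      mu <- gp_predict(mm, xb)$mean
      Xa <- rbind(Xa, xb); ya <- c(ya, mu)
      used <- c(used, best)
    }
    expect_equal(vapply(prop$conditions, `[[`, numeric(1), "x"), picks)
  }
})

test_that("proposals are deterministic given history, config and seed", {
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:6, ]
  cfg <- acq_config(seed = 11, n_candidates = 512, refine_top = 3)
  st <- new_campaign(sp, t1, cfg)
  m <- gp_fit(encode_conditions(sp, conditions_from_records(sp, t1)),
              t1$yield_pct, seed = 11)
  p1 <- propose_batch(st, m)
  p2 <- propose_batch(st, m)
  expect_identical(p1$conditions, p2$conditions)
  expect_identical(p1$acq_values, p2$acq_values)
})

test_that("proposed conditions are in-bounds, on-grid and distinct", {
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:9, ]
  cfg <- acq_config(seed = 4, n_candidates = 1024, refine_top = 5)
  st <- new_campaign(sp, t1, cfg)
  prop <- propose_batch(st)
  keys <- character(0)
  for (cc in prop$conditions) {
    cc2 <- validate_condition(sp, cc)      # errors if out of bounds
    expect_equal(snap_to_lab_grid(sp, cc2), cc2)  # already on the lab grid
    keys <- c(keys, paste(unlist(cc2), collapse = "|"))
  }
  expect_equal(anyDuplicated(keys), 0L)
  # never re-proposes an already-run condition
  hist_keys <- vapply(conditions_from_records(sp, t1), function(cc)
    paste(unlist(cc), collapse = "|"), "")
  expect_length(intersect(keys, hist_keys), 0)
})

test_that("hallucination never increases posterior variance", {
  set.seed(37)
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:6, ]
  X <- encode_conditions(sp, conditions_from_records(sp, t1))
  m <- gp_fit(X, t1$yield_pct, seed = 1)
  Xs <- matrix(stats::runif(50 * 8), ncol = 8)
  sd_before <- gp_predict(m, Xs)$sd
  xnew <- Xs[1, , drop = FALSE]
  m2 <- gp_augment(m, xnew, gp_predict(m, xnew)$mean)
  sd_after <- gp_predict(m2, Xs)$sd
  expect_true(all(sd_after <= sd_before + 1e-8))
})

test_that("advance_round appends records and validates its inputs", {
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:6, ]
  cfg <- acq_config(seed = 3, n_candidates = 256, refine_top = 2)
  st <- new_campaign(sp, t1, cfg)
  prop <- propose_batch(st)
  expect_error(advance_round(st, prop, c(50, 60)), "3 proposed")
  expect_error(advance_round(st, prop, c(50, 60, 105)), "\\[0, 100\\]")
  st2 <- advance_round(st, prop, c(50, 60, 70))
  expect_equal(nrow(st2$history), 9)
  expect_equal(st2$round, 1L)
  expect_equal(st2$history$entry, 1:9)
  expect_equal(st2$history$yield_pct[7:9], c(50, 60, 70))
})

test_that("a saved campaign resumes with identical proposals", {
  sp <- widened_space()
  t1 <- load_fixture("table1")[1:6, ]
  cfg <- acq_config(seed = 21, n_candidates = 512, refine_top = 3)
  st <- new_campaign(sp, t1, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_campaign(st, f)
  st2 <- load_campaign(f)
  expect_equal(st2$history$yield_pct, st$history$yield_pct)
  expect_equal(st2$round, st$round)
  p1 <- propose_batch(st)
  p2 <- propose_batch(st2)
  expect_equal(p1$conditions, p2$conditions)
})

test_that("the closed loop with zero rounds only evaluates the design", {
  sp <- widened_space()
  obj <- make_flow_yield_objective(8)
  init <- init_design_lhs(sp, 6, seed = 8)
  res <- run_closed_loop(sp, obj, init, rounds = 0, acq_config(seed = 8))
  expect_equal(nrow(res$state$history), 6)
  expect_equal(res$trace, cummax(res$yields))
  expect_true(all(diff(res$trace) >= 0))
})

test_that("the initial design covers every category and the lab grid", {
  sp <- widened_space()
  d <- init_design_lhs(sp, 6, seed = 13)
  expect_equal(nrow(d), 6)
  expect_setequal(unique(d$mixer), c("comet_x", "beta_type", "t_shaped"))
  expect_equal(table(d$mixer)[["comet_x"]], 2)
  for (i in seq_len(6)) {
    cc <- validate_condition(sp, as.list(d[i, ]))
    expect_equal(snap_to_lab_grid(sp, cc), cc)
  }
  # deterministic under the same seed
  expect_identical(d, init_design_lhs(sp, 6, seed = 13))
})
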