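# Seeded synthetic flow-yield objectives with mixer-dependent optima, the
# optimizer evaluation harness (BO variants vs random search), the packaged
# campaign fixtures, and campaign replay statistics.

#' Seeded synthetic flow-reaction yield objective
#'
#' Builds a black-box yield surface over the six-parameter flow space that
#' emulates the structure of the real campaigns: each micromixer has its own
#' achievable amplitude and its own optimum location in the continuous
#' parameters, so choosing the right reactor matters as much as tuning the
#' numeric conditions. The noiseless surface is
#' `amplitude(mixer) * prod_d exp(-(x_d - opt_d(mixer))^2 / (2 w_d(mixer)^2))`
#' on the unit-scaled continuous coordinates, clipped to \[0, 100\]. One
#' mixer is the global optimum and its amplitude exceeds every other mixer's
#' by at least 10 yield points. Evaluations add Gaussian noise (sd
#' `noise_sd` yield points) that is deterministic given (seed, call index),
#' then clip to \[0, 100\].
#'
#' Amplitudes, optima and widths are drawn per seed (best amplitude
#' U\[85, 100\], others 10-30 points lower, optima U\[0.15, 0.85\], widths
#' U\[0.4, 0.75\]), so different seeds give different landscapes and no test
#' can overfit one surface.
#'
#' @param seed integer seed for the landscape draw.
#' @param space a `flowbo_space` with exactly one categorical parameter
#'   (default [widened_space()]).
#' @param noise_sd evaluation noise in yield points (default 2; 0 disables).
#' @return an object of class `flowbo_objective`.
#' @export
make_flow_yield_objective <- function(seed = 1L, space = widened_space(),
                                      noise_sd = 2) {
  types <- vapply(space$params, function(p) p$type, "")
  cats <- space$params[types == "categorical"]
  cont <- space$params[types == "continuous"]
  if (length(cats) != 1L)
    stopf("the synthetic objective needs exactly one categorical parameter")
  catp <- cats[[1L]]
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  nd <- length(cont)
  per_category <- with_seed(derive_seed(seed, 11L), {
    k <- length(catp$choices)
    best <- sample.int(k, 1L)
    amp_best <- stats::runif(1, 85, 100)
    amps <- amp_best - stats::runif(k, 10, 30)
    amps[best] <- amp_best
    out <- list()
    for (i in seq_len(k)) {
      out[[catp$choices[i]]] <- list(
        amplitude = amps[i],
        opt = stats::runif(nd, 0.15, 0.85),
        width = stats::runif(nd, 0.4, 0.75)
      )
    }
    out
  })
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(
    list(space = space, cat_name = catp$name,
         cont_names = vapply(cont, function(p) p$name, ""),
         per_category = per_category, noise_sd = noise_sd,
         seed = as.integer(seed), env = env),
    class = "flowbo_objective"
  )
}

#' @export
print.flowbo_objective <- function(x, ...) {
  cat(sprintf("<flowbo_objective> seed %d, noise sd %g, optimum %g%% (%s)\n",
              x$seed, x$noise_sd, objective_optimum(x),
              objective_best_category(x)))
  invisible(x)
}

unit_scale_cond <- function(obj, cond) {
  vapply(obj$cont_names, function(nm) {
    p <- get_param(obj$space, nm)
    (cond[[nm]] - p$low) / (p$high - p$low)
  }, numeric(1))
}

#' Evaluate a synthetic yield objective
#'
#' @param obj a `flowbo_objective`.
#' @param cond a valid condition of the objective's space.
#' @param noiseless if `TRUE`, return the deterministic surface value.
#' @return yield in \[0, 100\].
#' @export
eval_objective <- function(obj, cond, noiseless = FALSE) {
  if (!inherits(obj, "flowbo_objective")) stopf("obj must be a flowbo_objective")
  cond <- validate_condition(obj$space, cond)
  pc <- obj$per_category[[cond[[obj$cat_name]]]]
  x <- unit_scale_cond(obj, cond)
  val <- pc$amplitude * exp(-sum((x - pc$opt)^2 / (2 * pc$width^2)))
  val <- min(max(val, 0), 100)
  if (!noiseless && obj$noise_sd > 0) {
    obj$env$calls <- obj$env$calls + 1L
    eps <- with_seed(derive_seed(obj$seed, 29L, obj$env$calls),
                     stats::rnorm(1, 0, obj$noise_sd))
    val <- min(max(val + eps, 0), 100)
  }
  val
}

#' True optimum of a synthetic objective
#'
#' By construction the noiseless maximum is the largest per-mixer amplitude
#' (attained at that mixer's optimum location).
#'
#' @param obj a `flowbo_objective`.
#' @return `objective_optimum()`: the maximal noiseless yield;
#'   `objective_best_category()`: the label of the optimal mixer.
#' @export
objective_optimum <- function(obj) {
  max(vapply(obj$per_category, function(p) min(p$amplitude, 100), numeric(1)))
}

#' @rdname objective_optimum
#' @export
objective_best_category <- function(obj) {
  amps <- vapply(obj$per_category, function(p) p$amplitude, numeric(1))
  names(amps)[which.max(amps)]
}

#' Random-search baseline
#'
#' Draws `budget` conditions uniformly at random (continuous uniform within
#' bounds, snapped to the lab grid; categorical uniform over choices) and
#' evaluates the objective at each. Shares the campaign record format with
#' the BO loop so both go through the same evaluation harness.
#'
#' @param space a `flowbo_space`.
#' @param objective as in [run_closed_loop()].
#' @param budget number of evaluations.
#' @param seed integer seed.
#' @return list with `state`, `yields`, and monotone best-so-far `trace`.
#' @export
random_search <- function(space, objective, budget, seed = 1L) {
  budget <- as.integer(budget)
  if (budget < 1L) stopf("budget must be >= 1")
  evalfun <- if (inherits(objective, "flowbo_objective")) {
    function(cc) eval_objective(objective, cc)
  } else objective
  conds <- with_seed(derive_seed(seed, 5L), {
    lapply(seq_len(budget), function(i) {
      cc <- list()
      for (p in space$params) {
        cc[[p$name]] <- if (p$type == "continuous")
          stats::runif(1, p$low, p$high) else sample(p$choices, 1L)
      }
      snap_to_lab_grid(space, cc)
    })
  })
  y <- vapply(conds, function(cc) as.numeric(evalfun(cc)), numeric(1))
  state <- new_campaign(space, records_frame(space, conds, y))
  list(state = state, yields = y, trace = cummax(y))
}

#' Compare an optimizer against the synthetic benchmark
#'
#' Runs one full campaign per seed -- either the batch-BO closed loop
#' (initial space-filling design of `n_init`, then rounds of `q` proposals
#' until `budget` evaluations) or plain random search -- on a freshly drawn
#' synthetic landscape per seed, and records for each seed the best-so-far
#' trace and the number of evaluations needed to reach
#' `(1 - epsilon) * objective_optimum` (`NA` when never reached within
#' budget; the reported median censors `NA` at `budget + 1`).
#'
#' @param optimizer `"random"` or an acquisition kind accepted by
#'   [acq_config()] (`"parallel_lcb"`, `"parallel_ei"`, `"lcb"`, `"ei"`).
#' @param objective factory `function(seed)` returning a `flowbo_objective`
#'   (default [make_flow_yield_objective()]); a fresh landscape per seed.
#' @param budget total evaluations per seed (default 33 = 6 + 9 rounds of 3).
#' @param n_seeds number of independent repetitions (default 20).
#' @param n_init initial design size for the BO loop (default 6).
#' @param config acquisition settings for the BO loop; `kind` and `seed` are
#'   overridden per run.
#' @param epsilon success threshold margin (default 0.05, i.e. 95% of the
#'   true optimum).
#' @param base_seed offset added to the per-repetition seeds.
#' @return an object of class `flowbo_evalreport`: `traces` (n_seeds x
#'   budget matrix), `evals_to_threshold`, `median_evals` (censored),
#'   `n_reached`, plus the run parameters.
#' @export
evaluate_optimizer <- function(optimizer, objective = make_flow_yield_objective,
                               budget = 33L, n_seeds = 20L, n_init = 6L,
                               config = acq_config(), epsilon = 0.05,
                               base_seed = 0L) {
  budget <- as.integer(budget); n_seeds <- as.integer(n_seeds)
  if (n_seeds < 1L) stopf("n_seeds must be >= 1")
  if (budget < n_init) stopf("budget (%d) must cover the initial design (%d)",
                             budget, n_init)
  traces <- matrix(NA_real_, nrow = n_seeds, ncol = budget)
  ett <- rep(NA_integer_, n_seeds)
  thresholds <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    seed_i <- as.integer(base_seed) + i
    obj <- objective(seed_i)
    if (!inherits(obj, "flowbo_objective"))
      stopf("objective factory must return a flowbo_objective")
    res <- tryCatch({
      if (identical(optimizer, "random")) {
        random_search(obj$space, obj, budget, seed = seed_i)
      } else {
        q <- config$batch_size
        rounds <- (budget - n_init) %/% q
        cfg <- acq_config(kind = optimizer, beta = config$beta, xi = config$xi,
                          batch_size = q, n_candidates = config$n_candidates,
                          refine_top = config$refine_top,
                          refine_maxit = config$refine_maxit, seed = seed_i)
        init <- init_design_lhs(obj$space, n_init, seed = seed_i)
        run_closed_loop(obj$space, obj, init, rounds, cfg)
      }
    }, error = function(e)
      stopf("optimizer '%s' failed on seed %d: %s", optimizer, seed_i,
            conditionMessage(e)))
    tr <- res$trace
    if (length(tr) < budget) tr <- c(tr, rep(tr[length(tr)], budget - length(tr)))
    traces[i, ] <- tr[seq_len(budget)]
    thr <- (1 - epsilon) * objective_optimum(obj)
    thresholds[i] <- thr
    hit <- which(tr[seq_len(budget)] >= thr)
    if (length(hit)) ett[i] <- hit[1L]
  }
  censored <- ifelse(is.na(ett), budget + 1L, ett)
  structure(
    list(optimizer = optimizer, budget = budget, n_seeds = n_seeds,
         n_init = n_init, epsilon = epsilon, base_seed = base_seed,
         traces = traces, evals_to_threshold = ett,
         thresholds = thresholds,
         median_evals = stats::median(censored),
         n_reached = sum(!is.na(ett))),
    class = "flowbo_evalreport"
  )
}

#' @export
print.flowbo_evalreport <- function(x, ...) {
  cat(sprintf("<flowbo_evalreport> %s: %d/%d seeds reached %.0f%% of optimum\n",
              x$optimizer, x$n_reached, x$n_seeds, 100 * (1 - x$epsilon)))
  cat(sprintf("  median evaluations to threshold (censored at %d): %g\n",
              x$budget + 1L, x$median_evals))
  cat(sprintf("  median final best yield: %.1f%%\n",
              stats::median(x$traces[, x$budget])))
  invisible(x)
}

# ---- packaged campaign fixtures ---------------------------------------------

fixture_md5 <- c(
  table1 = "d0a4b5e03a4c953d7d6ff7143bd8d5fb",
  table2 = "8d8fd36c8603977868a62bdbb0637fbf"
)

#' Load a packaged screening-campaign transcription
#'
#' Two complete 15-experiment optimization campaigns for the organocatalytic
#' flow cross-coupling ship with the package: `table1` (iminoquinone
#' monoacetal + 2-naphthol; six initial screening experiments followed by
#' three BO rounds of three, best NMR yield 96%) and `table2` (quinone
#' monoacetal + 5-bromoresorcinol under the same initial conditions, best
#' 69%). Entries 1-6 of both campaigns are the shared initial design. An MD5
#' checksum guards against accidental edits of the fixture files.
#'
#' @param name `"table1"` or `"table2"`.
#' @param space the space to validate against (default [widened_space()];
#'   several BO-suggested conditions extrapolate beyond the announced
#'   screening ranges, so the screening-range space rejects them).
#' @return data.frame of 15 validated experiment records.
#' @export
load_fixture <- function(name = c("table1", "table2"), space = widened_space()) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "flowbo")
  if (!nzchar(path) || !file.exists(path))
    stopf("packaged fixture '%s' not found", name)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(fixture_md5[name])))
    stopf("fixture '%s' failed its checksum (%s): file corrupted or edited",
          name, md5)
  read_records(path, space = space)
}

#' Per-round replay statistics of a campaign
#'
#' Summarizes a recorded campaign round by round: the maximum yield within
#' each round's entries and the running best, plus the overall best
#' condition. The default partition is the packaged campaign structure --
#' six initial experiments, then three rounds of three proposals.
#'
#' @param records data.frame of experiment records (needs `entry` and
#'   `yield_pct`).
#' @param rounds_partition list of integer vectors of entry numbers; must
#'   cover all record entries disjointly.
#' @return an object of class `flowbo_replay`: data.frame `summary` (round,
#'   entries, max_yield, best_so_far), `best_yield`, `best_entry`, and the
#'   `best_condition` row.
#' @export
replay_stats <- function(records,
                         rounds_partition = list(1:6, 7:9, 10:12, 13:15)) {
  if (!all(c("entry", "yield_pct") %in% names(records)))
    stopf("records need 'entry' and 'yield_pct' columns")
  entries <- as.integer(records$entry)
  part <- lapply(rounds_partition, as.integer)
  flat <- unlist(part)
  if (anyDuplicated(flat))
    stopf("rounds partition has overlapping entries (%d)",
          flat[duplicated(flat)][1L])
  if (!setequal(flat, entries))
    stopf("rounds partition does not cover the record entries exactly")
  max_yield <- vapply(part, function(e)
    max(records$yield_pct[entries %in% e], na.rm = TRUE), numeric(1))
  summary <- data.frame(
    round = seq_along(part) - 1L,
    entries = vapply(part, function(e) paste0(min(e), "-", max(e)), ""),
    max_yield = max_yield,
    best_so_far = cummax(max_yield)
  )
  best_i <- which.max(records$yield_pct)
  structure(
    list(summary = summary,
         best_yield = records$yield_pct[best_i],
         best_entry = entries[best_i],
         best_condition = records[best_i, , drop = FALSE]),
    class = "flowbo_replay"
  )
}

#' @export
print.flowbo_replay <- function(x, ...) {
  cat("<flowbo_replay>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("  overall best: %g%% (entry %d)\n", x$best_yield, x$best_entry))
  invisible(x)
}
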