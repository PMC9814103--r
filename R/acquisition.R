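# Acquisition functions (confidence-bound, expected improvement), batch
# proposals by sequential hallucination (kriging believer), and the round
# based campaign loop: propose -> run experiments -> append -> refit.

#' Confidence-bound acquisition on a maximized yield
#'
#' The campaign maximizes yield, so the "lower confidence bound" of the
#' negated objective is the optimistic bound `mean + beta * sd` on yield;
#' larger is more promising. `beta = 0` is pure exploitation of the posterior
#' mean.
#'
#' @param mean,sd posterior mean and standard deviation (yield %); vectors
#'   are accepted and recycled together. `sd` must be non-negative.
#' @param beta exploration weight, `>= 0` (default 2).
#' @return acquisition value(s), same length as the inputs.
#' @export
acq_lcb <- function(mean, sd, beta = 2) {
  if (any(sd < 0)) stopf("sd must be non-negative")
  if (beta < 0) stopf("beta must be non-negative")
  mean + beta * sd
}

#' Expected-improvement acquisition
#'
#' Expected amount by which the yield at a candidate exceeds
#' `best_observed + xi` under the Gaussian posterior. Zero when `sd = 0` and
#' the mean does not beat the margin.
#'
#' @param mean,sd posterior mean and standard deviation (yield %); `sd >= 0`.
#' @param best_observed incumbent best observed yield.
#' @param xi improvement margin, `>= 0` (default 0).
#' @return expected improvement value(s).
#' @export
acq_ei <- function(mean, sd, best_observed, xi = 0) {
  if (any(sd < 0)) stopf("sd must be non-negative")
  if (xi < 0) stopf("xi must be non-negative")
  gap <- mean - best_observed - xi
  out <- pmax(gap, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- gap[pos] / sd[pos]
    out[pos] <- gap[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  out
}

#' Acquisition / batch configuration
#'
#' @param kind one of `"parallel_lcb"` (default), `"parallel_ei"`, `"lcb"`,
#'   `"ei"`. The `parallel_*` kinds hallucinate a posterior-mean observation
#'   at each selected batch point before choosing the next (kriging
#'   believer); the single kinds select the batch from one acquisition
#'   surface with deduplication only.
#' @param beta exploration weight for confidence-bound kinds (default 2).
#' @param xi margin for expected-improvement kinds (default 0).
#' @param batch_size number of conditions proposed per round, `q >= 1`
#'   (default 3).
#' @param n_candidates size of the relaxed-space candidate pool per batch
#'   slot (default 4096).
#' @param refine_top how many top pool candidates get local L-BFGS-B
#'   refinement (default 10).
#' @param refine_maxit iteration cap of each local refinement (default 25).
#' @param seed integer seed; all batch randomness derives from it.
#' @return an object of class `flowbo_acq_config`.
#' @export
acq_config <- function(kind = c("parallel_lcb", "parallel_ei", "lcb", "ei"),
                       beta = 2, xi = 0, batch_size = 3L,
                       n_candidates = 4096L, refine_top = 10L,
                       refine_maxit = 25L, seed = 1L) {
  kind <- match.arg(kind)
  if (beta < 0) stopf("beta must be >= 0")
  if (xi < 0) stopf("xi must be >= 0")
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L) stopf("batch_size must be >= 1")
  structure(
    list(kind = kind, beta = beta, xi = xi, batch_size = batch_size,
         n_candidates = as.integer(n_candidates),
         refine_top = as.integer(refine_top),
         refine_maxit = as.integer(refine_maxit),
         seed = as.integer(seed)),
    class = "flowbo_acq_config"
  )
}

# ---- campaign records -------------------------------------------------------

# A campaign history is a data.frame: entry, one column per space parameter,
# residence_min (derived, NA when the space has no mixer/flow pairing),
# yield_pct, note.

record_columns <- function(space) {
  c("entry", param_names(space), "residence_min", "yield_pct", "note")
}

derived_residence <- function(space, cond) {
  if (!("mixer" %in% param_names(space)) ||
      !("flow_ml_min" %in% param_names(space)) ||
      is.null(space$mixers)) return(NA_real_)
  m <- lookup_mixer(space, cond$mixer)
  if (is.null(m)) return(NA_real_)
  residence_time(m, cond$flow_ml_min)
}

records_frame <- function(space, conds, yields = NULL, entries = NULL,
                          notes = NULL) {
  n <- length(conds)
  if (is.null(entries)) entries <- seq_len(n)
  if (is.null(yields)) yields <- rep(NA_real_, n)
  if (is.null(notes)) notes <- rep("", n)
  cols <- list(entry = as.integer(entries))
  for (p in space$params) {
    vals <- lapply(conds, function(cc) cc[[p$name]])
    cols[[p$name]] <- if (p$type == "continuous") as.numeric(unlist(vals))
                      else as.character(unlist(vals))
  }
  cols$residence_min <- vapply(conds, function(cc)
    derived_residence(space, cc), numeric(1))
  cols$yield_pct <- as.numeric(yields)
  cols$note <- as.character(notes)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Extract conditions from a campaign history
#'
#' @param space a `flowbo_space`.
#' @param records data.frame with one column per space parameter.
#' @return list of conditions (named lists), one per row.
#' @export
conditions_from_records <- function(space, records) {
  nm <- param_names(space)
  miss <- setdiff(nm, names(records))
  if (length(miss)) stopf("records are missing column '%s'", miss[1L])
  lapply(seq_len(nrow(records)), function(i)
    validate_condition(space, as.list(records[i, nm, drop = FALSE])))
}

#' Start a campaign
#'
#' @param space a `flowbo_space`.
#' @param records optional data.frame of already-run experiments (one column
#'   per parameter plus `yield_pct`; `entry`, `residence_min` and `note` are
#'   filled in if absent). Yields must lie in \[0, 100\].
#' @param config an [acq_config()].
#' @return an object of class `flowbo_campaign` with fields `space`,
#'   `history`, `round`, `config`.
#' @export
new_campaign <- function(space, records = NULL, config = acq_config()) {
  if (!inherits(space, "flowbo_space")) stopf("space must be a flowbo_space")
  if (!inherits(config, "flowbo_acq_config")) stopf("config must be an acq_config()")
  if (is.null(records)) {
    history <- records_frame(space, list())[0, ]
  } else {
    conds <- conditions_from_records(space, records)
    yields <- if ("yield_pct" %in% names(records)) as.numeric(records$yield_pct)
              else rep(NA_real_, length(conds))
    bad <- which(!is.na(yields) & (yields < 0 | yields > 100))
    if (length(bad))
      stopf("row %d: yield_pct %g outside [0, 100]", bad[1L], yields[bad[1L]])
    entries <- if ("entry" %in% names(records)) as.integer(records$entry)
               else seq_along(conds)
    if (anyDuplicated(entries)) stopf("duplicate entry number %d",
                                      entries[duplicated(entries)][1L])
    notes <- if ("note" %in% names(records)) as.character(records$note)
             else NULL
    history <- records_frame(space, conds, yields, entries, notes)
  }
  structure(list(space = space, history = history, round = 0L,
                 config = config),
            class = "flowbo_campaign")
}

#' @export
print.flowbo_campaign <- function(x, ...) {
  cat(sprintf("<flowbo_campaign> %d experiments, round %d, acquisition %s (q = %d)\n",
              nrow(x$history), x$round, x$config$kind, x$config$batch_size))
  if (nrow(x$history) && any(!is.na(x$history$yield_pct)))
    cat(sprintf("  best observed yield: %g%%\n",
                max(x$history$yield_pct, na.rm = TRUE)))
  invisible(x)
}

# Fit the surrogate on the campaign history (deterministic given state).
fit_surrogate <- function(state, seed = NULL) {
  h <- state$history
  h <- h[!is.na(h$yield_pct), , drop = FALSE]
  if (nrow(h) < 2L)
    stopf("campaign has %d completed experiments; need >= 2 to fit", nrow(h))
  X <- encode_conditions(state$space, conditions_from_records(state$space, h))
  gp_fit(X, h$yield_pct,
         seed = seed %||% derive_seed(state$config$seed, state$round, 1L))
}

acq_eval <- function(model, X, config, best_observed) {
  p <- gp_predict_fast(model, X)
  switch(config$kind,
         parallel_lcb = ,
         lcb = acq_lcb(p$mean, p$sd, config$beta),
         parallel_ei = ,
         ei = acq_ei(p$mean, p$sd, best_observed, config$xi))
}

# Vectorized decode -> lab-grid snap -> vertex re-encode of a whole matrix of
# relaxed candidates. Matrix-level fast path of decode_vector() +
# snap_to_lab_grid() + encode_condition(); candidates are in [0,1] by
# construction so no per-row validation is needed.
snap_encode_batch <- function(space, Xrel) {
  m <- nrow(Xrel)
  Xv <- matrix(0, nrow = m, ncol = space$encoded_dim)
  native <- vector("list", length(space$params))
  names(native) <- param_names(space)
  key_parts <- vector("list", length(space$params))
  for (pi in seq_along(space$params)) {
    p <- space$params[[pi]]
    cols <- space$layout[[p$name]]$cols
    if (p$type == "continuous") {
      u <- pmin(pmax(Xrel[, cols], 0), 1)
      v <- p$low + u * (p$high - p$low)
      v <- pmin(pmax(round(v / p$precision) * p$precision, p$low), p$high)
      native[[pi]] <- v
      Xv[, cols] <- (v - p$low) / (p$high - p$low)
      key_parts[[pi]] <- sprintf("%.9g", round(v, 9))
    } else {
      idx <- max.col(Xrel[, cols, drop = FALSE], ties.method = "first")
      native[[pi]] <- p$choices[idx]
      Xv[cbind(seq_len(m), cols[idx])] <- 1
      key_parts[[pi]] <- native[[pi]]
    }
  }
  keys <- do.call(paste, c(key_parts, sep = "|"))
  list(Xv = Xv, keys = keys, native = native)
}

# Local refinement of one relaxed candidate: projected gradient ascent on the
# acquisition with batched central-difference gradients (one vectorized
# posterior evaluation per step), box-clipped to [0, 1]. Deterministic.
refine_candidate <- function(m, cfg, best_observed, x0, f0 = NULL,
                             h = 1e-3) {
  D <- length(x0)
  x <- x0
  fx <- f0 %||% acq_eval(m, matrix(x, nrow = 1L), cfg, best_observed)
  step <- 0.05
  for (it in seq_len(cfg$refine_maxit)) {
    P <- matrix(rep(x, each = 2L * D), nrow = 2L * D)
    idx <- rep(seq_len(D), each = 2L)
    P[cbind(seq_len(2L * D), idx)] <-
      P[cbind(seq_len(2L * D), idx)] + rep(c(h, -h), D)
    fp <- acq_eval(m, pmin(pmax(P, 0), 1), cfg, best_observed)
    g <- (fp[seq(1L, 2L * D, by = 2L)] - fp[seq(2L, 2L * D, by = 2L)]) / (2 * h)
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-12) break
    x1 <- pmin(pmax(x + step * g / gn, 0), 1)
    f1 <- acq_eval(m, matrix(x1, nrow = 1L), cfg, best_observed)
    if (f1 > fx) {
      x <- x1; fx <- f1; step <- min(step * 1.5, 0.25)
    } else {
      step <- step / 2
      if (step < 1e-4) break
    }
  }
  x
}

#' Propose the next batch of conditions
#'
#' Selects `q = batch_size` conditions sequentially. Each slot maximizes the
#' acquisition over a seeded pool of relaxed encoded candidates (uniform in
#' the unit cube over continuous and one-hot dimensions) plus local L-BFGS-B
#' refinement of the top pool points; every candidate is then decoded by
#' nearest-vertex rounding, snapped to the laboratory precision grid, and
#' ranked by its acquisition value at the snapped vertex encoding. Conditions
#' equal (after snapping) to any history point or to an earlier batch slot
#' are skipped. For the `parallel_*` kinds the surrogate is then conditioned
#' on a hallucinated posterior-mean observation at the selected point
#' (kriging believer) before the next slot is chosen, so pending batch
#' members repel each other through shrunken variance.
#'
#' @param state a `flowbo_campaign` whose history holds the experiments the
#'   model was fitted on.
#' @param model a fitted `flowbo_gp`; when `NULL`, fitted from the state's
#'   completed history with a seed derived from the config seed and round.
#' @return an object of class `flowbo_proposal`: fields `round`,
#'   `conditions` (list of q snapped conditions), `acq_values`, and
#'   `provenance` (config echo, seeds, fitted hyperparameters).
#' @export
propose_batch <- function(state, model = NULL) {
  if (!inherits(state, "flowbo_campaign")) stopf("state must be a flowbo_campaign")
  cfg <- state$config
  space <- state$space
  if (nrow(state$history) == 0L) stopf("cannot propose from an empty history")
  if (is.null(model)) model <- fit_surrogate(state)
  if (!inherits(model, "flowbo_gp")) stopf("model must be a fitted flowbo_gp")
  D <- encoded_dim(space)
  if (ncol(model$X) != D) stopf("model dimension %d does not match space (%d)",
                                ncol(model$X), D)

  obs <- state$history$yield_pct
  best_observed <- if (all(is.na(obs))) -Inf else max(obs, na.rm = TRUE)
  hist_keys <- vapply(conditions_from_records(space, state$history),
                      function(cc) condition_key(space, snap_to_lab_grid(space, cc)),
                      "")

  chosen <- list()
  chosen_keys <- character(0)
  acq_values <- numeric(0)
  m <- model

  for (s in seq_len(cfg$batch_size)) {
    slot_seed <- derive_seed(cfg$seed, state$round + 1L, s)
    Xc <- with_seed(slot_seed,
                    matrix(stats::runif(cfg$n_candidates * D), ncol = D))
    av <- acq_eval(m, Xc, cfg, best_observed)
    n_ref <- min(cfg$refine_top, nrow(Xc))
    top <- order(av, decreasing = TRUE)[seq_len(n_ref)]
    refined <- lapply(top, function(i)
      refine_candidate(m, cfg, best_observed, Xc[i, ], av[i]))
    Xall <- rbind(Xc, do.call(rbind, refined))
    sb <- snap_encode_batch(space, Xall)
    keep <- which(!duplicated(sb$keys))
    keys <- sb$keys[keep]
    Xv <- sb$Xv[keep, , drop = FALSE]
    av2 <- acq_eval(m, Xv, cfg, best_observed)
    sel <- NA_integer_
    for (j in order(av2, decreasing = TRUE)) {
      if (!(keys[j] %in% hist_keys) && !(keys[j] %in% chosen_keys)) {
        sel <- j; break
      }
    }
    if (is.na(sel))
      stopf(paste0("batch slot %d: every candidate grid point duplicates the ",
                   "history or the growing batch (design space exhausted?)"), s)
    row <- keep[sel]
    cond_sel <- lapply(sb$native, function(col) col[row])
    chosen[[s]] <- validate_condition(space, cond_sel)
    chosen_keys <- c(chosen_keys, keys[sel])
    acq_values <- c(acq_values, av2[sel])
    if (cfg$kind %in% c("parallel_lcb", "parallel_ei") && s < cfg$batch_size) {
      xsel <- Xv[sel, , drop = FALSE]
      mu <- gp_predict(m, xsel)$mean
      m <- gp_augment(m, xsel, mu)
    }
  }

  structure(
    list(round = state$round + 1L, conditions = chosen,
         acq_values = acq_values,
         provenance = list(config = unclass(cfg), seed = cfg$seed,
                           kernel = model$kernel,
                           n_train = model$n)),
    class = "flowbo_proposal"
  )
}

#' @export
print.flowbo_proposal <- function(x, ...) {
  cat(sprintf("<flowbo_proposal> round %d, %d conditions\n",
              x$round, length(x$conditions)))
  for (i in seq_along(x$conditions)) {
    cc <- x$conditions[[i]]
    cat(sprintf("  %d. %s  (acq %.2f)\n", i,
                paste(names(cc), vapply(cc, function(v) format(v, digits = 4), ""),
                      sep = "=", collapse = " "),
                x$acq_values[i]))
  }
  invisible(x)
}

#' Convert a proposal to the record-table schema
#'
#' @param state the campaign the proposal was made for.
#' @param proposal a `flowbo_proposal`.
#' @return data.frame in the campaign record schema plus `acq_value` and
#'   `round`; `yield_pct` is `NA` (pending).
#' @export
proposal_to_records <- function(state, proposal) {
  n_prev <- nrow(state$history)
  start <- if (n_prev) max(state$history$entry) else 0L
  df <- records_frame(state$space, proposal$conditions,
                      entries = start + seq_along(proposal$conditions))
  df$acq_value <- proposal$acq_values
  df$round <- proposal$round
  df
}

#' Record the observed yields of a proposed batch
#'
#' Appends one experiment record per proposed condition and advances the
#' round counter.
#'
#' @param state a `flowbo_campaign`.
#' @param proposal the `flowbo_proposal` that was run.
#' @param observed_yields numeric vector, one yield in \[0, 100\] per
#'   proposed condition (order preserved).
#' @param notes optional character vector of free-text notes.
#' @return the updated `flowbo_campaign`.
#' @export
advance_round <- function(state, proposal, observed_yields, notes = NULL) {
  if (!inherits(state, "flowbo_campaign")) stopf("state must be a flowbo_campaign")
  if (!inherits(proposal, "flowbo_proposal")) stopf("proposal must be a flowbo_proposal")
  q <- length(proposal$conditions)
  if (q == 0L) stopf("empty proposal: nothing to record")
  observed_yields <- as.numeric(observed_yields)
  if (length(observed_yields) != q)
    stopf("got %d yields for %d proposed conditions", length(observed_yields), q)
  if (any(!is.finite(observed_yields)))
    stopf("observed yields must be finite")
  bad <- which(observed_yields < 0 | observed_yields > 100)
  if (length(bad))
    stopf("yield %g (position %d) outside [0, 100]",
          observed_yields[bad[1L]], bad[1L])
  n_prev <- nrow(state$history)
  start <- if (n_prev) max(state$history$entry) else 0L
  newrec <- records_frame(state$space, proposal$conditions, observed_yields,
                          entries = start + seq_len(q), notes = notes)
  state$history <- rbind(state$history, newrec)
  state$round <- state$round + 1L
  state
}

#' Save / load a campaign state file
#'
#' The state (space declaration, history, round counter, acquisition config)
#' is written as versioned JSON; reloading is lossless, so a resumed campaign
#' proposes identical batches from the same seed.
#'
#' @param state a `flowbo_campaign`.
#' @param path file path.
#' @return `save_campaign()` returns `path` invisibly; `load_campaign()` the
#'   restored `flowbo_campaign`.
#' @export
save_campaign <- function(state, path) {
  if (!inherits(state, "flowbo_campaign")) stopf("state must be a flowbo_campaign")
  obj <- list(schema = "flowbo_campaign/1",
              space = space_to_list(state$space),
              history = state$history,
              round = state$round,
              config = unclass(state$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_campaign
#' @export
load_campaign <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "flowbo_campaign/1"))
    stopf("not a flowbo campaign file: %s", path)
  space <- space_from_list(obj$space)
  cfg <- obj$config
  config <- acq_config(kind = cfg$kind, beta = cfg$beta, xi = cfg$xi,
                       batch_size = cfg$batch_size,
                       n_candidates = cfg$n_candidates,
                       refine_top = cfg$refine_top,
                       refine_maxit = cfg$refine_maxit, seed = cfg$seed)
  history <- if (length(obj$history) == 0L) NULL else {
    do.call(rbind, lapply(obj$history, function(row) {
      row <- lapply(row, function(v) if (is.null(v)) NA else v)
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
  }
  state <- new_campaign(space, history, config)
  state$round <- as.integer(obj$round)
  state
}

#' Seeded space-filling initial design
#'
#' Maximin Latin-hypercube sample over the continuous dimensions (snapped to
#' the lab grid) with balanced coverage of every categorical choice, shuffled
#' deterministically. This mirrors starting a campaign from a handful of
#' spread-out screening experiments covering each reactor type.
#'
#' @param space a `flowbo_space`.
#' @param n number of conditions.
#' @param seed integer seed.
#' @return data.frame of `n` conditions (one column per parameter).
#' @export
init_design_lhs <- function(space, n, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stopf("initial design size must be >= 1")
  types <- vapply(space$params, function(p) p$type, "")
  cont <- space$params[types == "continuous"]
  cats <- space$params[types == "categorical"]
  with_seed(derive_seed(seed, 3L), {
    U <- if (length(cont)) lhs::maximinLHS(n, length(cont)) else NULL
    conds <- lapply(seq_len(n), function(i) {
      cc <- list()
      for (j in seq_along(cont)) {
        p <- cont[[j]]
        cc[[p$name]] <- p$low + U[i, j] * (p$high - p$low)
      }
      cc
    })
    for (p in cats) {
      lev <- rep_len(p$choices, n)
      lev <- sample(lev)
      for (i in seq_len(n)) conds[[i]][[p$name]] <- lev[i]
    }
    conds <- lapply(conds, function(cc) snap_to_lab_grid(space, cc))
    do.call(rbind, lapply(conds, function(cc)
      as.data.frame(cc, stringsAsFactors = FALSE)))
  })
}

#' Run a simulated closed-loop campaign
#'
#' Executes the propose / evaluate / append cycle against an in-silico
#' objective: evaluate the initial design, then `rounds` times fit the
#' surrogate, propose a batch, evaluate it, and append. This is the
#' computational stand-in for the human-executed loop of a real screening
#' campaign.
#'
#' @param space a `flowbo_space`.
#' @param objective a `flowbo_objective` (see
#'   [make_flow_yield_objective()]) or any `function(condition)` returning a
#'   yield in \[0, 100\].
#' @param init_design data.frame or list of initial conditions.
#' @param rounds number of proposal rounds (0 = evaluate the design only).
#' @param config an [acq_config()].
#' @return list with the final `state`, the per-evaluation `yields`, and the
#'   monotone best-so-far `trace`.
#' @export
run_closed_loop <- function(space, objective, init_design, rounds,
                            config = acq_config()) {
  rounds <- as.integer(rounds)
  if (rounds < 0L) stopf("rounds must be >= 0")
  evalfun <- if (inherits(objective, "flowbo_objective")) {
    function(cc) eval_objective(objective, cc)
  } else if (is.function(objective)) {
    objective
  } else stopf("objective must be a flowbo_objective or a function")

  if (is.data.frame(init_design)) {
    init_design <- lapply(seq_len(nrow(init_design)), function(i)
      as.list(init_design[i, , drop = FALSE]))
  }
  if (length(init_design) == 0L) stopf("init_design must be nonempty")
  init_design <- lapply(init_design, function(cc) validate_condition(space, cc))
  y0 <- vapply(init_design, function(cc) {
    v <- tryCatch(evalfun(cc), error = function(e)
      stopf("objective evaluation failed on the initial design: %s",
            conditionMessage(e)))
    as.numeric(v)
  }, numeric(1))
  state <- new_campaign(space, records_frame(space, init_design, y0), config)
  for (r in seq_len(rounds)) {
    model <- fit_surrogate(state)
    prop <- propose_batch(state, model)
    ys <- vapply(prop$conditions, function(cc) {
      tryCatch(as.numeric(evalfun(cc)), error = function(e)
        stopf("objective evaluation failed in round %d: %s", r,
              conditionMessage(e)))
    }, numeric(1))
    state <- advance_round(state, prop, ys)
  }
  yields <- state$history$yield_pct
  list(state = state, yields = yields, trace = cummax(yields))
}
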