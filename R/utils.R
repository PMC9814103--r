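# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores whatever stream was active before. All randomness in the package
#' flows through this helper so that every operation is reproducible from the
#' seeds recorded in its provenance.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a sub-seed from a base seed and small indices, kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed)
  for (k in seq_along(idx)) s <- (s * 7919 + idx[k] * 104729 + k) %% 2147483587
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
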