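# Gaussian-process regression surrogate over the encoded design space.
# Matern-5/2 ARD kernel, evidence (log marginal likelihood) maximization with
# seeded multi-restart L-BFGS-B, Cholesky solves with jitter escalation.

SQRT5 <- sqrt(5)

# Matern-5/2 ARD covariance between the rows of X1 and X2 (no noise term).
kernel_matern52 <- function(X1, X2, lengthscales, signal_var) {
  A <- sweep(X1, 2, lengthscales, "/")
  B <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 0))
  signal_var * (1 + SQRT5 * r + 5 * r^2 / 3) * exp(-SQRT5 * r)
}

# Cholesky with additive jitter escalation 1e-10 -> 1e-6 (standardized units).
chol_with_jitter <- function(K) {
  for (j in c(0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6)) {
    U <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = j))
  }
  stopf(paste0("kernel matrix is not positive definite even after jitter ",
               "escalation to 1e-6; check for duplicated rows with ",
               "conflicting responses or degenerate lengthscales"))
}

#' Construct a GP surrogate with given hyperparameters
#'
#' Builds the cached Cholesky solve for a Matern-5/2 ARD Gaussian process with
#' fixed hyperparameters. Responses are standardized to mean 0 / sd 1 inside
#' the model (`y_stats` overrides the standardization frame, which is how
#' hallucinated batch points are added without shifting the frame mid-batch).
#' Use [gp_fit()] to select hyperparameters by evidence maximization.
#'
#' @param X numeric matrix of encoded inputs (n x encoded_dim).
#' @param y numeric vector of responses in native units (yield %).
#' @param lengthscales positive ARD lengthscale per encoded dimension
#'   (unit-cube scale).
#' @param signal_var,noise_var positive signal / noise variances in
#'   standardized response units.
#' @param y_stats optional `list(mean =, sd =)` fixing the standardization.
#' @return an object of class `flowbo_gp`.
#' @export
gp_model <- function(X, y, lengthscales, signal_var, noise_var,
                     y_stats = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 1L || length(y) != n) stopf("X and y sizes disagree (%d rows, %d responses)", n, length(y))
  if (any(!is.finite(X))) stopf("X contains non-finite values")
  if (any(!is.finite(y))) stopf("y contains non-finite values")
  d <- ncol(X)
  lengthscales <- rep_len(as.numeric(lengthscales), d)
  if (any(lengthscales <= 0) || signal_var <= 0 || noise_var < 0)
    stopf("kernel hyperparameters must be positive")
  if (is.null(y_stats)) {
    y_mean <- mean(y)
    y_sd <- stats::sd(y)
    # constant responses: unit frame avoids division by zero
    if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  } else {
    y_mean <- y_stats$mean; y_sd <- y_stats$sd
  }
  ys <- (y - y_mean) / y_sd
  K <- kernel_matern52(X, X, lengthscales, signal_var) + diag(noise_var, n)
  ch <- chol_with_jitter(K)
  U <- ch$U
  alpha <- backsolve(U, backsolve(U, ys, transpose = TRUE))
  lml <- -0.5 * sum(ys * alpha) - sum(log(diag(U))) - n / 2 * log(2 * pi)
  structure(
    list(X = X, y = y, ys = ys, y_mean = y_mean, y_sd = y_sd, n = n,
         kernel = list(family = "matern52", lengthscales = lengthscales,
                       signal_var = signal_var, noise_var = noise_var),
         U = U, alpha = alpha, jitter = ch$jitter, lml = lml),
    class = "flowbo_gp"
  )
}

#' @export
print.flowbo_gp <- function(x, ...) {
  k <- x$kernel
  cat(sprintf("<flowbo_gp> Matern-5/2 ARD, n = %d, d = %d\n", x$n, ncol(x$X)))
  cat(sprintf("  signal_var %.4g  noise_var %.4g  log evidence %.3f\n",
              k$signal_var, k$noise_var, x$lml))
  cat("  lengthscales:", paste(sprintf("%.3g", k$lengthscales), collapse = " "), "\n")
  invisible(x)
}

#' Fit a GP surrogate by evidence maximization
#'
#' Selects Matern-5/2 ARD hyperparameters by maximizing the log marginal
#' likelihood of the standardized responses with multi-restart L-BFGS-B in
#' log-hyperparameter space. The first start is a fixed default (lengthscales
#' 0.5, signal variance 1, noise 0.01); the remaining restarts are seeded
#' log-uniform draws within the bounds, so the fit is deterministic given
#' (data, seed).
#'
#' @param X numeric matrix of encoded inputs, at least 2 rows.
#' @param y numeric responses in native units (yield %).
#' @param seed integer seed for the restarts.
#' @param n_restarts number of optimizer starts (>= 1, default 5).
#' @param lengthscale_bounds,signal_bounds,noise_bounds box constraints for
#'   the hyperparameters, on the unit-cube / standardized scale. The noise
#'   lower bound acts as the noise floor (default 1e-6).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return a fitted `flowbo_gp` with field `fit` recording the optimization.
#' @export
gp_fit <- function(X, y, seed = 1L, n_restarts = 5L,
                   lengthscale_bounds = c(1e-2, 10),
                   signal_bounds = c(1e-2, 1e2),
                   noise_bounds = c(1e-6, 1),
                   maxit = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stopf("GP fitting needs at least 2 observations (got %d)", n)
  if (length(y) != n) stopf("X and y sizes disagree")
  if (any(!is.finite(y))) stopf("y contains non-finite values")
  if (any(!is.finite(X))) stopf("X contains non-finite values")
  d <- ncol(X)

  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  lower <- log(c(rep(lengthscale_bounds[1], d), signal_bounds[1], noise_bounds[1]))
  upper <- log(c(rep(lengthscale_bounds[2], d), signal_bounds[2], noise_bounds[2]))

  neg_lml <- function(theta) {
    ls <- exp(theta[seq_len(d)])
    sf2 <- exp(theta[d + 1L])
    sn2 <- exp(theta[d + 2L])
    K <- kernel_matern52(X, X, ls, sf2) + diag(sn2, n)
    ch <- tryCatch(chol_with_jitter(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    U <- ch$U
    a <- backsolve(U, backsolve(U, ys, transpose = TRUE))
    val <- 0.5 * sum(ys * a) + sum(log(diag(U))) + n / 2 * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- list(pmin(pmax(log(c(rep(0.5, d), 1, 1e-2)), lower), upper))
  if (n_restarts > 1L) {
    extra <- with_seed(derive_seed(seed, 17L), {
      lapply(seq_len(n_restarts - 1L), function(i)
        stats::runif(d + 2L, lower, upper))
    })
    starts <- c(starts, extra)
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, neg_lml, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stopf("all hyperparameter optimization restarts failed")

  th <- best$par
  model <- gp_model(X, y,
                    lengthscales = exp(th[seq_len(d)]),
                    signal_var = exp(th[d + 1L]),
                    noise_var = exp(th[d + 2L]),
                    y_stats = list(mean = y_mean, sd = y_sd))
  model$fit <- list(seed = seed, n_restarts = n_restarts,
                    neg_lml = best$value, convergence = best$convergence)
  model
}

# Hot-path posterior evaluation: list(mean, sd) without data.frame overhead.
gp_predict_fast <- function(model, Xstar) {
  k <- model$kernel
  Ks <- kernel_matern52(model$X, Xstar, k$lengthscales, k$signal_var)
  mean_s <- drop(crossprod(Ks, model$alpha))
  V <- backsolve(model$U, Ks, transpose = TRUE)
  var_s <- pmax(k$signal_var - colSums(V^2), 0)
  list(mean = mean_s * model$y_sd + model$y_mean,
       sd = sqrt(var_s) * model$y_sd)
}

#' GP posterior prediction
#'
#' Exact posterior mean and standard deviation of the latent yield surface at
#' new encoded points, destandardized to native units (yield %). Numerical
#' round-off can make the posterior variance marginally negative; it is
#' clamped at zero and the clamping is recorded in attribute `"n_clamped"`.
#'
#' @param model a `flowbo_gp`.
#' @param Xstar encoded matrix (m x encoded_dim) or a single encoded vector.
#' @return data.frame with columns `mean` and `sd` (one row per input point).
#' @export
gp_predict <- function(model, Xstar) {
  if (!inherits(model, "flowbo_gp")) stopf("model must be a flowbo_gp")
  if (is.null(dim(Xstar))) Xstar <- matrix(Xstar, nrow = 1L)
  Xstar <- as.matrix(Xstar)
  if (ncol(Xstar) != ncol(model$X))
    stopf("prediction inputs have %d columns, expected %d",
          ncol(Xstar), ncol(model$X))
  k <- model$kernel
  Ks <- kernel_matern52(model$X, Xstar, k$lengthscales, k$signal_var)
  mean_s <- drop(crossprod(Ks, model$alpha))
  V <- backsolve(model$U, Ks, transpose = TRUE)
  var_s <- k$signal_var - colSums(V^2)
  n_clamped <- sum(var_s < 0)
  var_s <- pmax(var_s, 0)
  out <- data.frame(mean = mean_s * model$y_sd + model$y_mean,
                    sd = sqrt(var_s) * model$y_sd)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Log marginal likelihood of a GP
#'
#' With only `model`, returns the evidence of the training data cached at
#' construction. With `X`/`y`, re-evaluates the evidence of that dataset under
#' the model's hyperparameters and standardization frame (used e.g. to score
#' alternative datasets under fixed kernel settings).
#'
#' @param model a `flowbo_gp`.
#' @param X,y optional alternative dataset.
#' @return the log marginal likelihood (standardized-response scale).
#' @export
gp_log_marginal_likelihood <- function(model, X = NULL, y = NULL) {
  if (!inherits(model, "flowbo_gp")) stopf("model must be a flowbo_gp")
  if (is.null(X) && is.null(y)) return(model$lml)
  if (is.null(X) || is.null(y)) stopf("provide both X and y, or neither")
  k <- model$kernel
  m <- gp_model(X, y, k$lengthscales, k$signal_var, k$noise_var,
                y_stats = list(mean = model$y_mean, sd = model$y_sd))
  m$lml
}

#' Condition a GP on additional observations without refitting
#'
#' Appends `(Xnew, ynew)` to the training set and rebuilds the cached solve
#' under the *same* hyperparameters and standardization frame. This is the
#' hallucination step of the kriging-believer batch construction: adding a
#' point can only shrink posterior variance, never change the kernel.
#'
#' @param model a `flowbo_gp`.
#' @param Xnew encoded matrix or single encoded vector of new inputs.
#' @param ynew responses in native units (for hallucination, the posterior
#'   mean at `Xnew`).
#' @return a new `flowbo_gp`.
#' @export
gp_augment <- function(model, Xnew, ynew) {
  if (!inherits(model, "flowbo_gp")) stopf("model must be a flowbo_gp")
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1L)
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(model$X))
    stopf("new inputs have %d columns, expected %d", ncol(Xnew), ncol(model$X))
  if (nrow(Xnew) != length(ynew)) stopf("Xnew and ynew sizes disagree")
  k <- model$kernel
  gp_model(rbind(model$X, Xnew), c(model$y, as.numeric(ynew)),
           k$lengthscales, k$signal_var, k$noise_var,
           y_stats = list(mean = model$y_mean, sd = model$y_sd))
}

#' Serialize / restore a fitted GP
#'
#' Writes the training data, hyperparameters and standardization frame to a
#' JSON file; `gp_load()` rebuilds the model (the Cholesky cache is
#' recomputed, so the round-trip is lossless for predictions).
#'
#' @param model a `flowbo_gp`.
#' @param path file path.
#' @return `gp_save()` returns `path` invisibly; `gp_load()` a `flowbo_gp`.
#' @export
gp_save <- function(model, path) {
  if (!inherits(model, "flowbo_gp")) stopf("model must be a flowbo_gp")
  k <- model$kernel
  obj <- list(schema = "flowbo_gp/1",
              X = unname(apply(model$X, 1, as.numeric, simplify = FALSE)),
              y = model$y,
              y_mean = model$y_mean, y_sd = model$y_sd,
              lengthscales = k$lengthscales, signal_var = k$signal_var,
              noise_var = k$noise_var)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gp_save
#' @export
gp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "flowbo_gp/1")) stopf("not a flowbo_gp file: %s", path)
  X <- if (is.list(obj$X)) do.call(rbind, obj$X) else as.matrix(obj$X)
  gp_model(X, obj$y, obj$lengthscales, obj$signal_var, obj$noise_var,
           y_stats = list(mean = obj$y_mean, sd = obj$y_sd))
}
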