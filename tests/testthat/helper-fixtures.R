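# Shared fixtures: small, fast phantoms and datasets built in code.

# Noise specification that disables speckle and additive noise entirely.
no_noise <- function() noise_spec(speckle_contrast = 0, snr_db = Inf)

# A phantom with configurable noise; defaults mirror the package defaults.
test_phantom <- function(noise = noise_spec(), gains = NULL, seed = 1L) {
  args <- list(noise = noise, seed = seed)
  if (!is.null(gains)) args$gains <- gains
  do.call(muscle_phantom, args)
}

# Small dataset: 3 trials x 3 s at 50 Hz (150 frames/trial) keeps module
# tests fast; acceptance tests use the full 5 s default.
small_dataset <- function(phantom = test_phantom(), seed = 1L, n_trials = 3,
                          duration_s = 3, force_noise_sd = 20) {
  generate_trial_dataset(
    phantom, n_trials = n_trials, duration_s = duration_s, ramp_s = 0.75,
    force_noise_sd = force_noise_sd, seed = seed)
}

# Brute-force loop oracle for the weighted mean depth (kept deliberately
# naive and separate from the implementation).
mean_depth_loop <- function(A, D) {
  num <- 0
  den <- 0
  for (i in seq_along(A)) {
    num <- num + A[i] * D[i]
    den <- den + A[i]
  }
  num / den
}

# Numeric minimizer of the penalized objective
# sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j b_j^2
# via BFGS with an analytic gradient: the independent oracle for fit_ridge.
ridge_objective_minimizer <- function(X, y, lambda) {
  obj <- function(par) {
    b0 <- par[1]
    b <- par[-1]
    r <- y - b0 - drop(X %*% b)
    sum(r^2) + lambda * sum(b^2)
  }
  grad <- function(par) {
    b0 <- par[1]
    b <- par[-1]
    r <- y - b0 - drop(X %*% b)
    c(-2 * sum(r), -2 * drop(crossprod(X, r)) + 2 * lambda * b)
  }
  fit <- stats::optim(numeric(ncol(X) + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  list(beta0 = fit$par[1], beta = fit$par[-1])
}
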