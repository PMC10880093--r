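# Shared fixtures and independent oracles for the test suite.
# Expensive fixtures are generated once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default study-condition cohort (20 participants, 3 repeats, both actions).
default_sim_cohort <- function(seed = 7)
  cached(paste0("cohort", seed), generate_cohort(seed = seed))

noise_free_effect <- function()
  effect_spec(noise_amp_pre = 0, noise_amp_post = 0, noise_amp_base = 0,
              range_shift_deg = 0, per_participant_sd = 0)

null_effect <- function()
  effect_spec(noise_amp_pre = 0.8, noise_amp_post = 0.8, range_shift_deg = 0)

# --- independent oracles -------------------------------------------------

# Angle between two 2D vectors via normalised dot product (independent of
# the law-of-cosines route used by the implementation).
oracle_angle_2d <- function(m, n) {
  acos(sum(m * n) / (sqrt(sum(m^2)) * sqrt(sum(n^2)))) * 180 / pi
}

# Brute-force finite differences with an explicit loop.
oracle_derivatives <- function(theta, dt) {
  omega <- numeric(length(theta) - 1L)
  for (i in seq_along(omega)) omega[i] <- (theta[i + 1L] - theta[i]) / dt
  alpha <- numeric(length(omega) - 1L)
  for (i in seq_along(alpha)) alpha[i] <- (omega[i + 1L] - omega[i]) / dt
  list(omega = omega, alpha = alpha)
}

# Brute-force trapezoidal integral of |alpha|.
oracle_trapz_abs <- function(alpha, dt) {
  a <- abs(alpha)
  total <- 0
  for (i in seq_len(length(a) - 1L))
    total <- total + (a[i] + a[i + 1L]) / 2 * dt
  total
}

# PCA importance by explicit eigendecomposition of the covariance matrix.
oracle_pca_importance <- function(M, n_components = 2L) {
  C <- stats::cov(scale(M, center = TRUE, scale = FALSE))
  e <- eigen(C, symmetric = TRUE)
  evr <- e$values[seq_len(n_components)] / sum(e$values)
  load <- e$vectors[, seq_len(n_components), drop = FALSE]
  imp <- as.vector(abs(load) %*% evr)
  stats::setNames(imp, colnames(M))
}
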