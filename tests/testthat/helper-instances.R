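# Shared generators for small reconstruction and frame instances.

# Jittered near-critical-unit locations with redundancy r over an n_t-point
# band; jitter_frac is the per-point jitter as a fraction of the spacing.
jittered_locations <- function(n_t, r, jitter_frac, seed) {
  withr::with_seed(seed, {
    n_f <- round(r * n_t)
    k <- sort((seq_len(n_f) - 1) / r +
      runif(n_f, -jitter_frac, jitter_frac) / r)
    k <- k - min(k)
    if (any(diff(k) < 1e-3)) k <- cumsum(c(0, pmax(diff(k), 1e-3)))
    if (max(k) >= n_t - 1e-6) k <- k / max(k) * (n_t - 0.6)
    k
  })
}

# Random small k-sample instance (values ~ circular complex normal).
jittered_instance <- function(n_t, r, jitter_frac, seed) {
  k <- jittered_locations(n_t, r, jitter_frac, seed)
  values <- withr::with_seed(
    seed + 1L,
    complex(real = rnorm(length(k)), imaginary = rnorm(length(k)))
  )
  k_sample_set(k, values, nyquist_interval = 1, n_out = n_t)
}

# Discrete analysis frame of the reconstruction model in natural depth
# order: row n is Lambda_n exp(-i kappa_n s) / sqrt(n_t); applying its
# pseudoinverse to the measured values (scaled by 1/sqrt(n_t)) is the
# dual-frame oracle the scaled NDFT approximates.
recon_frame <- function(samples, n_t) {
  gm <- map_k_to_grid(samples, n_t, mode = "nyquist", wrap = TRUE)
  kappa <- 2 * pi * gm$mapped / n_t
  lambda <- lambda_scales(gm$mapped, 1)
  rows <- lambda * exp(-1i * outer(kappa, seq_len(n_t) - 1)) / sqrt(n_t)
  frame_matrix(rows, lower_limit = 0.01, upper_limit = 4)
}

# Pseudoinverse oracle reconstruction in natural depth order.
pinv_reconstruction <- function(samples, n_t) {
  phi <- recon_frame(samples, n_t)
  as.vector(dual_frame_pinv(phi) %*% (samples$value / sqrt(n_t)))
}

# Irregular location set with a prescribed maximum gap delta (first gaps hit
# delta exactly so max Lambda^2 = delta/T).
irregular_locations <- function(delta, n = 40, seed = 1) {
  withr::with_seed(
    seed,
    cumsum(c(0, c(delta, delta, runif(n - 2, 0.55 * delta, delta))))
  )
}
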