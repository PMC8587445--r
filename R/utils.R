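# Internal helpers shared across modules.

# Round half away from zero, so gridding is platform-independent
# (base round() uses banker's rounding).
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Evaluate sin(pi x)/(pi x) with the removable singularity filled in.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > .Machine$double.eps
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

check_locations <- function(values, nyquist_interval, call = rlang::caller_env()) {
  if (!is.numeric(values) || length(values) < 3) {
    abort("`values` must be a numeric sequence of length >= 3.", call = call)
  }
  if (any(!is.finite(values))) {
    abort("Sample locations must be finite.", call = call)
  }
  if (any(diff(values) <= 0)) {
    abort("Sample locations must be strictly increasing.", call = call)
  }
  if (!is.numeric(nyquist_interval) || length(nyquist_interval) != 1 ||
      !is.finite(nyquist_interval) || nyquist_interval <= 0) {
    abort("`nyquist_interval` must be a single positive number.", call = call)
  }
  invisible(values)
}

# Complex circular white noise with total per-sample variance sigma2.
rcnorm <- function(n, sigma2 = 1) {
  sd1 <- sqrt(sigma2 / 2)
  complex(real = rnorm(n, sd = sd1), imaginary = rnorm(n, sd = sd1))
}
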