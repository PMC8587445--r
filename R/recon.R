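#' Reconstruction configuration
#'
#' Bundles the options shared by the A-scan reconstruction kernels.
#'
#' @param method Reconstruction path: `"scaled_ndft"` (local-spacing weighted
#'   non-uniform DFT, the default), `"standard_ndft"` (the unweighted
#'   baseline), or `"gridded_fft"` (nearest-grid accumulation + one FFT).
#' @param n_out Output length `N_T` (number of Nyquist samples). When `NULL`
#'   it defaults to `round(delta * N_f / K)` computed from the sample set, or
#'   to the sample set's own `n_out` attribute when present.
#' @param residual_phase For `"gridded_fft"`: `"drop"` ignores the
#'   off-grid residual phase (the fast nearest-grid approximation), `"exact"`
#'   evaluates off-grid samples by the direct sum so the result matches the
#'   scaled NDFT to numerical precision.
#' @param boundary_rule Endpoint rule passed to [lambda_scales()].
#' @param grid_mapping How measured `k` locations are mapped to grid units:
#'   `"nyquist"` (default) divides the offsets from `min(k)` by the Nyquist
#'   interval `K`, so a critical spacing becomes exactly one grid unit and
#'   R-fold redundant uniform sampling reconstructs the same shape as
#'   critical sampling; `"endpoints"` affinely maps `min(k) -> 0`,
#'   `max(k) -> n_out - 1`.
#' @param frame_check What to do when the maximum mapped gap exceeds one
#'   Nyquist grid unit (the sinc-frame condition): `"error"` (default) stops;
#'   `"warn"` proceeds with a warning, which mirrors practical swept-source
#'   acquisition at near-critical rates where the condition is marginal and
#'   the reconstruction degrades gracefully.
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(method = c("scaled_ndft", "standard_ndft", "gridded_fft"),
                         n_out = NULL,
                         residual_phase = c("drop", "exact"),
                         boundary_rule = c("one_sided", "periodic"),
                         grid_mapping = c("nyquist", "endpoints"),
                         frame_check = c("error", "warn")) {
  method <- match.arg(method)
  if (!is.null(n_out)) {
    n_out <- as.integer(n_out)
    if (n_out < 2) abort("`n_out` must be at least 2.")
  }
  structure(
    list(
      method = method, n_out = n_out,
      residual_phase = match.arg(residual_phase),
      boundary_rule = match.arg(boundary_rule),
      grid_mapping = match.arg(grid_mapping),
      frame_check = match.arg(frame_check)
    ),
    class = "recon_config"
  )
}

#' Map measured k-space locations onto a uniform reconstruction grid
#'
#' Linearly maps the measured range of `k` onto grid units for an output of
#' `n_out` Nyquist samples and rounds to the nearest grid index
#' (half away from zero, so results are platform independent). Duplicate
#' rounded indices are permitted: they are how redundant samples land in the
#' same grid bin.
#'
#' @param samples A [k_sample_set()].
#' @param n_out Positive integer (>= 2): target grid length `N_T`.
#' @param mode `"endpoints"` maps `min(k) -> 0`, `max(k) -> n_out - 1`
#'   (default for this utility); `"nyquist"` maps offsets by the Nyquist
#'   interval, `mapped = (k - min(k)) / K`.
#' @param wrap Treat grid indices as circular (modulo `n_out`) when rounding,
#'   the natural convention for FFT bins. When `FALSE`, rounded indices are
#'   clamped into `[0, n_out - 1]`.
#' @return A tibble of class `grid_mapping` with columns `mapped`, `rounded`,
#'   `residual` (`mapped - rounded` before wrapping/clamping, always in
#'   `[-0.5, 0.5]`) and attribute `n_out`.
#' @examples
#' ks <- k_sample_set(c(1.0, 1.2, 1.7, 1.9), c(1, 1, 1, 1))
#' map_k_to_grid(ks, 4)
#' @export
map_k_to_grid <- function(samples, n_out,
                          mode = c("endpoints", "nyquist"), wrap = FALSE) {
  mode <- match.arg(mode)
  n_out <- as.integer(n_out)
  if (n_out < 2) abort("`n_out` must be at least 2.")
  k <- samples$k
  span <- max(k) - min(k)
  if (span <= 0) abort("Degenerate k range: all sample locations are equal.")
  mapped <- if (mode == "endpoints") {
    (k - min(k)) / span * (n_out - 1)
  } else {
    (k - min(k)) / k_nyquist(samples)
  }
  if (mode == "nyquist" && max(mapped) >= n_out) {
    # the reconstruction band is circular with width n_out grid units;
    # mapped = n_out aliases onto the minimum location
    abort(paste0(
      "Mapped k range (", signif(max(mapped), 6), " grid units) exceeds the ",
      n_out, "-point output band; increase `n_out` to at least ",
      ceiling(max(mapped) * (1 + 1e-12)), "."
    ))
  }
  nearest <- round_half_away(mapped)
  rounded <- if (wrap) nearest %% n_out else pmin(pmax(nearest, 0), n_out - 1)
  new_tibble(
    list(
      mapped = mapped,
      rounded = as.integer(rounded),
      residual = mapped - nearest
    ),
    nrow = length(mapped), n_out = n_out, mode = mode, wrap = wrap,
    class = "grid_mapping"
  )
}

# Shared setup for the reconstruction kernels: grid mapping, frame-condition
# check, and Lambda weights on the mapped (unit-Nyquist) locations.
recon_setup <- function(samples, config) {
  n_out <- config$n_out %||% default_n_out(samples)
  gm <- map_k_to_grid(samples, n_out, mode = config$grid_mapping, wrap = TRUE)
  delta <- max(diff(gm$mapped))
  if (delta > 1 + 1e-8) {
    msg <- paste0(
      "Frame condition violated: maximum mapped gap ", signif(delta, 6),
      " exceeds one Nyquist grid unit. Use a larger `n_out` or provide more ",
      "(denser) k-space samples."
    )
    if (identical(config$frame_check, "warn")) warn(msg) else abort(msg)
  }
  lambda <- lambda_scales(gm$mapped, 1, config$boundary_rule)
  list(n_out = n_out, mapping = gm, lambda = lambda)
}

new_oct_ascan <- function(values, method, n_out) {
  new_tibble(
    list(z = seq_len(n_out) - 1L, value = values),
    nrow = n_out, flipped = TRUE, method = method, n_out = n_out,
    class = "oct_ascan"
  )
}

#' @export
print.oct_ascan <- function(x, ...) {
  cat(
    "<oct_ascan> ", attr(x, "n_out"), " points (",
    attr(x, "method"), ", flipped convention u(-z))\n",
    sep = ""
  )
  NextMethod()
}

ndft_sum <- function(values, kappa, n_out) {
  # natural-depth sum x[s] = sum_n values_n exp(+i kappa_n s), s = 0..n_out-1
  kernel <- exp(1i * outer(kappa, seq_len(n_out) - 1))
  as.vector(crossprod(kernel, values))
}

# Store a natural-depth profile in the flipped convention u(-z_s):
# y[z] = x[(-z) mod N]. On uniform grids this index reversal coincides with
# evaluating the flipped-kernel sum directly; for non-integer mapped
# frequencies the index reversal is the stable reading (the literal
# negative-depth evaluation leaves the support of a depth-limited signal).
flip_profile <- function(x) {
  n <- length(x)
  x[c(1L, seq.int(n, 2L))]
}

#' Scaled NDFT reconstruction of an A-scan
#'
#' Reconstructs the (flipped) depth profile `u(-z_s)`,
#' `z_s = 0, ..., N_T - 1`, from non-uniform k-space samples by the
#' local-spacing weighted non-uniform DFT
#' `u(-z_s) = (1/N_T) sum_n Lambda_n u^(k_n) exp(-i kappa_n z_s)`,
#' where `kappa_n = 2 pi m_n / N_T` and `m_n` are the sample locations in
#' reconstruction-grid units. The weights `Lambda_n` ([lambda_scales()]) make
#' the underlying sinc frame approximately tight, so this direct sum tracks
#' the dual-frame (pseudoinverse) reconstruction; on a uniform critical grid
#' it reduces exactly to the inverse DFT of the samples, index-flipped.
#'
#' @param samples A [k_sample_set()].
#' @param config A [recon_config()]; `config$method` is ignored here.
#' @param ... Convenience overrides passed to [recon_config()] when `config`
#'   is not supplied.
#' @return An `oct_ascan` tibble (columns `z`, `value`) in the flipped
#'   convention; use [as_depth_profile()] for natural depth order.
#' @examples
#' x <- cos(2 * pi * (0:15) / 16)
#' ks <- k_sample_set(0:15, fft(x))
#' prof <- as_depth_profile(scaled_ndft(ks))
#' max(Mod(prof$value - x)) # ~ 1e-15
#' @export
scaled_ndft <- function(samples, config = recon_config(...), ...) {
  s <- recon_setup(samples, config)
  kappa <- 2 * pi * s$mapping$mapped / s$n_out
  values <- ndft_sum(s$lambda * samples$value, kappa, s$n_out) / s$n_out
  new_oct_ascan(flip_profile(values), "scaled_ndft", s$n_out)
}

#' Standard (unweighted) NDFT reconstruction baseline
#'
#' Identical to [scaled_ndft()] but with every `Lambda_n` replaced by 1: the
#' conventional non-uniform DFT reconstruction used as the comparison
#' baseline. On a uniform critical grid the two coincide; on irregular or
#' redundant sampling the missing local-spacing compensation distorts the
#' reconstruction.
#'
#' @inheritParams scaled_ndft
#' @return An `oct_ascan` tibble in the flipped convention.
#' @export
standard_ndft <- function(samples, config = recon_config(...), ...) {
  s <- recon_setup(samples, config)
  kappa <- 2 * pi * s$mapping$mapped / s$n_out
  values <- ndft_sum(samples$value, kappa, s$n_out) / s$n_out
  new_oct_ascan(flip_profile(values), "standard_ndft", s$n_out)
}

#' FFT-accelerated gridded reconstruction
#'
#' Evaluates the scaled NDFT by accumulating the `Lambda_n`-weighted samples
#' into their nearest reconstruction-grid bins followed by a single
#' length-`N_T` FFT. Writing `kappa_n = kappa~_n + r_n` with `kappa~_n` the
#' nearest on-grid frequency, the exact sum carries a z-dependent residual
#' phase `exp(-i (kappa_n - kappa~_n) z_s)` per sample:
#' * `residual_phase = "drop"` ignores it (the O(N_f) + FFT fast path; exact
#'   whenever all samples fall on grid positions);
#' * `residual_phase = "exact"` evaluates the off-grid samples by the direct
#'   sum, making the result equal to [scaled_ndft()] to numerical precision.
#'
#' @inheritParams scaled_ndft
#' @return An `oct_ascan` tibble in the flipped convention.
#' @export
gridded_fft_reconstruct <- function(samples, config = recon_config(...), ...) {
  s <- recon_setup(samples, config)
  n_out <- s$n_out
  weighted <- s$lambda * samples$value
  on_grid <- abs(s$mapping$residual) < 1e-9
  use_fft <- if (config$residual_phase == "drop") rep(TRUE, nrow(samples)) else on_grid
  bins <- complex(n_out)
  for (i in which(use_fft)) {
    b <- s$mapping$rounded[i] + 1L
    bins[b] <- bins[b] + weighted[i]
  }
  values <- fft(bins, inverse = TRUE) / n_out
  if (any(!use_fft)) {
    kappa <- 2 * pi * s$mapping$mapped[!use_fft] / n_out
    values <- values + ndft_sum(weighted[!use_fft], kappa, n_out) / n_out
  }
  new_oct_ascan(flip_profile(values), "gridded_fft", n_out)
}

#' Reconstruct an A-scan with the configured method
#'
#' Thin dispatcher over [scaled_ndft()], [standard_ndft()] and
#' [gridded_fft_reconstruct()] driven by `config$method`.
#'
#' @inheritParams scaled_ndft
#' @return An `oct_ascan` tibble.
#' @export
reconstruct_ascan <- function(samples, config = recon_config(...), ...) {
  switch(config$method,
    scaled_ndft = scaled_ndft(samples, config),
    standard_ndft = standard_ndft(samples, config),
    gridded_fft = gridded_fft_reconstruct(samples, config)
  )
}

#' Un-flip an A-scan into natural depth order
#'
#' The reconstruction kernels return `u(-z_s)`; this reorders the values to
#' the natural depth profile `u(z)` (index `s -> (N - s) mod N`).
#'
#' @param ascan An `oct_ascan` tibble.
#' @return A tibble with columns `depth`, `value`, `magnitude`.
#' @export
as_depth_profile <- function(ascan) {
  n <- attr(ascan, "n_out")
  v <- ascan$value[c(1L, seq.int(n, 2L))]
  tibble(depth = seq_len(n) - 1L, value = v, magnitude = Mod(v))
}
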