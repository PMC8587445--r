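#' Layered reflectivity phantom
#'
#' Builds a depth x lateral non-negative test image made of horizontal
#' layers, a desk-scale stand-in for a structural OCT B-scan: each layer is
#' a depth band of constant reflectivity, optionally textured with
#' multiplicative exponential speckle. Generation is a pure function of
#' `seed`.
#'
#' @param depth,width Image dimensions (>= 8 each); `depth` is the intended
#'   A-scan length.
#' @param layers List of layer specs `list(from, to, intensity, speckle)`,
#'   with `from < to` depth fractions in `[0, 1]` and `speckle` optional
#'   (default `FALSE`). `NULL` uses a default three-layer phantom; an empty
#'   list gives an all-zero image. Overlapping depth ranges are an error.
#' @param seed Integer seed (controls the speckle texture only).
#' @return An `oct_phantom`: a numeric depth x width matrix with the layer
#'   spec and seed attached.
#' @export
make_phantom <- function(depth, width, layers = NULL, seed = 1) {
  if (depth < 8 || width < 8) abort("`depth` and `width` must be at least 8.")
  if (is.null(layers)) {
    layers <- list(
      list(from = 0.10, to = 0.22, intensity = 0.9),
      list(from = 0.35, to = 0.55, intensity = 0.5, speckle = TRUE),
      list(from = 0.70, to = 0.78, intensity = 1.0)
    )
  }
  rows <- lapply(layers, function(l) {
    if (l$from >= l$to || l$from < 0 || l$to > 1) {
      abort("Each layer needs depth fractions 0 <= from < to <= 1.")
    }
    seq.int(floor(l$from * depth) + 1L, min(depth, ceiling(l$to * depth)))
  })
  all_rows <- unlist(rows)
  if (anyDuplicated(all_rows)) abort("Layer depth ranges overlap.")
  img <- matrix(0, depth, width)
  withr::with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      block <- matrix(l$intensity, length(rows[[i]]), width)
      if (isTRUE(l$speckle)) {
        block <- block * matrix(
          stats::rexp(length(block)), nrow(block), ncol(block)
        )
      }
      img[rows[[i]], ] <- block
    }
  })
  structure(img,
    layers = layers, seed = seed,
    class = c("oct_phantom", "matrix", "array")
  )
}

#' Dense oversampled k-space spectra of an image's A-scans
#'
#' Emulates synthetic swept-source acquisition: each image column (A-scan)
#' is zero-padded to `oversample_factor` times its depth and forward
#' Fourier transformed, giving a dense spectrum on an implicit uniform fine
#' grid with `oversample_factor` bins per critical (Nyquist) k-space
#' interval. Non-uniform sample sets are then drawn from these dense
#' spectra with [select_nonuniform()].
#'
#' @param image Numeric matrix (depth x width), e.g. a [make_phantom()]
#'   output.
#' @param oversample_factor Integer >= 1: fine-grid density per column.
#' @return A list of `dense_spectrum` objects (fields `values`, `oversample`,
#'   `depth`), one per column.
#' @export
spectra_from_image <- function(image, oversample_factor = 20) {
  oversample_factor <- as.integer(oversample_factor)
  if (oversample_factor < 1) abort("`oversample_factor` must be >= 1.")
  depth <- nrow(image)
  lapply(seq_len(ncol(image)), function(j) {
    padded <- c(image[, j], numeric(depth * (oversample_factor - 1)))
    structure(
      list(
        values = fft(padded),
        oversample = oversample_factor,
        depth = depth
      ),
      class = "dense_spectrum"
    )
  })
}

#' Select a non-uniform k-sample set from a dense spectrum
#'
#' Draws `n_select` strictly increasing sample locations from the fine
#' spectral grid of a `dense_spectrum`, mimicking non-uniform swept-source
#' acquisition. Locations are reported in critical k-space units (Nyquist
#' interval 1). Selection schemes:
#' * `"uniform"`: plain decimation at spacing `depth / n_select` critical
#'   units (`n_select = depth` recovers the critical uniform grid exactly);
#' * `"jitter"` (default): the uniform grid plus independent per-point
#'   jitter, uniform on `+/- jitter_frac` of the spacing, snapped to the
#'   nearest fine-grid bin. `jitter_frac < 0.5` keeps the points in order;
#'   the max-gap frame condition `delta < 1` is guaranteed only when
#'   `spacing * (1 + 2 jitter_frac) <= 1`, i.e. for sufficiently redundant
#'   selection;
#' * `"sweep_law"`: locations spaced as the wavenumbers of a swept laser,
#'   `k(t) = 2 pi / lambda(t)` at uniform acquisition times, affinely mapped
#'   onto the spectral band (the physically motivated non-uniformity).
#'
#' Fine-grid snapping can collide for highly redundant selections; colliding
#' bins are bumped to the nearest free bin and the number of adjustments is
#' reported via [rlang::inform()] and the `adjusted` attribute.
#'
#' @param dense_spectrum A `dense_spectrum` from [spectra_from_image()].
#' @param n_select Number of samples (3 <= n_select <= fine-grid length).
#' @param scheme Selection scheme, see above.
#' @param jitter_frac Jitter half-width as a fraction of the spacing
#'   (`< 0.5`).
#' @param sweep A [sweep_model()] for `scheme = "sweep_law"`.
#' @param sweep_window Acquisition time window (ns) for `"sweep_law"`.
#' @param seed Integer seed (jitter only).
#' @return A [k_sample_set()] with `nyquist_interval = 1` and
#'   `n_out = depth`.
#' @export
select_nonuniform <- function(dense_spectrum, n_select,
                              scheme = c("jitter", "sweep_law", "uniform"),
                              jitter_frac = 0.4, sweep = NULL,
                              sweep_window = c(0, 2000), seed = 1) {
  scheme <- match.arg(scheme)
  f <- dense_spectrum$oversample
  depth <- dense_spectrum$depth
  n_fine <- length(dense_spectrum$values)
  if (n_select < 3 || n_select > n_fine) {
    abort("`n_select` must be between 3 and the fine-grid length.")
  }
  spacing <- depth / n_select
  positions <- switch(scheme,
    uniform = (seq_len(n_select) - 1) * spacing,
    jitter = {
      if (jitter_frac >= 0.5) abort("`jitter_frac` must be below 0.5.")
      withr::with_seed(
        seed,
        (seq_len(n_select) - 1) * spacing +
          runif(n_select, -jitter_frac, jitter_frac) * spacing
      )
    },
    sweep_law = {
      if (is.null(sweep)) abort("`sweep` model required for scheme = 'sweep_law'.")
      t <- seq(sweep_window[1], sweep_window[2], length.out = n_select)
      ks <- k_locations_from_sweep(t, sweep)$k
      (ks - min(ks)) / (max(ks) - min(ks)) * (depth - 1)
    }
  )
  bins <- pmin(pmax(round_half_away(positions * f), 0), n_fine - 1L)
  bins <- sort(bins)
  adjusted <- 0L
  # bump colliding fine-grid bins forward to the next free bin
  for (i in seq_along(bins)[-1]) {
    if (bins[i] <= bins[i - 1]) {
      bins[i] <- bins[i - 1] + 1L
      adjusted <- adjusted + 1L
    }
  }
  if (any(bins > n_fine - 1L)) abort("Could not resolve bin collisions within the grid.")
  if (adjusted > 0) {
    rlang::inform(paste0(
      "select_nonuniform: adjusted ", adjusted,
      " colliding fine-grid bins to keep locations strictly increasing."
    ))
  }
  out <- k_sample_set(
    k = bins / f,
    value = dense_spectrum$values[bins + 1L],
    nyquist_interval = 1,
    n_out = depth
  )
  attr(out, "adjusted") <- adjusted
  out
}

#' Add zero-mean white noise to k-space samples
#'
#' Adds independent circular complex Gaussian noise with total per-sample
#' variance `sigma^2` (standard deviation `sigma / sqrt(2)` per real and
#' imaginary component), the additive white-noise model for spectral-domain
#' measurements. Deterministic given `seed`.
#'
#' @param samples A [k_sample_set()].
#' @param sigma Noise standard deviation (>= 0; 0 returns the input values).
#' @param seed Integer seed.
#' @return A [k_sample_set()] with noisy values.
#' @export
add_noise <- function(samples, sigma, seed = 1) {
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (sigma == 0) {
    return(samples)
  }
  noisy <- withr::with_seed(
    seed,
    samples$value + rcnorm(nrow(samples), sigma^2)
  )
  k_sample_set(samples$k, noisy,
    nyquist_interval = k_nyquist(samples),
    n_out = attr(samples, "n_out")
  )
}

#' Synthesise a noisy MZI calibration trace
#'
#' Forward-evaluates [mzi_model()] for a sweep law and adds real Gaussian
#' amplitude noise; the generator used for sweep-calibration experiments.
#'
#' @inheritParams mzi_model
#' @param d MZI path difference (nm); see [path_difference_for_fringes()].
#' @param sigma Amplitude noise standard deviation (0 for a clean trace).
#' @param seed Integer seed.
#' @return An [mzi_trace()].
#' @export
synth_mzi <- function(model, d, t, sigma = 0, seed = 1) {
  amp <- mzi_model(t, model, d)
  if (sigma > 0) {
    amp <- withr::with_seed(seed, amp + rnorm(length(amp), sd = sigma))
  }
  mzi_trace(t, amp, path_difference = d, lambda0 = model$lambda0)
}
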