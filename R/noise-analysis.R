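#' Upper bound on the projected-noise power of a frame reconstruction
#'
#' White noise of variance `sigma^2` on the measured samples enters the
#' frame-coefficient vector scaled by the frame-vector norms and is then
#' orthogonally projected by the dual-frame (pseudoinverse) reconstruction.
#' The resulting per-coefficient noise power is bounded by
#' `sigma^2 * max_n ||phi_n||^2 / A`, with `A` the lower frame bound. For
#' the scaled sinc frame `||phi_n||^2 = Lambda_n^2 <= delta/T`, so
#' oversampling (small `delta/T`) reduces the reconstructed noise power.
#'
#' @param sigma2 Positive noise variance on the measured samples.
#' @param frame A [frame_matrix()]; its `lower_limit` attribute supplies `A`
#'   and its row norms supply `max ||phi_n||^2`.
#' @return The bound `sigma2 * max ||phi_n||^2 / A` (scalar).
#' @export
projected_noise_bound <- function(sigma2, frame) {
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  a <- attr(frame, "lower_limit")
  if (is.null(a) || a <= 0) {
    abort("Frame must carry a positive analytic lower bound `lower_limit`.")
  }
  sigma2 * max(rowSums(Mod(unclass(frame))^2)) / a
}

#' Worst-case noise reduction of oversampled frame reconstruction
#'
#' For oversampling ratio `T/delta = ratio`, the minimum noise-variance
#' reduction of the scaled sinc-frame reconstruction follows from the
#' projected-noise bound with `max ||phi_n||^2 = delta/T` and
#' `A = (1 - delta/T)^2`: in decibels, with `x = 1/ratio`,
#' `10 log10((1 - x)^2 / x)`. Positive values mean a net reduction; the
#' curve crosses 0 dB at [crossover_ratio()] and grows without bound as the
#' ratio increases.
#'
#' @param ratio Oversampling ratio `T/delta`, strictly greater than 1.
#' @return Minimum noise reduction in dB (vectorised over `ratio`).
#' @examples
#' theoretical_min_reduction_db(4) # 3.522 dB
#' @export
theoretical_min_reduction_db <- function(ratio) {
  if (any(ratio <= 1)) abort("`ratio` must be greater than 1.")
  x <- 1 / ratio
  10 * log10((1 - x)^2 / x)
}

#' Noise reduction of sequential acquisition and averaging
#'
#' Acquiring `ratio` critically sampled A-scans sequentially and averaging
#' them reduces the noise variance by the factor `ratio`:
#' `10 log10(ratio)` dB. This is the baseline the oversampling method is
#' compared against; it is always slightly above the worst-case
#' oversampling reduction, but requires `ratio` times the acquisition time.
#'
#' @param ratio Averaging factor / oversampling ratio (>= 1).
#' @return Reduction in dB (vectorised).
#' @export
averaging_reduction_db <- function(ratio) {
  if (any(ratio < 1)) abort("`ratio` must be at least 1.")
  10 * log10(ratio)
}

#' Oversampling ratio where the worst-case reduction reaches 0 dB
#'
#' Solves `theoretical_min_reduction_db(ratio) = 0` by bracketed root
#' finding (tolerance 1e-12). With `x = 1/ratio` the condition
#' `x = (1 - x)^2` gives `ratio^2 - 3 ratio + 1 = 0`, i.e. analytically
#' `(3 + sqrt(5)) / 2 ~= 2.618`: oversampling pays off, even in the worst
#' case, once the sampling rate exceeds roughly 2.6 times the critical
#' rate.
#'
#' @return The crossover oversampling ratio (scalar).
#' @export
crossover_ratio <- function() {
  uniroot(theoretical_min_reduction_db,
    lower = 1.5, upper = 8, tol = 1e-12
  )$root
}

#' Worst-case and averaging noise-reduction curves
#'
#' Tabulates [theoretical_min_reduction_db()] and
#' [averaging_reduction_db()] over a grid of oversampling ratios.
#'
#' @param ratios Numeric vector of oversampling ratios (> 1).
#' @return A tibble of class `noise_reduction_curve` with columns `ratio`,
#'   `min_reduction_db`, `averaging_db`.
#' @export
noise_reduction_curve <- function(ratios = seq(1.1, 8, by = 0.1)) {
  out <- tibble(
    ratio = ratios,
    min_reduction_db = theoretical_min_reduction_db(ratios),
    averaging_db = averaging_reduction_db(ratios)
  )
  class(out) <- c("noise_reduction_curve", class(out))
  out
}

#' @export
autoplot.noise_reduction_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"ratio",
    names_to = "curve", values_to = "reduction_db"
  )
  df$curve <- ifelse(df$curve == "min_reduction_db",
    "oversampled reconstruction (worst case)", "sequential averaging"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$reduction_db,
    colour = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "oversampling ratio T/δ",
      y = "noise variance reduction (dB)", colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Monte-Carlo projected-noise power of a frame reconstruction
#'
#' Draws white noise on the measured samples (per-coefficient standard
#' deviation `sigma * ||phi_n||`, the scaling with which sample noise
#' reaches the frame-coefficient vector), applies the pseudoinverse
#' [dual_frame_pinv()], and averages the squared magnitude per output
#' coefficient (energy divided by the number of retained modes, i.e. the
#' dimension of the signal subspace the frame represents). When the frame
#' carries a positive analytic `lower_limit` `A`, the pseudoinverse is
#' truncated at singular value `sqrt(A)`: a finite sampling window leaves a
#' tail of edge modes below the frame bound whose inversion has no analogue
#' in the bounded-frame model. The estimate must stay below
#' [projected_noise_bound()] up to Monte-Carlo error.
#'
#' @param frame A [frame_matrix()].
#' @param sigma2 Sample noise variance.
#' @param trials Number of Monte-Carlo noise draws (>= 1000).
#' @param seed Integer seed.
#' @return A list with `power` (mean per-coefficient noise power),
#'   `se` (Monte-Carlo standard error of the mean), `trials`, and `rank`.
#' @export
monte_carlo_projected_noise <- function(frame, sigma2, trials = 5000, seed = 1) {
  if (trials < 1000) abort("`trials` must be at least 1000.")
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  a <- attr(frame, "lower_limit")
  min_singular <- if (!is.null(a) && a > 0) sqrt(a) else NULL
  pinv <- dual_frame_pinv(frame, min_singular = min_singular)
  r <- attr(pinv, "rank")
  norms <- sqrt(rowSums(Mod(unclass(frame))^2))
  n_f <- nrow(frame)
  powers <- withr::with_seed(seed, {
    vapply(seq_len(trials), function(i) {
      w <- rcnorm(n_f, sigma2) * norms
      sum(Mod(pinv %*% w)^2) / r
    }, numeric(1))
  })
  list(
    power = mean(powers),
    se = sd(powers) / sqrt(trials),
    trials = trials,
    rank = r
  )
}
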