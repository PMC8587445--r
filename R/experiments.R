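# Seeded desk-scale experiments shared by the test suite, the acceptance
# script and the vignette.

#' Scaled vs standard NDFT on jittered redundant phantom sampling
#'
#' For each seed: build a layered phantom, take its dense oversampled
#' spectra, draw a jittered redundant k-sample set per column, reconstruct
#' the B-scan with both the scaled and the standard NDFT, and record the
#' mean per-A-scan correlation of each against the phantom. The
#' local-spacing weights of the scaled method compensate the sampling
#' irregularity, so its correlation is expected to exceed the unweighted
#' baseline's in essentially every trial.
#'
#' @param seeds Integer vector of experiment seeds (one trial per seed).
#' @param depth,width Phantom dimensions.
#' @param oversample Dense-spectrum fine-grid factor.
#' @param redundancy Samples per critical interval (`n_select =
#'   redundancy * depth`); with `redundancy * (1 - 2 * jitter_frac /
#'   redundancy) ...` chosen so the max-gap condition holds.
#' @param jitter_frac Per-point jitter fraction of the sample spacing.
#' @return A tibble with columns `seed`, `scaled`, `standard` (mean
#'   correlations) and `scaled_wins`.
#' @export
compare_ndft_methods <- function(seeds = 1:20, depth = 96, width = 8,
                                 oversample = 20, redundancy = 2,
                                 jitter_frac = 0.4) {
  rows <- purrr::map(seeds, function(s) {
    phantom <- make_phantom(depth, width, seed = s)
    dense <- spectra_from_image(phantom, oversample)
    spectra <- purrr::imap(dense, function(d, j) {
      select_nonuniform(d,
        n_select = round(redundancy * depth),
        scheme = "jitter", jitter_frac = jitter_frac,
        seed = s * 1000L + j
      )
    })
    img_scaled <- reconstruct_bscan(
      spectra, recon_config("scaled_ndft", n_out = depth)
    )
    img_standard <- reconstruct_bscan(
      spectra, recon_config("standard_ndft", n_out = depth)
    )
    tibble(
      seed = s,
      scaled = mean(ascan_correlations(unclass(phantom), unclass(img_scaled))),
      standard = mean(ascan_correlations(unclass(phantom), unclass(img_standard)))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$scaled_wins <- out$scaled > out$standard
  out
}

#' PSNR of scaled-NDFT reconstructions vs oversampling ratio
#'
#' Emulates the redundancy/noise trade-off experiment: fixed additive white
#' k-space noise, reconstruction from sample sets of increasing oversampling
#' ratio, and PSNR against a reference reconstructed from a much higher
#' sampling rate. Both noise averaging across redundant samples and the
#' improving frame approximation make the PSNR increase with the ratio.
#'
#' Every ratio uses the same physical acquisition geometry — sample
#' locations following the wavenumber law of a linearly swept laser
#' ([select_nonuniform()] scheme `"sweep_law"`) — so only the sampling rate
#' varies, as when decimating one measured sweep. At ratio 1 the max-gap
#' frame condition is marginal (`delta/K` slightly above 1, as in practical
#' near-critical swept-source data), so reconstruction runs with
#' `frame_check = "warn"`. The noise level is `sigma_rel` times the RMS
#' magnitude of the clean dense spectrum; the reference is the noiseless
#' sweep-law acquisition at `reference_ratio`, and PSNR is gain-normalised.
#'
#' @param ratios Oversampling ratios to score.
#' @param sigma_rel Noise std as a fraction of the RMS spectral magnitude.
#' @param depth,width Phantom dimensions.
#' @param oversample Dense-grid factor (bounds the largest ratio).
#' @param reference_ratio Sampling ratio of the noiseless reference.
#' @param sweep Sweep law generating the sampling geometry (default the
#'   linear 1250-1375 nm sweep).
#' @param sweep_window Acquisition window (ns) covering the full sweep.
#' @param seed Integer seed for phantom and noise.
#' @return A tibble with columns `ratio` and `psnr_db`.
#' @export
psnr_vs_oversampling <- function(ratios = c(1, 1.6, 2, 2.6, 4),
                                 sigma_rel = 0.1, depth = 96, width = 8,
                                 oversample = 20, reference_ratio = 8,
                                 sweep = sweep_model(1250, a = 0.00225),
                                 sweep_window = c(0, 55555.6),
                                 seed = 1) {
  phantom <- make_phantom(depth, width, seed = seed)
  dense <- spectra_from_image(phantom, oversample)
  sigma <- sigma_rel *
    sqrt(mean(vapply(dense, function(d) mean(Mod(d$values)^2), numeric(1))))
  acquire <- function(d, ratio) {
    select_nonuniform(d,
      n_select = round(ratio * depth), scheme = "sweep_law",
      sweep = sweep, sweep_window = sweep_window
    )
  }
  cfg <- recon_config("scaled_ndft", n_out = depth, frame_check = "warn")
  reference <- suppressWarnings(reconstruct_bscan(
    purrr::map(dense, acquire, ratio = reference_ratio), cfg
  ))
  rows <- purrr::map(ratios, function(r) {
    spectra <- purrr::imap(
      dense,
      function(d, j) add_noise(acquire(d, r), sigma, seed = seed * 104729L + j)
    )
    img <- suppressWarnings(reconstruct_bscan(spectra, cfg))
    tibble(
      ratio = r,
      psnr_db = as.numeric(
        psnr(unclass(reference), unclass(img), normalize = TRUE)
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Sweep-recovery experiment: synthesise, fit, compare
#'
#' Generates a noiseless MZI fringe trace from a cubic sweep law, fits it by
#' Gauss-Newton from a perturbed starting point, and returns truth and
#' estimates side by side. This is the package's self-consistency check for
#' the calibration pipeline.
#'
#' @param model True [sweep_model()] generating the trace.
#' @param t_max Sweep window end (ns); samples are uniform on `[0, t_max]`.
#' @param n_samples Trace length.
#' @param fringes Target fringe count used to choose the MZI path difference.
#' @param perturb Relative perturbation applied to the true coefficients to
#'   form the Gauss-Newton starting point.
#' @param seed Integer seed for the perturbation.
#' @return A list with the fitted `sweep_fit` (element `fit`) and a tibble
#'   `comparison` of truth vs estimate per coefficient.
#' @export
sweep_recovery_experiment <- function(model = sweep_model(1250,
                                        a = 0.00225, b = 1.9812e-6,
                                        c = 1.999e-9
                                      ),
                                      t_max = 2000, n_samples = 4096,
                                      fringes = 100, perturb = 0.1,
                                      seed = 1) {
  d <- path_difference_for_fringes(model, t_max, fringes)
  t <- seq(0, t_max, length.out = n_samples)
  trace <- synth_mzi(model, d, t)
  init <- withr::with_seed(seed, sweep_model(
    model$lambda0,
    a = model$a * (1 + runif(1, -perturb, perturb)),
    b = model$b * (1 + runif(1, -perturb, perturb)),
    c = model$c * (1 + runif(1, -perturb, perturb))
  ))
  fit <- fit_sweep(trace, init = init)
  comparison <- tibble(
    term = c("a", "b", "c"),
    truth = c(model$a, model$b, model$c),
    estimate = c(fit$model$a, fit$model$b, fit$model$c)
  )
  comparison$rel_error <- abs(comparison$estimate - comparison$truth) /
    abs(comparison$truth)
  list(fit = fit, comparison = comparison)
}
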