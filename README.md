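# octframe

Frame-based reconstruction of swept-source OCT images from redundant and
non-uniformly spaced spectral samples.

## The problem

Swept-source optical coherence tomography (SS-OCT) records an interferogram
while a laser sweeps its wavelength in time. Because the sweep is nonlinear,
the samples land at non-uniform positions in wavenumber (k) space, while the
standard FFT-based A-scan reconstruction assumes uniform spacing. Practical
systems either resample to a uniform k grid or evaluate a non-uniform
discrete Fourier transform (NDFT) directly.

`octframe` treats the measured samples as coefficients in a *frame* — a
redundant generalisation of a basis made of shifted sinc functions. For
sample locations `k_n` with maximum gap `δ` below the Nyquist interval `K`,
the scaled sinc family

```
φ_n(k) = Λ_n K^{-1/2} sinc((k - k_n)/K),   Λ_n = sqrt((k_{n+1} - k_{n-1}) / (2K))
```

is a frame with bounds `A ≥ (1 - δ/K)²`, `B ≤ (1 + δ/K)²`. Dual-frame
inversion then yields a *scaled NDFT* A-scan reconstruction

```
u(-z_s) ≅ (1/N_T) Σ_n Λ_n û(k_n) e^{-j k_n z_s},   z_s = 0, …, N_T - 1,
```

whose local-spacing weights `Λ_n` compensate both oversampling and sampling
irregularity — the correction absent from the unweighted (standard) NDFT.
The package implements:

* **frame core** — Λ scales, max-gap condition, analytic and Monte-Carlo
  frame bounds, sinc-frame discretisation, dual-frame pseudoinverse oracles;
* **reconstruction** — the scaled NDFT, the standard NDFT baseline, and an
  FFT-accelerated gridded evaluation (nearest-grid binning + one FFT, with
  an exact residual-phase fallback), plus B-scan assembly;
* **sweep calibration** — the cubic wavelength-vs-time law
  `λ(t) = λ0 + a t + b t² + c t³`, Mach–Zehnder interferometer (MZI) fringe
  synthesis, Gauss–Newton nonlinear least-squares fitting, and conversion to
  k-space sample locations;
* **noise analysis** — the projected-noise bound
  `σ² max‖φ_n‖² / A`, the worst-case noise-reduction curve
  `10 log10((1 - x)²/x)` with `x = δ/K`, its 0 dB crossover at an
  oversampling ratio of `(3 + √5)/2 ≈ 2.62`, and the sequential-averaging
  baseline `10 log10(K/δ)`;
* **synthetic generators** — layered phantoms, 20× oversampled spectra,
  jittered / sweep-law / uniform non-uniform sample selection, additive
  white spectral noise, and noisy MZI traces;
* **metrics & I/O** — per-A-scan Pearson correlation profiles, PSNR,
  CSV/JSON sample-set and trace formats, PNG/TIFF images, ggplot2
  `autoplot()` methods, and broom-style `tidy()`/`glance()` for fits.

## Worked example

Reconstruct a layered phantom from 2× redundant, jittered k-space samples
with both methods, and calibrate a sweep from its fringe trace:

```r
library(octframe)

ph <- make_phantom(96, 16, seed = 42)                 # depth x lateral phantom
dense <- spectra_from_image(ph, 20)                   # 20x oversampled spectra
spectra <- purrr::imap(dense, function(d, j) {
  select_nonuniform(d, n_select = 192, scheme = "jitter",
                    jitter_frac = 0.4, seed = 100 + j)
})
img_scaled   <- reconstruct_bscan(spectra, recon_config("scaled_ndft",   n_out = 96))
img_standard <- reconstruct_bscan(spectra, recon_config("standard_ndft", n_out = 96))
mean(ascan_correlations(unclass(ph), unclass(img_scaled)))    # 0.9941
mean(ascan_correlations(unclass(ph), unclass(img_standard)))  # 0.9902

fit <- sweep_recovery_experiment(seed = 1)   # synthesise + refit the cubic sweep
tidy(fit$fit)
#>   term estimate      unit
#>   a    0.00225      nm/ns
#>   b    1.9812e-06   nm/ns^2
#>   c    1.999e-09    nm/ns^3
crossover_ratio()                            # 2.618034
```

The scaled NDFT's mean per-A-scan correlation (0.9941) exceeds the
unweighted baseline's (0.9902): the `Λ_n` weights recover what sampling
irregularity distorts. The sweep fit recovers its generating coefficients
to machine precision from a noiseless trace, and the noise-reduction
crossover says redundant acquisition pays off, even in the worst case, once
the sampling rate exceeds ~2.62× critical.

A thin CLI over the same functions lives in `inst/scripts/octframe-cli.R`
(subcommands `synth`, `calibrate`, `reconstruct`, `noise-analysis`,
`metrics`).

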