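---
title: "Frame-based OCT reconstruction: model, numerics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-based OCT reconstruction: model, numerics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octframe)
```

## The signal model

A swept-source OCT A-scan `u(z)` (reflectivity vs depth) is measured through
its spectrum: the detector records `û(k_n)` at wavenumbers `k_n` that follow
the laser's sweep law and are therefore non-uniformly spaced, and possibly
redundant (denser than the Nyquist spacing `K` of the depth-limited signal).

`octframe` models these measurements as coefficients in a *frame* of shifted
sinc functions. With the local-spacing scale

\[
\Lambda_n = \sqrt{\frac{k_{n+1} - k_{n-1}}{2K}},
\]

the family \(\varphi_n(k) = \Lambda_n K^{-1/2}\,\mathrm{sinc}((k - k_n)/K)\)
is a frame of the bandlimited space whenever the maximum gap
\(\delta = \max_n (k_{n+1} - k_n)\) stays below \(K\), with bounds
\(A \ge (1 - \delta/K)^2\) and \(B \le (1 + \delta/K)^2\)
(`frame_bound_limits()`). Dual-frame inversion — multiplication by the
pseudoinverse \(\Phi^+ = (\Phi^*\Phi)^{-1}\Phi^*\) of the analysis matrix —
reduces, for this family, to the *scaled NDFT*

\[
u(-z_s) \;\cong\; \frac{1}{N_T}\sum_{n=0}^{N_f-1}
\Lambda_n\, \hat u(k_n)\, e^{-j k_n z_s},
\qquad z_s = 0,\dots,N_T-1 ,
\]

implemented by `scaled_ndft()`. Dropping the \(\Lambda_n\) weights gives the
conventional (standard) NDFT baseline, `standard_ndft()`. The package treats
the measured values as the frame-coefficient vector directly, which is the
working convention of the formula above; the alternative reading (an extra
\(\Lambda_n K^{1/2}\) factor between samples and coefficients) changes only
the overall output scale, and every comparison in the package is scale
invariant (correlation, gain-normalised PSNR) for exactly this reason.

**Assumptions.** The A-scan is depth limited (length `N_T` at the Nyquist
rate); the sample locations are strictly increasing; `δ < K` (checked, see
below); noise, when modelled, is additive, zero mean, white, and enters the
measured samples.

## Reconstruction paths and their tolerances

Three paths share one configuration object (`recon_config()`):

* `scaled_ndft` — direct \(O(N_f N_T)\) evaluation; the reference method.
* `standard_ndft` — identical with \(\Lambda_n \equiv 1\); the baseline the
  scaled method is compared against.
* `gridded_fft` — each weighted sample is accumulated into its nearest
  reconstruction-grid bin, followed by a single length-`N_T` FFT. Writing
  \(\kappa_n = \tilde\kappa_n + r_n\) with \(\tilde\kappa_n\) on-grid, the
  neglected factor is the z-dependent residual phase
  \(e^{-j r_n z_s}\): `residual_phase = "drop"` ignores it (exact when all
  samples are on-grid; error shrinking with the maximum residual), while
  `residual_phase = "exact"` evaluates off-grid samples by the direct sum,
  which the test suite verifies agrees with `scaled_ndft` to `1e-10` — the
  gridded form is an algebraic rewriting, not an approximation, once the
  residual phase is kept.

The suite also verifies that on uniform critical grids all three paths
collapse onto the index-flipped inverse DFT to `1e-10`, and that the scaled
NDFT tracks the dual-frame pseudoinverse reconstruction on small jittered
instances (relative L2 error below 5% at 2x redundancy with 5% location
jitter). That agreement is *first order in the irregularity*: measured over
the instance generator, the discrepancy grows roughly linearly with the
jitter fraction (about 0.9x the jitter fraction at 2x redundancy), so the
oracle suite probes the mild-jitter regime where the scaled NDFT is an
accurate stand-in for the exact dual-frame inverse. Heavier irregularity
still reconstructs well against ground truth, but the cheap sum and the
pseudoinverse are no longer interchangeable to within a few percent.

### Numerical choices

* **Frequency normalisation.** Measured locations are mapped to grid units
  as `mapped = (k - min(k)) / K`, and \(\kappa_n = 2\pi\,\mathrm{mapped}_n /
  N_T\), so a critical uniform set reduces the sum to the standard DFT
  kernel exactly. An alternative endpoint map (`min -> 0`,
  `max -> n_out - 1`; `grid_mapping = "endpoints"`, the default in the
  standalone `map_k_to_grid()` utility) is also provided, but the kernels
  default to the Nyquist map: the endpoint map stretches the frequency axis
  by a factor `(N_T - 1)/(N_T - 1/R)` for `R`-fold redundant input, which
  chirps deep-depth content, whereas under the Nyquist map uniform R-fold
  redundancy is *exactly* consistent (the reconstruction equals \(\sqrt
  R\) times the critical one — the suite asserts shape correlation > 0.999
  and the \(\sqrt R\) gain).
* **Flip convention.** The kernels compute the naturally oriented profile
  with the conjugate kernel \(e^{+j\kappa_n s}\) and store its index
  reversal as the flipped A-scan `u(-z_s)`. On uniform grids this is
  identical to evaluating the flipped kernel directly; for non-integer
  mapped frequencies it is the only stable reading — the literal
  negative-depth evaluation leaves the support of a depth-limited signal
  and is meaningful only through the periodicity that integer DFT
  frequencies provide. `as_depth_profile()` undoes the flip.
* **Rounding.** Grid rounding is half-away-from-zero (`round_half_away`),
  so gridded results are platform independent; bin indices wrap modulo
  `N_T` (frequencies are circular).
* **`N_T` default.** `round(delta * N_f / K)`, floored at 2, or the sample
  set's own `n_out` when the generator recorded one.
* **Frame-condition check.** The kernels verify `max mapped gap <= 1` grid
  unit and abort with a remediation hint. `frame_check = "warn"` downgrades
  this to a warning: near-critical swept-source sampling sits marginally
  above the bound and degrades gracefully, and the PSNR experiment uses
  this mode for its ratio-1 acquisition.
* **Endpoint \(\Lambda\).** The central difference is undefined at the two
  ends; the default `one_sided` rule substitutes the single adjacent gap
  (preserving \(\Lambda = 1\) on uniform critical grids), and `periodic`
  wraps the gap from the opposite end for circular sample sets.

## Sweep calibration

The sweep law is the cubic \(\lambda(t) = \lambda_0 + a t + b t^2 + c t^3\)
(nm, ns), with \(\lambda_0\) fixed at its known value (1250 nm in all
examples) and only `a`, `b`, `c` estimated, by Gauss-Newton on the fringe
model \(I(t) = \cos(2\pi d/\lambda(t) - 2\pi d/\lambda_0)\) with the
analytic Jacobian. Iterations run on time rescaled to `[0, 1]` (fitting
`a t_max`, `b t_max^2`, `c t_max^3`), because the raw Jacobian columns
`t, t^2, t^3` with `t ~ 10^3` ns differ by six orders of magnitude and
destroy the normal equations in double precision. Steps that do not reduce
the residual are halved (up to 20 times); convergence is declared when the
relative step norm falls below `tol = 1e-10` or the relative residual gain
falls below `1e-12` (the noise floor). Exhausting `max_iter = 100` without
convergence raises a typed error (`octframe_fit_divergence`) carrying the
last iterate and the residual history.

**Initialisation.** The least-squares surface is oscillatory — shifting the
fit by one fringe creates a local minimum — so the basin around the global
minimum is narrow. Two devices make the fit practical:

* the default initial guess (`init_phase_unwrap()`) recovers the fringe
  phase directly: analytic signal of the normalised trace, unwrapped phase,
  conversion to wavelength, then *linear* least squares for `a`, `b`, `c`.
  A simpler fringe-count heuristic (`init_fringe_count()`: `a` from the
  zero-crossing count, `b = c = 0`) is kept for reference, but for strongly
  curved sweeps the cubic terms dominate the accumulated phase and it lands
  several fringes away from the truth — outside any Gauss-Newton basin;
* `continuation = TRUE` fits on nested prefixes of the trace, doubling from
  about 128 samples to the full record. Early windows accumulate little
  phase, so their basins are wide; each stage's estimate seeds the next. The
  final full-window solve also restarts from the caller's own starting
  point and keeps the better converged run, which protects a good
  user-supplied start from drift on short noisy windows.

The defaults for synthetic traces — a 2000 ns window, 4096 samples, and an
MZI path difference `d` chosen for ~100 fringes
(`path_difference_for_fringes()`, giving `d` of a few millimetres) — are
desk-scale choices: enough fringes to identify the curvature terms, enough
samples (> 4 per fringe everywhere) for the phase initialiser, and
oscilloscope-plausible record lengths. On noiseless traces the fit recovers
its generating coefficients to near machine precision; the suite checks
`1e-4` relative, plus unbiasedness within Monte-Carlo error at amplitude
noise `sigma = 0.05` over 50 seeds.

`k_locations_from_sweep()` converts fitted sweeps to wavenumbers
\(k = 2\pi/\lambda(t)\), sorted ascending with the acquisition pairing kept,
and feeds the `sweep_law` selection scheme of the generators.

## Noise analysis

White noise of variance \(\sigma^2\) on the measured samples reaches the
frame-coefficient vector scaled by the frame-vector norms
(\(\langle u,\varphi_n\rangle = \Lambda_n\sqrt K\, u(k_n)\), so sample noise
becomes coefficient noise of standard deviation \(\sigma\|\varphi_n\|\)) and
is then orthogonally projected by \(\Phi^+\). The per-coefficient power of
the projected noise is bounded by \(\sigma^2 \max_n \|\varphi_n\|^2 / A\)
(`projected_noise_bound()`). This measured-sample reading is the only one
consistent with the worst-case reduction curve: a near-tight frame fed
plain white coefficient noise would keep the power at \(\sigma^2\)
regardless of oversampling.

For the sinc family \(\|\varphi_n\|^2 = \Lambda_n^2 \le \delta/K\), giving
the worst-case reduction \(10\log_{10}((1-x)^2/x)\) dB at \(x = \delta/K\)
(`theoretical_min_reduction_db()`), always slightly below the
sequential-averaging baseline \(10\log_{10}(K/\delta)\)
(`averaging_reduction_db()`) — the price of acquiring the redundancy in a
single sweep instead of `K/δ` separate sweeps. The 0 dB crossover solves
\(x = (1-x)^2\): `crossover_ratio()` finds it by bracketed root solving to
`1e-12`; analytically it is \((3+\sqrt5)/2 \approx 2.618\), comfortably
above the round figure of 2.3 quoted for it.

`monte_carlo_projected_noise()` verifies the bound empirically. Two
numerical guards matter for fine-grid sinc frames on a finite window:

* the pseudoinverse is truncated at singular value \(\sqrt A\): a finite
  sampling window leaves a tail of *edge modes* below the analytic frame
  bound (half-captured sincs at the window ends) whose inversion amplifies
  discretisation artifacts without any analogue in the bounded-frame model;
* `empirical_frame_bounds()` probes the frame with random unit vectors
  built from critical-grid sinc atoms centred at least 3 Nyquist intervals
  inside the sampled span — the analytic bounds describe signals whose
  energy lies where sampling coverage exists. For frames whose rows span
  the whole space (orthonormal or duplicated bases) the probes reduce to
  the uniform sphere and the estimates are exact Parseval constants.

Sinc frames are discretised (`build_sinc_frame()`) at 8 grid points per
Nyquist interval with the window padded 8 intervals beyond the location
span, rows scaled by \(\sqrt h\) so Euclidean inner products approximate
the continuous ones; the slow `1/t` sinc decay makes truncation the
dominant error (about 1% in inner products at this padding), and the
frame-level tolerances are set accordingly.

## What the generators emulate — and what they do not

`make_phantom()` builds piecewise-constant layered reflectivity images with
optional multiplicative exponential speckle texture; `spectra_from_image()`
zero-pads each column 20-fold and Fourier transforms it, so selected fine
bins carry the *continuous-frequency* spectrum of the depth-limited A-scan;
`select_nonuniform()` draws jittered, sweep-law, or uniformly decimated
sample sets; `add_noise()` injects circular complex white noise in k-space
(per-component standard deviation \(\sigma/\sqrt2\)); `synth_mzi()`
generates noisy fringe traces. All generators are pure functions of their
seeds.

Two desk-scale experiments package the comparative studies:

* `compare_ndft_methods()` — per seed: phantom, 2x-redundant jittered
  selection (jitter 0.4 of the spacing, so the max gap stays below `K`),
  both reconstructions, mean per-A-scan correlation of each. Default 96x8
  phantoms over 20 seeds.
* `psnr_vs_oversampling()` — one sweep-law acquisition geometry (the linear
  1250-1375 nm law) decimated to ratios {1, 1.6, 2, 2.6, 4}, fixed k-space
  noise at 10% of the RMS spectral magnitude, gain-normalised PSNR against
  the noiseless ratio-8 acquisition. Every ratio shares the same physical
  non-uniformity, so only the sampling rate varies.

A per-point jitter scheme cannot guarantee `δ < K` at critical density —
independent jitter `u ~ U(±f)` makes a gap `1 + u_{i+1} - u_i` exceed the
Nyquist interval with probability ~1/2 per gap — so the guarantee holds
only for redundant selection with `spacing × (1 + 2f) ≤ K`, and the
comparative experiments operate in that regime (which is also the regime of
interest: redundant, non-uniform acquisition).

What passing tests show about real data is correspondingly limited: the
phantoms are noise-free, piecewise-constant, and perfectly depth limited;
there is no speckle decorrelation, dispersion, detector nonlinearity, or
complex-conjugate artifact. The synthetic results validate the *transform
chain* — that the scaled NDFT inverts what the generator's acquisition
model produces, with the predicted noise behaviour — not the full physics
of an SS-OCT instrument.

## Problem sizes

The test and acceptance workloads use 96x8 to 96x16 phantoms, 20x dense
spectra, `N_f ≤ 32` / `N_T ≤ 16` oracle instances (50 of them), 40-vector
sinc frames, 5000-draw noise Monte Carlos, and 2048-4096-sample fringe
traces — sizes chosen so the whole suite completes in well under a minute
while every statistic retains a comfortable margin over its Monte-Carlo
error.

## Known limitations

* The scaled NDFT is a first-order surrogate for the dual-frame inverse;
  at heavy irregularity (jitter beyond ~10% of the spacing at 2x
  redundancy) it drifts percent-level away from the pseudoinverse even
  though both still reconstruct ground truth well.
* The analytic bound limits `(1 ∓ δ/K)²` are loose for near-uniform sets
  (actual bounds cluster near 1) and degenerate to `(0, 4)` at the critical
  boundary `δ = K`, where the uniform grid is in fact orthonormal.
* Sinc-frame discretisation error decays only like `1/padding`; tolerances
  tied to it (Gram orthonormality, row norms) are percent-level, not
  machine precision.
* No dispersion compensation, k-linearization by interpolation, or
  complex-conjugate-artifact removal: the package reconstructs from the
  samples it is given.
* Volumetric (C-scan) pipelines and DICOM I/O are out of scope; images are
  2-D matrices exchanged as PNG/TIFF.
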