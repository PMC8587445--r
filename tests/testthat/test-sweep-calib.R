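eq18_model <- sweep_model(1250, a = 0.00225, b = 1.9812e-6, c = 1.999e-9)

test_that("the cubic sweep law evaluates to printed wavelengths", {
  expect_equal(sweep_wavelength(0, eq18_model), 1250)
  expect_equal(sweep_wavelength(1000, eq18_model), 1256.2302, tolerance = 1e-10)
  linear <- sweep_model(1250, a = 0.00225)
  expect_equal(sweep_wavelength(1000, linear), 1252.25, tolerance = 1e-12)
})

test_that("the MZI fringe model starts at unity and slows as the wavelength grows", {
  linear <- sweep_model(1250, a = 0.00225)
  d <- path_difference_for_fringes(linear, 50000, 80)
  t <- seq(0, 50000, length.out = 20000)
  y <- mzi_model(t, linear, d)
  expect_equal(y[1], 1)
  # constant sweep: no phase accumulates
  expect_equal(mzi_model(t, sweep_model(1250), d), rep(1, length(t)))
  # zero-crossing spacing widens monotonically for a linear-in-lambda sweep;
  # crossings are located by linear interpolation between samples so the
  # comparison is not limited by the sampling resolution
  idx <- which(diff(sign(y)) != 0)
  crossings <- t[idx] - y[idx] * (t[idx + 1] - t[idx]) / (y[idx + 1] - y[idx])
  spacing <- diff(crossings)
  expect_true(all(diff(spacing) > 0))
})

test_that("noiseless fringe traces refit their generating cubic exactly", {
  ex <- sweep_recovery_experiment(seed = 1)
  expect_lt(max(ex$comparison$rel_error), 1e-6)
  expect_true(ex$fit$converged)
})

test_that("a nested linear sweep fits with vanishing curvature terms", {
  linear <- sweep_model(1250, a = 0.00225)
  d <- path_difference_for_fringes(linear, 2000, 30)
  trace <- synth_mzi(linear, d, seq(0, 2000, length.out = 2048))
  fit <- fit_sweep(trace)
  expect_equal(fit$model$a, 0.00225, tolerance = 1e-6)
  expect_lt(abs(fit$model$b), 1e-9)
  expect_lt(abs(fit$model$c), 1e-12)
})

test_that("starting at the truth is a fixed point of the Gauss-Newton iteration", {
  d <- path_difference_for_fringes(eq18_model, 2000, 100)
  trace <- synth_mzi(eq18_model, d, seq(0, 2000, length.out = 2048))
  fit <- fit_sweep(trace, init = eq18_model, continuation = FALSE)
  expect_lte(fit$iterations, 2)
  expect_equal(fit$model$a, eq18_model$a, tolerance = 1e-10)
  expect_equal(fit$model$b, eq18_model$b, tolerance = 1e-10)
  expect_equal(fit$model$c, eq18_model$c, tolerance = 1e-10)
})

test_that("noisy fits are unbiased within Monte-Carlo error and tighten with SNR", {
  d <- path_difference_for_fringes(eq18_model, 2000, 100)
  t <- seq(0, 2000, length.out = 2048)
  fit_at <- function(sigma, seeds) {
    vapply(seeds, function(s) {
      trace <- synth_mzi(eq18_model, d, t, sigma = sigma, seed = s)
      fit_sweep(trace, init = eq18_model)$model$a
    }, numeric(1))
  }
  a_hat <- fit_at(0.05, 1:50)
  se <- sd(a_hat) / sqrt(length(a_hat))
  expect_lt(abs(mean(a_hat) - eq18_model$a), 3 * se + 1e-12)
  # median recovery error shrinks as the noise level drops
  err_lo <- median(abs(fit_at(0.01, 1:15) - eq18_model$a))
  err_hi <- median(abs(fit_at(0.1, 1:15) - eq18_model$a))
  expect_lt(err_lo, err_hi)
})

test_that("divergence raises a typed error carrying the last iterate", {
  d <- path_difference_for_fringes(eq18_model, 2000, 100)
  trace <- synth_mzi(eq18_model, d, seq(0, 2000, length.out = 512))
  bad_init <- sweep_model(1250, a = 0.02)
  cnd <- tryCatch(
    fit_sweep(trace, init = bad_init, continuation = FALSE, max_iter = 5),
    error = function(e) e
  )
  expect_s3_class(cnd, "octframe_fit_divergence")
  expect_s3_class(cnd$last, "sweep_model")
  expect_true(length(cnd$residual_history) >= 1)
})

test_that("sweep wavenumbers are sorted, paired, and round-trip to wavelengths", {
  linear <- sweep_model(1250, a = 0.00225)
  t <- seq(0, 55555.6, length.out = 500)
  kl <- k_locations_from_sweep(t, linear)
  expect_true(all(diff(kl$k) > 0))
  # endpoints span 2 pi / 1375 ... 2 pi / 1250 (sweep reaches 1375 nm)
  expect_equal(min(kl$k), 2 * pi / sweep_wavelength(55555.6, linear),
    tolerance = 1e-9
  )
  expect_equal(max(kl$k), 2 * pi / 1250, tolerance = 1e-12)
  # wavenumber spacing is strictly non-uniform for uniform-in-t sampling
  expect_gt(diff(range(diff(kl$k))) / mean(diff(kl$k)), 0.1)
  # acquisition pairing: lambda = 2 pi / k reproduces the sweep law at time t
  expect_equal(2 * pi / kl$k, sweep_wavelength(kl$time, linear),
    tolerance = 1e-12
  )
  expect_error(
    k_locations_from_sweep(t, sweep_model(1250)),
    "strictly monotone"
  )
})

test_that("traces and sweep models survive their file round trips", {
  d <- path_difference_for_fringes(eq18_model, 2000, 50)
  trace <- synth_mzi(eq18_model, d, seq(0, 2000, length.out = 256),
    sigma = 0.02, seed = 4
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_mzi_trace(trace, path)
  back <- read_mzi_trace(path)
  expect_equal(back$time, trace$time, tolerance = 1e-12)
  expect_equal(back$amplitude, trace$amplitude, tolerance = 1e-12)
  expect_equal(attr(back, "path_difference"), d, tolerance = 1e-9)
  mpath <- withr::local_tempfile(fileext = ".json")
  write_sweep_model(eq18_model, mpath)
  m2 <- read_sweep_model(mpath)
  expect_equal(unclass(m2), unclass(eq18_model), tolerance = 1e-12)
})

test_that("sweep fits expose tidy, glance and autoplot interfaces", {
  d <- path_difference_for_fringes(eq18_model, 2000, 60)
  trace <- synth_mzi(eq18_model, d, seq(0, 2000, length.out = 1024))
  fit <- fit_sweep(trace)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(td$estimate[1], eq18_model$a, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 1024L)
  expect_s3_class(autoplot(fit), "ggplot")
})
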