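test_that("endpoint grid mapping reproduces direct affine arithmetic", {
  ks <- k_sample_set(c(1.0, 1.2, 1.7, 1.9), rep(1 + 0i, 4))
  gm <- map_k_to_grid(ks, 4)
  expect_equal(gm$mapped, c(0, 2 / 3, 7 / 3, 3), tolerance = 1e-12)
  expect_equal(gm$rounded, c(0L, 1L, 2L, 3L))
  expect_equal(gm$residual, c(0, -1 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_true(all(abs(gm$residual) <= 0.5))
})

test_that("uniform critical grids map to the identity with zero residuals", {
  ks <- k_sample_set(0:7, rep(1 + 0i, 8))
  for (mode in c("endpoints", "nyquist")) {
    gm <- map_k_to_grid(ks, 8, mode = mode)
    expect_equal(gm$mapped, as.numeric(0:7))
    expect_equal(gm$rounded, 0:7)
    expect_equal(gm$residual, rep(0, 8))
  }
})

test_that("two-fold redundant uniform grids hit every rounded index exactly twice", {
  n_t <- 6
  ks <- k_sample_set((0:(2 * n_t - 1)) / 2, rep(1 + 0i, 2 * n_t))
  gm_ep <- map_k_to_grid(ks, n_t, mode = "endpoints")
  expect_true(all(table(gm_ep$rounded) == 2))
  gm_ny <- map_k_to_grid(ks, n_t, mode = "nyquist", wrap = TRUE)
  expect_true(all(table(gm_ny$rounded) == 2))
})

test_that("degenerate k ranges and undersized grids are rejected", {
  ks <- k_sample_set(c(0, 4, 8), c(1, 1, 1))
  expect_error(map_k_to_grid(ks, 4, mode = "nyquist"), "output band")
  expect_error(recon_config(n_out = 1), "at least 2")
  # frame condition: three samples across an 8-point band
  sparse <- k_sample_set(c(0, 3.5, 7.4), c(1, 1, 1))
  expect_error(scaled_ndft(sparse, n_out = 8), "Frame condition")
  expect_warning(
    scaled_ndft(sparse, recon_config(n_out = 8, frame_check = "warn")),
    "Frame condition"
  )
})

test_that("all reconstruction paths equal the flipped inverse DFT on critical grids", {
  set.seed(21)
  x <- rnorm(32)
  ks <- k_sample_set(0:31, fft(x))
  flipped_idft <- fft(fft(x)) / 32 # u(-z) of the DFT model
  y_scaled <- scaled_ndft(ks)$value
  y_standard <- standard_ndft(ks)$value
  y_fft <- gridded_fft_reconstruct(ks, residual_phase = "drop")$value
  expect_lt(max(Mod(y_scaled - flipped_idft)), 1e-10)
  expect_lt(max(Mod(y_standard - flipped_idft)), 1e-10)
  expect_lt(max(Mod(y_fft - flipped_idft)), 1e-10)
  # natural depth order recovers the signal
  expect_lt(max(Mod(as_depth_profile(scaled_ndft(ks))$value - x)), 1e-10)
})

test_that("a flat spectrum reconstructs to an impulse at zero depth", {
  ks <- k_sample_set(0:15, rep(1 + 0i, 16))
  y <- scaled_ndft(ks)$value
  expect_equal(Mod(y[1]), 1, tolerance = 1e-12)
  expect_lt(max(Mod(y[-1])), 1e-10)
})

test_that("scaled and standard NDFT differ whenever some Lambda is not one", {
  ks <- jittered_instance(12, 2, 0.3, seed = 3)
  y_scaled <- scaled_ndft(ks, n_out = 12)$value
  y_standard <- standard_ndft(ks, n_out = 12)$value
  expect_gt(max(Mod(y_scaled - y_standard)), 1e-3)
})

test_that("reconstruction is linear in the sample values", {
  ks <- jittered_instance(10, 2, 0.25, seed = 11)
  v2 <- withr::with_seed(
    99,
    complex(real = rnorm(nrow(ks)), imaginary = rnorm(nrow(ks)))
  )
  ks2 <- k_sample_set(ks$k, v2, 1, n_out = 10)
  mix <- k_sample_set(ks$k, 2 * ks$value - 3i * v2, 1, n_out = 10)
  for (fun in list(scaled_ndft, standard_ndft, gridded_fft_reconstruct)) {
    lhs <- fun(mix, n_out = 10)$value
    rhs <- 2 * fun(ks, n_out = 10)$value - 3i * fun(ks2, n_out = 10)$value
    expect_lt(max(Mod(lhs - rhs)), 1e-10)
  }
})

test_that("exact residual-phase gridding is an algebraic rewriting of the scaled NDFT", {
  for (s in 1:5) {
    ks <- jittered_instance(12, 2, 0.35, seed = s)
    y_exact <- gridded_fft_reconstruct(
      ks, recon_config(n_out = 12, residual_phase = "exact")
    )$value
    y_direct <- scaled_ndft(ks, n_out = 12)$value
    expect_lt(max(Mod(y_exact - y_direct)), 1e-10)
  }
})

test_that("dropped residual phase error shrinks as samples approach the grid", {
  # max |residual| is controlled by the jitter fraction at critical density
  errs <- vapply(c(0.25, 0.1, 0.05), function(jf) {
    e <- vapply(1:6, function(s) {
      n_t <- 16
      k <- jittered_locations(n_t, 1.001, jf, seed = 100 * s)
      values <- withr::with_seed(
        s,
        complex(real = rnorm(length(k)), imaginary = rnorm(length(k)))
      )
      ks <- k_sample_set(k, values, 1, n_out = n_t)
      cfg_w <- recon_config(
        n_out = n_t, residual_phase = "drop", frame_check = "warn"
      )
      y_drop <- suppressWarnings(gridded_fft_reconstruct(ks, cfg_w)$value)
      y_ref <- suppressWarnings(scaled_ndft(
        ks, recon_config(n_out = n_t, frame_check = "warn")
      )$value)
      sqrt(sum(Mod(y_drop - y_ref)^2) / sum(Mod(y_ref)^2))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.15)
})

test_that("scaled NDFT tracks the dual-frame pseudoinverse on small instances", {
  errs <- vapply(1:20, function(s) {
    n_t <- withr::with_seed(s, sample(8:16, 1))
    ks <- jittered_instance(n_t, 2, 0.05, seed = 300 + s)
    x_hat <- as_depth_profile(scaled_ndft(ks, n_out = n_t))$value
    x_oracle <- pinv_reconstruction(ks, n_t)
    sqrt(sum(Mod(x_hat - x_oracle)^2) / sum(Mod(x_oracle)^2))
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("reconstructed shape is independent of uniform redundancy", {
  phantom <- make_phantom(64, 8, seed = 2)
  dense <- spectra_from_image(phantom, 20)
  recon_at <- function(r) {
    reconstruct_bscan(
      purrr::map(dense, select_nonuniform,
        n_select = r * 64, scheme = "uniform"
      ),
      recon_config("scaled_ndft", n_out = 64)
    )
  }
  base <- recon_at(1)
  for (r in c(2, 4)) {
    img <- recon_at(r)
    expect_gt(mean(ascan_correlations(unclass(base), unclass(img))), 0.999)
    # overall amplitude grows like sqrt(R) under the single-Lambda weighting
    expect_equal(max(img) / max(base), sqrt(r), tolerance = 1e-6)
  }
})

test_that("B-scan assembly stacks columns, un-flips, and validates widths", {
  phantom <- make_phantom(48, 8, seed = 5)
  dense <- spectra_from_image(phantom, 20)
  spectra <- purrr::map(dense, select_nonuniform, n_select = 48, scheme = "uniform")
  img <- reconstruct_bscan(spectra, recon_config(n_out = 48))
  expect_equal(dim(img), c(48L, 8L))
  expect_gt(mean(ascan_correlations(unclass(phantom), unclass(img))), 0.999)
  single <- reconstruct_bscan(spectra[1], recon_config(n_out = 48))
  expect_equal(ncol(single), 1L)
  # mixed natural output lengths are an error without an explicit n_out
  mixed <- list(
    k_sample_set(0:15, rep(1 + 0i, 16)),
    k_sample_set(0:11, rep(1 + 0i, 12))
  )
  expect_error(reconstruct_bscan(mixed, recon_config()), "Mixed output")
  logged <- reconstruct_bscan(spectra[1:2],
    recon_config(n_out = 48),
    log_compress = TRUE, dynamic_range_db = 40
  )
  expect_lte(max(logged), 0)
  expect_gte(min(logged), -40)
})

test_that("scaled NDFT beats the unweighted baseline on jittered redundant sampling", {
  cmp <- compare_ndft_methods(seeds = 1:6)
  expect_true(all(cmp$scaled_wins))
  expect_gt(mean(cmp$scaled), 0.98)
})

test_that("k-sample sets survive a CSV + sidecar round trip", {
  ks <- jittered_instance(10, 1.5, 0.2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_k_samples(ks, path)
  back <- read_k_samples(path)
  expect_equal(back$k, ks$k, tolerance = 1e-12)
  expect_equal(back$value, ks$value, tolerance = 1e-12)
  expect_equal(attr(back, "nyquist_interval"), 1)
  expect_equal(attr(back, "n_out"), 10)
})
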