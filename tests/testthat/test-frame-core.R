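test_that("lambda scales reduce to known values on uniform and irregular grids", {
  # uniform critical grid: every scale is 1
  expect_equal(lambda_scales(0:9, 1), rep(1, 10))
  # uniform 2x oversampled grid: sqrt(1/2) everywhere (one-sided ends agree)
  expect_equal(lambda_scales(seq(0, 4.5, by = 0.5), 1),
    rep(sqrt(0.5), 10),
    tolerance = 1e-12
  )
  # central differences on an irregular set
  lam <- lambda_scales(c(0, 0.6, 1.0, 1.8), 1)
  expect_equal(lam[2:3], c(sqrt(0.5), sqrt(0.6)), tolerance = 1e-12)
  # one-sided endpoints use the single adjacent gap
  expect_equal(lam[c(1, 4)], c(sqrt(0.6), sqrt(0.8)), tolerance = 1e-12)
})

test_that("lambda scales are covariant under joint rescaling of locations and T", {
  locs <- c(0, 0.37, 0.81, 1.9, 2.2, 3.05)
  for (s in c(0.25, 3, 17)) {
    expect_equal(
      lambda_scales(locs * s, s),
      lambda_scales(locs, 1),
      tolerance = 1e-12
    )
  }
})

test_that("invalid sample locations are rejected", {
  expect_error(lambda_scales(c(0, 1, 1), 1), "strictly increasing")
  expect_error(lambda_scales(c(0, 2, 1), 1), "strictly increasing")
  expect_error(lambda_scales(c(0, 1), 1), "length >= 3")
  expect_error(max_gap(c(3, 2, 1), 1), "strictly increasing")
})

test_that("max gap and the frame condition flag match direct computation", {
  u <- max_gap(seq(0, 5, by = 0.5), 1)
  expect_equal(u$delta, 0.5)
  expect_true(u$satisfied)
  irr <- max_gap(c(0, 0.6, 1.0, 1.8), 1)
  expect_equal(irr$delta, 0.8)
  expect_true(irr$satisfied)
  wide <- max_gap(seq(0, 6, by = 1.5), 1)
  expect_equal(wide$delta, 1.5)
  expect_false(wide$satisfied)
})

test_that("analytic frame-bound limits follow (1 -/+ delta/T)^2", {
  lim <- frame_bound_limits(0.5, 1)
  expect_equal(lim$lower, 0.25)
  expect_equal(lim$upper, 2.25)
  lim <- frame_bound_limits(0.8, 1)
  expect_equal(lim$lower, 0.04, tolerance = 1e-12)
  expect_equal(lim$upper, 3.24, tolerance = 1e-12)
  # both limits approach 1 as the gap vanishes
  lim <- frame_bound_limits(1e-9, 1)
  expect_equal(lim$lower, 1, tolerance = 1e-8)
  expect_equal(lim$upper, 1, tolerance = 1e-8)
  expect_error(frame_bound_limits(1.2, 1), "Frame condition")
})

test_that("critical uniform sinc frame is numerically orthonormal", {
  fr <- build_sinc_frame(0:12, 1)
  expect_equal(attr(fr, "lambda"), rep(1, 13))
  gram <- unclass(fr) %*% t(unclass(fr))
  # tolerance is truncation-dominated: the 1/t sinc tails cut at the window
  # edge leave O(1/pad) inner-product error even for interior rows
  expect_lt(max(abs(gram[4:10, 4:10] - diag(13)[4:10, 4:10])), 0.02)
})

test_that("oversampled sinc frame has redundant rows (Gram rank < row count)", {
  fr <- build_sinc_frame(seq(0, 12, by = 0.5), 1)
  gram <- unclass(fr) %*% t(unclass(fr))
  sv <- svd(gram)$d
  expect_lt(sum(sv > 1e-6 * sv[1]), nrow(fr))
  expect_error(build_sinc_frame(seq(0, 12, by = 1.5), 1), "Frame condition")
})

test_that("pseudoinverse dual matches closed forms on orthonormal and tight frames", {
  # unitary analysis matrix: dual is the conjugate transpose
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(dual_frame_pinv(frame_matrix(q, 1, 1)), t(q),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # each orthonormal row twice: 2x redundant tight frame, dual rows halved
  dup <- rbind(q, q)
  expect_equal(
    dual_frame_pinv(frame_matrix(dup, 2, 2)), t(dup) / 2,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # random tall full-rank matrix: left inverse property
  set.seed(5)
  m <- matrix(rnorm(40), 8, 5)
  expect_lt(max(abs(dual_frame_pinv(m) %*% m - diag(5))), 1e-10)
})

test_that("rank-deficient tall frames are rejected with a named deficiency", {
  bad <- matrix(rnorm(40), 8, 5)
  bad[, 5] <- bad[, 4] # dependent columns -> rank 4
  expect_error(dual_frame_pinv(bad), "rank deficient")
})

test_that("reconstruct-then-analyse is idempotent for coefficients in range", {
  set.seed(9)
  for (i in 1:8) {
    nr <- sample(6:20, 1)
    nc <- sample(4:16, 1)
    phi <- matrix(rnorm(nr * nc), nr, nc) +
      1i * matrix(rnorm(nr * nc), nr, nc)
    pinv <- tryCatch(dual_frame_pinv(phi), error = function(e) NULL)
    if (is.null(pinv)) next
    c0 <- phi %*% (rnorm(nc) + 1i * rnorm(nc))
    expect_lt(max(Mod(phi %*% (pinv %*% c0) - c0)), 1e-8)
  }
})

test_that("frequency-domain dual of a periodic shift-invariant frame matches the pseudoinverse", {
  # circulant sinc (Dirichlet) frame on a 48-point circle, band |m| <= 10,
  # 24 shifts: the frame operator is diagonal in frequency, so the dual is
  # phi_n-hat / sum_n |phi_n-hat|^2 (with the discrete Parseval factor G)
  G <- 48
  B <- 10
  base <- Re(fft(c(rep(1, B + 1), rep(0, G - 2 * B - 1), rep(1, B)),
    inverse = TRUE
  )) / G
  shifts <- seq(0, G - 2, by = 2)
  phi <- t(vapply(
    shifts,
    function(s) base[((seq_len(G) - 1 - s) %% G) + 1],
    numeric(G)
  ))
  pinv <- dual_frame_pinv(frame_matrix(phi, 0.1, 10))
  s_freq <- rowSums(vapply(
    seq_len(nrow(phi)),
    function(n) Mod(fft(phi[n, ]))^2, numeric(G)
  ))
  dual_freq <- vapply(seq_len(nrow(phi)), function(n) {
    spec <- fft(phi[n, ])
    spec <- ifelse(s_freq > 1e-12, spec * G / s_freq, 0)
    Re(fft(spec, inverse = TRUE) / G)
  }, numeric(G))
  expect_lt(max(abs(pinv - dual_freq)), 1e-6)
})

test_that("empirical frame bounds recover Parseval constants exactly", {
  q <- frame_matrix(diag(8), 1, 1)
  eb <- empirical_frame_bounds(q, trials = 200, seed = 2)
  expect_equal(eb$lower, 1, tolerance = 1e-12)
  expect_equal(eb$upper, 1, tolerance = 1e-12)
  dup <- frame_matrix(rbind(diag(8), diag(8)), 2, 2)
  eb <- empirical_frame_bounds(dup, trials = 200, seed = 2)
  expect_equal(eb$lower, 2, tolerance = 1e-12)
  expect_equal(eb$upper, 2, tolerance = 1e-12)
})

test_that("empirical bounds of irregular sinc frames respect the analytic limits", {
  locs <- irregular_locations(0.5, n = 28, seed = 4)
  fr <- build_sinc_frame(locs, 1)
  eb <- empirical_frame_bounds(fr, trials = 1000, seed = 7)
  expect_gte(eb$lower, attr(fr, "lower_limit"))
  expect_lte(eb$upper, attr(fr, "upper_limit"))
})

test_that("frame matrices round-trip through tidiers and CSV", {
  fr <- build_sinc_frame(c(0, 0.9, 1.7, 2.4, 3.4), 1)
  td <- tidy(fr)
  expect_named(td, c("vector", "norm", "location", "lambda"))
  expect_equal(td$norm, attr(fr, "lambda"), tolerance = 0.02)
  gl <- glance(fr)
  expect_equal(gl$n_vectors, 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(fr, path)
  back <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
  expect_equal(unname(back), unclass(fr), tolerance = 1e-12, ignore_attr = TRUE)
})
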