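#' Cubic wavelength-sweep model of a swept laser source
#'
#' The instantaneous wavelength of the swept source is modelled as a cubic
#' polynomial in time, `lambda(t) = lambda0 + a t + b t^2 + c t^3`, with
#' wavelength in nanometres and time in nanoseconds. `lambda0` is the start
#' wavelength of the sweep and is treated as known throughout (only `a`,
#' `b`, `c` are fitted from calibration fringes).
#'
#' @param lambda0 Start wavelength (nm), positive.
#' @param a,b,c Sweep coefficients (nm/ns, nm/ns^2, nm/ns^3).
#' @return A list of class `sweep_model`.
#' @examples
#' m <- sweep_model(1250, a = 0.00225, b = 1.9812e-6, c = 1.999e-9)
#' sweep_wavelength(1000, m) # 1256.2302 nm
#' @export
sweep_model <- function(lambda0 = 1250, a = 0, b = 0, c = 0) {
  if (lambda0 <= 0) abort("`lambda0` must be positive.")
  structure(
    list(lambda0 = lambda0, a = a, b = b, c = c),
    class = "sweep_model"
  )
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(
    "<sweep_model> lambda(t) = ", x$lambda0, " + ", signif(x$a, 6), " t + ",
    signif(x$b, 6), " t^2 + ", signif(x$c, 6),
    " t^3   [nm, t in ns]\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate the wavelength sweep
#'
#' @param t Numeric vector of times (ns).
#' @param model A [sweep_model()].
#' @return Wavelengths `lambda0 + a t + b t^2 + c t^3` (nm).
#' @export
sweep_wavelength <- function(t, model) {
  model$lambda0 + model$a * t + model$b * t^2 + model$c * t^3
}

#' Mach-Zehnder interferometer fringe model
#'
#' An MZI with fixed path difference `d` between its arms, illuminated by
#' the swept source, produces the normalised fringe
#' `I(t) = cos(2 pi d / lambda(t) - 2 pi d / lambda0)`: phase zero (value 1)
#' at the sweep start, accumulating one fringe per wavenumber step `2 pi / d`.
#'
#' @inheritParams sweep_wavelength
#' @param d Positive path-length difference between the MZI arms (nm).
#' @return Numeric fringe amplitudes in `[-1, 1]`.
#' @export
mzi_model <- function(t, model, d) {
  if (d <= 0) abort("`d` must be positive.")
  lam <- sweep_wavelength(t, model)
  if (any(lam <= 0)) abort("Sweep wavelength must stay positive over the window.")
  cos(2 * pi * d / lam - 2 * pi * d / model$lambda0)
}

#' Path difference giving a target fringe count
#'
#' Chooses the MZI path difference `d` so the model sweep accumulates
#' `fringes` full fringes over `[0, t_max]`.
#'
#' @inheritParams mzi_model
#' @param t_max Sweep window end (ns).
#' @param fringes Target fringe count (default 100).
#' @return Path difference `d` in nm.
#' @export
path_difference_for_fringes <- function(model, t_max, fringes = 100) {
  lam_end <- sweep_wavelength(t_max, model)
  dk <- 1 / model$lambda0 - 1 / lam_end
  if (dk <= 0) abort("Sweep must increase the wavelength over the window.")
  fringes / dk
}

#' Measured MZI calibration trace
#'
#' A tibble of (time, amplitude) fringe samples with the interferometer path
#' difference and the known sweep start wavelength attached.
#'
#' @param time Increasing numeric vector (ns).
#' @param amplitude Numeric fringe amplitudes, same length.
#' @param path_difference MZI arm path difference `d` (nm).
#' @param lambda0 Known sweep start wavelength (nm).
#' @return A tibble of class `mzi_trace`.
#' @export
mzi_trace <- function(time, amplitude, path_difference, lambda0 = 1250) {
  if (length(time) != length(amplitude)) {
    abort("`time` and `amplitude` must have the same length.")
  }
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing.")
  if (path_difference <= 0) abort("`path_difference` must be positive.")
  new_tibble(
    list(time = as.double(time), amplitude = as.double(amplitude)),
    nrow = length(time),
    path_difference = path_difference, lambda0 = lambda0,
    class = "mzi_trace"
  )
}

#' @export
print.mzi_trace <- function(x, ...) {
  cat(
    "<mzi_trace> ", nrow(x), " samples over [",
    signif(min(x$time), 6), ", ", signif(max(x$time), 6), "] ns, d = ",
    signif(attr(x, "path_difference"), 6), " nm\n",
    sep = ""
  )
  NextMethod()
}

# Discrete analytic signal (FFT half-spectrum); used by the phase initialiser.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  d <- diff(p)
  adj <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  p + adj
}

#' Initial sweep guesses from a fringe trace
#'
#' `init_fringe_count()` is the simple heuristic: it counts zero crossings to
#' get the total fringe number, solves for the linear rate `a` that would
#' produce it (with `b = c = 0`). For strongly nonlinear sweeps the cubic
#' terms dominate the accumulated phase, so this lands far from the truth.
#'
#' `init_phase_unwrap()` (the [fit_sweep()] default) recovers the fringe
#' phase itself: it forms the analytic signal of the amplitude-normalised
#' trace, unwraps its phase `phi(t)`, converts it to a wavelength estimate
#' `lambda(t) = 1 / (1/lambda0 - phi/(2 pi d))`, and fits `a`, `b`, `c` by
#' ordinary linear least squares. The 2% trace edges are discarded to avoid
#' the analytic-signal end artifacts.
#'
#' @param trace An [mzi_trace()].
#' @return A [sweep_model()] initial guess.
#' @export
init_phase_unwrap <- function(trace) {
  d <- attr(trace, "path_difference")
  lambda0 <- attr(trace, "lambda0")
  y <- trace$amplitude
  scale <- max(abs(y))
  if (scale > 0) y <- y / scale
  phi <- unwrap_phase(Arg(analytic_signal(y)))
  phi <- phi - phi[1]
  n <- length(phi)
  keep <- seq.int(max(1, floor(0.02 * n)), ceiling(0.98 * n))
  inv_lam <- 1 / lambda0 - phi[keep] / (2 * pi * d)
  if (any(inv_lam <= 0)) abort("Unwrapped phase implies non-physical wavelengths.")
  dl <- 1 / inv_lam - lambda0
  tm <- max(abs(trace$time))
  tau <- trace$time[keep] / tm
  beta <- unname(stats::lm.fit(cbind(tau, tau^2, tau^3), dl)$coefficients)
  sweep_model(lambda0,
    a = beta[1] / tm, b = beta[2] / tm^2, c = beta[3] / tm^3
  )
}

#' @rdname init_phase_unwrap
#' @export
init_fringe_count <- function(trace) {
  d <- attr(trace, "path_difference")
  lambda0 <- attr(trace, "lambda0")
  y <- trace$amplitude
  crossings <- sum(diff(sign(y)) != 0 & sign(y[-length(y)]) != 0)
  fringes <- max(crossings / 2, 0.5)
  t_max <- max(trace$time)
  inv_end <- 1 / lambda0 - fringes / d
  if (inv_end <= 0) abort("Fringe count implies non-physical wavelengths.")
  sweep_model(lambda0, a = (1 / inv_end - lambda0) / t_max)
}

#' Fit the cubic sweep model to an MZI trace by Gauss-Newton
#'
#' Solves the nonlinear least-squares problem
#' `min_{a,b,c} || I_MZI(t; a, b, c) - y(t) ||^2`, with `lambda0` held fixed,
#' by Gauss-Newton iterations with the analytic Jacobian. Iterations run on
#' time rescaled to `[0, 1]` (coefficients `a t_max`, `b t_max^2`,
#' `c t_max^3`) so the Jacobian stays well conditioned for nanosecond time
#' bases. Steps that increase the residual are halved up to 10 times; the
#' iteration stops when the relative step norm falls below `tol`.
#'
#' @param trace An [mzi_trace()] (amplitudes are fit as given; normalise
#'   detector traces to unit amplitude first).
#' @param init Optional [sweep_model()] starting point; defaults to
#'   [init_phase_unwrap()].
#' @param tol Relative step-norm convergence tolerance (default 1e-10).
#' @param max_iter Maximum Gauss-Newton iterations per stage (default 100).
#' @param continuation The least-squares surface is oscillatory (one local
#'   minimum per fringe shift), so the raw Gauss-Newton basin around the
#'   global minimum is narrow. With `continuation = TRUE` (default) the fit
#'   proceeds on nested prefixes of the trace, doubling the window from
#'   about 128 samples to the full record and re-using each stage's
#'   estimate as the next starting point: early windows accumulate little
#'   phase, so the basin there is wide, and each doubling keeps the iterate
#'   within the next basin. `FALSE` runs a single full-window fit.
#' @return A `sweep_fit` object: the fitted [sweep_model()] plus diagnostics
#'   (`residual_norm`, `iterations` across stages, `converged`,
#'   `residual_history` of the final stage). Divergence (or exhausting
#'   `max_iter`) raises an error of class `octframe_fit_divergence` carrying
#'   the last iterate and the residual history.
#' @export
fit_sweep <- function(trace, init = NULL, tol = 1e-10, max_iter = 100,
                      continuation = TRUE) {
  d <- attr(trace, "path_difference")
  lambda0 <- attr(trace, "lambda0")
  if (is.null(init)) init <- init_phase_unwrap(trace)
  tm <- max(abs(trace$time))
  n <- nrow(trace)
  theta <- c(init$a * tm, init$b * tm^2, init$c * tm^3)
  model_of <- function(theta) sweep_model(lambda0,
    a = unname(theta[1] / tm), b = unname(theta[2] / tm^2),
    c = unname(theta[3] / tm^3)
  )

  theta0 <- theta
  sizes <- integer()
  if (continuation && n > 256) {
    m <- floor(log2(n / 128))
    sizes <- unique(ceiling(n / 2^(m:1)))
    sizes <- sizes[sizes < n]
  }
  stage_iters <- 0
  for (sz in sizes) {
    st <- gauss_newton_mzi(
      tau = trace$time[seq_len(sz)] / tm, y = trace$amplitude[seq_len(sz)],
      theta = theta, d = d, lambda0 = lambda0,
      tol = max(tol, 1e-9), max_iter = max_iter, model_of = model_of,
      error_on_maxiter = FALSE
    )
    theta <- st$theta
    stage_iters <- stage_iters + st$iterations
  }
  # Final full-window solve from the continuation iterate and, when it
  # differs, from the caller's starting point: short noisy windows can drift
  # into a neighbouring fringe-shift minimum, while a good caller-supplied
  # start can reach the global basin directly. Keep the better converged run.
  starts <- list(theta)
  if (any(theta != theta0)) starts <- c(starts, list(theta0))
  runs <- lapply(starts, function(th) {
    gauss_newton_mzi(
      tau = trace$time / tm, y = trace$amplitude, theta = th, d = d,
      lambda0 = lambda0, tol = tol, max_iter = max_iter,
      model_of = model_of, error_on_maxiter = FALSE
    )
  })
  ok <- vapply(runs, function(r) r$converged, logical(1))
  if (!any(ok)) {
    abort(paste0("Gauss-Newton did not converge in ", max_iter, " iterations."),
      class = "octframe_fit_divergence",
      last = model_of(runs[[1]]$theta),
      residual_history = runs[[1]]$rss_history
    )
  }
  runs <- runs[ok]
  st <- runs[[which.min(vapply(runs, function(r) r$rss, numeric(1)))]]
  structure(
    list(
      model = model_of(st$theta), lambda0 = lambda0, path_difference = d,
      residual_norm = sqrt(st$rss),
      iterations = stage_iters + sum(vapply(runs, function(r) r$iterations, numeric(1))),
      converged = TRUE, residual_history = st$rss_history,
      n = n, trace = trace
    ),
    class = "sweep_fit"
  )
}

# One Gauss-Newton solve of min ||cos(phi(tau; theta)) - y||^2 with analytic
# Jacobian and step halving; time already rescaled to tau in [0, 1].
gauss_newton_mzi <- function(tau, y, theta, d, lambda0, tol, max_iter,
                             model_of, error_on_maxiter = TRUE) {
  resid_of <- function(theta) {
    lam <- lambda0 + theta[1] * tau + theta[2] * tau^2 + theta[3] * tau^3
    if (any(lam <= 0)) {
      return(NULL)
    }
    phi <- 2 * pi * d / lam - 2 * pi * d / lambda0
    list(r = cos(phi) - y, lam = lam, phi = phi)
  }
  st <- resid_of(theta)
  if (is.null(st)) {
    abort("Initial guess implies non-positive wavelengths.",
      class = "octframe_fit_divergence",
      last = model_of(theta), residual_history = numeric()
    )
  }
  rss_history <- sum(st$r^2)
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    # d cos(phi)/d theta_j = sin(phi) * 2 pi d * tau^j / lambda^2
    base <- sin(st$phi) * 2 * pi * d / st$lam^2
    J <- cbind(base * tau, base * tau^2, base * tau^3)
    step <- tryCatch(qr.solve(J, -st$r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      abort("Gauss-Newton step failed (singular Jacobian).",
        class = "octframe_fit_divergence",
        last = model_of(theta), residual_history = rss_history
      )
    }
    rss <- sum(st$r^2)
    improved <- FALSE
    for (h in 0:20) {
      cand <- theta + step / 2^h
      st_new <- resid_of(cand)
      if (!is.null(st_new) && sum(st_new$r^2) < rss) {
        theta_new <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) {
      # no damped Gauss-Newton step decreases the residual: the iterate is a
      # numerical stationary point (at the noise floor of the data)
      converged <- TRUE
      break
    }
    rel_step <- sqrt(sum((theta_new - theta)^2)) / (sqrt(sum(theta^2)) + 1e-30)
    rel_gain <- (rss - sum(st_new$r^2)) / (sum(st_new$r^2) + 1e-30)
    theta <- theta_new
    st <- st_new
    rss_history <- c(rss_history, sum(st$r^2))
    if (rel_step < tol || rel_gain < 1e-12) {
      # converged: negligible step, or the residual is at its (noise) floor
      converged <- TRUE
      break
    }
  }
  if (!converged && error_on_maxiter) {
    abort(paste0("Gauss-Newton did not converge in ", max_iter, " iterations."),
      class = "octframe_fit_divergence",
      last = model_of(theta), residual_history = rss_history
    )
  }
  list(
    theta = theta, rss = sum(st$r^2), rss_history = rss_history,
    iterations = iter, converged = converged
  )
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat(
    "<sweep_fit> converged in ", x$iterations, " iterations, ||r|| = ",
    signif(x$residual_norm, 4), "\n",
    sep = ""
  )
  print(x$model)
  invisible(x)
}

#' @export
tidy.sweep_fit <- function(x, ...) {
  tibble(
    term = c("a", "b", "c"),
    estimate = c(x$model$a, x$model$b, x$model$c),
    unit = c("nm/ns", "nm/ns^2", "nm/ns^3")
  )
}

#' @export
glance.sweep_fit <- function(x, ...) {
  tibble(
    residual_norm = x$residual_norm,
    iterations = x$iterations,
    converged = x$converged,
    nobs = x$n,
    lambda0 = x$lambda0,
    path_difference = x$path_difference
  )
}

#' @export
autoplot.sweep_fit <- function(object, n_show = 400, ...) {
  tr <- object$trace
  idx <- seq_len(min(n_show, nrow(tr)))
  df <- tibble(
    time = tr$time[idx],
    observed = tr$amplitude[idx],
    fitted = mzi_model(tr$time[idx], object$model, object$path_difference)
  )
  df <- tidyr::pivot_longer(df, c("observed", "fitted"),
    names_to = "series", values_to = "amplitude"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude,
    colour = .data$series, linetype = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "fringe amplitude") +
    ggplot2::theme_minimal()
}

#' k-space sample locations implied by a sweep law
#'
#' Converts sweep times to optical wavenumbers `k(t) = 2 pi / lambda(t)`.
#' Because the wavelength increases during the sweep, the wavenumbers arrive
#' in decreasing order; the result is sorted ascending in `k` with the
#' acquisition time kept alongside so the pairing to the recorded samples is
#' preserved.
#'
#' @inheritParams sweep_wavelength
#' @return A tibble with columns `k` (ascending, nm^-1) and `time` (ns).
#' @export
k_locations_from_sweep <- function(t, model) {
  lam <- sweep_wavelength(t, model)
  if (any(lam <= 0)) abort("Sweep wavelength must stay positive over the window.")
  dl <- diff(lam)
  if (!(all(dl > 0) || all(dl < 0))) {
    abort("Sweep wavelength must be strictly monotone over the window.")
  }
  out <- tibble(k = 2 * pi / lam, time = t)
  dplyr::arrange(out, .data$k)
}

#' Read and write MZI traces as CSV with a JSON sidecar
#'
#' Two-column CSV (`t_ns`, `amplitude`) plus `<path>.json` carrying
#' `lambda0_nm` and `d_nm`.
#'
#' @param trace An [mzi_trace()].
#' @param path CSV path.
#' @return `write_mzi_trace()` returns `path` invisibly; `read_mzi_trace()`
#'   an [mzi_trace()].
#' @export
write_mzi_trace <- function(trace, path) {
  readr::write_csv(tibble(t_ns = trace$time, amplitude = trace$amplitude), path)
  jsonlite::write_json(
    list(
      lambda0_nm = attr(trace, "lambda0"),
      d_nm = attr(trace, "path_difference")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mzi_trace
#' @export
read_mzi_trace <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  mzi_trace(df$t_ns, df$amplitude,
    path_difference = meta$d_nm, lambda0 = meta$lambda0_nm %||% 1250
  )
}

#' Serialise a sweep model to JSON
#'
#' @param model A [sweep_model()] (or the `model` element of a `sweep_fit`).
#' @param path JSON path.
#' @return `write_sweep_model()` returns `path` invisibly; `read_sweep_model()`
#'   a [sweep_model()].
#' @export
write_sweep_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep_model
#' @export
read_sweep_model <- function(path) {
  m <- jsonlite::read_json(path)
  sweep_model(m$lambda0, a = m$a, b = m$b, c = m$c)
}
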