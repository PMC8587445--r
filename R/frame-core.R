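#' Local-spacing scale factors for irregularly sampled sinc frames
#'
#' For sample locations `t_n` with Nyquist interval `T`, the frame vector
#' attached to sample `n` is the shifted sinc scaled by
#' `Lambda_n = sqrt((t_{n+1} - t_{n-1}) / (2 T))`. The scale compensates both
#' for oversampling (average spacing below `T`) and for local irregularity of
#' the sample positions: on a uniform critical grid every `Lambda_n` is 1, and
#' on a uniform grid oversampled R-fold every interior `Lambda_n` is
#' `sqrt(1/R)`.
#'
#' The central difference is undefined at the two endpoints; `boundary_rule`
#' chooses how the missing neighbour gap is filled in:
#' * `"one_sided"` (default) substitutes the single adjacent gap, i.e.
#'   `Lambda_1 = sqrt((t_2 - t_1) / T)`, which preserves `Lambda = 1` on
#'   uniform critical grids;
#' * `"periodic"` wraps around, borrowing the gap from the opposite end of
#'   the sequence (natural for circular/periodic sample sets).
#'
#' @param locations Strictly increasing numeric vector of sample positions
#'   (k-space or time units), length >= 3.
#' @param nyquist_interval Positive scalar: the critical (Nyquist) sample
#'   spacing `T` for the signal band.
#' @param boundary_rule `"one_sided"` or `"periodic"` endpoint handling.
#' @return Numeric vector of positive scale factors, one per location.
#' @examples
#' lambda_scales(0:7, 1)            # uniform critical grid: all 1
#' lambda_scales(seq(0, 3.5, 0.5), 1)  # 2x oversampled: sqrt(0.5)
#' @export
lambda_scales <- function(locations, nyquist_interval = 1,
                          boundary_rule = c("one_sided", "periodic")) {
  boundary_rule <- match.arg(boundary_rule)
  check_locations(locations, nyquist_interval)
  gaps <- diff(locations)
  n <- length(locations)
  if (boundary_rule == "one_sided") {
    first <- gaps[1]
    last <- gaps[n - 1]
  } else {
    first <- gaps[n - 1]
    last <- gaps[1]
  }
  padded <- c(first, gaps, last) # gap before t_n is padded[n], after is padded[n + 1]
  sqrt((padded[seq_len(n)] + padded[seq_len(n) + 1]) / (2 * nyquist_interval))
}

#' Maximum sampling gap and the frame condition
#'
#' Computes the maximum consecutive spacing `delta` of a sample-location set
#' and whether it satisfies the irregular-sampling frame condition
#' `delta < T`, under which the shifted-sinc family is a frame for the band
#' limited space with analytic bound limits given by [frame_bound_limits()].
#'
#' @inheritParams lambda_scales
#' @return A list with elements `delta` (positive scalar) and `satisfied`
#'   (logical: `delta < nyquist_interval`).
#' @examples
#' max_gap(c(0, 0.6, 1.0, 1.8), 1) # delta = 0.8, satisfied
#' @export
max_gap <- function(locations, nyquist_interval = 1) {
  check_locations(locations, nyquist_interval)
  delta <- max(diff(locations))
  list(delta = delta, satisfied = delta < nyquist_interval)
}

#' Analytic frame-bound limits for irregular sinc frames
#'
#' When the maximum gap `delta` of the sample locations is below the Nyquist
#' interval `T`, the scaled shifted-sinc family is a frame whose bounds
#' satisfy `A >= (1 - delta/T)^2` and `B <= (1 + delta/T)^2`. These limits
#' bracket every admissible frame bound; actual bounds of near-uniform sets
#' cluster near 1.
#'
#' @param delta Positive scalar, the maximum sampling gap.
#' @param nyquist_interval Positive scalar `T` with `delta < T`.
#' @return A list with `lower` and `upper` limits.
#' @examples
#' frame_bound_limits(0.5, 1) # lower 0.25, upper 2.25
#' @export
frame_bound_limits <- function(delta, nyquist_interval = 1) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a single positive number.")
  }
  x <- delta / nyquist_interval
  if (x >= 1) {
    abort(paste0(
      "Frame condition broken: maximum gap (", signif(delta, 6),
      ") must be below the Nyquist interval (", signif(nyquist_interval, 6), ")."
    ))
  }
  list(lower = (1 - x)^2, upper = (1 + x)^2)
}

#' Construct a frame matrix from explicit frame vectors
#'
#' A `frame_matrix` stores sampled frame vectors as the rows of a numeric or
#' complex matrix, together with analytic lower/upper frame-bound limits. It
#' is the small-instance oracle container: [dual_frame_pinv()] computes the
#' dual (pseudoinverse) operator, [empirical_frame_bounds()] estimates the
#' actual bounds, and the noise-analysis module projects white noise through
#' it.
#'
#' @param rows Matrix whose rows are the frame vectors (common dimension).
#' @param lower_limit,upper_limit Positive analytic bound limits (defaults 0
#'   and Inf mean "unknown").
#' @param weight Optional quadrature weight: row vectors sampled from
#'   continuous functions on a uniform grid of spacing `h` should be scaled
#'   by `sqrt(h)` so that Euclidean inner products approximate the continuous
#'   ones. Stored for provenance only.
#' @param ... Further attributes (e.g. `locations`, `lambda`) attached as-is.
#' @return A `frame_matrix` object (a matrix with metadata attributes).
#' @export
frame_matrix <- function(rows, lower_limit = 0, upper_limit = Inf,
                         weight = NULL, ...) {
  if (!is.matrix(rows)) rows <- matrix(rows, nrow = 1)
  if (lower_limit < 0 || upper_limit < lower_limit) {
    abort("Bound limits must satisfy 0 <= lower_limit <= upper_limit.")
  }
  structure(rows,
    lower_limit = lower_limit, upper_limit = upper_limit,
    weight = weight, ...,
    class = c("frame_matrix", class(rows))
  )
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(
    "<frame_matrix> ", nrow(x), " frame vectors of dimension ", ncol(x),
    "\n  analytic bound limits: [", signif(attr(x, "lower_limit"), 6), ", ",
    signif(attr(x, "upper_limit"), 6), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Sample a shifted-sinc frame on a fine uniform grid
#'
#' Discretises the scaled sinc frame for a bandlimited space with Nyquist
#' interval `T`: row `n` is `Lambda_n T^{-1/2} sinc((g - t_n)/T)` evaluated on
#' a uniform grid `g`, multiplied by the quadrature weight `sqrt(h)` (grid
#' spacing `h`) so that Euclidean inner products of rows approximate the
#' continuous L2 inner products. On a uniform critical location grid the rows
#' are then numerically orthonormal (Gram close to the identity, up to sinc
#' truncation at the window edges).
#'
#' The grid defaults to `oversample` points per Nyquist interval, extended
#' `pad` Nyquist intervals beyond the location span; the slow 1/t sinc decay
#' makes truncation the dominant numerical error, so generous padding is used
#' and oracle tolerances elsewhere account for the remainder.
#'
#' @inheritParams lambda_scales
#' @param grid Optional explicit uniform grid; computed from `oversample` and
#'   `pad` when `NULL`.
#' @param oversample Grid density, points per Nyquist interval (default 8).
#' @param pad Window padding beyond the location span, in Nyquist intervals.
#' @return A [frame_matrix()] with attributes `locations`, `lambda`, `grid`,
#'   `delta`, and analytic bound limits from [frame_bound_limits()].
#' @export
build_sinc_frame <- function(locations, nyquist_interval = 1, grid = NULL,
                             oversample = 8, pad = 8,
                             boundary_rule = c("one_sided", "periodic")) {
  boundary_rule <- match.arg(boundary_rule)
  check_locations(locations, nyquist_interval)
  T_ <- nyquist_interval
  gap <- max_gap(locations, T_)
  x <- gap$delta / T_
  if (x > 1 + 1e-12) {
    abort(paste0(
      "Frame condition broken: maximum gap (", signif(gap$delta, 6),
      ") exceeds the Nyquist interval (", signif(T_, 6), ")."
    ))
  }
  # at the critical boundary delta == T the analytic limits degenerate to
  # (0, 4); the uniform critical frame itself is orthonormal (bounds 1)
  limits <- list(lower = max(0, (1 - x))^2, upper = (1 + x)^2)
  if (is.null(grid)) {
    h <- T_ / oversample
    grid <- seq(min(locations) - pad * T_, max(locations) + pad * T_, by = h)
  } else {
    h <- unique(round(diff(grid), 12))
    if (length(h) != 1) abort("`grid` must be uniform.")
  }
  lambda <- lambda_scales(locations, T_, boundary_rule)
  rows <- vapply(
    seq_along(locations),
    function(n) lambda[n] / sqrt(T_) * sinc((grid - locations[n]) / T_) * sqrt(h),
    numeric(length(grid))
  )
  frame_matrix(t(rows),
    lower_limit = limits$lower, upper_limit = limits$upper,
    weight = sqrt(h), locations = locations, lambda = lambda,
    grid = grid, delta = gap$delta, nyquist_interval = T_
  )
}

# Numerical rank and SVD shared by the dual/bound estimators.
frame_svd <- function(frame, tol = NULL) {
  sv <- svd(unclass(frame))
  if (is.null(tol)) tol <- max(dim(frame)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  list(svd = sv, rank = rank, tol = tol)
}

#' Dual-frame operator via the pseudoinverse
#'
#' Computes the Moore-Penrose pseudoinverse `Phi^+ = (Phi* Phi)^{-1} Phi*` of
#' a frame analysis matrix `Phi` (rows = frame vectors). Column `n` of the
#' result is the dual-frame vector of row `n`; applying `Phi^+` to a
#' coefficient vector performs the dual-frame (least-squares) reconstruction.
#'
#' For tall matrices (`nrow >= ncol`) the spec of a frame for the whole
#' column space requires full column rank; a rank-deficient tall matrix
#' raises an error naming the deficiency. Wide matrices (fine-grid
#' discretisations of sinc frames, where the rows span only the bandlimited
#' subspace) are handled by the minimum-norm pseudoinverse restricted to the
#' row space.
#'
#' @param frame A [frame_matrix()] or plain matrix with frame vectors as rows.
#' @param tol Singular-value tolerance for the numerical rank (default
#'   `max(dim) * eps * d_max`).
#' @param min_singular Optional positive cutoff: singular values below it are
#'   excluded from the inverse. Fine-grid discretisations of sinc frames on a
#'   finite window carry a decaying tail of edge modes below the analytic
#'   frame bound (`sqrt(lower_limit)`); inverting those amplifies numerical
#'   truncation artifacts, so bounded-noise analyses cut there.
#' @return The pseudoinverse matrix (`ncol(frame)` x `nrow(frame)`), with the
#'   number of retained modes attached as attribute `rank`.
#' @export
dual_frame_pinv <- function(frame, tol = NULL, min_singular = NULL) {
  fs <- frame_svd(frame, tol)
  if (nrow(frame) >= ncol(frame) && fs$rank < ncol(frame)) {
    abort(paste0(
      "Frame matrix is rank deficient: numerical rank ", fs$rank,
      " < dimension ", ncol(frame),
      "; the rows do not span the signal space, so no dual frame exists."
    ))
  }
  sv <- fs$svd
  rank <- fs$rank
  if (!is.null(min_singular)) {
    rank <- min(rank, sum(sv$d >= min_singular * (1 - 1e-9)))
  }
  keep <- seq_len(rank)
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(Conj(sv$u[, keep, drop = FALSE])) / sv$d[keep])
  attr(pinv, "rank") <- rank
  pinv
}

# Orthonormalised interior probe subspace for a grid-discretised sinc frame:
# critical-grid sinc atoms centred `margin` Nyquist intervals inside the
# sampled span, discretised on the frame's own grid with the same sqrt(h)
# quadrature weight. The analytic frame bounds describe signals whose energy
# lies where sampling coverage exists; probing with these atoms avoids the
# edge modes of the finite window.
interior_atoms <- function(frame, margin = 3) {
  grid <- attr(frame, "grid")
  locs <- attr(frame, "locations")
  T_ <- attr(frame, "nyquist_interval")
  if (is.null(grid) || is.null(locs) || is.null(T_)) {
    return(NULL)
  }
  h <- grid[2] - grid[1]
  centres <- seq(min(locs) + margin * T_, max(locs) - margin * T_, by = T_)
  if (length(centres) < 2) {
    return(NULL)
  }
  atoms <- vapply(
    centres,
    function(m) sinc((grid - m) / T_) / sqrt(T_) * sqrt(h),
    numeric(length(grid))
  )
  qr.Q(qr(atoms)) # orthonormalise (atoms are only near-orthogonal when truncated)
}

#' Monte-Carlo estimate of frame bounds
#'
#' Estimates the frame bounds `A` and `B` in
#' `A ||f||^2 <= sum_n |<f, phi_n>|^2 <= B ||f||^2` by evaluating the frame
#' energy for random unit vectors `f` with independent standard-normal
#' components in the subspace the frame actually represents:
#' * for fine-grid sinc discretisations (frames built by
#'   [build_sinc_frame()]) `f` is drawn from critical-grid sinc atoms centred
#'   in the interior of the sampled span, where the analytic limits of
#'   [frame_bound_limits()] apply (the edge modes of a finite window fall
#'   below any bound);
#' * otherwise from the frame's SVD row space, which for full-dimensional
#'   frames is the uniform sphere of the whole space.
#'
#' @inheritParams dual_frame_pinv
#' @param trials Number of random vectors (>= 100).
#' @param seed Integer seed for reproducibility.
#' @return List with `lower` (min energy) and `upper` (max energy) estimates.
#' @export
empirical_frame_bounds <- function(frame, trials = 1000, seed = 1, tol = NULL) {
  if (trials < 100) abort("`trials` must be at least 100.")
  basis <- interior_atoms(frame)
  if (is.null(basis)) {
    fs <- frame_svd(frame, tol)
    basis <- fs$svd$v[, seq_len(fs$rank), drop = FALSE]
  }
  cmplx <- is.complex(unclass(frame))
  nb <- ncol(basis)
  energies <- withr::with_seed(seed, {
    vapply(seq_len(trials), function(i) {
      coef <- if (cmplx) rcnorm(nb) else rnorm(nb)
      f <- basis %*% coef
      f <- f / sqrt(sum(Mod(f)^2))
      sum(Mod(Conj(unclass(frame)) %*% f)^2)
    }, numeric(1))
  })
  list(lower = min(energies), upper = max(energies))
}

#' @export
tidy.frame_matrix <- function(x, ...) {
  out <- tibble(
    vector = seq_len(nrow(x)),
    norm = sqrt(rowSums(Mod(unclass(x))^2))
  )
  if (!is.null(attr(x, "locations"))) out$location <- attr(x, "locations")
  if (!is.null(attr(x, "lambda"))) out$lambda <- attr(x, "lambda")
  out
}

#' @export
glance.frame_matrix <- function(x, ...) {
  tibble(
    n_vectors = nrow(x),
    dimension = ncol(x),
    lower_limit = attr(x, "lower_limit"),
    upper_limit = attr(x, "upper_limit"),
    delta = attr(x, "delta") %||% NA_real_,
    nyquist_interval = attr(x, "nyquist_interval") %||% NA_real_
  )
}

#' Write a frame matrix to CSV for inspection
#'
#' Serialises the (possibly complex) frame vectors to a plain CSV file, one
#' row per frame vector; complex entries are split into `re_*`/`im_*` column
#' pairs.
#'
#' @param frame A [frame_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_csv <- function(frame, path) {
  m <- unclass(frame)
  if (is.complex(m)) {
    df <- as.data.frame(cbind(Re(m), Im(m)))
    names(df) <- c(
      paste0("re_", seq_len(ncol(m))),
      paste0("im_", seq_len(ncol(m)))
    )
  } else {
    df <- as.data.frame(m)
    names(df) <- paste0("v", seq_len(ncol(m)))
  }
  readr::write_csv(df, path)
  invisible(path)
}
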