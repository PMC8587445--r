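#' One A-scan's k-space measurements
#'
#' A `k_sample_set` is a tibble with one row per spectral measurement:
#' column `k` holds the strictly increasing sample locations (wavenumber,
#' expressed in units of the critical spacing unless stated otherwise) and
#' column `value` the complex measured interferogram samples. The Nyquist
#' interval `K` of the underlying bandlimited spectrum is carried as an
#' attribute, together with an optional natural output length `n_out`.
#'
#' @param k Strictly increasing numeric vector of k-space locations
#'   (length >= 3).
#' @param value Complex (or numeric) vector of measured samples, same length.
#' @param nyquist_interval Positive scalar `K`: the critical k-space spacing.
#' @param n_out Optional integer: natural number of Nyquist samples for
#'   reconstruction (e.g. the depth of the generating A-scan).
#' @return A tibble of class `k_sample_set` with columns `k` and `value`.
#' @examples
#' x <- c(1, 0.5, 0.25, 0, 0.25, 0.5, 1, 2)
#' ks <- k_sample_set(0:7, fft(x), nyquist_interval = 1)
#' ks
#' @export
k_sample_set <- function(k, value, nyquist_interval = 1, n_out = NULL) {
  check_locations(k, nyquist_interval)
  if (length(value) != length(k)) {
    abort("`k` and `value` must have the same length.")
  }
  out <- new_tibble(
    list(k = as.double(k), value = as.complex(value)),
    nrow = length(k),
    nyquist_interval = nyquist_interval,
    n_out = n_out,
    class = "k_sample_set"
  )
  out
}

#' @export
print.k_sample_set <- function(x, ...) {
  cat(
    "<k_sample_set> ", nrow(x), " samples, Nyquist interval K = ",
    signif(attr(x, "nyquist_interval"), 6), "\n",
    sep = ""
  )
  NextMethod()
}

k_nyquist <- function(samples) {
  attr(samples, "nyquist_interval") %||% 1
}

# Default number of Nyquist samples N_T = round(delta * N_f / K), floored at 2.
default_n_out <- function(samples) {
  n_out <- attr(samples, "n_out")
  if (!is.null(n_out)) {
    return(as.integer(n_out))
  }
  delta <- max(diff(samples$k))
  max(2L, as.integer(round_half_away(delta * nrow(samples) / k_nyquist(samples))))
}

#' Read and write k-sample sets as CSV with a JSON sidecar
#'
#' The on-disk convention is a three-column CSV (`k`, `re`, `im`) plus a JSON
#' sidecar `<path>.json` holding `nyquist_interval` and, when known, `n_out`.
#'
#' @param samples A [k_sample_set()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_k_samples()` returns `path` invisibly; `read_k_samples()`
#'   returns a [k_sample_set()].
#' @export
write_k_samples <- function(samples, path) {
  readr::write_csv(
    tibble(k = samples$k, re = Re(samples$value), im = Im(samples$value)),
    path
  )
  meta <- list(nyquist_interval = k_nyquist(samples))
  if (!is.null(attr(samples, "n_out"))) meta$n_out <- attr(samples, "n_out")
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_k_samples
#' @export
read_k_samples <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  k_sample_set(
    k = df$k,
    value = complex(real = df$re, imaginary = df$im),
    nyquist_interval = meta$nyquist_interval %||% 1,
    n_out = meta$n_out
  )
}
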