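#' Assemble a B-scan image from per-column k-sample sets
#'
#' Reconstructs every A-scan with the configured method and stacks the
#' magnitudes column-wise into a depth x lateral image. The flipped
#' convention of the kernels is undone so the image is in natural depth
#' order.
#'
#' @param spectra List of [k_sample_set()] objects, one per lateral position.
#' @param config A [recon_config()]. When `config$n_out` is `NULL` every
#'   column must agree on its natural output length, otherwise an error is
#'   raised (mixed depths cannot be stacked).
#' @param log_compress Display transform: when `TRUE` the magnitude image is
#'   converted to dB relative to its maximum, floored at `dynamic_range_db`
#'   below the peak.
#' @param dynamic_range_db Dynamic range of the log display (default 60 dB).
#' @param ... Overrides passed to [recon_config()] when `config` is missing.
#' @return An `oct_bscan`: a numeric depth x width matrix with attributes
#'   `method` and `log_compressed`.
#' @export
reconstruct_bscan <- function(spectra, config = recon_config(...),
                              log_compress = FALSE, dynamic_range_db = 60,
                              ...) {
  if (!length(spectra)) abort("`spectra` must contain at least one A-scan.")
  n_outs <- vapply(
    spectra,
    function(s) config$n_out %||% default_n_out(s),
    integer(1)
  )
  if (length(unique(n_outs)) != 1) {
    abort(paste0(
      "Mixed output lengths across columns (",
      paste(unique(n_outs), collapse = ", "),
      "); set `n_out` explicitly in the config."
    ))
  }
  cols <- purrr::map(spectra, function(s) {
    cfg <- config
    cfg$n_out <- n_outs[[1]]
    as_depth_profile(reconstruct_ascan(s, cfg))$magnitude
  })
  img <- do.call(cbind, cols)
  if (log_compress) {
    peak <- max(img)
    floor_lin <- peak * 10^(-dynamic_range_db / 20)
    img <- 20 * log10(pmax(img, floor_lin) / peak)
  }
  structure(img,
    method = config$method, log_compressed = log_compress,
    class = c("oct_bscan", "matrix", "array")
  )
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(
    "<oct_bscan> ", nrow(x), " x ", ncol(x), " (depth x lateral), method: ",
    attr(x, "method") %||% "unknown",
    if (isTRUE(attr(x, "log_compressed"))) ", log-compressed" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
autoplot.oct_bscan <- function(object, ...) {
  df <- tidyr::expand_grid(
    depth = seq_len(nrow(object)) - 1L,
    lateral = seq_len(ncol(object)) - 1L
  )
  df$intensity <- as.vector(unclass(object))[df$depth + 1L + nrow(object) * df$lateral]
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral, .data$depth, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(
      x = "lateral position (A-scan)", y = "depth (Nyquist samples)",
      fill = if (isTRUE(attr(object, "log_compressed"))) "dB" else "|u(z)|"
    ) +
    ggplot2::theme_minimal()
}
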