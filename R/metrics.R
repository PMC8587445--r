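#' Per-A-scan correlation profile between two B-scans
#'
#' Computes the Pearson correlation between corresponding columns (A-scans)
#' of a reference and a test image, plus their mean — the standard
#' column-wise fidelity summary for reconstructed OCT images. Columns where
#' either image is constant have undefined correlation; they are recorded
#' as `NA`, excluded from the mean, and flagged with a warning.
#'
#' @param reference,test Numeric matrices of identical dimensions
#'   (depth x width).
#' @return A tibble of class `ascan_correlation` with columns `column` and
#'   `correlation`, and the mean in attribute `mean` (also via `mean()`).
#' @export
ascan_correlations <- function(reference, test) {
  if (!all(dim(reference) == dim(test))) {
    abort("`reference` and `test` must have identical dimensions.")
  }
  cors <- vapply(seq_len(ncol(reference)), function(j) {
    r <- reference[, j]
    t_ <- test[, j]
    if (sd(r) == 0 || sd(t_) == 0) {
      return(NA_real_)
    }
    cor(r, t_)
  }, numeric(1))
  if (anyNA(cors)) {
    warn(paste0(
      sum(is.na(cors)),
      " constant column(s) have undefined correlation; excluded from the mean."
    ))
  }
  out <- new_tibble(
    list(column = seq_along(cors), correlation = cors),
    nrow = length(cors),
    mean = mean(cors, na.rm = TRUE),
    class = "ascan_correlation"
  )
  out
}

#' @export
mean.ascan_correlation <- function(x, ...) {
  attr(x, "mean")
}

#' @export
print.ascan_correlation <- function(x, ...) {
  cat(
    "<ascan_correlation> mean over ", sum(!is.na(x$correlation)),
    " columns: ", signif(attr(x, "mean"), 6), "\n",
    sep = ""
  )
  NextMethod()
}

#' @export
autoplot.ascan_correlation <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$column, .data$correlation)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = attr(object, "mean"),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "A-scan (column)", y = "Pearson correlation") +
    ggplot2::theme_minimal()
}

#' Peak signal-to-noise ratio between two images
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB, with the mean squared error taken
#' over all pixels. `peak` defaults to the maximum of the reference image
#' (recorded in the result's attributes, since PSNR conventions differ).
#' Identical images have zero MSE; the result is then `Inf`.
#'
#' When `normalize = TRUE` the test image is first rescaled by the
#' least-squares gain `sum(ref * test) / sum(test^2)`, making the metric
#' invariant to the overall reconstruction scale (reconstructions from
#' redundant sampling carry a redundancy-dependent gain).
#'
#' @param reference,test Numeric matrices of identical dimensions.
#' @param peak Positive peak value (default `max(reference)`).
#' @param normalize Remove a global gain from `test` first (default `FALSE`).
#' @return PSNR in dB (scalar, possibly `Inf`), with attributes `peak` and
#'   `normalize`.
#' @examples
#' a <- matrix(0, 8, 8)
#' psnr(a + 255, a + 254, peak = 255) # 20*log10(255) = 48.13 dB
#' @export
psnr <- function(reference, test, peak = max(reference), normalize = FALSE) {
  if (!all(dim(reference) == dim(test))) {
    abort("`reference` and `test` must have identical dimensions.")
  }
  if (peak <= 0) abort("`peak` must be positive.")
  if (normalize) {
    denom <- sum(test^2)
    if (denom > 0) test <- test * sum(reference * test) / denom
  }
  mse <- mean((reference - test)^2)
  out <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  structure(out, peak = peak, normalize = normalize)
}
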