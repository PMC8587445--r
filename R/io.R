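#' Read and write grayscale B-scan images
#'
#' Writes a numeric matrix as an 8- or 16-bit grayscale PNG or TIFF
#' (format chosen from the file extension). Values are rescaled to `[0, 1]`
#' by the image maximum before quantisation (the scale is not preserved;
#' all image-domain metrics in this package are scale invariant).
#'
#' @param image Numeric matrix (depth x width), non-negative.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth, 8 or 16 (default 16).
#' @return `write_bscan_image()` returns `path` invisibly;
#'   `read_bscan_image()` a numeric matrix with values in `[0, 1]`
#'   (multi-channel images are averaged to grayscale).
#' @export
write_bscan_image <- function(image, path, bits = 16) {
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  m <- unclass(as.matrix(image))
  if (min(m) < 0) m <- m - min(m)
  peak <- max(m)
  if (peak > 0) m <- m / peak
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = bits)
  } else {
    abort("Unsupported image extension; use .png, .tif or .tiff.")
  }
  invisible(path)
}

#' @rdname write_bscan_image
#' @export
read_bscan_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort("Unsupported image extension; use .png, .tif or .tiff.")
  }
  if (length(dim(img)) == 3) {
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  }
  img
}
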