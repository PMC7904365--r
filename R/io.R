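## Grayscale image I/O. Internally every image is a numeric matrix in [0,1];
## bit depth only exists at the file boundary, where values are scaled by
## the maximum representable integer.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF into a numeric matrix scaled
#' to `[0, 1]`. Multi-channel inputs are converted to a single channel by
#' averaging the channels, with a warning.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_octedema("file not found: ", path, class = "octedema_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop_octedema("unsupported image format: .", ext,
                              class = "octedema_io_error"))
  if (length(dim(img)) == 3L) {
    warning("multi-channel image ", basename(path),
            ": converting to grayscale by channel average")
    img <- apply(img, c(1, 2), mean)
  }
  if (!is.matrix(img))
    stop_octedema("could not interpret ", path, " as a 2-D image",
                  class = "octedema_io_error")
  img
}

#' Write a grayscale image
#'
#' Writes a `[0, 1]` numeric matrix as 8-bit PNG or 8/16-bit TIFF (the PNG
#' writer is 8-bit only). Values are clipped to `[0, 1]` before quantization
#' so round trips are lossless at the chosen depth.
#'
#' @param image Numeric matrix.
#' @param path Output path; format chosen by extension.
#' @param bit_depth 8 or 16 (16 supported for TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 8L) {
  assert_gray(image)
  img <- pmin(pmax(image, 0), 1)
  dim(img) <- dim(image)
  ext <- tolower(tools::file_ext(path))
  if (!bit_depth %in% c(8L, 16L))
    stop_octedema("bit_depth must be 8 or 16", class = "octedema_io_error")
  if (ext == "png") {
    if (bit_depth != 8L)
      stop_octedema("PNG output is 8-bit only; use TIFF for 16-bit",
                    class = "octedema_io_error")
    # quantize explicitly so write/read round trips are exact
    png::writePNG(round(img * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    maxv <- 2^bit_depth - 1
    tiff::writeTIFF(round(img * maxv) / maxv, path,
                    bits.per.sample = as.integer(bit_depth))
  } else {
    stop_octedema("unsupported image format: .", ext, class = "octedema_io_error")
  }
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_image(ifelse(mask, 1, 0), path, 8L)
}

#' Read a 0/255 mask PNG back as a logical matrix
#'
#' @param path PNG path.
#' @return Logical matrix (`TRUE` where the stored value exceeds one half).
#' @export
read_mask <- function(path) {
  read_image(path) > 0.5
}
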