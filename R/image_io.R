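# Image reading/writing.  Internal representation throughout the package:
# numeric array H x W x 3 with 8-bit intensities in [0, 255] (0-based pixel
# coordinates, x = column, y = row; row 1 of the array is y = 0).

#' Read an RGB image
#'
#' Reads a PNG or TIFF raster image (JPEG if the EBImage package is
#' installed) into the package's standard representation: a numeric
#' `H x W x 3` array of 8-bit intensities in `[0, 255]`.  Grayscale images
#' are expanded to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif(f)` or `.jpg/.jpeg` file.
#' @return Numeric `H x W x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) hx_io_error("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      jpg = ,
      jpeg = {
        if (!requireNamespace("EBImage", quietly = TRUE)) {
          hx_io_error("reading JPEG requires the EBImage package; convert to PNG/TIFF instead")
        }
        e <- EBImage::imageData(EBImage::readImage(path))
        # EBImage stores (x, y, channel); transpose to (row, col, channel)
        if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
      },
      hx_io_error("unsupported image format '.", ext, "' (use PNG, TIFF or JPEG)")
    ),
    error = function(e) {
      if (inherits(e, "histex_error")) stop(e)
      hx_io_error("unreadable image '", path, "': ", conditionMessage(e))
    }
  )
  as_rgb255(img)
}

# Coerce decoder output ([0,1] scale, possibly gray or RGBA) to H x W x 3 in [0,255].
as_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) hx_validation_error("image must be a 2- or 3-dimensional array")
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (dim(img)[3] != 3L) hx_validation_error("image must have 3 channels, got ", dim(img)[3])
  if (max(img) <= 1 + 1e-9) img <- img * 255
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "double"
  img
}

#' Write an RGB image to PNG
#'
#' @param image Numeric `H x W x 3` array with values in `[0, 255]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    hx_validation_error("expected an H x W x 3 RGB image array")
  }
  invisible(TRUE)
}

# sRGB (0..255) -> CIELAB.  Returns list(L, a, b) as H x W matrices; L in 0..100.
rgb_to_lab <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  m <- matrix(image, ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(
    L = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  )
}

lab_to_rgb <- function(L, a, b) {
  m <- grDevices::convertColor(cbind(as.vector(L), as.vector(a), as.vector(b)),
    from = "Lab", to = "sRGB", clip = TRUE
  )
  out <- array(0, c(dim(L), 3L))
  out[, , 1] <- matrix(m[, 1], dim(L)[1], dim(L)[2])
  out[, , 2] <- matrix(m[, 2], dim(L)[1], dim(L)[2])
  out[, , 3] <- matrix(m[, 3], dim(L)[1], dim(L)[2])
  round(out * 255)
}
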