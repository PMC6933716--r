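# Images are H x W x 3 numeric arrays with 8-bit values in [0, 255];
# masks are H x W logical matrices (TRUE = retained foreground).

#' Read an RGB image as an 8-bit array
#'
#' PNG is read natively; other formats (JPEG, TIFF) go through EBImage.
#' Any alpha channel is dropped.
#'
#' @param path image file path.
#' @return H x W x 3 numeric array with values in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  assert_that(file.exists(path), "panicler_io_error", "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    img <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  img * 255
}

#' Write an RGB image or a binary mask as PNG
#'
#' Masks are written as 8-bit grayscale with foreground 255 and
#' background 0.
#'
#' @param x H x W x 3 array in `[0, 255]`, or a logical mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x) * 255, nrow(x), ncol(x))
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Convert an 8-bit RGB image to HSV
#'
#' Standard hexcone conversion; all three output channels lie in `[0, 1]`
#' (hue as a fraction of the full circle).
#'
#' @param image H x W x 3 numeric array with values in `[0, 255]`.
#' @return H x W x 3 numeric array of hue, saturation, value.
#' @export
rgb_to_hsv_img <- function(image) {
  d <- dim(image)
  assert_that(length(d) == 3 && d[3] == 3, "panicler_validation_error",
              "expected an H x W x 3 image, got dims [%s]",
              paste(d, collapse = ", "))
  m <- matrix(image, ncol = 3)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  array(t(hsv), dim = d)
}
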