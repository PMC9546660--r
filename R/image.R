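# Image container conventions and I/O.
#
# RGB images are plain numeric arrays of dimension H x W x 3 with intensities
# in [0, 255]; l-alpha-beta images are numeric arrays of the same shape with
# unconstrained finite real values.

#' Validate an RGB image array
#'
#' Checks that `img` is an H x W x 3 numeric array with all intensities in
#' \[0, 255\]. Used internally by every operation that consumes RGB input.
#'
#' @param img numeric array to validate.
#' @param what name used in error messages.
#' @return the validated array, invisibly unchanged.
#' @export
validate_rgb_image <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L)
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[3] != 3L)
    stop(what, " must have exactly three channels, got ", dim(img)[3], call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " has zero area", call. = FALSE)
  if (!is.numeric(img) || anyNA(img) || any(!is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Read an image file as an H x W x 3 RGB array
#'
#' Reads PNG, TIFF or JPEG via EBImage and returns intensities on the
#' \[0, 255\] scale. Grayscale input is replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path.
#' @return numeric H x W x 3 array with values in \[0, 255\].
#' @export
read_image <- function(path) {
  x <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  img <- aperm(x, c(2L, 1L, 3L)) * 255
  validate_rgb_image(img, what = path)
  img
}

#' Write an RGB array to an image file
#'
#' Format is chosen from the file extension (png, tiff/tif, jpg/jpeg).
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_rgb_image(img)
  x <- EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(x, path)
  invisible(path)
}

# EBImage Image (x,y,c in [0,1]) from an H x W x 3 [0,255] array, and back.
as_ebimage <- function(img) {
  EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)), colormode = "Color")
}
from_ebimage <- function(x) {
  aperm(EBImage::imageData(x), c(2L, 1L, 3L)) * 255
}
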