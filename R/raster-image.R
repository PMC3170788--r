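#' Raster image container
#'
#' A `raster_image` is the unit of visual feature extraction: a decoded pixel
#' grid of integer intensities in \[0, 255\] with 1 (grayscale) or 3 (RGB)
#' channels.
#'
#' @param pixels integer-valued matrix (H x W) or array (H x W x 3) with all
#'   entries in \[0, 255\].
#' @return An object of class `raster_image` with elements `pixels`,
#'   `height`, `width`, `channels`.
#' @examples
#' img <- raster_image(matrix(0:255, 16, 16))
#' img$channels
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    channels <- 3L
  } else {
    stop("pixels must be an H x W matrix or an H x W x 3 array", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 255) || any(pixels != round(pixels))) {
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  }
  d <- dim(pixels)
  structure(
    list(
      pixels = pixels,
      height = as.integer(d[1]),
      width = as.integer(d[2]),
      channels = channels
    ),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf(
    "<raster_image %d x %d, %d channel%s>\n",
    x$height, x$width, x$channels, if (x$channels > 1) "s" else ""
  ))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

#' Convert an image to a single grayscale channel
#'
#' RGB images are converted with luminance weights 0.299 R + 0.587 G +
#' 0.114 B, rounded to the nearest integer; grayscale images pass through.
#'
#' @param image a [raster_image()].
#' @return A 1-channel `raster_image`.
#' @export
as_gray <- function(image) {
  stopifnot(is_raster_image(image))
  if (image$channels == 1L) {
    return(image)
  }
  p <- image$pixels
  g <- round(0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3])
  raster_image(pmin(pmax(g, 0), 255))
}

#' Read an image file as a raster_image
#'
#' Decodes a PNG or JPEG file (via EBImage) and rescales intensities to
#' integer \[0, 255\]. Images with an alpha channel are reduced to their color
#' planes; single-plane images become grayscale.
#'
#' @param path path to a PNG or JPEG file.
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  d <- dim(dat)
  # EBImage stores (x, y[, channel]) in [0, 1]; transpose to row = y
  if (length(d) == 2) {
    px <- t(dat)
  } else {
    nch <- d[3]
    if (nch >= 3) {
      px <- array(0, dim = c(d[2], d[1], 3))
      for (k in 1:3) px[, , k] <- t(dat[, , k])
    } else {
      px <- t(dat[, , 1])
    }
  }
  raster_image(pmin(pmax(round(px * 255), 0), 255))
}

#' Resize an image to a standard square size
#'
#' Bilinear resize (via EBImage) used to standardize all images before
#' feature extraction, so block grids and histogram scales are comparable
#' across inputs. A no-op when the image already has the target size.
#'
#' @param image a [raster_image()].
#' @param size target side length in pixels (default 256).
#' @return A `raster_image` of dimensions `size` x `size`.
#' @export
standardize_image <- function(image, size = 256L) {
  stopifnot(is_raster_image(image), size >= 1)
  if (image$height == size && image$width == size) {
    return(image)
  }
  if (image$channels == 1L) {
    eb <- EBImage::Image(t(image$pixels) / 255)
    out <- EBImage::resize(eb, w = size, h = size)
    px <- t(EBImage::imageData(out))
  } else {
    dat <- array(0, dim = c(image$width, image$height, 3))
    for (k in 1:3) dat[, , k] <- t(image$pixels[, , k])
    eb <- EBImage::Image(dat / 255, colormode = "Color")
    out <- EBImage::resize(eb, w = size, h = size)
    od <- EBImage::imageData(out)
    px <- array(0, dim = c(size, size, 3))
    for (k in 1:3) px[, , k] <- t(od[, , k])
  }
  raster_image(pmin(pmax(round(px * 255), 0), 255))
}
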