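#' Normalize histogram counts to relative frequencies
#'
#' Divides each count by the total so the output sums to 1. An all-zero
#' input (possible for degenerate images, e.g. the edge histogram of a
#' constant block) is returned unchanged as the all-zero vector rather than
#' raising, so constant images remain processable end to end; the chi-square
#' distance downstream handles zero coordinates.
#'
#' @param counts numeric vector of nonnegative, finite counts.
#' @return Numeric vector of the same length summing to 1 (or all zero).
#' @examples
#' normalize_histogram(c(1, 3))
#' @export
normalize_histogram <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop("counts must be finite numeric values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) {
    return(as.numeric(counts))
  }
  as.numeric(counts) / total
}

# Half-open equal-width binning over [0, upper): bin b gets v in
# [b*upper/n, (b+1)*upper/n), except the last bin which is closed (and, when
# clamp = TRUE, absorbs any overflow above upper). Returns 1-based indices.
bin_index <- function(v, n_bins, upper) {
  idx <- floor(v * n_bins / upper)
  pmin(pmax(idx, 0), n_bins - 1) + 1L
}

#' Gray intensity histogram
#'
#' Counts pixel intensities into `n_bins` equal-width bins over \[0, 256)
#' and normalizes to relative frequencies. RGB images are first converted to
#' luminance grayscale.
#'
#' @param image a [raster_image()].
#' @param n_bins number of intensity bins (default 256, one per gray level).
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
gray_histogram <- function(image, n_bins = 256L) {
  stopifnot(is_raster_image(image))
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  g <- as_gray(image)
  counts <- tabulate(bin_index(as.vector(g$pixels), n_bins, 256), nbins = n_bins)
  normalize_histogram(counts)
}

#' Quantized joint color histogram
#'
#' Quantizes the red, green and blue channels into `bins[1]`, `bins[2]` and
#' `bins[3]` equal-width bins respectively and counts pixels in the joint
#' (red-major, then green, then blue) bin space, normalized to sum 1.
#'
#' @param image a 3-channel [raster_image()].
#' @param bins integer vector `c(k, m, l)` of per-channel bin counts
#'   (default `c(4, 4, 4)`, a 64-bin joint histogram).
#' @return Numeric vector of length `prod(bins)` summing to 1.
#' @export
color_histogram <- function(image, bins = c(4L, 4L, 4L)) {
  stopifnot(is_raster_image(image))
  if (image$channels != 3L) {
    stop("color_histogram requires a 3-channel image", call. = FALSE)
  }
  if (length(bins) != 3 || any(bins < 1)) {
    stop("bins must be three positive integers", call. = FALSE)
  }
  k <- bins[1]; m <- bins[2]; l <- bins[3]
  r <- bin_index(as.vector(image$pixels[, , 1]), k, 256) - 1L
  g <- bin_index(as.vector(image$pixels[, , 2]), m, 256) - 1L
  b <- bin_index(as.vector(image$pixels[, , 3]), l, 256) - 1L
  # red-major flattening: red varies slowest
  joint <- r * (m * l) + g * l + b + 1L
  counts <- tabulate(joint, nbins = k * m * l)
  normalize_histogram(counts)
}

#' Block grid over an image
#'
#' Partitions an H x W image into `rows` x `cols` half-open pixel ranges
#' that tile it exactly (boundary i at `floor(i * H / rows)`).
#'
#' @param height,width image dimensions in pixels.
#' @param rows,cols grid dimensions (default 4 x 4).
#' @return List with `rows`, `cols`, and the per-axis boundary vectors
#'   `row_breaks`, `col_breaks` (length rows + 1 / cols + 1).
#' @export
block_grid <- function(height, width, rows = 4L, cols = 4L) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  if (height < rows || width < cols) {
    stop("image smaller than block grid", call. = FALSE)
  }
  list(
    rows = as.integer(rows),
    cols = as.integer(cols),
    row_breaks = floor((0:rows) * height / rows),
    col_breaks = floor((0:cols) * width / cols)
  )
}

# Per-pixel central-difference gradients with replicate-border padding.
# Returns list(gx, gy) matrices; gx is the horizontal (column) derivative,
# gy the vertical (row) derivative.
image_gradients <- function(px) {
  h <- nrow(px); w <- ncol(px)
  right <- px[, c(2:w, w), drop = FALSE]
  left <- px[, c(1, 1:(w - 1)), drop = FALSE]
  down <- px[c(2:h, h), , drop = FALSE]
  up <- px[c(1, 1:(h - 1)), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

#' Block-based gradient-weighted edge orientation histogram
#'
#' Computes per-pixel gradients (central differences, replicate borders),
#' then, within each cell of a block grid, accumulates gradient magnitude
#' into `n_bins` equal-width orientation bins over \[0, 360) degrees. Each
#' block's histogram is normalized independently (so every block contributes
#' equal mass regardless of local contrast; a zero-gradient block yields an
#' all-zero sub-histogram) and blocks are concatenated row-major. With the
#' default 4 x 4 grid and 20 bins the descriptor has 320 dimensions.
#'
#' @param image a [raster_image()] (converted to grayscale if RGB).
#' @param rows,cols block grid dimensions (default 4 x 4).
#' @param n_bins orientation bins per block (default 20).
#' @return Numeric vector of length `rows * cols * n_bins`.
#' @export
edge_histogram <- function(image, rows = 4L, cols = 4L, n_bins = 20L) {
  stopifnot(is_raster_image(image))
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  g <- as_gray(image)
  grid <- block_grid(g$height, g$width, rows, cols)
  gr <- image_gradients(g$pixels)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  theta <- atan2(gr$gy, gr$gx) * 180 / pi
  theta <- theta %% 360
  obin <- bin_index(theta, n_bins, 360)
  out <- numeric(rows * cols * n_bins)
  for (br in seq_len(grid$rows)) {
    ri <- (grid$row_breaks[br] + 1):grid$row_breaks[br + 1]
    for (bc in seq_len(grid$cols)) {
      ci <- (grid$col_breaks[bc] + 1):grid$col_breaks[bc + 1]
      acc <- numeric(n_bins)
      m <- as.vector(mag[ri, ci])
      b <- as.vector(obin[ri, ci])
      keep <- m > 0
      if (any(keep)) {
        tab <- vapply(
          split(m[keep], factor(b[keep], levels = seq_len(n_bins))),
          sum, numeric(1)
        )
        acc <- unname(tab)
      }
      offset <- ((br - 1) * grid$cols + (bc - 1)) * n_bins
      out[offset + seq_len(n_bins)] <- normalize_histogram(acc)
    }
  }
  out
}

#' Block-based local variance histogram
#'
#' For every interior pixel, computes the (population) variance of the
#' `(2r+1) x (2r+1)` patch centered on it, then histograms those variances
#' into `n_bins` equal-width bins over \[0, 255^2/4\] — the maximum variance
#' attainable by values bounded in \[0, 255\] — with overflow clamped into
#' the last bin, and normalizes to sum 1.
#'
#' @param image a [raster_image()] (converted to grayscale if RGB), at least
#'   `2 * patch_radius + 1` pixels in each dimension.
#' @param patch_radius patch half-width r (default 2, a 5 x 5 patch).
#' @param n_bins number of variance bins (default 32).
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
variance_histogram <- function(image, patch_radius = 2L, n_bins = 32L) {
  stopifnot(is_raster_image(image))
  if (patch_radius < 1) stop("patch_radius must be >= 1", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  g <- as_gray(image)
  side <- 2L * patch_radius + 1L
  if (g$height < side || g$width < side) {
    stop("image too small for one full patch", call. = FALSE)
  }
  v <- patch_variances(g$pixels, patch_radius)
  counts <- tabulate(bin_index(as.vector(v), n_bins, 255^2 / 4), nbins = n_bins)
  normalize_histogram(counts)
}

# Variance of every full (2r+1)^2 patch via summed-area tables.
patch_variances <- function(px, r) {
  s1 <- box_sums(px, r)
  s2 <- box_sums(px^2, r)
  n <- (2 * r + 1)^2
  v <- s2 / n - (s1 / n)^2
  pmax(v, 0) # guard tiny negative round-off
}

# Sum over the (2r+1)x(2r+1) window centered at each interior pixel,
# computed with an integral image; returns an (H-2r) x (W-2r) matrix.
box_sums <- function(px, r) {
  h <- nrow(px); w <- ncol(px)
  ii <- rbind(0, cbind(0, t(apply(apply(px, 2, cumsum), 1, cumsum))))
  side <- 2 * r + 1
  rows <- 1:(h - side + 1)
  cols <- 1:(w - side + 1)
  ii[rows + side, cols + side, drop = FALSE] -
    ii[rows, cols + side, drop = FALSE] -
    ii[rows + side, cols, drop = FALSE] +
    ii[rows, cols, drop = FALSE]
}
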