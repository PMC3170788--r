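#' Dense grid patch sampling
#'
#' Extracts square pixel patches anchored at rows/cols 0, stride, 2*stride,
#' ... such that every patch lies entirely inside the image, in row-major
#' order of the anchors. Grid sampling (rather than interest points) covers
#' homogeneous regions too, which matters for modality cues like uniform
#' backgrounds.
#'
#' @param image a [raster_image()] (converted to grayscale if RGB).
#' @param patch_size patch side length in pixels (default 16).
#' @param stride anchor step in pixels (default 8).
#' @return List with `patches` (list of patch matrices) and `positions`
#'   (two-column matrix of 0-based row/col anchors).
#' @export
sample_grid_patches <- function(image, patch_size = 16L, stride = 8L) {
  stopifnot(is_raster_image(image))
  if (patch_size < 1 || stride < 1) {
    stop("patch_size and stride must be positive", call. = FALSE)
  }
  g <- as_gray(image)
  if (patch_size > g$height || patch_size > g$width) {
    stop("patch_size exceeds image extent", call. = FALSE)
  }
  row_anchors <- seq(0L, g$height - patch_size, by = stride)
  col_anchors <- seq(0L, g$width - patch_size, by = stride)
  patches <- vector("list", length(row_anchors) * length(col_anchors))
  positions <- matrix(0L, length(patches), 2,
                      dimnames = list(NULL, c("row", "col")))
  i <- 0L
  for (r in row_anchors) {
    for (cc in col_anchors) {
      i <- i + 1L
      patches[[i]] <- g$pixels[(r + 1):(r + patch_size),
                               (cc + 1):(cc + patch_size), drop = FALSE]
      positions[i, ] <- c(r, cc)
    }
  }
  list(patches = patches, positions = positions)
}

#' SIFT descriptor of a square patch
#'
#' Gradient-orientation histogram over a 4 x 4 grid of spatial cells with 8
#' orientation planes each (128 dimensions). Each pixel's gradient magnitude
#' is weighted by a Gaussian window centered on the patch (sigma = half the
#' patch side), de-emphasizing gradients far from the center, and accumulated
#' into the hard-assigned (cell, orientation) bin. The final vector is scaled
#' to unit L2 norm, which makes the descriptor invariant to affine intensity
#' changes a*I + b (a > 0); a gradient-free patch yields the all-zero vector.
#'
#' Entry ordering: spatial cells row-major, the 8 orientation bins fastest.
#'
#' @param patch square numeric matrix of intensities, side >= 4.
#' @return Numeric vector of length 128 with unit L2 norm (or all zero).
#' @export
sift_descriptor <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    stop("patch must be a square matrix", call. = FALSE)
  }
  s <- nrow(patch)
  if (s < 4) stop("patch side must be >= 4", call. = FALSE)
  gr <- image_gradients(patch)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  theta <- (atan2(gr$gy, gr$gx) * 180 / pi) %% 360
  obin <- bin_index(theta, 8L, 360) - 1L
  # Gaussian window centered on the patch, sigma = s / 2
  ctr <- (s - 1) / 2
  d2 <- outer((0:(s - 1) - ctr)^2, (0:(s - 1) - ctr)^2, "+")
  wmag <- mag * exp(-d2 / (2 * (s / 2)^2))
  # 4 x 4 spatial cells via exact tiling
  cell_r <- matrix(floor((0:(s - 1)) * 4 / s), s, s)
  cell_c <- t(cell_r)
  idx <- (cell_r * 4L + cell_c) * 8L + obin + 1L
  desc <- vapply(
    split(as.vector(wmag), factor(as.vector(idx), levels = 1:128)),
    sum, numeric(1)
  )
  desc <- unname(desc)
  nrm <- sqrt(sum(desc^2))
  if (nrm == 0) return(numeric(128))
  desc / nrm
}

#' SIFT descriptors for all dense patches of an image
#'
#' Convenience wrapper: [sample_grid_patches()] followed by
#' [sift_descriptor()] on each patch.
#'
#' @inheritParams sample_grid_patches
#' @return Matrix with one 128-dimensional descriptor per row.
#' @export
image_descriptors <- function(image, patch_size = 16L, stride = 8L) {
  ps <- sample_grid_patches(image, patch_size, stride)
  t(vapply(ps$patches, sift_descriptor, numeric(128)))
}

# Squared Euclidean distances between rows of x and rows of centers.
cross_sqdist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# Nearest-center assignment with deterministic lowest-index tie-breaking.
nearest_center <- function(x, centers) {
  max.col(-cross_sqdist(x, centers), ties.method = "first")
}

#' Build a k-means codebook of local descriptors
#'
#' Lloyd's algorithm under Euclidean distance with greedy
#' distance-proportional (k-means++-style) seeding driven by an explicit
#' seed, so codebooks are bit-reproducible. Assignment ties break to the
#' lowest center index; an emptied cluster keeps its previous center. The
#' within-cluster sum-of-squares objective is recorded at every iteration
#' (it is non-increasing under Lloyd updates).
#'
#' @param descriptors numeric matrix, one descriptor per row (at least `C`
#'   rows).
#' @param C codebook size, the number of cluster centers.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 100); stops early on a fixed point.
#' @return Object of class `codebook`: `centers` (C x dim matrix), `C`,
#'   `seed`, `iterations`, `objective` (final value) and
#'   `objective_trace` (per-iteration values).
#' @export
build_codebook <- function(descriptors, C, seed, max_iter = 100L) {
  if (!is.matrix(descriptors)) descriptors <- as.matrix(descriptors)
  n <- nrow(descriptors)
  if (C < 1) stop("C must be >= 1", call. = FALSE)
  if (n < C) stop("fewer descriptors than centers requested", call. = FALSE)
  centers <- kmeanspp_init(descriptors, C, seed)
  trace <- numeric(0)
  assign_prev <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- cross_sqdist(descriptors, centers)
    assign <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign)]))
    for (k in seq_len(C)) {
      members <- assign == k
      if (any(members)) {
        centers[k, ] <- colMeans(descriptors[members, , drop = FALSE])
      }
    }
    if (!is.null(assign_prev) && all(assign == assign_prev)) break
    if (iter >= max_iter) break
    assign_prev <- assign
  }
  d2 <- cross_sqdist(descriptors, centers)
  assign <- max.col(-d2, ties.method = "first")
  objective <- sum(d2[cbind(seq_len(n), assign)])
  structure(
    list(
      centers = centers, C = as.integer(C), seed = as.integer(seed),
      iterations = iter, objective = objective, objective_trace = trace
    ),
    class = "codebook"
  )
}

# Greedy distance-proportional seeding: first center uniform, each further
# center sampled with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_init <- function(x, C, seed) {
  with_rng_seed(seed, {
    n <- nrow(x)
    idx <- integer(C)
    idx[1] <- sample.int(n, 1)
    mind2 <- cross_sqdist(x, x[idx[1], , drop = FALSE])[, 1]
    if (C > 1) {
      for (k in 2:C) {
        if (sum(mind2) == 0) {
          idx[k] <- sample.int(n, 1)
        } else {
          idx[k] <- sample.int(n, 1, prob = mind2)
        }
        mind2 <- pmin(mind2, cross_sqdist(x, x[idx[k], , drop = FALSE])[, 1])
      }
    }
    x[idx, , drop = FALSE]
  })
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "<codebook C = %d, dim = %d, seed = %d, objective = %.6g (%d iterations)>\n",
    x$C, ncol(x$centers), x$seed, x$objective, x$iterations
  ))
  invisible(x)
}

#' Bag-of-visual-words histogram
#'
#' Assigns each descriptor to its Euclidean-nearest codebook center (ties to
#' the lowest center index) and returns the normalized count vector
#' h_c = (1/L) * sum_l delta(c, c(x_l)), which sums to 1.
#'
#' @param descriptors numeric matrix of descriptors, one per row (L >= 1).
#' @param codebook a [build_codebook()] result.
#' @return Numeric vector of length `codebook$C` summing to 1.
#' @export
bow_histogram <- function(descriptors, codebook) {
  if (!is.matrix(descriptors)) descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) == 0) {
    stop("empty patch set", call. = FALSE)
  }
  if (ncol(descriptors) != ncol(codebook$centers)) {
    stop("descriptor and codebook dimensions differ", call. = FALSE)
  }
  assign <- nearest_center(descriptors, codebook$centers)
  tabulate(assign, nbins = codebook$C) / nrow(descriptors)
}

#' Write a codebook to a plain-text file
#'
#' Format: header line `C<TAB>dim<TAB>seed`, then one center per line,
#' tab-separated decimals at full double precision.
#'
#' @param codebook a [build_codebook()] result.
#' @param path output file path.
#' @export
write_codebook <- function(codebook, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(codebook$C, ncol(codebook$centers), codebook$seed,
                   sep = "\t"), con)
  apply(codebook$centers, 1, function(row) {
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con)
  })
  invisible(path)
}

#' Read a codebook written by [write_codebook()]
#'
#' @param path codebook file path.
#' @return A `codebook` object (training trace fields absent).
#' @export
read_codebook <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  C <- hdr[1]; dm <- hdr[2]; seed <- hdr[3]
  centers <- matrix(0, C, dm)
  for (i in seq_len(C)) {
    centers[i, ] <- as.numeric(strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]])
  }
  structure(
    list(centers = centers, C = C, seed = seed,
         iterations = NA_integer_, objective = NA_real_,
         objective_trace = numeric(0)),
    class = "codebook"
  )
}
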