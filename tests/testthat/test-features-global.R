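test_that("normalize_histogram divides by the total and handles degenerate input", {
  expect_equal(normalize_histogram(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_histogram(c(1, 3)), c(0.25, 0.75))
  set.seed(42)
  counts <- runif(50, 0, 10)
  out <- normalize_histogram(counts)
  expect_lt(abs(sum(out) - 1), 1e-12)
  oracle <- vapply(seq_along(counts), function(i) counts[i] / sum(counts),
                   numeric(1))
  expect_equal(out, oracle, tolerance = 1e-14)
  # degenerate all-zero input passes through
  expect_equal(normalize_histogram(numeric(5)), numeric(5))
  expect_error(normalize_histogram(c(1, -1)), "nonnegative")
  expect_error(normalize_histogram(c(1, NaN)), "finite")
})

test_that("gray_histogram matches an exhaustive per-pixel counting oracle", {
  img <- constant_image(7)
  h <- gray_histogram(img)
  expect_equal(which(h > 0), 8L)
  expect_equal(h[8], 1)

  img2 <- raster_image(matrix(c(0, 0, 255, 255), 2, 2))
  h2 <- gray_histogram(img2)
  expect_equal(h2[1], 0.5)
  expect_equal(h2[256], 0.5)

  img3 <- rand_gray_image(16, 16, seed = 9)
  h3 <- gray_histogram(img3)
  oracle <- numeric(256)
  for (v in as.vector(img3$pixels)) oracle[v + 1] <- oracle[v + 1] + 1
  expect_equal(h3, oracle / sum(oracle), tolerance = 1e-14)
  expect_error(gray_histogram(img3, n_bins = 0), "n_bins")
})

test_that("color_histogram quantizes jointly red-major and matches a counting oracle", {
  img <- rand_rgb_image(4, 4, seed = 1)
  expect_equal(color_histogram(img, bins = c(1, 1, 1)), 1.0)

  solid_red <- raster_image(array(rep(c(255, 0, 0), each = 9), c(3, 3, 3)))
  h <- color_histogram(solid_red, bins = c(2, 2, 2))
  # joint bin (r=1, g=0, b=0), red-major: index r*4 + g*2 + b + 1 = 5
  expect_equal(h, c(0, 0, 0, 0, 1, 0, 0, 0))

  img2 <- rand_rgb_image(8, 8, seed = 2)
  h2 <- color_histogram(img2, bins = c(4, 4, 4))
  oracle <- numeric(64)
  for (i in 1:8) for (j in 1:8) {
    r <- img2$pixels[i, j, 1] %/% 64
    g <- img2$pixels[i, j, 2] %/% 64
    b <- img2$pixels[i, j, 3] %/% 64
    k <- r * 16 + g * 4 + b + 1
    oracle[k] <- oracle[k] + 1
  }
  expect_equal(h2, oracle / 64, tolerance = 1e-14)

  expect_error(color_histogram(rand_gray_image(4, 4)), "3-channel")
  expect_error(color_histogram(img2, bins = c(0, 4, 4)), "positive")
})

test_that("edge_histogram has the documented 320-dim default and zero response on constant images", {
  img <- rand_gray_image(32, 32, seed = 3)
  expect_length(edge_histogram(img), 320L)
  expect_equal(edge_histogram(constant_image(50, 32, 32)), numeric(320))
  expect_error(edge_histogram(rand_gray_image(3, 3)), "smaller")
})

test_that("edge_histogram concentrates step-edge mass at 0/180 degrees, matching a gradient oracle", {
  px <- matrix(0, 64, 64)
  px[, 33:64] <- 255
  img <- raster_image(px)
  h <- edge_histogram(img) # 4x4 grid, 20 bins of 18 degrees
  for (blk in 0:15) {
    sub <- h[blk * 20 + 1:20]
    if (sum(sub) == 0) next
    # bins containing 0 and 180 degrees are bins 1 and 11
    expect_gte(sub[1] + sub[11], 0.9)
  }
  # direct per-pixel oracle on a single-block layout
  h1 <- edge_histogram(img, rows = 1, cols = 1)
  oracle <- numeric(20)
  pad <- function(i, n) min(max(i, 1), n)
  for (i in 1:64) for (j in 1:64) {
    gx <- (px[i, pad(j + 1, 64)] - px[i, pad(j - 1, 64)]) / 2
    gy <- (px[pad(i + 1, 64), j] - px[pad(i - 1, 64), j]) / 2
    m <- sqrt(gx^2 + gy^2)
    if (m > 0) {
      th <- (atan2(gy, gx) * 180 / pi) %% 360
      b <- min(floor(th / 18), 19) + 1
      oracle[b] <- oracle[b] + m
    }
  }
  expect_equal(h1, oracle / sum(oracle), tolerance = 1e-12)
})

test_that("180-degree rotation permutes orientation bins by a half cycle", {
  img <- rand_gray_image(32, 32, seed = 5)
  rot <- raster_image(img$pixels[32:1, 32:1])
  h <- edge_histogram(img, rows = 1, cols = 1, n_bins = 20)
  hr <- edge_histogram(rot, rows = 1, cols = 1, n_bins = 20)
  shift <- c(11:20, 1:10) # bin b maps to b + n/2 (mod n)
  expect_equal(hr, h[shift], tolerance = 1e-12)
})

test_that("intensity histograms are pixel-permutation invariant; spatial ones are not", {
  img <- rand_gray_image(16, 16, seed = 7)
  set.seed(99)
  perm <- raster_image(matrix(sample(as.vector(img$pixels)), 16, 16))
  expect_equal(gray_histogram(img), gray_histogram(perm))
  expect_false(isTRUE(all.equal(edge_histogram(img), edge_histogram(perm))))
  expect_false(isTRUE(all.equal(variance_histogram(img),
                                variance_histogram(perm))))

  rgb <- rand_rgb_image(8, 8, seed = 8)
  set.seed(100)
  ord <- sample(64)
  ppx <- array(0, c(8, 8, 3))
  for (k in 1:3) ppx[, , k] <- matrix(as.vector(rgb$pixels[, , k])[ord], 8, 8)
  expect_equal(color_histogram(rgb), color_histogram(raster_image(ppx)))
})

test_that("variance_histogram equals a per-pixel loop oracle", {
  expect_equal(variance_histogram(constant_image(90, 16, 16))[1], 1)
  img <- rand_gray_image(32, 32, seed = 11)
  for (nb in c(16L, 32L)) {
    expect_length(variance_histogram(img, n_bins = nb), nb)
  }
  h <- variance_histogram(img, patch_radius = 2, n_bins = 32)
  px <- img$pixels
  vs <- c()
  for (i in 3:30) for (j in 3:30) {
    patch <- as.vector(px[(i - 2):(i + 2), (j - 2):(j + 2)])
    vs <- c(vs, mean(patch^2) - mean(patch)^2)
  }
  oracle <- numeric(32)
  width <- 255^2 / 4 / 32
  for (v in vs) {
    b <- min(floor(v / width), 31) + 1
    oracle[b] <- oracle[b] + 1
  }
  expect_equal(h, oracle / sum(oracle), tolerance = 1e-12)
  expect_error(variance_histogram(constant_image(1, 3, 3), patch_radius = 2),
               "too small")
})

test_that("histogram outputs sum to 1 for arbitrary images", {
  for (s in 1:5) {
    img <- rand_gray_image(24, 24, seed = 100 + s)
    expect_lt(abs(sum(gray_histogram(img)) - 1), 1e-9)
    expect_lt(abs(sum(variance_histogram(img)) - 1), 1e-9)
    eh <- edge_histogram(img)
    blocks <- matrix(eh, nrow = 20)
    expect_true(all(abs(colSums(blocks) - 1) < 1e-9 | colSums(blocks) == 0))
    rgb <- rand_rgb_image(12, 12, seed = 200 + s)
    expect_lt(abs(sum(color_histogram(rgb)) - 1), 1e-9)
  }
})

test_that("feature extraction is deterministic and grayscale conversion uses luminance weights", {
  img <- rand_rgb_image(16, 16, seed = 13)
  expect_identical(edge_histogram(img), edge_histogram(img))
  g <- as_gray(img)
  p <- img$pixels
  expect_equal(
    g$pixels,
    pmin(pmax(round(0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]),
              0), 255)
  )
})
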