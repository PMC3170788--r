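# Shared fixtures: deterministic random images and small synthetic datasets
# built in code at test time.

rand_gray_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  raster_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

rand_rgb_image <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  raster_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

constant_image <- function(value, h = 16, w = 16) {
  raster_image(matrix(value, h, w))
}

# Generate (once per session) a small synthetic dataset and return its
# loaded manifest; cached by name under the session temp dir.
cached_dataset <- function(name, spec) {
  dir <- file.path(tempdir(), paste0("modfuse_", name))
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    generate_dataset(spec, dir)
  }
  load_manifest(manifest_path)
}

# Compact experiment config for 64 px synthetic images.
test_config <- function(...) {
  cfg <- default_config()
  cfg$image_size <- 64L
  cfg$codebook_size <- 40L
  cfg$folds <- 5L
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

# Independent loop-based distance oracle (reference for the vectorized
# implementations).
loop_distance <- function(x, y, metric) {
  s <- 0
  for (l in seq_along(x)) {
    if (metric == "L1") {
      s <- s + abs(x[l] - y[l])
    } else if (metric == "L2") {
      s <- s + (x[l] - y[l])^2
    } else {
      d <- x[l] + y[l]
      if (d > 0) s <- s + (x[l] - y[l])^2 / d
    }
  }
  if (metric == "L2") sqrt(s) else s
}
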