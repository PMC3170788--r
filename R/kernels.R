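#' Distance between two feature vectors
#'
#' Supported metrics: `"L1"` (sum of absolute differences), `"L2"`
#' (Euclidean), and `"chi2"`, the chi-square histogram distance
#' sum_l (x_l - y_l)^2 / (x_l + y_l), which emphasizes relative differences
#' in small bins and is the default similarity measure for all features.
#' Chi-square terms with x_l + y_l = 0 (hence x_l = y_l = 0 on nonnegative
#' vectors) contribute 0, the standard continuous extension. No 1/2 factor
#' is applied; the downstream mean-distance normalization cancels any
#' constant factor.
#'
#' @param x,y numeric vectors of equal length; `chi2` additionally requires
#'   nonnegative entries.
#' @param metric one of `"chi2"`, `"L1"`, `"L2"`.
#' @return A single nonnegative number.
#' @examples
#' feature_distance(c(1, 0), c(0, 1), "chi2") # 2
#' @export
feature_distance <- function(x, y, metric = c("chi2", "L1", "L2")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) {
    stop("feature vectors have different lengths", call. = FALSE)
  }
  switch(metric,
    L1 = sum(abs(x - y)),
    L2 = sqrt(sum((x - y)^2)),
    chi2 = {
      if (any(x < 0) || any(y < 0)) {
        stop("chi2 distance requires nonnegative entries", call. = FALSE)
      }
      s <- x + y
      keep <- s > 0
      sum((x[keep] - y[keep])^2 / s[keep])
    }
  )
}

#' Pairwise distance matrix for one feature
#'
#' Symmetric N x N matrix of [feature_distance()] values between the rows of
#' a feature matrix; the diagonal is exactly zero.
#'
#' @param features numeric matrix, one sample's feature vector per row.
#' @param metric distance metric, see [feature_distance()].
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(features, metric = c("chi2", "L1", "L2")) {
  metric <- match.arg(metric)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 1) stop("no samples", call. = FALSE)
  n <- nrow(features)
  D <- cross_distances(features, features, metric)
  D <- (D + t(D)) / 2 # enforce exact symmetry against round-off
  diag(D) <- 0
  D
}

#' Rectangular distance matrix between two sample sets
#'
#' Distances from each row of `a` (e.g. test samples) to each row of `b`
#' (e.g. training samples) under one metric, vectorized over pairs.
#'
#' @param a,b numeric matrices with the same number of columns.
#' @param metric distance metric, see [feature_distance()].
#' @return `nrow(a)` x `nrow(b)` numeric matrix.
#' @export
cross_distances <- function(a, b, metric = c("chi2", "L1", "L2")) {
  metric <- match.arg(metric)
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature dimensions differ", call. = FALSE)
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (metric == "L2") {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    return(sqrt(pmax(d2, 0)))
  }
  if (metric == "chi2" && (any(a < 0) || any(b < 0))) {
    stop("chi2 distance requires nonnegative entries", call. = FALSE)
  }
  # accumulate one coordinate at a time (keeps memory at N^2, not N^2 * d)
  for (l in seq_len(ncol(a))) {
    diff <- outer(a[, l], b[, l], "-")
    if (metric == "L1") {
      out <- out + abs(diff)
    } else {
      s <- outer(a[, l], b[, l], "+")
      term <- diff^2 / s
      term[s == 0] <- 0
      out <- out + term
    }
  }
  out
}

#' Mean-distance normalizer gamma for one feature
#'
#' gamma_m = (1/N^2) * sum_{i,j} S_m^{i,j}, the mean distance over all N^2
#' ordered training pairs including the zero diagonal. Dividing a feature's
#' distances by its own gamma_m puts every feature's kernel on the same
#' scale, which is what lets features of different dimension and magnitude
#' contribute equally to the fused kernel. If all samples are identical the
#' mean is 0; gamma then falls back to 1 with a warning so degenerate toy
#' inputs remain runnable.
#'
#' @param distances square symmetric distance matrix from
#'   [pairwise_distances()].
#' @return A single positive number.
#' @export
compute_gamma <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop("distances must be a square matrix", call. = FALSE)
  }
  g <- sum(distances) / (nrow(distances)^2)
  if (g == 0) {
    warning("all pairwise distances are zero; gamma falls back to 1",
            call. = FALSE)
    g <- 1
  }
  g
}

#' RBF kernel from a distance matrix
#'
#' K^{i,j} = exp(-S^{i,j} / gamma). Entries lie in (0, 1]; a square distance
#' matrix with zero diagonal yields a symmetric kernel with unit diagonal.
#' At test time the training-derived gamma is reused so train and test
#' kernels share one scale.
#'
#' @param distances nonnegative distance matrix (square train x train or
#'   rectangular test x train).
#' @param gamma positive normalizer, usually [compute_gamma()] of the
#'   training distances.
#' @return Numeric matrix of kernel values in (0, 1].
#' @export
rbf_kernel <- function(distances, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number", call. = FALSE)
  }
  exp(-distances / gamma)
}

#' Fuse per-feature kernels by equal-contribution averaging
#'
#' The joint kernel equal contribution (JKEC) rule: the fused kernel is the
#' unweighted elementwise mean of the M per-feature kernels (each already on
#' a common scale through its gamma normalization). An optional weight
#' vector (summing to 1) gives an elementwise weighted mean instead — an
#' extension hook, not the default behavior.
#'
#' @param kernels list of >= 1 kernel matrices with identical dimensions and
#'   sample orderings.
#' @param weights optional nonnegative weights summing to 1, one per kernel.
#' @return Fused kernel matrix with entries in (0, 1].
#' @export
jkec_combine <- function(kernels, weights = NULL) {
  if (!is.list(kernels) || length(kernels) < 1) {
    stop("kernels must be a non-empty list", call. = FALSE)
  }
  dims <- lapply(kernels, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    stop("kernel matrices have mismatched shapes", call. = FALSE)
  }
  M <- length(kernels)
  if (is.null(weights)) {
    weights <- rep(1 / M, M)
  } else {
    if (length(weights) != M || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-9) {
      stop("weights must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  out <- kernels[[1]] * weights[1]
  if (M > 1) {
    for (m in 2:M) out <- out + kernels[[m]] * weights[m]
  }
  out
}

#' Write a kernel or distance matrix as tab-separated text
#'
#' Header row of sample identifiers, then one row per sample with its
#' identifier and values at 17 significant digits (bit-exact round trip).
#'
#' @param mat numeric matrix; row/column names are used as identifiers
#'   (generated as s1, s2, ... when absent).
#' @param path output file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  ids_col <- colnames(mat)
  if (is.null(ids_col)) ids_col <- paste0("s", seq_len(ncol(mat)))
  ids_row <- rownames(mat)
  if (is.null(ids_row)) ids_row <- paste0("s", seq_len(nrow(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", ids_col), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(ids_row[i], sprintf("%.17g", mat[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path input file path.
#' @return Numeric matrix with row and column names restored.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(hdr))))
  rownames(mat) <- vapply(body, `[`, character(1), 1)
  colnames(mat) <- hdr
  mat
}
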