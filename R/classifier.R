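#' Confusion groups of easily misclassified modalities
#'
#' The default groups are the three modality sets that a global classifier
#' tends to confuse among themselves: \{CT, MR, XR\}, \{NM, PET\} and
#' \{GX, PX\}. Each group gets its own local classifier during refinement.
#' User-supplied groups must be pairwise disjoint; an empty list makes
#' refinement the identity.
#'
#' @param groups optional list of character vectors overriding the default.
#' @return List of character vectors (possibly empty).
#' @export
define_confusion_groups <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(c("CT", "MR", "XR"), c("NM", "PET"), c("GX", "PX"))
  }
  if (!is.list(groups)) stop("groups must be a list", call. = FALSE)
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) {
    stop("confusion groups must be pairwise disjoint", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each confusion group needs at least 2 members", call. = FALSE)
  }
  groups
}

# ---- one-vs-one SVM on a precomputed kernel -------------------------------

#' Train a one-vs-one multi-class SVM on a precomputed kernel
#'
#' One binary C-SVM (kernlab) per unordered label pair, trained on the
#' corresponding sub-kernel. Prediction is by voting; ties break to the
#' label that comes first in `label_order`, so results are deterministic.
#'
#' @param K square fused train kernel matrix.
#' @param labels character vector of training labels, one per kernel row.
#' @param cost SVM regularization parameter C (default 1).
#' @param label_order the experiment's label ordering (default sorted unique
#'   labels); fixes vote tie-breaking.
#' @return Object of class `ovo_svm`.
#' @export
train_global <- function(K, labels, cost = 1, label_order = NULL) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("K must be a square kernel matrix", call. = FALSE)
  }
  if (length(labels) != nrow(K)) {
    stop("kernel order and label count differ", call. = FALSE)
  }
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(label_order)) label_order <- sort(unique(labels))
  present <- label_order[label_order %in% labels]
  if (length(present) < 2) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  pairs <- utils::combn(present, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- which(labels %in% pr)
    y <- factor(labels[idx], levels = pr)
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[idx, idx, drop = FALSE]),
                       y, type = "C-svc", C = cost)
    list(pair = pr, idx = idx, model = m)
  })
  structure(
    list(models = models, label_order = present, n_train = nrow(K),
         cost = cost),
    class = "ovo_svm"
  )
}

#' Predict with a one-vs-one SVM from a test-vs-train kernel
#'
#' @param object an `ovo_svm` model.
#' @param K_test `n_test` x `n_train` kernel between test and training
#'   samples (training columns in training order).
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.ovo_svm <- function(object, K_test, ...) {
  if (!is.matrix(K_test)) K_test <- matrix(K_test, nrow = 1)
  if (ncol(K_test) != object$n_train) {
    stop("test kernel has wrong number of training columns", call. = FALSE)
  }
  n <- nrow(K_test)
  if (n == 0) return(character(0))
  votes <- matrix(0L, n, length(object$label_order),
                  dimnames = list(NULL, object$label_order))
  for (bm in object$models) {
    Ksub <- K_test[, bm$idx, drop = FALSE]
    sv <- kernlab::SVindex(bm$model)
    p <- kernlab::predict(bm$model,
                          kernlab::as.kernelMatrix(Ksub[, sv, drop = FALSE]))
    p <- as.character(p)
    for (lab in bm$pair) {
      votes[, lab] <- votes[, lab] + (p == lab)
    }
  }
  # ties break to the earliest label in label_order
  object$label_order[max.col(votes, ties.method = "first")]
}

# ---- kernel construction from feature bundles -----------------------------

# Per-feature gamma and fused train kernel from a named list of train
# feature matrices.
fuse_train_kernel <- function(features, metrics) {
  stopifnot(is.list(features), length(features) >= 1)
  gammas <- numeric(0)
  kernels <- list()
  for (nm in names(features)) {
    D <- pairwise_distances(features[[nm]], metrics[[nm]])
    g <- compute_gamma(D)
    gammas[nm] <- g
    kernels[[nm]] <- rbf_kernel(D, g)
  }
  list(K = jkec_combine(kernels), gammas = gammas)
}

# Fused test-vs-train kernel using training-derived gammas.
fuse_test_kernel <- function(features_test, features_train, gammas, metrics) {
  kernels <- lapply(names(features_train), function(nm) {
    D <- cross_distances(features_test[[nm]], features_train[[nm]],
                         metrics[[nm]])
    rbf_kernel(D, gammas[[nm]])
  })
  jkec_combine(kernels)
}

# ---- hierarchical model ---------------------------------------------------

#' Train the hierarchical modality classifier
#'
#' Fits the global fused-kernel SVM over all classes, then one local
#' classifier per confusion group whose training subset contains at least
#' two of the group's classes. Each local classifier is trained only on the
#' group's samples, with every feature's gamma recomputed on that subset —
#' within-group distances are typically much smaller than the global mean
#' distance, so the rescaled local kernels spread the group's weak
#' between-class signal over a usable range.
#'
#' @param features named list of training feature matrices (one row per
#'   sample, shared row order).
#' @param labels character vector of training labels.
#' @param metrics named list mapping each feature to its distance metric
#'   (default chi2 for every feature).
#' @param cost SVM regularization parameter (default 1).
#' @param groups confusion groups from [define_confusion_groups()]; `NULL`
#'   for the defaults, `list()` to disable refinement.
#' @param label_order optional fixed label ordering.
#' @return Object of class `hier_model` holding the training features,
#'   gammas, global and local classifiers.
#' @export
train_hierarchical <- function(features, labels, metrics = NULL, cost = 1,
                               groups = NULL, label_order = NULL) {
  labels <- as.character(labels)
  if (is.null(metrics)) {
    metrics <- stats::setNames(as.list(rep("chi2", length(features))),
                               names(features))
  }
  if (is.null(label_order)) label_order <- sort(unique(labels))
  groups <- define_confusion_groups(groups %||% list_default_groups(label_order))
  fused <- fuse_train_kernel(features, metrics)
  global_model <- train_global(fused$K, labels, cost, label_order)
  local_models <- list()
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    idx <- which(labels %in% members)
    present <- unique(labels[idx])
    if (length(present) < 2) {
      warning(sprintf(
        "confusion group {%s}: fewer than 2 classes in training data; no local model",
        paste(members, collapse = ", ")), call. = FALSE)
      next
    }
    sub_feats <- lapply(features, function(f) f[idx, , drop = FALSE])
    sub_fused <- fuse_train_kernel(sub_feats, metrics)
    sub_model <- train_global(sub_fused$K, labels[idx], cost,
                              label_order[label_order %in% members])
    local_models[[length(local_models) + 1]] <- list(
      members = members, idx = idx, gammas = sub_fused$gammas,
      model = sub_model
    )
  }
  structure(
    list(
      features = features, labels = labels, metrics = metrics, cost = cost,
      label_order = label_order, gammas = fused$gammas,
      global_model = global_model, groups = groups,
      local_models = local_models
    ),
    class = "hier_model"
  )
}

# Default groups restricted to the labels actually present; an empty list
# when none of the canonical group members appear (synthetic class names).
list_default_groups <- function(label_order) {
  defaults <- list(c("CT", "MR", "XR"), c("NM", "PET"), c("GX", "PX"))
  keep <- lapply(defaults, function(g) g[g %in% label_order])
  keep[vapply(keep, length, integer(1)) >= 2]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf(
    "<hier_model: %d training samples, %d classes, %d features, %d local model%s>\n",
    length(x$labels), length(x$label_order), length(x$features),
    length(x$local_models), if (length(x$local_models) == 1) "" else "s"
  ))
  invisible(x)
}

#' Predict modality labels with a hierarchical model
#'
#' Computes test-vs-train per-feature distances, applies the stored
#' training gammas, fuses the kernels, classifies with the global SVM, and
#' then refines: every sample whose global prediction falls inside a
#' confusion group with a trained local model is re-classified by that
#' group's local classifier (whose output necessarily stays within the
#' group); all other predictions pass through unchanged. Refinement is
#' applied once, not iterated.
#'
#' @param object a [train_hierarchical()] model.
#' @param features_test named list of test feature matrices matching the
#'   training feature set.
#' @param refine apply the local-classifier refinement (default TRUE).
#' @param ... unused.
#' @return List with character vectors `global` and `refined`.
#' @export
predict.hier_model <- function(object, features_test, refine = TRUE, ...) {
  if (!setequal(names(features_test), names(object$features))) {
    stop("test feature set does not match the model's features", call. = FALSE)
  }
  features_test <- features_test[names(object$features)]
  n <- nrow(features_test[[1]])
  if (n == 0) return(list(global = character(0), refined = character(0)))
  K_test <- fuse_test_kernel(features_test, object$features, object$gammas,
                             object$metrics)
  global_pred <- predict(object$global_model, K_test)
  refined <- global_pred
  if (refine) {
    refined <- refine_predictions(global_pred, features_test, object)
  }
  list(global = global_pred, refined = refined)
}

#' Refine global predictions with confusion-group local classifiers
#'
#' @param global_preds character vector of global predictions.
#' @param features_test named list of test feature matrices.
#' @param model a `hier_model` carrying the local classifiers.
#' @return Character vector of refined predictions; samples predicted
#'   outside every group are returned unchanged.
#' @export
refine_predictions <- function(global_preds, features_test, model) {
  refined <- global_preds
  for (lm in model$local_models) {
    sel <- which(global_preds %in% lm$members)
    if (length(sel) == 0) next
    sub_test <- lapply(features_test, function(f) f[sel, , drop = FALSE])
    sub_train <- lapply(model$features,
                        function(f) f[lm$idx, , drop = FALSE])
    K_loc <- fuse_test_kernel(sub_test, sub_train, lm$gammas, model$metrics)
    refined[sel] <- predict(lm$model, K_loc)
  }
  refined
}

# ---- evaluation helpers ---------------------------------------------------

#' Row-normalized confusion matrix in percent
#'
#' Rows are true classes, columns predicted classes; each row with support
#' sums to 100 (rows with zero support are all-NA).
#'
#' @param truth,pred character vectors of equal length.
#' @param labels label ordering for rows/columns (default sorted union).
#' @return Numeric matrix of row percentages.
#' @export
confusion_matrix_pct <- function(truth, pred, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = labels),
               factor(pred, levels = labels))
  m <- matrix(as.numeric(tab), nrow = length(labels),
              dimnames = list(labels, labels))
  support <- rowSums(m)
  out <- m
  for (i in seq_along(labels)) {
    out[i, ] <- if (support[i] > 0) 100 * m[i, ] / support[i] else NA_real_
  }
  out
}

#' Classification accuracy in percent
#'
#' @param truth,pred character vectors of equal length.
#' @return Percent of matching entries (micro accuracy).
#' @export
accuracy_pct <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred lengths differ", call. = FALSE)
  }
  if (length(truth) == 0) return(NA_real_)
  100 * mean(truth == pred)
}
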