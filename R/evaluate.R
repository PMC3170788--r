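# Evaluation drivers: stratified cross-validation, the fixed
# train-per-class split, and the per-feature distance-metric comparison.

#' Stratified fold assignment
#'
#' Assigns every sample to one of `k` folds so that within each class the
#' fold sizes differ by at most one. Deterministic given `seed`.
#'
#' @param labels character vector of class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < k)) {
    stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                 names(counts)[which.min(counts)], min(counts), k),
         call. = FALSE)
  }
  folds <- integer(length(labels))
  with_rng_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Feature bundle rows for an index subset (named list of matrices).
subset_bundle <- function(feats, idx) {
  lapply(feats, function(f) f[idx, , drop = FALSE])
}

# All fold-independent feature matrices (everything except bow, whose
# codebook must be trained per fold on training descriptors only).
static_feature_bundle <- function(images, captions, config, vocab) {
  static <- setdiff(config$features, "bow")
  if (length(static) == 0) return(list())
  cfg <- utils::modifyList(config, list(features = static))
  extract_feature_bundle(images, captions, cfg, vocab = vocab)
}

#' Stratified k-fold cross-validation of the fused pipeline
#'
#' Evaluates three conditions per fold, mirroring the standard ablation:
#' all visual features fused (`visual`), visual plus textual (`
#' visual_textual`), and visual plus textual followed by confusion-group
#' refinement (`refined`). Within every fold the codebook, the per-feature
#' gammas and all SVMs are trained on the training folds only; descriptors
#' and fold-independent features are cached across folds.
#'
#' @param manifest labeled [load_manifest()] data.frame.
#' @param config configuration list; `config$folds` sets k and
#'   `config$seed` drives fold assignment and per-fold codebook seeds.
#' @return List with `per_fold` (data.frame of per-fold accuracies), `mean`
#'   (named sample-weighted mean accuracies), `predictions` (per-sample
#'   data.frame), and `confusion` (pooled row-percent confusion matrix of
#'   the refined condition).
#' @export
run_cross_validation <- function(manifest, config = default_config()) {
  labels <- as.character(manifest$label)
  if (any(!nzchar(labels))) {
    stop("cross-validation requires a fully labeled manifest", call. = FALSE)
  }
  k <- config$folds
  images <- prepare_images(manifest, config)
  vocab <- if ("text" %in% config$features) {
    load_vocabulary(config$vocabulary_path)
  } else NULL
  descriptors <- compute_all_descriptors(images, config)
  static_all <- static_feature_bundle(images, manifest$caption, config, vocab)
  folds <- stratified_folds(labels, k, derive_seed(config$seed, 7))
  visual_features <- setdiff(config$features, "text")
  n <- nrow(manifest)
  pred_visual <- pred_fused <- pred_refined <- character(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    cfg_fold <- utils::modifyList(config,
                                  list(seed = derive_seed(config$seed, f)))
    codebook <- NULL
    feats_all <- static_all
    if ("bow" %in% config$features) {
      codebook <- build_codebook(
        do.call(rbind, descriptors[train_idx]),
        C = config$codebook_size,
        seed = derive_seed(cfg_fold$seed, 101),
        max_iter = config$codebook_max_iter
      )
      feats_all$bow <- t(vapply(descriptors, bow_histogram,
                                numeric(codebook$C), codebook = codebook))
    }
    feats_all <- feats_all[config$features]
    metrics <- stats::setNames(
      lapply(config$features, metric_for, cfg = config), config$features)
    train_feats <- subset_bundle(feats_all, train_idx)
    test_feats <- subset_bundle(feats_all, test_idx)
    # full-feature hierarchical model (fused + refined conditions)
    model_full <- train_hierarchical(
      train_feats, labels[train_idx], metrics = metrics,
      cost = config$svm_cost, groups = config$confusion_groups,
      label_order = sort(unique(labels))
    )
    p_full <- predict(model_full, test_feats, refine = TRUE)
    # visual-only condition (global classifier, no refinement)
    if (length(visual_features) > 0 &&
        !identical(sort(visual_features), sort(config$features))) {
      model_vis <- train_hierarchical(
        train_feats[visual_features],
        labels[train_idx], metrics = metrics[visual_features],
        cost = config$svm_cost, groups = list(),
        label_order = sort(unique(labels))
      )
      p_vis <- predict(model_vis, test_feats[visual_features],
                       refine = FALSE)$global
    } else {
      p_vis <- p_full$global
    }
    pred_visual[test_idx] <- p_vis
    pred_fused[test_idx] <- p_full$global
    pred_refined[test_idx] <- p_full$refined
    per_fold[[f]] <- data.frame(
      fold = f,
      n_test = length(test_idx),
      acc_visual = accuracy_pct(labels[test_idx], p_vis),
      acc_visual_textual = accuracy_pct(labels[test_idx], p_full$global),
      acc_refined = accuracy_pct(labels[test_idx], p_full$refined)
    )
  }
  per_fold <- do.call(rbind, per_fold)
  list(
    per_fold = per_fold,
    mean = c(
      visual = accuracy_pct(labels, pred_visual),
      visual_textual = accuracy_pct(labels, pred_fused),
      refined = accuracy_pct(labels, pred_refined)
    ),
    predictions = data.frame(
      sample_id = manifest$sample_id, label = labels, fold = folds,
      visual = pred_visual, visual_textual = pred_fused,
      refined = pred_refined, stringsAsFactors = FALSE
    ),
    confusion = confusion_matrix_pct(labels, pred_refined,
                                     sort(unique(labels)))
  )
}

#' Per-class fixed-count train/test split
#'
#' Randomly selects `n_train_per_class` training samples from each class
#' (the remainder is the test set), deterministically per seed.
#'
#' @param labels character vector of class labels.
#' @param n_train_per_class training samples per class.
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
fixed_split <- function(labels, n_train_per_class, seed) {
  counts <- table(labels)
  if (any(counts <= n_train_per_class)) {
    stop(sprintf(
      "class '%s' has %d samples; need more than n_train_per_class = %d",
      names(counts)[which.min(counts)], min(counts), n_train_per_class),
      call. = FALSE)
  }
  train <- integer(0)
  with_rng_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      train <- c(train, idx[sample.int(length(idx), n_train_per_class)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train/evaluate on a per-class fixed split
#'
#' The split protocol used for confusion analysis: a fixed number of
#' training images per class, the rest for test, one run per seed. Returns
#' accuracies with and without refinement and the row-percent confusion
#' matrix of the refined predictions.
#'
#' @param manifest labeled manifest data.frame.
#' @param config configuration list.
#' @param n_train_per_class training samples per class (ignored when
#'   `split` is given).
#' @param seed split seed (default `config$seed`).
#' @param split optional precomputed `list(train, test)` of row indices,
#'   overriding the per-class random split.
#' @param return_model also return the fitted classifier (default FALSE).
#' @return List with `split`, per-sample predictions, `accuracy_global`,
#'   `accuracy_refined`, `confusion`, and optionally `model`.
#' @export
run_fixed_split <- function(manifest, config = default_config(),
                            n_train_per_class = NULL, seed = NULL,
                            split = NULL, return_model = FALSE) {
  labels <- as.character(manifest$label)
  if (is.null(seed)) seed <- config$seed
  sp <- split %||%
    fixed_split(labels, n_train_per_class, derive_seed(seed, 13))
  images <- prepare_images(manifest, config)
  descriptors <- compute_all_descriptors(images, config)
  cfg <- utils::modifyList(config, list(seed = as.integer(seed)))
  fitted <- fit_modality_classifier_prepared(
    images[sp$train], manifest$caption[sp$train], labels[sp$train], cfg,
    descriptors = if (is.null(descriptors)) NULL else descriptors[sp$train]
  )
  vocab <- fitted$vocab
  test_feats <- extract_feature_bundle(
    images[sp$test], manifest$caption[sp$test], cfg, fitted$codebook, vocab,
    descriptors = if (is.null(descriptors)) NULL else descriptors[sp$test]
  )
  preds <- predict(fitted$model, test_feats, refine = TRUE)
  truth <- labels[sp$test]
  out <- list(
    split = sp,
    sample_id = manifest$sample_id[sp$test],
    truth = truth,
    global = preds$global,
    refined = preds$refined,
    accuracy_global = accuracy_pct(truth, preds$global),
    accuracy_refined = accuracy_pct(truth, preds$refined),
    confusion = confusion_matrix_pct(truth, preds$refined,
                                     sort(unique(labels[sp$train])))
  )
  if (return_model) out$model <- fitted
  out
}

#' Compare distance metrics per feature
#'
#' For every enabled feature and every metric in \{L1, L2, chi2\}, runs the
#' fixed-split protocol with that single feature and metric and tabulates
#' the global-classifier accuracy. Images, descriptors and the per-fold
#' codebook are shared across the table's cells.
#'
#' @param manifest labeled manifest data.frame.
#' @param config configuration list (its `features` toggle selects the rows
#'   of the table).
#' @param n_train_per_class training samples per class.
#' @param seed split seed (default `config$seed`).
#' @return data.frame with columns feature, metric, accuracy.
#' @export
compare_metrics <- function(manifest, config = default_config(),
                            n_train_per_class, seed = NULL) {
  labels <- as.character(manifest$label)
  if (is.null(seed)) seed <- config$seed
  sp <- fixed_split(labels, n_train_per_class, derive_seed(seed, 13))
  images <- prepare_images(manifest, config)
  vocab <- if ("text" %in% config$features) {
    load_vocabulary(config$vocabulary_path)
  } else NULL
  descriptors <- compute_all_descriptors(images, config)
  feats_all <- static_feature_bundle(images, manifest$caption, config, vocab)
  if ("bow" %in% config$features) {
    codebook <- build_codebook(
      do.call(rbind, descriptors[sp$train]), C = config$codebook_size,
      seed = derive_seed(seed, 101), max_iter = config$codebook_max_iter
    )
    feats_all$bow <- t(vapply(descriptors, bow_histogram,
                              numeric(codebook$C), codebook = codebook))
  }
  rows <- list()
  label_order <- sort(unique(labels))
  for (f in config$features) {
    for (metric in c("L1", "L2", "chi2")) {
      feat_train <- feats_all[[f]][sp$train, , drop = FALSE]
      feat_test <- feats_all[[f]][sp$test, , drop = FALSE]
      D <- pairwise_distances(feat_train, metric)
      g <- compute_gamma(D)
      K <- rbf_kernel(D, g)
      model <- train_global(K, labels[sp$train], config$svm_cost,
                            label_order)
      K_test <- rbf_kernel(cross_distances(feat_test, feat_train, metric), g)
      p <- predict(model, K_test)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, metric = metric,
        accuracy = accuracy_pct(labels[sp$test], p),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
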