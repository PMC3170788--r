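# Manifest-level pipeline: images + captions -> feature bundles -> trained
# hierarchical model -> predictions. A "feature bundle" is a named list of
# N x d matrices sharing one row (sample) order; bundles are compositional,
# so adding the textual feature never requires re-extracting visual ones.

#' Read and standardize all manifest images
#'
#' @param manifest a [load_manifest()] data.frame.
#' @param config configuration list ([default_config()]).
#' @return List of standardized [raster_image()] objects.
#' @export
prepare_images <- function(manifest, config = default_config()) {
  lapply(manifest$image_path, function(p) {
    standardize_image(read_image(p), config$image_size)
  })
}

# Dense SIFT descriptors per image (list of matrices); NULL when the bag of
# visual words is disabled.
compute_all_descriptors <- function(images, config) {
  if (!("bow" %in% config$features)) return(NULL)
  lapply(images, image_descriptors,
         patch_size = config$patch_size, stride = config$stride)
}

#' Extract the configured feature bundle
#'
#' Runs every enabled extractor over prepared images and captions. The bag
#' of visual words requires a codebook (trained beforehand on training-set
#' descriptors only); the textual histogram requires the vocabulary.
#'
#' @param images list of standardized [raster_image()] objects.
#' @param captions character vector of captions (same order).
#' @param config configuration list.
#' @param codebook a [build_codebook()] result (when `bow` is enabled).
#' @param vocab a [load_vocabulary()] result (when `text` is enabled).
#' @param descriptors optional precomputed per-image descriptor list (saves
#'   recomputation across cross-validation folds).
#' @return Named list of N x d feature matrices.
#' @export
extract_feature_bundle <- function(images, captions, config = default_config(),
                                   codebook = NULL, vocab = NULL,
                                   descriptors = NULL) {
  n <- length(images)
  feats <- list()
  for (f in config$features) {
    feats[[f]] <- switch(f,
      gray = t(vapply(images, gray_histogram, numeric(config$gray_bins),
                      n_bins = config$gray_bins)),
      color = t(vapply(images, color_histogram,
                       numeric(prod(config$color_bins)),
                       bins = config$color_bins)),
      edge = t(vapply(images, edge_histogram,
                      numeric(prod(config$edge_grid) * config$edge_bins),
                      rows = config$edge_grid[1], cols = config$edge_grid[2],
                      n_bins = config$edge_bins)),
      variance = t(vapply(images, variance_histogram,
                          numeric(config$variance_bins),
                          patch_radius = config$variance_patch_radius,
                          n_bins = config$variance_bins)),
      bow = {
        if (is.null(codebook)) {
          stop("bow feature requires a codebook", call. = FALSE)
        }
        if (is.null(descriptors)) {
          descriptors <- compute_all_descriptors(images, config)
        }
        t(vapply(descriptors, bow_histogram, numeric(codebook$C),
                 codebook = codebook))
      },
      text = {
        if (is.null(vocab)) vocab <- load_vocabulary(config$vocabulary_path)
        t(vapply(captions, binary_keyword_histogram,
                 numeric(length(vocab)), vocab = vocab, USE.NAMES = FALSE))
      }
    )
  }
  feats
}

#' Fit the full modality classifier from a labeled manifest
#'
#' End-to-end training: reads and standardizes images, computes dense SIFT
#' descriptors, trains the codebook (on these training samples only),
#' extracts the configured feature bundle, fuses per-feature chi-square RBF
#' kernels with equal contribution, and trains the global plus
#' confusion-group local SVMs.
#'
#' @param manifest labeled [load_manifest()] data.frame.
#' @param config configuration list.
#' @return Object of class `modality_classifier` wrapping the
#'   [train_hierarchical()] model, the codebook, vocabulary and config.
#' @export
fit_modality_classifier <- function(manifest, config = default_config()) {
  if (any(!nzchar(manifest$label))) {
    stop("training manifest must be fully labeled", call. = FALSE)
  }
  images <- prepare_images(manifest, config)
  fit_modality_classifier_prepared(
    images, manifest$caption, manifest$label, config,
    descriptors = compute_all_descriptors(images, config)
  )
}

# Training entry point over already-prepared images/descriptors (shared by
# the cross-validation driver, which caches both across folds).
fit_modality_classifier_prepared <- function(images, captions, labels, config,
                                             descriptors = NULL,
                                             static_feats = NULL,
                                             codebook = NULL) {
  vocab <- if ("text" %in% config$features) {
    load_vocabulary(config$vocabulary_path)
  } else NULL
  if ("bow" %in% config$features && is.null(codebook)) {
    if (is.null(descriptors)) {
      descriptors <- compute_all_descriptors(images, config)
    }
    codebook <- build_codebook(do.call(rbind, descriptors),
                               C = config$codebook_size,
                               seed = derive_seed(config$seed, 101),
                               max_iter = config$codebook_max_iter)
  }
  feats <- if (is.null(static_feats)) {
    extract_feature_bundle(images, captions, config, codebook, vocab,
                           descriptors)
  } else {
    c(static_feats,
      extract_feature_bundle(
        images, captions,
        utils::modifyList(config, list(
          features = setdiff(config$features, names(static_feats)))),
        codebook, vocab, descriptors
      ))[config$features]
  }
  metrics <- stats::setNames(
    lapply(config$features, metric_for, cfg = config), config$features)
  model <- train_hierarchical(
    feats, labels, metrics = metrics, cost = config$svm_cost,
    groups = config$confusion_groups,
    label_order = sort(unique(as.character(labels)))
  )
  structure(
    list(model = model, codebook = codebook, vocab = vocab, config = config),
    class = "modality_classifier"
  )
}

#' @export
print.modality_classifier <- function(x, ...) {
  cat(sprintf(
    "<modality_classifier: features [%s], %d classes, %d training samples>\n",
    paste(x$config$features, collapse = ", "),
    length(x$model$label_order), length(x$model$labels)
  ))
  invisible(x)
}

#' Predict modalities for a manifest
#'
#' Extracts the model's feature set from the test images/captions (reusing
#' the trained codebook and vocabulary), builds the test-vs-train fused
#' kernel with the training gammas, and runs global classification followed
#' by confusion-group refinement.
#'
#' @param object a [fit_modality_classifier()] result.
#' @param manifest test manifest (labels optional).
#' @param refine apply refinement (default from the config).
#' @param ... unused.
#' @return List with `sample_id`, `global`, `refined`, and — when the
#'   manifest has labels — `accuracy_global`, `accuracy_refined` (percent)
#'   and the row-percent `confusion` matrix of the refined predictions.
#' @export
predict.modality_classifier <- function(object, manifest,
                                        refine = NULL, ...) {
  config <- object$config
  if (is.null(refine)) refine <- isTRUE(config$refine)
  images <- prepare_images(manifest, config)
  feats <- extract_feature_bundle(images, manifest$caption, config,
                                  object$codebook, object$vocab)
  preds <- predict(object$model, feats, refine = refine)
  out <- list(sample_id = manifest$sample_id,
              global = preds$global, refined = preds$refined)
  if (all(nzchar(manifest$label))) {
    out$accuracy_global <- accuracy_pct(manifest$label, preds$global)
    out$accuracy_refined <- accuracy_pct(manifest$label, preds$refined)
    out$confusion <- confusion_matrix_pct(manifest$label, preds$refined,
                                          object$model$label_order)
  }
  out
}
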