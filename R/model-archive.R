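# Model persistence: a directory holding the fitted classifier plus
# human-readable sidecars (config snapshot, codebook, gammas, training
# sample ids). The SVM coefficients and training features live in a single
# RDS payload; the sidecars exist for inspection and provenance.

#' Save a fitted modality classifier to a directory archive
#'
#' @param object a [fit_modality_classifier()] result.
#' @param dir archive directory (created if needed).
#' @param sample_ids optional training sample identifiers recorded in the
#'   archive manifest.
#' @export
save_modality_classifier <- function(object, dir, sample_ids = NULL) {
  stopifnot(inherits(object, "modality_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, file.path(dir, "model.rds"))
  cfg <- object$config
  cfg$vocabulary_path <- cfg$vocabulary_path %||% "(bundled)"
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(object$codebook)) {
    write_codebook(object$codebook, file.path(dir, "codebook.tsv"))
  }
  if (!is.null(object$vocab)) {
    writeLines(as.character(object$vocab), file.path(dir, "vocabulary.txt"))
  }
  g <- object$model$gammas
  writeLines(paste(names(g), sprintf("%.17g", g), sep = "\t"),
             file.path(dir, "gammas.tsv"))
  if (!is.null(sample_ids)) {
    writeLines(sample_ids, file.path(dir, "training_ids.txt"))
  }
  invisible(dir)
}

#' Load a modality classifier archive
#'
#' @param dir archive directory written by [save_modality_classifier()].
#' @return The `modality_classifier` object.
#' @export
load_modality_classifier <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) {
    stop(sprintf("not a model archive (missing model.rds): %s", dir),
         call. = FALSE)
  }
  readRDS(path)
}
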