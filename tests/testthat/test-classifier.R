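# Feature-level fixtures: separable histogram-like class profiles, no image
# pipeline involved.
sep_bundle <- function(classes, n_per_class, seed, noise = 0.05, dim = 12) {
  set.seed(seed)
  labels <- rep(classes, each = n_per_class)
  make_feat <- function(offset) {
    profiles <- lapply(seq_along(classes), function(ci) {
      p <- rep(0.2, dim)
      p[((ci + offset - 1) %% dim) + 1] <- 3
      p / sum(p)
    })
    rows <- lapply(seq_along(labels), function(i) {
      ci <- match(labels[i], classes)
      v <- profiles[[ci]] + runif(dim, 0, noise)
      v / sum(v)
    })
    do.call(rbind, rows)
  }
  list(features = list(a = make_feat(0), b = make_feat(3)), labels = labels)
}

test_that("default confusion groups are the three canonical modality sets", {
  groups <- define_confusion_groups()
  expect_equal(groups,
               list(c("CT", "MR", "XR"), c("NM", "PET"), c("GX", "PX")))
  expect_error(define_confusion_groups(list(c("A", "B"), c("B", "C"))),
               "disjoint")
  expect_equal(define_confusion_groups(list()), list())
  expect_error(define_confusion_groups(list("A")), "at least 2")
})

test_that("one-vs-one SVM separates well-separated classes and validates inputs", {
  fx <- sep_bundle(c("p", "q"), 12, seed = 1)
  D <- pairwise_distances(fx$features$a, "chi2")
  K <- rbf_kernel(D, compute_gamma(D))
  model <- train_global(K, fx$labels)
  pred <- predict(model, K)
  expect_equal(pred, fx$labels)
  expect_true(all(pred %in% fx$labels))
  expect_error(train_global(K, fx$labels[-1]), "differ")
  expect_error(train_global(K, rep("p", 24)), "2 classes")
  expect_error(train_global(K[, 1:3], fx$labels), "square")
})

test_that("hierarchical model reclassifies only group predictions, within the group", {
  fx <- sep_bundle(c("w", "x", "y", "z"), 10, seed = 2)
  model <- train_hierarchical(fx$features, fx$labels,
                              groups = list(c("y", "z")))
  expect_length(model$local_models, 1L)
  expect_setequal(unique(fx$labels[model$local_models[[1]]$idx]),
                  c("y", "z"))
  preds <- predict(model, fx$features)
  # projection: predictions outside the group are untouched
  outside <- !(preds$global %in% c("y", "z"))
  expect_identical(preds$refined[outside], preds$global[outside])
  # any changed label stays within the group
  changed <- preds$refined != preds$global
  expect_true(all(preds$global[changed] %in% c("y", "z")))
  expect_true(all(preds$refined[changed] %in% c("y", "z")))
  # separable training data is perfectly recovered
  expect_equal(preds$refined, fx$labels)
})

test_that("local models are skipped with a warning when a group lacks classes", {
  fx <- sep_bundle(c("w", "x"), 8, seed = 3)
  expect_warning(
    model <- train_hierarchical(fx$features, fx$labels,
                                groups = list(c("y", "z"))),
    "no local model"
  )
  expect_length(model$local_models, 0L)
  preds <- predict(model, fx$features)
  expect_identical(preds$refined, preds$global)
})

test_that("training and prediction are deterministic given fixed inputs", {
  fx <- sep_bundle(c("p", "q", "r"), 8, seed = 4, noise = 0.3)
  m1 <- train_hierarchical(fx$features, fx$labels, groups = list())
  m2 <- train_hierarchical(fx$features, fx$labels, groups = list())
  expect_identical(m1$gammas, m2$gammas)
  p1 <- predict(m1, fx$features)
  p2 <- predict(m2, fx$features)
  expect_identical(p1, p2)
})

test_that("empty test sets and feature-set mismatches are handled", {
  fx <- sep_bundle(c("p", "q"), 6, seed = 5)
  model <- train_hierarchical(fx$features, fx$labels, groups = list())
  empty <- lapply(fx$features, function(f) f[0, , drop = FALSE])
  preds <- predict(model, empty)
  expect_identical(preds$global, character(0))
  expect_identical(preds$refined, character(0))
  expect_error(predict(model, fx$features["a"]), "feature set")
})

test_that("confusion matrix rows with support sum to 100", {
  truth <- c("a", "a", "b", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "c", "c")
  cm <- confusion_matrix_pct(truth, pred)
  expect_equal(rowSums(cm), c(a = 100, b = 100, c = 100), tolerance = 1e-6)
  cm2 <- confusion_matrix_pct(truth, pred, labels = c("a", "b", "c", "d"))
  expect_true(all(is.na(cm2["d", ])))
  expect_equal(accuracy_pct(truth, pred), 100 * 4 / 6)
})
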