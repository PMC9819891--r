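# RBF-kernel SVM harness shared by the EEG and music pipelines: min-max
# feature scaling fitted on training data only, grid search over (C, gamma)
# with seeded stratified k-fold cross-validation, confusion matrices, and
# EEG channel ranking / top-k selection.

#' Min-max feature scaling to [-1, 1]
#'
#' Fits per-feature minimum and maximum on `train` only and maps both tables
#' linearly to `[-1, 1]`; features constant on the training data map to 0.
#'
#' @param train numeric matrix or data frame of training features.
#' @param apply_to optional second table with the same feature names to scale
#'   with the training parameters.
#' @return List with `train` (scaled matrix), `applied` (scaled `apply_to` or
#'   NULL), and `params` (`min`, `max` per feature).
#' @export
scale_features <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    if (!identical(colnames(train), colnames(apply_to)))
      stop_input("feature names differ between 'train' and 'apply_to'")
  }
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  map <- function(m) {
    out <- sweep(m, 2, lo)
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
    out[, rng == 0] <- 0
    out
  }
  list(train = map(train), applied = if (is.null(apply_to)) NULL else map(apply_to),
       params = list(min = lo, max = hi))
}

#' SVM harness configuration
#'
#' The default grids are the canonical coarse grids for RBF-kernel model
#' selection: `C = 2^(-5), 2^(-3), ..., 2^15` and
#' `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param C_grid cost grid.
#' @param gamma_grid kernel width grid.
#' @param folds number of cross-validation folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return An `"svm_config"` list.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, 2), gamma_grid = 2^seq(-15, 3, 2),
                       folds = 10, seed = 1) {
  check_numeric_vector(C_grid, "C_grid")
  check_numeric_vector(gamma_grid, "gamma_grid")
  check_scalar(folds, "folds", lower = 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "svm_config")
}

# Seeded stratified fold assignment: within each class, instances are
# shuffled and dealt to folds cyclically.
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  counts <- table(labels)
  small <- names(counts)[counts < folds]
  if (length(small))
    stop_input("class(es) with fewer than %d instances: %s", folds,
               paste(small, collapse = ", "))
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
    }
  })
  assign
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return Integer counts matrix (rows = true, columns = predicted) over the
#'   union of observed labels, with the row-normalized matrix attached as
#'   attribute `"normalized"`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop_input("label lengths differ: %d vs %d",
               length(true_labels), length(predicted_labels))
  lev <- sort(unique(c(as.character(true_labels), as.character(predicted_labels))))
  cm <- table(factor(as.character(true_labels), lev),
              factor(as.character(predicted_labels), lev))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  rs <- rowSums(cm)
  attr(cm, "normalized") <- cm / ifelse(rs > 0, rs, 1)
  cm
}

#' Grid-search cross-validation for the RBF-kernel SVM
#'
#' For every `(C, gamma)` pair on the grid, runs seeded stratified k-fold
#' cross-validation (features min-max scaled to `[-1, 1]` on each training
#' split only) and retains the pair with the highest pooled accuracy. Ties
#' resolve to the earlier grid point (C-major order).
#'
#' @param x numeric feature matrix (rows = instances) or data frame.
#' @param labels class label per row.
#' @param config an [svm_config()].
#' @return An object of class `"emotion_cv"`: `fold_accuracy` (per-fold
#'   accuracies at the best pair), `mean_accuracy`, `max_accuracy`, `best_C`,
#'   `best_gamma`, `confusion` (pooled over folds), `folds` (assignment),
#'   `grid` (accuracy per grid pair), `config`.
#' @export
grid_search_cv <- function(x, labels, config = svm_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(as.character(labels))
  if (nrow(x) != length(labels))
    stop_input("%d rows but %d labels", nrow(x), length(labels))
  if (anyNA(x)) stop_input("feature matrix contains NA")
  fold_of <- stratified_folds(labels, config$folds, config$seed)
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), ]
  # precompute per-fold scaled splits once; reused across the whole grid
  splits <- lapply(seq_len(config$folds), function(k) {
    tr <- fold_of != k
    sc <- scale_features(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    list(xtr = sc$train, ytr = labels[tr], xte = sc$applied, yte = labels[!tr])
  })
  best <- NULL
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    preds <- true <- character(0)
    fold_acc <- numeric(config$folds)
    for (k in seq_len(config$folds)) {
      sp <- splits[[k]]
      fit <- e1071::svm(sp$xtr, sp$ytr, kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g], scale = FALSE)
      p <- as.character(stats::predict(fit, sp$xte))
      fold_acc[k] <- mean(p == as.character(sp$yte))
      preds <- c(preds, p); true <- c(true, as.character(sp$yte))
    }
    acc <- mean(preds == true)
    grid$accuracy[g] <- acc
    if (is.null(best) || acc > best$accuracy + 1e-12) {
      best <- list(accuracy = acc, C = grid$C[g], gamma = grid$gamma[g],
                   fold_acc = fold_acc, preds = preds, true = true)
    }
  }
  structure(list(fold_accuracy = best$fold_acc,
                 mean_accuracy = mean(best$fold_acc),
                 max_accuracy = max(best$fold_acc),
                 accuracy = best$accuracy,
                 best_C = best$C, best_gamma = best$gamma,
                 confusion = confusion_matrix(best$true, best$preds),
                 folds = fold_of, grid = grid, config = config,
                 n = nrow(x), classes = levels(labels)),
            class = "emotion_cv")
}

#' @export
print.emotion_cv <- function(x, ...) {
  cat(sprintf("<emotion_cv> %d instances, %d classes, %d-fold CV\n",
              x$n, length(x$classes), x$config$folds))
  cat(sprintf("  best C = 2^%g, gamma = 2^%g\n", log2(x$best_C), log2(x$best_gamma)))
  cat(sprintf("  accuracy: mean %.4f, max fold %.4f\n",
              x$mean_accuracy, x$max_accuracy))
  invisible(x)
}

#' Fit an emotion SVM classifier
#'
#' The front end of the classification harness: selects `(C, gamma)` by
#' [grid_search_cv()], then fits a final RBF-kernel SVM on all instances with
#' the selected pair (features min-max scaled to `[-1, 1]`).
#'
#' @param x numeric feature matrix or data frame (rows = instances).
#' @param labels class label per row.
#' @param config an [svm_config()].
#' @return An object of class `"emotion_svm"` with `print`, `summary`,
#'   `predict` and `plot` methods; `$cv` holds the [grid_search_cv()] result.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 4), 30))
#' y <- rep(c("calm", "tense"), each = 30)
#' fit <- emotion_svm(x, y, svm_config(C_grid = c(1, 8), gamma_grid = c(0.1, 1),
#'                                     folds = 5))
#' predict(fit, x[1:3, ])
#' @export
emotion_svm <- function(x, labels, config = svm_config()) {
  x <- as.matrix(x)
  cv <- grid_search_cv(x, labels, config)
  sc <- scale_features(x)
  fit <- e1071::svm(sc$train, as.factor(as.character(labels)), kernel = "radial",
                    cost = cv$best_C, gamma = cv$best_gamma, scale = FALSE)
  structure(list(cv = cv, svm = fit, scaling = sc$params,
                 feature_names = colnames(x)),
            class = "emotion_svm")
}

#' @export
print.emotion_svm <- function(x, ...) {
  cat("<emotion_svm> RBF-kernel SVM\n")
  print(x$cv)
  invisible(x)
}

#' @export
summary.emotion_svm <- function(object, ...) {
  cat("Emotion SVM (RBF kernel)\n")
  print(object$cv)
  cat("  per-fold accuracy:",
      paste(sprintf("%.3f", object$cv$fold_accuracy), collapse = " "), "\n")
  cat("  confusion matrix (pooled over CV folds):\n")
  print(object$cv$confusion)
  invisible(object)
}

#' @export
predict.emotion_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  lo <- object$scaling$min; hi <- object$scaling$max
  rng <- hi - lo
  sc <- sweep(sweep(newdata, 2, lo), 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  sc[, rng == 0] <- 0
  stats::predict(object$svm, sc, ...)
}

#' @export
plot.emotion_svm <- function(x, ...) {
  cm <- attr(x$cv$confusion, "normalized")
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "CV confusion (row-normalized)", ...)
  graphics::axis(1, seq_len(n), colnames(cm), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(cm)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Rank channels by single-channel accuracy
#'
#' Orders channels by descending accuracy; ties resolve to the channel that
#' appears first in the input (ascending channel index).
#'
#' @param acc_channel named numeric vector of per-channel accuracies.
#' @return A `"channel_ranking"` data frame with columns `channel`,
#'   `accuracy`, `rank`.
#' @export
rank_channels <- function(acc_channel) {
  if (!length(acc_channel)) stop_input("'acc_channel' is empty")
  if (is.null(names(acc_channel))) stop_input("'acc_channel' must be named")
  ord <- order(-acc_channel, seq_along(acc_channel))
  structure(data.frame(channel = names(acc_channel)[ord],
                       accuracy = as.numeric(acc_channel[ord]),
                       rank = seq_along(ord), stringsAsFactors = FALSE),
            class = c("channel_ranking", "data.frame"))
}

# Channel of a "<channel>_<band>" feature column name.
feature_channel <- function(feature_names) {
  sub("_[^_]+$", "", feature_names)
}

#' Per-channel cross-validation accuracies of an EEG feature table
#'
#' Runs [grid_search_cv()] on the feature columns of each channel alone.
#'
#' @param features data frame from [eeg_feature_table()] (columns
#'   `<channel>_<band>`, plus `trial_id`/`label`).
#' @param labels class labels (defaults to the table's `label` column).
#' @param config an [svm_config()]; a reduced grid is usually enough here.
#' @return Named numeric vector of accuracies, one per channel, in the
#'   table's channel order.
#' @export
channel_accuracies <- function(features, labels = features$label,
                               config = svm_config()) {
  x <- feature_matrix(features)
  chans <- unique(feature_channel(colnames(x)))
  vapply(chans, function(ch) {
    cols <- feature_channel(colnames(x)) == ch
    grid_search_cv(x[, cols, drop = FALSE], labels, config)$accuracy
  }, numeric(1))
}

#' Cross-validated accuracy using only the top-k ranked channels
#'
#' For each `k`, restricts the feature table to the features of the `k`
#' best-ranked channels and reruns [grid_search_cv()].
#'
#' @param features data frame from [eeg_feature_table()].
#' @param ranking a [rank_channels()] result.
#' @param ks integer vector of channel-subset sizes.
#' @param labels class labels (defaults to the table's `label` column).
#' @param config an [svm_config()].
#' @return Named list mapping `k` to its `"emotion_cv"` result.
#' @export
evaluate_topk_channels <- function(features, ranking, ks,
                                   labels = features$label,
                                   config = svm_config()) {
  if (!inherits(ranking, "channel_ranking")) stop_input("'ranking' must be a channel_ranking")
  x <- feature_matrix(features)
  n_ch <- length(unique(feature_channel(colnames(x))))
  if (any(ks < 1 | ks > n_ch))
    stop_input("ks must lie in [1, %d]", n_ch)
  out <- lapply(ks, function(k) {
    keep <- feature_channel(colnames(x)) %in% ranking$channel[seq_len(k)]
    grid_search_cv(x[, keep, drop = FALSE], labels, config)
  })
  names(out) <- as.character(ks)
  out
}

# Strip id/label columns from a feature table.
feature_matrix <- function(features) {
  drop <- intersect(c("trial_id", "source_id", "clip_index", "label"),
                    colnames(features))
  as.matrix(features[, setdiff(colnames(features), drop), drop = FALSE])
}
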