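# Feature scaling, grid-search CV, confusion matrices, channel ranking and
# top-k channel selection.

two_gaussians <- function(n_per, sep, dim = 2, seed = 1) {
  x <- with_test_seed(seed, rbind(matrix(rnorm(n_per * dim), n_per),
                                  matrix(rnorm(n_per * dim, mean = sep), n_per)))
  colnames(x) <- paste0("f", seq_len(dim))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

small_grid <- function(folds = 10, seed = 1)
  svm_config(C_grid = 2^seq(-3, 7, 2), gamma_grid = 2^seq(-7, 1, 2),
             folds = folds, seed = seed)

test_that("min-max scaling maps train to [-1, 1] and constants to 0", {
  tr <- cbind(a = c(2, 4), b = c(5, 5))
  sc <- scale_features(tr)
  expect_identical(sc$train[, "a"], c(-1, 1))
  expect_identical(sc$train[, "b"], c(0, 0))
  # applying train parameters to the training table reproduces the fit output
  sc2 <- scale_features(tr, tr)
  expect_identical(sc2$applied, sc2$train)
  bad <- tr; colnames(bad) <- c("a", "c")
  expect_error(scale_features(tr, bad), "feature names")
})

test_that("grid search separates well-separated classes and not permuted ones", {
  d <- two_gaussians(50, sep = 10, seed = 701)
  cv <- grid_search_cv(d$x, d$y, small_grid())
  expect_equal(cv$accuracy, 1.0)
  expect_true(cv$best_C %in% small_grid()$C_grid)
  expect_true(cv$best_gamma %in% small_grid()$gamma_grid)
  yperm <- with_test_seed(702, sample(d$y))
  cvp <- grid_search_cv(d$x, yperm, small_grid())
  # chance-level performance: within the 95% binomial band around 0.5
  expect_lt(abs(cvp$accuracy - 0.5), 1.96 * sqrt(0.25 / 100) + 0.05)
  few <- c(1:6, 51:56)
  expect_error(grid_search_cv(d$x[few, ], d$y[few], small_grid()),
               "fewer than 10")
})

test_that("cross-validation is a seeded partition and reproducible", {
  d <- two_gaussians(30, sep = 3, seed = 703)
  cfg <- small_grid(folds = 5, seed = 9)
  cv1 <- grid_search_cv(d$x, d$y, cfg)
  cv2 <- grid_search_cv(d$x, d$y, cfg)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$fold_accuracy, cv2$fold_accuracy, tolerance = 1e-12)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_identical(sort(unique(cv1$folds)), 1:5)
  expect_length(cv1$folds, 60)
  # accuracy identity: trace over total
  expect_equal(cv1$accuracy, sum(diag(cv1$confusion)) / sum(cv1$confusion))
})

test_that("confusion matrix matches a tally-loop oracle", {
  true <- with_test_seed(704, sample(letters[1:4], 200, replace = TRUE))
  pred <- with_test_seed(705, sample(letters[1:4], 200, replace = TRUE))
  cm <- confusion_matrix(true, pred)
  oracle <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  for (i in seq_along(true)) oracle[true[i], pred[i]] <- oracle[true[i], pred[i]] + 1L
  expect_identical(unname(unclass(cm))[1:4, 1:4], unname(oracle))
  expect_identical(sum(cm), 200L)
  perfect <- confusion_matrix(true, true)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  onecol <- confusion_matrix(true, rep("a", 200))
  expect_true(all(onecol[, setdiff(letters[1:4], "a")] == 0))
  expect_error(confusion_matrix(true, pred[-1]), "lengths differ")
})

test_that("channel ranking sorts by accuracy with index tie-breaks", {
  rk <- rank_channels(c(ch1 = 0.5, ch2 = 0.9, ch3 = 0.7))
  expect_identical(rk$channel, c("ch2", "ch3", "ch1"))
  tie <- rank_channels(c(ch1 = 0.8, ch2 = 0.8))
  expect_identical(tie$channel, c("ch1", "ch2"))
  acc <- with_test_seed(706, stats::setNames(runif(16), paste0("c", 1:16)))
  rk2 <- rank_channels(acc)
  # selection-sort oracle with the same tie rule
  nm <- names(acc); vals <- unname(acc); order_oracle <- character(0)
  while (length(vals)) {
    i <- which.max(vals)
    order_oracle <- c(order_oracle, nm[i])
    nm <- nm[-i]; vals <- vals[-i]
  }
  expect_identical(rk2$channel, order_oracle)
  expect_error(rank_channels(numeric(0)), "empty")
})

test_that("informative channels rank on top and drive top-k accuracy", {
  # 3 channels carry the class signal; 5 are pure noise
  amp <- matrix(1, 2, 4); amp[1, 2] <- 4; amp[2, 4] <- 4
  spec <- eeg_sim_spec(n_classes = 2, trials_per_class = 15, n_channels = 8,
                       duration_s = 5, band_amplitudes = amp,
                       informative_channels = c(2, 5, 7), noise_sigma = 1,
                       seed = 71)
  sim <- simulate_eeg(spec)
  tbl <- eeg_feature_table(sim$recordings, sim$labels, denoise = FALSE)
  cfg <- small_grid(folds = 5, seed = 3)
  acc <- channel_accuracies(tbl, config = cfg)
  rk <- rank_channels(acc)
  expect_setequal(rk$channel[1:3], paste0("ch", c(2, 5, 7)))
  res <- evaluate_topk_channels(tbl, rk, ks = c(1, 3, 8), config = cfg)
  expect_named(res, c("1", "3", "8"))
  expect_gte(res[["3"]]$accuracy, res[["1"]]$accuracy - 0.02)
  # k = n_channels reproduces the full-table grid search exactly
  expect_equal(res[["8"]]$accuracy,
               grid_search_cv(emomap:::feature_matrix(tbl), tbl$label, cfg)$accuracy)
})

test_that("the fitted emotion SVM predicts and summarizes", {
  d <- two_gaussians(25, sep = 8, seed = 707)
  fit <- emotion_svm(d$x, d$y, small_grid(folds = 5))
  expect_s3_class(fit, "emotion_svm")
  pred <- predict(fit, d$x)
  expect_gte(mean(as.character(pred) == d$y), 0.98)
  out <- capture.output(print(fit))
  expect_true(any(grepl("emotion_cv", out)))
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
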