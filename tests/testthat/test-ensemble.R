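toy_fm <- function(n, p = 4, shift = 2, seed = 1) {
  y <- rep(c(1L, 0L), each = n / 2)
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  x[y == 1L, 1:2] <- x[y == 1L, 1:2] + shift
  colnames(x) <- paste0("f", seq_len(p))
  fm <- data.frame(id = sprintf("r%04d", seq_len(n)), label = y, x,
                   check.names = FALSE)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

test_that("the 85:15 split has exact sizes, is seeded and partitions the input", {
  fm <- toy_fm(2380)
  sp <- split_train_validation(fm, ensemble_config(seed = 40))
  expect_equal(nrow(sp$train), 2023L)
  expect_equal(nrow(sp$validation), 357L)
  expect_setequal(c(sp$train$id, sp$validation$id), fm$id)
  expect_length(intersect(sp$train$id, sp$validation$id), 0L)
  sp2 <- split_train_validation(fm, ensemble_config(seed = 40))
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- split_train_validation(fm, ensemble_config(seed = 41))
  expect_false(identical(sp$train$id, sp3$train$id))
})

test_that("metrics match hand arithmetic and the confusion oracle", {
  # TP=90 FP=10 FN=10 TN=90
  pred <- data.frame(probability = c(rep(0.9, 100), rep(0.1, 100)),
                     class = rep(c(1L, 0L), each = 100))
  truth <- c(rep(1L, 90), rep(0L, 10), rep(1L, 10), rep(0L, 90))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$accuracy, 0.9)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(90, 10, 10, 90))

  # random prediction/truth pairs against the brute-force oracle
  withr::with_seed(55, {
    for (r in 1:100) {
      n <- sample(10:60, 1)
      prob <- runif(n)
      truth <- sample(0:1, n, replace = TRUE)
      pred <- data.frame(probability = prob, class = as.integer(prob >= 0.5))
      m <- evaluate_predictions(pred, truth)
      cf <- oracle_confusion(pred$class, truth)
      expect_equal(c(m$tp, m$fp, m$fn, m$tn), unname(cf))
      expect_equal(m$accuracy, (cf["tp"] + cf["tn"]) / n,
                   ignore_attr = TRUE)
    }
  })
})

test_that("ROC AUC is the rank statistic: 1 for perfect ranking, 0.5 at chance", {
  truth <- rep(c(1L, 0L), each = 50)
  prob <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  pred <- data.frame(probability = prob, class = as.integer(prob >= 0.5))
  expect_equal(evaluate_predictions(pred, truth)$roc_auc, 1.0)

  withr::with_seed(60, {
    prob <- runif(2000)
    truth <- sample(0:1, 2000, replace = TRUE)
  })
  pred <- data.frame(probability = prob, class = as.integer(prob >= 0.5))
  expect_equal(evaluate_predictions(pred, truth)$roc_auc, 0.5,
               tolerance = 0.06)
  # cross-check against an independent AUC implementation
  auc_ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                            direction = "<")))
  expect_equal(evaluate_predictions(pred, truth)$roc_auc, auc_ref,
               tolerance = 1e-12)
  expect_warning(
    m <- evaluate_predictions(pred[truth == 1, ], truth[truth == 1]),
    "single-class")
  expect_true(is.na(m$roc_auc))
})

test_that("the stacked ensemble separates a shifted-class problem and is seeded", {
  fm <- toy_fm(300, shift = 2.5)
  sp <- split_train_validation(fm, ensemble_config(seed = 40))
  model <- train_stack(sp$train, ensemble_config(seed = 40))
  pred <- predict(model, sp$validation)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_true(all(pred$class %in% c(0L, 1L)))
  m <- evaluate_predictions(pred, sp$validation$label)
  expect_gte(m$precision, 0.9)
  # higher mean probability for the positive class
  expect_gt(mean(pred$probability[sp$validation$label == 1]),
            mean(pred$probability[sp$validation$label == 0]))
  # seeded rerun: identical predictions on a fixed probe set
  model2 <- train_stack(sp$train, ensemble_config(seed = 40))
  expect_identical(predict(model2, sp$validation), pred)
  # duplicated row gives identical output
  probe <- sp$validation[c(1, 1), , drop = FALSE]
  p2 <- predict(model, probe)
  expect_identical(p2[1, ], p2[2, ], ignore_attr = TRUE)
  expect_error(train_stack(sp$train[sp$train$label == 1, , drop = FALSE]),
               "both classes")
})

test_that("prediction refuses feature manifests that do not match training", {
  fm <- toy_fm(100)
  model <- train_stack(fm, ensemble_config(seed = 40, stack_folds = 3))
  x <- as.matrix(fm[, c("f1", "f2", "f3")])
  expect_error(predict(model, x), "missing.*f4")
  x5 <- cbind(as.matrix(fm[, paste0("f", 1:4)]), f5 = 1)
  expect_error(predict(model, x5), "extra.*f5")
})

test_that("soft-voting ablation averages the base probabilities", {
  fm <- toy_fm(100)
  model <- train_stack(fm, ensemble_config(seed = 40, combine = "vote",
                                           stack_folds = 3))
  expect_null(model$meta)
  pred <- predict(model, fm)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
})

test_that("grid search returns grid members and prefers the better point", {
  fm <- toy_fm(160, shift = 2.5)
  cfg <- ensemble_config(seed = 40, cv_folds = 5, xgb_nrounds = 30)
  # one-point grid returns that point
  out <- grid_search(fm, list(knn = data.frame(k = 7)), cfg)
  expect_equal(out$knn_k, 7L)
  # the sensible neighbor count beats a degenerate k = n variant
  out <- grid_search(fm, list(knn = data.frame(k = c(5, 159))), cfg)
  expect_equal(out$knn_k, 5L)
  scores <- attr(out, "grid_scores")$knn
  expect_equal(nrow(scores), 2L)
  expect_true(all(c("precision", "accuracy") %in% names(scores)))
  # forest grid: winner is a member of the grid
  out <- grid_search(fm, list(forest = data.frame(ntree = c(10, 20))), cfg)
  expect_true(out$rf_ntree %in% c(10L, 20L))
  expect_error(grid_search(toy_fm(12), list(knn = data.frame(k = 3)),
                           ensemble_config(cv_folds = 10)), "cv_folds")
})

test_that("kNN probabilities use inverse-distance weighting with exact-match override", {
  x <- matrix(c(0, 0, 1, 1, 4, 4), 3, 2, byrow = TRUE)
  y <- c(1, 0, 0)
  m <- pepstack:::fit_knn(x, y, k = 3)
  # query equals training point 1: zero-distance override gives its label
  expect_equal(pepstack:::predict_knn(m, matrix(c(0, 0), 1, 2)), 1)
  # manhattan distances from (2,2): d = c(4, 2, 4); weights 1/d
  w <- 1 / c(4, 2, 4)
  expect_equal(pepstack:::predict_knn(m, matrix(c(2, 2), 1, 2)),
               sum(w * y) / sum(w))
})
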