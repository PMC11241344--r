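# Stacked three-model ensemble: k-nearest neighbors (manhattan metric,
# inverse-distance weights), gradient-boosted trees, and a random forest,
# combined by an L2-regularized logistic meta-learner fit on out-of-fold
# base probabilities.

#' Ensemble configuration
#'
#' Hyperparameters of the three base learners, the train/validation split
#' and the cross-validation setup. Defaults are the tuned operating point of
#' the prediction pipeline: kNN with 18 neighbors, manhattan metric and
#' inverse-distance weighting; gradient boosting with 250 rounds, maximum
#' depth 8 and learning rate 0.0567; a 20-tree random forest with
#' log2-of-feature-count feature subsampling and Gini splits; an 85:15
#' shuffled split with seed 40; ten-fold cross-validation.
#'
#' @param knn_k Neighbor count.
#' @param xgb_nrounds,xgb_max_depth,xgb_eta Boosting rounds, tree depth,
#'   learning rate.
#' @param rf_ntree Random-forest tree count.
#' @param train_fraction Fraction of rows assigned to training (default
#'   0.85).
#' @param seed Global seed (default 40).
#' @param cv_folds Cross-validation folds for grid search (default 10).
#' @param stack_folds Internal folds for out-of-fold stacking (default 5).
#' @param combine `"stack"` (meta-learner, default) or `"vote"` (mean of
#'   base probabilities, for ablation).
#' @param threshold Decision threshold on the predicted probability.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(knn_k = 18L, xgb_nrounds = 250L,
                            xgb_max_depth = 8L, xgb_eta = 0.0567,
                            rf_ntree = 20L, train_fraction = 0.85,
                            seed = 40L, cv_folds = 10L, stack_folds = 5L,
                            combine = c("stack", "vote"), threshold = 0.5) {
  stopifnot(knn_k >= 1L, xgb_nrounds >= 1L, xgb_max_depth >= 1L,
            xgb_eta > 0, xgb_eta <= 1, rf_ntree >= 1L,
            train_fraction > 0, train_fraction < 1)
  structure(list(knn_k = as.integer(knn_k),
                 xgb_nrounds = as.integer(xgb_nrounds),
                 xgb_max_depth = as.integer(xgb_max_depth),
                 xgb_eta = xgb_eta,
                 rf_ntree = as.integer(rf_ntree),
                 train_fraction = train_fraction,
                 seed = as.integer(seed),
                 cv_folds = as.integer(cv_folds),
                 stack_folds = as.integer(stack_folds),
                 combine = match.arg(combine),
                 threshold = threshold),
            class = "ensemble_config")
}

#' Shuffled train/validation split
#'
#' Seeded shuffle, then the first `round(train_fraction * n)` rows go to
#' training and the remainder to validation (2380 rows at 0.85 give exactly
#' 2023 / 357). Class labels travel with their rows; a class missing from
#' either side triggers a warning, not an error.
#'
#' @param fm A labeled `feature_matrix`.
#' @param cfg An [ensemble_config()].
#' @return List with elements `train` and `validation`.
#' @export
split_train_validation <- function(fm, cfg = ensemble_config()) {
  n <- nrow(fm)
  perm <- withr::with_seed(cfg$seed, sample.int(n))
  n_train <- round(cfg$train_fraction * n)
  tr <- fm[perm[seq_len(n_train)], , drop = FALSE]
  va <- fm[perm[-seq_len(n_train)], , drop = FALSE]
  rownames(tr) <- rownames(va) <- NULL
  for (side in list(tr, va)) {
    if (length(unique(stats::na.omit(side$label))) < 2L) {
      warning("a class is absent from one side of the split (small n)")
      break
    }
  }
  class(tr) <- class(va) <- c("feature_matrix", "data.frame")
  list(train = tr, validation = va)
}

# --- k-nearest neighbors (manhattan, inverse-distance weights) -----------

fit_knn <- function(x, y, k) {
  structure(list(x = x, y = y, k = min(as.integer(k), nrow(x))),
            class = "knn_model")
}

predict_knn <- function(model, newx) {
  tx <- t(model$x)
  apply(newx, 1L, function(row) {
    d <- colSums(abs(tx - row))
    ord <- order(d, seq_along(d))          # deterministic tie-break by index
    nn <- ord[seq_len(model$k)]
    dn <- d[nn]
    if (any(dn == 0)) return(mean(model$y[nn[dn == 0]]))
    w <- 1 / dn
    sum(w * model$y[nn]) / sum(w)
  })
}

# --- base learners --------------------------------------------------------

fit_base_learners <- function(x, y, cfg, seed) {
  knn <- fit_knn(x, y, cfg$knn_k)
  xgb <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = cfg$xgb_max_depth, eta = cfg$xgb_eta,
                  nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
    nrounds = cfg$xgb_nrounds, verbose = 0)
  rf <- withr::with_seed(seed,
    randomForest::randomForest(
      x, factor(y, levels = c(0, 1)), ntree = cfg$rf_ntree,
      mtry = max(1L, floor(log2(ncol(x))))))
  list(knn = knn, xgb = xgb, rf = rf)
}

base_probabilities <- function(models, newx) {
  cbind(
    knn = predict_knn(models$knn, newx),
    xgb = as.numeric(stats::predict(models$xgb,
                                    xgboost::xgb.DMatrix(newx, nthread = 1L))),
    rf = stats::predict(models$rf, newx, type = "prob")[, "1"])
}

make_stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  foldid
}

#' Train the stacked ensemble
#'
#' Fits the three base learners and an L2-regularized logistic meta-learner.
#' The meta-learner is trained on out-of-fold base-learner probabilities
#' from a seeded, stratified internal split (`stack_folds`, default 5), so
#' it never sees in-sample base predictions; the base learners are then
#' refit on the full training set. With `combine = "vote"` the meta-learner
#' is skipped and prediction averages the three base probabilities.
#'
#' @param fm A labeled `feature_matrix` restricted to the selected features.
#' @param cfg An [ensemble_config()].
#' @return A `trained_ensemble` with the fitted learners, the feature-name
#'   manifest and the training seed.
#' @export
train_stack <- function(fm, cfg = ensemble_config()) {
  y <- fm$label
  if (anyNA(y) || length(unique(y)) < 2L) {
    stop("training requires both classes present and labeled", call. = FALSE)
  }
  cols <- feature_names(fm)
  x <- feature_values(fm, cols)
  meta <- NULL
  if (cfg$combine == "stack") {
    foldid <- make_stratified_folds(y, cfg$stack_folds, cfg$seed + 1L)
    z <- matrix(NA_real_, nrow(x), 3L,
                dimnames = list(NULL, c("knn", "xgb", "rf")))
    for (f in seq_len(cfg$stack_folds)) {
      inb <- foldid != f
      models <- fit_base_learners(x[inb, , drop = FALSE], y[inb], cfg,
                                  seed = cfg$seed + 10L + f)
      z[!inb, ] <- base_probabilities(models, x[!inb, , drop = FALSE])
    }
    meta <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                           lambda = 1 / length(y), standardize = FALSE)
  }
  base <- fit_base_learners(x, y, cfg, seed = cfg$seed)
  structure(list(base = base, meta = meta, manifest = cols, config = cfg,
                 seed = cfg$seed),
            class = "trained_ensemble")
}

check_manifest <- function(model, newdata) {
  if (inherits(newdata, "feature_matrix") || is.data.frame(newdata)) {
    have <- setdiff(names(newdata), c("id", "label"))
    missing <- setdiff(model$manifest, have)
    if (length(missing) > 0L) {
      stop("feature manifest mismatch; missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    as.matrix(newdata[, model$manifest, drop = FALSE])
  } else {
    x <- as.matrix(newdata)
    if (!identical(colnames(x), model$manifest)) {
      missing <- setdiff(model$manifest, colnames(x))
      extra <- setdiff(colnames(x), model$manifest)
      stop("feature manifest mismatch; missing: [",
           paste(missing, collapse = ", "), "]; extra: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    }
    x
  }
}

#' Predict with a trained ensemble
#'
#' @param object A `trained_ensemble`.
#' @param newdata A `feature_matrix` containing the manifest columns, or a
#'   numeric matrix whose columns exactly match the manifest.
#' @param ... Unused.
#' @return Data frame with columns `probability` (meta-learner output) and
#'   `class` (1 if probability >= threshold).
#' @export
predict.trained_ensemble <- function(object, newdata, ...) {
  x <- check_manifest(object, newdata)
  z <- base_probabilities(object$base, x)
  prob <- if (object$config$combine == "stack") {
    as.numeric(stats::predict(object$meta, z, type = "response"))
  } else {
    rowMeans(z)
  }
  data.frame(probability = prob,
             class = as.integer(prob >= object$config$threshold))
}

#' Classification metrics
#'
#' Confusion counts at the model threshold plus accuracy, precision,
#' recall, F1 and ROC AUC. The AUC is the rank statistic of the predicted
#' probabilities (midranks for ties); with single-class truth it is
#' undefined and reported as `NA` with a warning.
#'
#' @param pred Data frame with columns `probability` and `class` (as
#'   returned by [predict.trained_ensemble()]).
#' @param truth Binary 0/1 vector of true labels.
#' @return A `metrics_report` list.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(nrow(pred) == length(truth), all(truth %in% c(0L, 1L)))
  cl <- pred$class
  tp <- sum(cl == 1L & truth == 1L)
  fp <- sum(cl == 1L & truth == 0L)
  fn <- sum(cl == 0L & truth == 1L)
  tn <- sum(cl == 0L & truth == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("ROC AUC undefined for single-class truth")
    auc <- NA_real_
  } else {
    r <- rank(pred$probability)  # midranks for ties
    auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 roc_auc = auc, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f  precision %.4f  recall %.4f  ",
                     "f1 %.4f  roc_auc %.4f\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$roc_auc))
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# --- grid search ----------------------------------------------------------

cv_score_learner <- function(x, y, fit_fun, predict_fun, foldid,
                             threshold = 0.5) {
  k <- max(foldid)
  prec <- acc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    inb <- foldid != f
    m <- fit_fun(x[inb, , drop = FALSE], y[inb], f)
    p <- predict_fun(m, x[!inb, , drop = FALSE])
    cl <- as.integer(p >= threshold)
    yt <- y[!inb]
    tp <- sum(cl == 1L & yt == 1L)
    fp <- sum(cl == 1L & yt == 0L)
    if (tp + fp > 0L) prec[f] <- tp / (tp + fp)
    acc[f] <- mean(cl == yt)
  }
  c(precision = mean(prec, na.rm = TRUE), accuracy = mean(acc))
}

#' Grid search over base-learner hyperparameters
#'
#' Exhaustively evaluates each grid point for each base learner by seeded,
#' stratified k-fold cross-validation on the training set, and returns the
#' configuration maximizing mean fold precision (the fraction of predicted
#' positives that are true positives), ties broken by higher mean accuracy,
#' then by grid order. Folds in which no positive is predicted have
#' undefined precision and are dropped from the fold mean.
#'
#' @param fm A labeled training `feature_matrix`.
#' @param grids Named list with any of `knn` (data frame with column `k`),
#'   `boosting` (columns among `nrounds`, `max_depth`, `eta`) and `forest`
#'   (column `ntree`); each row is one grid point.
#' @param cfg An [ensemble_config()] supplying folds, seed and the
#'   non-searched parameters.
#' @return An updated `ensemble_config` with the winning hyperparameters,
#'   plus a `"grid_scores"` attribute holding per-point CV precision and
#'   accuracy.
#' @export
grid_search <- function(fm, grids, cfg = ensemble_config()) {
  y <- fm$label
  counts <- table(y)
  if (cfg$cv_folds > min(counts)) {
    stop("cv_folds exceeds the size of the smallest class; reduce folds ",
         "or supply more data", call. = FALSE)
  }
  x <- feature_values(fm)
  foldid <- make_stratified_folds(y, cfg$cv_folds, cfg$seed + 2L)
  scores <- list()
  pick <- function(tab) {
    ord <- order(-tab$precision, -tab$accuracy, seq_len(nrow(tab)))
    tab[ord[1L], , drop = FALSE]
  }
  out <- cfg
  if (!is.null(grids$knn)) {
    g <- grids$knn
    res <- t(vapply(seq_len(nrow(g)), function(i) {
      cv_score_learner(x, y,
        fit_fun = function(xt, yt, f) fit_knn(xt, yt, g$k[i]),
        predict_fun = predict_knn, foldid = foldid)
    }, numeric(2)))
    tab <- cbind(g, as.data.frame(res))
    scores$knn <- tab
    out$knn_k <- as.integer(pick(tab)$k)
  }
  if (!is.null(grids$boosting)) {
    g <- grids$boosting
    if (is.null(g$nrounds)) g$nrounds <- cfg$xgb_nrounds
    if (is.null(g$max_depth)) g$max_depth <- cfg$xgb_max_depth
    if (is.null(g$eta)) g$eta <- cfg$xgb_eta
    res <- t(vapply(seq_len(nrow(g)), function(i) {
      cv_score_learner(x, y,
        fit_fun = function(xt, yt, f) {
          xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = g$max_depth[i], eta = g$eta[i],
                          nthread = 1L, seed = cfg$seed + 100L + f),
            data = xgboost::xgb.DMatrix(xt, label = yt, nthread = 1L),
            nrounds = g$nrounds[i], verbose = 0)
        },
        predict_fun = function(m, xt) {
          as.numeric(stats::predict(m, xgboost::xgb.DMatrix(xt,
                                                            nthread = 1L)))
        },
        foldid = foldid)
    }, numeric(2)))
    tab <- cbind(g, as.data.frame(res))
    scores$boosting <- tab
    best <- pick(tab)
    out$xgb_nrounds <- as.integer(best$nrounds)
    out$xgb_max_depth <- as.integer(best$max_depth)
    out$xgb_eta <- best$eta
  }
  if (!is.null(grids$forest)) {
    g <- grids$forest
    res <- t(vapply(seq_len(nrow(g)), function(i) {
      cv_score_learner(x, y,
        fit_fun = function(xt, yt, f) {
          withr::with_seed(cfg$seed + 100L + f,
            randomForest::randomForest(
              xt, factor(yt, levels = c(0, 1)), ntree = g$ntree[i],
              mtry = max(1L, floor(log2(ncol(xt))))))
        },
        predict_fun = function(m, xt) {
          stats::predict(m, xt, type = "prob")[, "1"]
        },
        foldid = foldid)
    }, numeric(2)))
    tab <- cbind(g, as.data.frame(res))
    scores$forest <- tab
    out$rf_ntree <- as.integer(pick(tab)$ntree)
  }
  attr(out, "grid_scores") <- scores
  out
}
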