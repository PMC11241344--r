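# Two-stage feature reduction: correlation pruning followed by
# L1-regularized, cross-validated selection capped at 20 features.

#' Correlation pruning
#'
#' Drops zero-variance columns, then scans the remaining descriptor columns
#' in input order, keeping a column only if its absolute Pearson correlation
#' with every already-kept column is at or below `threshold` ("above 0.9"
#' excludes). Scan order and keep-first tie-breaking are fixed for
#' determinism.
#'
#' @param fm A `feature_matrix` from [featurize()].
#' @param threshold Absolute-correlation threshold in (0, 1]; default 0.9.
#' @return The pruned `feature_matrix` with a `"selection_report"` attribute
#'   listing kept columns, dropped columns and the partner that triggered
#'   each removal.
#' @export
correlation_prune <- function(fm, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(fm) < 2L) {
    stop("correlation undefined for fewer than 2 rows", call. = FALSE)
  }
  cols <- feature_names(fm)
  x <- feature_values(fm, cols)
  sds <- apply(x, 2L, stats::sd)
  zero_var <- cols[sds == 0]
  cols <- setdiff(cols, zero_var)
  x <- x[, cols, drop = FALSE]
  cm <- abs(suppressWarnings(stats::cor(x)))
  kept <- character(0)
  dropped <- character(0)
  partner <- character(0)
  for (cl in cols) {
    if (length(kept) > 0L && any(cm[cl, kept] > threshold)) {
      dropped <- c(dropped, cl)
      partner <- c(partner, kept[which(cm[cl, kept] > threshold)[1L]])
    } else {
      kept <- c(kept, cl)
    }
  }
  out <- fm[, c("id", "label", kept), drop = FALSE]
  class(out) <- c("feature_matrix", "data.frame")
  attr(out, "selection_report") <- list(
    kept = kept,
    dropped_zero_variance = zero_var,
    dropped_correlated = stats::setNames(partner, dropped),
    threshold = threshold)
  out
}

#' L1-regularized cross-validated feature selection
#'
#' Fits a least-squares lasso of the 0/1 label on the (internally
#' standardized) descriptor columns over a geometric penalty grid with
#' seeded k-fold cross-validation, and keeps the features with nonzero
#' coefficients at the chosen penalty. The penalty defaults to the largest
#' value within one cross-validation standard error of the minimum
#' (`rule = "1se"`, the usual parsimony rule for selection); `rule = "min"`
#' uses the CV-minimizing penalty instead. If more than `max_features`
#' survive, the `max_features` with largest absolute coefficient are kept.
#'
#' @param fm A `feature_matrix` (typically after [correlation_prune()]).
#' @param folds Number of cross-validation folds (default 10).
#' @param max_features Hard cap on the number of selected features
#'   (default 20).
#' @param rule `"1se"` (default) or `"min"`: which cross-validated penalty
#'   to select.
#' @param family `"gaussian"` (least-squares lasso on the 0/1 label, the
#'   default) or `"binomial"` (logistic lasso variant).
#' @param seed Integer seed for the fold assignment.
#' @return A `selection_report` list: `kept` (ordered as in the input),
#'   `l1_coefficients` (named, at the chosen penalty), `penalty`, `rule`,
#'   and `dropped_constant`.
#' @export
l1_select <- function(fm, folds = 10L, max_features = 20L, rule = c("1se", "min"),
                      family = c("gaussian", "binomial"), seed = 40L) {
  rule <- match.arg(rule)
  family <- match.arg(family)
  y <- fm$label
  if (anyNA(y) || length(unique(y)) < 2L) {
    stop("l1_select needs both classes present and labeled", call. = FALSE)
  }
  stopifnot(folds >= 2L)
  cols <- feature_names(fm)
  x <- feature_values(fm, cols)
  sds <- apply(x, 2L, stats::sd)
  constant <- cols[sds == 0]
  cols <- setdiff(cols, constant)
  x <- x[, cols, drop = FALSE]
  foldid <- withr::with_seed(seed,
    sample(rep(seq_len(folds), length.out = nrow(x))))
  cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                          standardize = TRUE)
  s <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- stats::coef(cv, s = s)[-1L, 1L]
  names(beta) <- cols
  nz <- beta[beta != 0]
  fallback <- FALSE
  if (length(nz) == 0L) {
    # degenerate signal-free input: the CV-chosen penalty zeroes everything;
    # fall back to the least-penalized end of the path so downstream stages
    # still receive a (noise) feature set of bounded size
    fallback <- TRUE
    beta <- stats::coef(cv, s = min(cv$lambda))[-1L, 1L]
    names(beta) <- cols
    nz <- beta[beta != 0]
  }
  if (length(nz) > max_features) {
    nz <- nz[order(-abs(nz))[seq_len(max_features)]]
  }
  kept <- cols[cols %in% names(nz)]  # restore input column order
  structure(list(kept = kept,
                 l1_coefficients = nz[kept],
                 penalty = s,
                 rule = rule,
                 family = family,
                 fallback = fallback,
                 dropped_constant = constant),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: %d features kept (penalty %.4g, %s rule)\n",
              length(x$kept), x$penalty, x$rule))
  print(round(x$l1_coefficients, 4))
  invisible(x)
}

#' Write/read a selected-feature list (one name per line)
#' @param report A `selection_report` from [l1_select()], or a character
#'   vector of feature names.
#' @param path Output path.
#' @export
write_feature_list <- function(report, path) {
  kept <- if (inherits(report, "selection_report")) report$kept else report
  writeLines(kept, path)
  invisible(path)
}
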