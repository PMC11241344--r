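# End-to-end training pipeline: curate -> redundancy-cluster -> featurize ->
# correlation-prune -> L1-select -> split -> (optional grid search) ->
# stack -> evaluate, with all artifacts written to an output directory.

#' Run the full training pipeline
#'
#' @param input A labeled [peptide_set()], or a path to a labeled TSV
#'   (columns id, sequence, label).
#' @param outdir Output directory (created if absent); `NULL` skips writing.
#' @param min_len,max_len Curation length window (default 5--61).
#' @param cluster_label Class label whose records are redundancy-clustered
#'   (default 0, the non-CPP class, mirroring the curation of heterogeneous
#'   negative sets); `NA` clusters all records; `NULL` skips clustering.
#' @param identity_cutoff Identity cutoff for clustering (default 0.45).
#' @param prune_threshold Correlation-pruning threshold (default 0.9).
#' @param max_features Cap on selected features (default 20).
#' @param grids Optional grid-search grids (see [grid_search()]); `NULL`
#'   trains at the configured hyperparameters.
#' @param cfg An [ensemble_config()].
#' @param ph pH for featurization.
#' @return (Invisibly) a list with `model`, `metrics`, `selection`,
#'   `split`, `curation_report` and `config`.
#' @export
run_pipeline <- function(input, outdir = NULL, min_len = 5L, max_len = 61L,
                         cluster_label = 0L, identity_cutoff = 0.45,
                         prune_threshold = 0.9, max_features = 20L,
                         grids = NULL, cfg = ensemble_config(), ph = 7.0) {
  ps <- if (is.character(input)) {
    if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
    read_labeled_tsv(input)
  } else input

  ps <- curate(ps, min_len, max_len)
  report <- attr(ps, "curation_report")

  if (!is.null(cluster_label)) {
    if (is.na(cluster_label)) {
      ps <- greedy_identity_cluster(ps, identity_cutoff)
    } else {
      target <- ps[ps$label %in% cluster_label, , drop = FALSE]
      rest <- ps[!(ps$label %in% cluster_label), , drop = FALSE]
      class(target) <- class(rest) <- c("peptide_set", "data.frame")
      clustered <- greedy_identity_cluster(target, identity_cutoff)
      ps <- rbind(rest, clustered)
      class(ps) <- c("peptide_set", "data.frame")
    }
  }

  fm <- featurize(ps, ph = ph)
  fm <- correlation_prune(fm, prune_threshold)
  prune_report <- attr(fm, "selection_report")
  sel <- l1_select(fm, folds = cfg$cv_folds, max_features = max_features,
                   seed = cfg$seed)
  fm_sel <- fm[, c("id", "label", sel$kept), drop = FALSE]
  class(fm_sel) <- c("feature_matrix", "data.frame")

  sp <- split_train_validation(fm_sel, cfg)
  if (!is.null(grids)) cfg <- grid_search(sp$train, grids, cfg)
  model <- train_stack(sp$train, cfg)
  pred <- stats::predict(model, sp$validation)
  metrics <- evaluate_predictions(pred, sp$validation$label)

  result <- list(model = model, metrics = metrics,
                 selection = sel, prune_report = prune_report,
                 split = sp, predictions = pred,
                 curation_report = report, config = cfg)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(fm_sel, file.path(outdir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_list(sel, file.path(outdir, "selected_features.txt"))
    jsonlite::write_json(
      list(kept = sel$kept,
           l1_coefficients = as.list(sel$l1_coefficients),
           penalty = sel$penalty,
           dropped_correlated = as.list(prune_report$dropped_correlated)),
      file.path(outdir, "selection.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(metrics),
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(
      cbind(sp$validation[, c("id", "label")], pred),
      file.path(outdir, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(model, file.path(outdir, "model.rds"))
    cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
    jsonlite::write_json(
      list(seed = cfg$seed,
           config = unclass(cfg),
           config_hash = unname(tools::md5sum(
             local({f <- tempfile(); writeLines(cfg_json, f); f}))),
           curation_report = report,
           n_selected_features = length(sel$kept),
           package_version = as.character(utils::packageVersion("pepstack")),
           r_version = R.version.string),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
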