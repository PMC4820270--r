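# Per-feature-group ablation: how well does each block of the
# representation predict on its own, versus all features combined.

#' Per-feature-group ablation report
#'
#' For each feature group (optionally intersected with a selected-feature
#' manifest) an SVM is optimized by grid search and scored by pooled
#' cross-validated accuracy (binary stages) or Q4 (the subtype stage); a
#' final row uses all features together. Groups contributing no features
#' are reported as not used.
#'
#' @param X Raw feature matrix.
#' @param y Stage labels.
#' @param folds Fold assignment from [make_folds()].
#' @param groups Named list of feature-name vectors; default
#'   [feature_groups()].
#' @param selected_features Optional manifest restricting every group.
#' @param C_grid,gamma_grid SVM grids for the per-group optimization.
#' @param seed Seed for the SVM fits.
#' @return Data frame with columns `group`, `n_features`, `value`
#'   (accuracy or Q4 in percent; `NA` when not used), `used`.
#' @export
ablation_report <- function(X, y, folds, groups = feature_groups(),
                            selected_features = NULL,
                            C_grid = 2^c(-1, 1, 3), gamma_grid = 2^c(-7, -4, -1),
                            seed = 1) {
  y <- factor(y)
  classes <- levels(y)
  score_set <- function(feats) {
    gs <- grid_search(X[, feats, drop = FALSE], y, folds, C_grid, gamma_grid,
                      seed = seed)
    cvr <- cross_validate(X[, feats, drop = FALSE], y, folds, gs$C, gs$gamma,
                          seed = seed, probability = FALSE)
    if (length(classes) == 2) {
      accuracy(confusion_counts(cvr$truth, cvr$pred, positive = classes[1]))
    } else {
      q4(confusion_matrix(as.character(cvr$truth), as.character(cvr$pred),
                          classes))
    }
  }
  rows <- lapply(names(groups), function(g) {
    feats <- intersect(groups[[g]], colnames(X))
    if (!is.null(selected_features)) feats <- intersect(feats, selected_features)
    if (length(feats) == 0)
      return(data.frame(group = g, n_features = 0, value = NA_real_,
                        used = FALSE))
    data.frame(group = g, n_features = length(feats),
               value = score_set(feats), used = TRUE)
  })
  all_feats <- if (is.null(selected_features)) colnames(X) else
    intersect(colnames(X), selected_features)
  rows[[length(rows) + 1]] <- data.frame(
    group = "all", n_features = length(all_feats),
    value = score_set(all_feats), used = TRUE)
  do.call(rbind, rows)
}
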