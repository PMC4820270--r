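# Five-step feature selection protocol:
#   1. stratified 5-fold split of the training data;
#   2. rank features by |point-biserial correlation| averaged over the five
#      training folds, drop those below a BCC cutoff;
#   3. greedy Pearson redundancy removal in rank order;
#   4. wrapper backward elimination scored by pooled cross-validated MCC;
#   5. RBF-SVM hyperparameter grid search.
# Steps 2-5 are swept over a (BCC cutoff x PCC cutoff) grid, with a
# PCA-based branch as the alternative to steps 2-4.

#' Selection protocol configuration
#'
#' @param bcc_cutoffs Minimum fold-averaged |BCC| cutoffs (step 2).
#' @param pcc_cutoffs Maximum pairwise |Pearson r| cutoffs (step 3).
#' @param pca_variance_cutoffs Cumulative explained-variance cutoffs for the
#'   PCA branch.
#' @param n_folds Number of cross-validation folds.
#' @param fold_seed Seed fixing the fold assignment.
#' @param C_grid,gamma_grid SVM hyperparameter grids (step 5).
#' @param include_pca Whether to evaluate the PCA branch.
#' @param wrapper_max_sweeps Safety cap on wrapper elimination sweeps.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(bcc_cutoffs = c(0.1, 0.15, 0.2, 0.25, 0.3),
                             pcc_cutoffs = c(0.7, 0.75, 0.8, 0.85, 0.9),
                             pca_variance_cutoffs = seq(0.1, 0.9, by = 0.1),
                             n_folds = 5, fold_seed = 1,
                             C_grid = 2^(-2:4), gamma_grid = 2^(-11:0),
                             include_pca = TRUE, wrapper_max_sweeps = 10) {
  stopifnot(all(bcc_cutoffs > 0 & bcc_cutoffs < 1),
            all(pcc_cutoffs > 0 & pcc_cutoffs < 1),
            all(pca_variance_cutoffs > 0 & pca_variance_cutoffs <= 1),
            n_folds >= 2)
  structure(list(bcc_cutoffs = bcc_cutoffs, pcc_cutoffs = pcc_cutoffs,
                 pca_variance_cutoffs = pca_variance_cutoffs,
                 n_folds = n_folds, fold_seed = fold_seed,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 include_pca = include_pca,
                 wrapper_max_sweeps = wrapper_max_sweeps),
            class = "selection_config")
}

#' Point-biserial correlation between a feature and binary labels
#'
#' Pearson correlation between the feature and a 0/1 encoding of the
#' labels. Constant features return 0.
#'
#' @param x Numeric feature vector.
#' @param y Binary label vector (factor, character or 0/1).
#' @return Correlation in [-1, 1].
#' @export
biserial_correlation <- function(x, y) {
  y01 <- as.numeric(factor(y)) - 1
  if (length(unique(y01)) < 2) stop("both classes must be present")
  if (length(x) != length(y01)) stop("x and y lengths differ")
  if (stats::sd(x) == 0) return(0)
  stats::cor(x, y01)
}

.feature_bcc <- function(X, y) {
  # |BCC| per column; multiclass labels reduce by max over one-vs-rest
  y <- factor(y)
  if (nlevels(y) == 2) {
    y01 <- as.numeric(y) - 1
    s <- apply(X, 2, stats::sd)
    r <- suppressWarnings(abs(as.vector(stats::cor(X, y01))))
    r[s == 0] <- 0
    r
  } else {
    per <- sapply(levels(y), function(cl) {
      y01 <- as.numeric(y == cl)
      s <- apply(X, 2, stats::sd)
      r <- suppressWarnings(abs(as.vector(stats::cor(X, y01))))
      r[s == 0] <- 0
      r
    })
    apply(per, 1, max)
  }
}

#' Rank features by fold-averaged |BCC|
#'
#' For each cross-validation fold, |BCC| is computed on the training portion
#' (the other folds) of every feature; features are ranked by the average
#' over folds. Multiclass labels are reduced one-vs-rest, keeping the
#' maximum absolute correlation over classes.
#'
#' @param X Raw feature matrix.
#' @param y Label vector.
#' @param folds Fold assignment from [make_folds()].
#' @return Data frame `feature` / `avg_bcc`, sorted descending.
#' @export
fold_averaged_bcc <- function(X, y, folds) {
  X <- as.matrix(X); y <- factor(y)
  per_fold <- sapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("fold ", f, ": training portion misses a class")
    .feature_bcc(X[tr, , drop = FALSE], y[tr])
  })
  avg <- rowMeans(per_fold)
  ord <- order(-avg, colnames(X))
  data.frame(feature = colnames(X)[ord], avg_bcc = avg[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Drop features below a BCC cutoff
#'
#' @param ranked Data frame from [fold_averaged_bcc()].
#' @param cutoff Minimum average |BCC| to keep.
#' @return Filtered ranked data frame (possibly empty).
#' @export
filter_by_bcc <- function(ranked, cutoff) {
  ranked[ranked$avg_bcc >= cutoff, , drop = FALSE]
}

#' Greedy Pearson redundancy removal
#'
#' Walks the ranked list from the top; a feature is admitted iff its
#' absolute Pearson correlation with every already-admitted feature is
#' below `pcc_cutoff`.
#'
#' @param ranked Ranked (already BCC-filtered) data frame.
#' @param X Raw feature matrix over the full training set.
#' @param pcc_cutoff Maximum allowed |Pearson r|.
#' @return Character vector of admitted feature names, in rank order.
#' @export
remove_redundant <- function(ranked, X, pcc_cutoff) {
  feats <- ranked$feature
  if (length(feats) == 0) return(character(0))
  admitted <- feats[1]
  for (f in feats[-1]) {
    r <- suppressWarnings(abs(stats::cor(X[, f], X[, admitted, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r < pcc_cutoff)) admitted <- c(admitted, f)
  }
  admitted
}

#' Wrapper backward elimination
#'
#' Sweeps the current feature set weakest-first (ascending average BCC);
#' a feature is permanently removed iff the pooled cross-validated MCC
#' strictly increases without it. Sweeps repeat until a full pass removes
#' nothing (or the sweep cap is reached). The SVM parameters stay fixed
#' during elimination.
#'
#' @param features Feature names, ordered by descending rank.
#' @param X Raw feature matrix.
#' @param y Label vector.
#' @param folds Fold assignment.
#' @param C,gamma Fixed SVM parameters used for every evaluation.
#' @param seed Seed for the SVM fits.
#' @param max_sweeps Sweep cap.
#' @return List with `features` (survivors, rank order preserved) and `mcc`.
#' @export
wrapper_eliminate <- function(features, X, y, folds, C, gamma, seed = 1,
                              max_sweeps = 10) {
  if (length(features) == 0) stop("empty feature set")
  classes <- levels(factor(y))
  score <- function(fs) {
    cvr <- cross_validate(X[, fs, drop = FALSE], y, folds, C, gamma,
                          seed = seed, probability = FALSE)
    stage_mcc(cvr$truth, cvr$pred, classes)
  }
  current <- features
  best <- score(current)
  for (sweep in seq_len(max_sweeps)) {
    removed_any <- FALSE
    for (f in rev(current)) {       # weakest (lowest-ranked) first
      if (length(current) == 1) break
      trial <- setdiff(current, f)
      m <- score(trial)
      if (m > best) {
        current <- trial
        best <- m
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  list(features = current, mcc = best)
}

#' PCA-based feature construction and pruning
#'
#' Projects the min-max normalized training matrix onto the smallest set of
#' leading principal components whose cumulative explained variance reaches
#' `variance_cutoff`, then prunes components with the same one-at-a-time
#' removal rule as [wrapper_eliminate()] and finishes with an SVM grid
#' search.
#'
#' @param X Raw feature matrix.
#' @param y Label vector.
#' @param variance_cutoff Cumulative explained-variance fraction in (0, 1].
#' @param folds Fold assignment.
#' @param config A [selection_config()] (grids and sweep cap are used).
#' @param seed Seed for the SVM fits.
#' @return List with `components` (names), `rotation`, `norm`, `C`,
#'   `gamma`, `mcc`, `n_features`.
#' @export
pca_select <- function(X, y, variance_cutoff, folds,
                       config = selection_config(), seed = 1) {
  if (variance_cutoff <= 0 || variance_cutoff > 1)
    stop("variance cutoff must lie in (0, 1]")
  norm <- fit_normalizer(X)
  Xn <- apply_normalizer(X, norm)
  keep <- apply(Xn, 2, stats::sd) > 0
  pc <- stats::prcomp(Xn[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cumvar >= variance_cutoff - 1e-12)[1]
  if (is.na(m)) m <- length(pc$sdev)
  scores <- pc$x[, seq_len(m), drop = FALSE]
  rownames(scores) <- rownames(X)
  gs <- grid_search(scores, y, folds, config$C_grid, config$gamma_grid, seed = seed)
  we <- wrapper_eliminate(colnames(scores), scores, y, folds, gs$C, gs$gamma,
                          seed = seed, max_sweeps = config$wrapper_max_sweeps)
  kept <- scores[, we$features, drop = FALSE]
  gs2 <- grid_search(kept, y, folds, config$C_grid, config$gamma_grid, seed = seed)
  list(components = we$features,
       rotation = pc$rotation[, seq_len(m), drop = FALSE],
       center = pc$center, norm = norm, variance_cutoff = variance_cutoff,
       C = gs2$C, gamma = gs2$gamma, mcc = gs2$mcc,
       n_features = length(we$features))
}

#' Run the full selection grid
#'
#' Evaluates every (BCC cutoff x PCC cutoff) cell - filter, redundancy
#' removal, grid search, wrapper elimination, final re-search - plus the
#' PCA cells, and returns the winning configuration. Ties break to higher
#' MCC, then fewer features, then smaller C, then smaller gamma. Cells whose
#' feature set comes out empty are recorded as invalid and skipped.
#'
#' @param X Raw n x 878 feature matrix.
#' @param y Stage labels.
#' @param config A [selection_config()].
#' @param seed Seed for all SVM fits.
#' @return Object of class `selection_result`: `ranked`, `selected_features`,
#'   `svm_params` (C, gamma), `cv_mcc`, `grid_table`, `pca_table`, `folds`,
#'   `best_cell`.
#' @export
run_selection_grid <- function(X, y, config = selection_config(), seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  folds <- make_folds(y, config$n_folds, config$fold_seed)
  ranked <- fold_averaged_bcc(X, y, folds)
  cells <- expand.grid(bcc = config$bcc_cutoffs, pcc = config$pcc_cutoffs)
  rows <- list(); selections <- list()
  for (i in seq_len(nrow(cells))) {
    bcc <- cells$bcc[i]; pcc <- cells$pcc[i]
    kept <- filter_by_bcc(ranked, bcc)
    sel <- remove_redundant(kept, X, pcc)
    if (length(sel) == 0) {
      rows[[i]] <- data.frame(bcc_cutoff = bcc, pcc_cutoff = pcc,
                              mcc = NA_real_, C = NA_real_, gamma = NA_real_,
                              n_features = 0, valid = FALSE)
      next
    }
    gs <- grid_search(X[, sel, drop = FALSE], y, folds,
                      config$C_grid, config$gamma_grid, seed = seed)
    we <- wrapper_eliminate(sel, X, y, folds, gs$C, gs$gamma, seed = seed,
                            max_sweeps = config$wrapper_max_sweeps)
    gs2 <- grid_search(X[, we$features, drop = FALSE], y, folds,
                       config$C_grid, config$gamma_grid, seed = seed)
    rows[[i]] <- data.frame(bcc_cutoff = bcc, pcc_cutoff = pcc, mcc = gs2$mcc,
                            C = gs2$C, gamma = gs2$gamma,
                            n_features = length(we$features), valid = TRUE)
    selections[[i]] <- we$features
  }
  grid_table <- do.call(rbind, rows)
  pca_table <- NULL
  if (isTRUE(config$include_pca)) {
    pca_rows <- lapply(config$pca_variance_cutoffs, function(vc) {
      pr <- pca_select(X, y, vc, folds, config, seed = seed)
      data.frame(variance_cutoff = vc, mcc = pr$mcc, C = pr$C,
                 gamma = pr$gamma, n_features = pr$n_features)
    })
    pca_table <- do.call(rbind, pca_rows)
  }
  valid <- which(grid_table$valid)
  if (length(valid) == 0) stop("all selection cells are empty")
  ord <- valid[order(-grid_table$mcc[valid], grid_table$n_features[valid],
                     grid_table$C[valid], grid_table$gamma[valid])]
  best <- ord[1]
  structure(list(ranked = ranked,
                 selected_features = selections[[best]],
                 svm_params = c(C = grid_table$C[best],
                                gamma = grid_table$gamma[best]),
                 cv_mcc = grid_table$mcc[best],
                 grid_table = grid_table, pca_table = pca_table,
                 folds = folds, fold_seed = config$fold_seed,
                 best_cell = grid_table[best, c("bcc_cutoff", "pcc_cutoff")]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$selected_features), "features, MCC =",
      round(x$cv_mcc, 3), ", C =", x$svm_params[["C"]],
      ", gamma =", x$svm_params[["gamma"]], "\n")
  invisible(x)
}

#' Write a selection report as TSV
#'
#' Mirrors the grid layout: one row per (BCC, PCC) cell with MCC, SVM
#' parameters and feature count; the winning cell is flagged.
#'
#' @param result A `selection_result`.
#' @param path Output TSV path.
#' @param manifest_path Optional path for the selected-feature name list.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path, manifest_path = NULL) {
  tab <- result$grid_table
  tab$selected <- seq_len(nrow(tab)) == which(
    tab$valid & tab$mcc == result$cv_mcc &
      tab$n_features == length(result$selected_features))[1]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path))
    writeLines(result$selected_features, manifest_path)
  invisible(path)
}
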