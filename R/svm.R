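# RBF-kernel SVM engine built on the LIBSVM binding (e1071): Platt-calibrated
# probabilities for binary stages, pairwise-coupled probabilities and
# one-against-one decomposition (k(k-1)/2 binary machines) for the subtype
# stage. Feature scaling is never delegated to the SVM: inputs are expected
# to be min-max normalized into [-1, 1] already, with parameters fitted on
# training folds only.

#' Stratified cross-validation fold assignment
#'
#' @param y Label vector.
#' @param n_folds Number of folds (>= 2).
#' @param seed RNG seed fixing the assignment.
#' @return Integer vector of fold ids in `1:n_folds`, named after `y`'s
#'   names when present.
#' @export
make_folds <- function(y, n_folds = 5, seed = 1) {
  if (n_folds < 2) stop("need at least 2 folds")
  y <- as.factor(y)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  names(folds) <- names(y)
  folds
}

#' Train an RBF-kernel SVM with probability outputs
#'
#' @param X n x d numeric matrix, already normalized into [-1, 1].
#' @param y Label vector with at least two classes present.
#' @param C Regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param seed Seed fixing the internal probability-calibration shuffling.
#' @param probability Fit the Platt / pairwise-coupling probability model
#'   (default). Inner selection loops that only need hard labels may turn
#'   this off for speed.
#' @return Fitted `svm` object.
#' @export
svm_fit <- function(X, y, C, gamma, seed = 1, probability = TRUE) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("training labels contain a single class")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  set.seed(seed)
  e1071::svm(as.matrix(X), y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, probability = probability, scale = FALSE)
}

#' Predict labels and per-class probabilities
#'
#' The reported label is the argmax of the per-class probabilities (for
#' binary problems the Platt-calibrated pair; for multiclass the
#' pairwise-coupled distribution), so label and probabilities are always
#' consistent.
#'
#' @param model Fitted object from [svm_fit()].
#' @param X m x d matrix in the model's feature order.
#' @return List with `label` (factor) and `prob` (m x k matrix, rows
#'   summing to 1).
#' @export
svm_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$SV))
    stop("feature count ", ncol(X), " does not match model (", ncol(model$SV), ")")
  if (is.null(model$compprob) || !model$compprob) {
    lab <- predict(model, X)
    return(list(label = lab, prob = NULL))
  }
  p <- predict(model, X, probability = TRUE)
  prob <- attr(p, "probabilities")
  prob <- prob[, model$levels, drop = FALSE]
  lab <- factor(model$levels[max.col(prob, ties.method = "first")],
                levels = model$levels)
  list(label = lab, prob = prob)
}

#' Number of pairwise binary classifiers in a one-against-one model
#'
#' LIBSVM decomposes a k-class problem into k(k-1)/2 pairwise machines; this
#' reads the count off the fitted model.
#'
#' @param model Fitted object from [svm_fit()].
#' @return Integer count.
#' @export
n_pairwise_classifiers <- function(model) length(model$rho)

#' Cross-validated predictions with per-fold normalization
#'
#' Each fold's min-max normalizer is fitted on that fold's training portion
#' only, then applied to both portions; every record is predicted exactly
#' once. Returns pooled predictions plus the fold assignment so pooled and
#' per-fold metrics can both be derived.
#'
#' @param X n x d raw (un-normalized) feature matrix.
#' @param y Label vector.
#' @param folds Fold assignment from [make_folds()].
#' @param C,gamma SVM parameters.
#' @param seed Seed passed to each fold's [svm_fit()].
#' @param probability Fit probability models per fold (default); selection
#'   loops that only score hard labels may disable it.
#' @return List with `pred` (factor), `prob` (n x k matrix, or `NULL` when
#'   `probability = FALSE`), `truth`, `folds`.
#' @export
cross_validate <- function(X, y, folds, C, gamma, seed = 1, probability = TRUE) {
  X <- as.matrix(X); y <- factor(y)
  classes <- levels(y)
  n <- nrow(X)
  pred <- factor(rep(NA_character_, n), levels = classes)
  prob <- if (probability)
    matrix(NA_real_, n, length(classes), dimnames = list(rownames(X), classes))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- folds == f
    if (nlevels(droplevels(y[tr])) < 2)
      stop("fold ", f, ": training portion contains a single class")
    norm <- fit_normalizer(X[tr, , drop = FALSE])
    model <- svm_fit(apply_normalizer(X[tr, , drop = FALSE], norm), y[tr],
                     C, gamma, seed = seed, probability = probability)
    out <- svm_predict(model, apply_normalizer(X[te, , drop = FALSE], norm))
    pred[te] <- as.character(out$label)
    if (probability) prob[te, colnames(out$prob)] <- out$prob
  }
  list(pred = pred, prob = prob, truth = y, folds = folds)
}

#' Grid search over SVM hyperparameters
#'
#' Evaluates every (C, gamma) combination by pooled cross-validated MCC and
#' returns the argmax; ties break to the smaller C, then the smaller gamma,
#' so the result does not depend on evaluation order.
#'
#' @param X Raw feature matrix.
#' @param y Label vector.
#' @param folds Fold assignment.
#' @param C_grid Candidate C values; default 2^(-2..4).
#' @param gamma_grid Candidate gamma values; default 2^(-11..0).
#' @param seed Seed for each fit.
#' @return List with `C`, `gamma`, `mcc` and the full `table`
#'   (data frame C / gamma / mcc).
#' @export
grid_search <- function(X, y, folds, C_grid = 2^(-2:4),
                        gamma_grid = 2^(-11:0), seed = 1) {
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  classes <- levels(factor(y))
  grid$mcc <- vapply(seq_len(nrow(grid)), function(i) {
    cvr <- cross_validate(X, y, folds, grid$C[i], grid$gamma[i], seed = seed,
                          probability = FALSE)
    stage_mcc(cvr$truth, cvr$pred, classes)
  }, numeric(1))
  ord <- order(-grid$mcc, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(C = best$C, gamma = best$gamma, mcc = best$mcc, table = grid)
}

#' Jackknife (leave-one-out) predictions
#'
#' One model per held-out protein, trained on the remaining n - 1 with a
#' freshly fitted normalizer.
#'
#' @param X Raw feature matrix (n >= 3).
#' @param y Label vector.
#' @param C,gamma SVM parameters.
#' @param seed Seed for each fit.
#' @return List with `pred`, `prob`, `truth`.
#' @export
jackknife <- function(X, y, C, gamma, seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  n <- nrow(X)
  if (n < 3) stop("jackknife needs at least 3 records")
  classes <- levels(y)
  pred <- factor(rep(NA_character_, n), levels = classes)
  prob <- matrix(NA_real_, n, length(classes), dimnames = list(rownames(X), classes))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    norm <- fit_normalizer(X[tr, , drop = FALSE])
    model <- svm_fit(apply_normalizer(X[tr, , drop = FALSE], norm), y[tr],
                     C, gamma, seed = seed)
    out <- svm_predict(model, apply_normalizer(X[i, , drop = FALSE], norm))
    pred[i] <- as.character(out$label)
    prob[i, colnames(out$prob)] <- out$prob
  }
  list(pred = pred, prob = prob, truth = y)
}

#' Train a deployable stage model
#'
#' Fits the normalizer on the full training matrix restricted to the
#' selected features, then the SVM on the normalized data. The returned
#' bundle carries everything prediction needs.
#'
#' @param X Raw n x 878 training feature matrix.
#' @param y Stage labels.
#' @param stage Hierarchy stage (`"ION"`, `"VLG"`, `"VGS"`).
#' @param features Selected feature names (columns of `X`).
#' @param C,gamma SVM parameters.
#' @param seed Seed for the fit.
#' @return Object of class `ion_stage_model`.
#' @export
train_stage_model <- function(X, y, stage, features, C, gamma, seed = 1) {
  stage <- match.arg(stage, c("ION", "VLG", "VGS"))
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0)
    stop("features absent from matrix: ", paste(head(missing, 5), collapse = ", "))
  Xs <- X[, features, drop = FALSE]
  norm <- fit_normalizer(Xs)
  y <- factor(y, levels = intersect(stage_classes(stage), unique(as.character(y))))
  model <- svm_fit(apply_normalizer(Xs, norm), y, C, gamma, seed = seed)
  structure(list(stage = stage, features = features, norm = norm,
                 C = C, gamma = gamma, svm = model, classes = levels(y)),
            class = "ion_stage_model")
}

#' @export
print.ion_stage_model <- function(x, ...) {
  cat("<ion_stage_model>", x$stage, "-", length(x$features), "features, C =",
      x$C, ", gamma =", x$gamma, "\n")
  invisible(x)
}

#' Predict with a trained stage model
#'
#' @param object An `ion_stage_model`.
#' @param X Raw feature matrix (full 878 columns or at least the model's
#'   selected features).
#' @param ... Unused.
#' @return List with `label` and `prob` as in [svm_predict()].
#' @export
predict.ion_stage_model <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  Xs <- X[, object$features, drop = FALSE]
  svm_predict(object$svm, apply_normalizer(Xs, object$norm))
}

#' Persist / restore a stage model directory
#'
#' The directory holds the feature manifest and normalization parameters as
#' TSV plus the serialized classifier state.
#'
#' @param model An `ion_stage_model`.
#' @param dir Directory path (created if needed).
#' @return `dir` (save) or the restored model (load).
#' @export
save_stage_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(model$features, file.path(dir, "features.txt"))
  utils::write.table(
    data.frame(feature = model$features, min = model$norm$min,
               max = model$norm$max),
    file.path(dir, "normalization.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(key = c("stage", "C", "gamma"),
               value = c(model$stage, model$C, model$gamma)),
    file.path(dir, "config.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_stage_model
#' @export
load_stage_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
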