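# Hybrid predictor: per stage, the BLAST best-hit transfer wins whenever a
# qualifying hit exists, otherwise the SVM decides. The three stages chain
# into the hierarchy either in cascade mode (type prediction only for
# predicted channels, subtype only for predicted voltage-gated channels) or
# flat mode (all stages always run; the evaluation default).

#' Construct a stage prediction result
#'
#' @param id Protein id.
#' @param stage Hierarchy stage.
#' @param label Predicted class label (must belong to the stage's classes).
#' @param score Numeric confidence in (0, 1].
#' @param source `"SVM"` or `"BLAST"`.
#' @return List of class `prediction_result`.
#' @export
prediction_result <- function(id, stage, label, score, source) {
  stage <- match.arg(stage, c("ION", "VLG", "VGS"))
  if (!label %in% stage_classes(stage))
    stop("label '", label, "' invalid for stage ", stage)
  if (!source %in% c("SVM", "BLAST")) stop("source must be SVM or BLAST")
  if (score <= 0 || score > 1) stop("score must lie in (0, 1]")
  structure(list(id = id, stage = stage, label = label,
                 score = score, source = source),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction> %s [%s] %s (%.3f, %s)\n",
              x$id, x$stage, x$label, x$score, x$source))
  invisible(x)
}

#' Combine an SVM prediction with a BLAST transfer
#'
#' The BLAST result takes precedence whenever present; otherwise the SVM
#' result is returned unchanged. Provenance is preserved.
#'
#' @param svm_result A `prediction_result` from the SVM path.
#' @param blast_result A `prediction_result` from BLAST transfer, or `NULL`.
#' @return A `prediction_result`.
#' @export
combine_predictions <- function(svm_result, blast_result = NULL) {
  if (is.null(blast_result)) return(svm_result)
  if (blast_result$stage != svm_result$stage)
    stop("stage mismatch: ", svm_result$stage, " vs ", blast_result$stage)
  if (blast_result$id != svm_result$id)
    stop("id mismatch: ", svm_result$id, " vs ", blast_result$id)
  blast_result
}

#' Predict one stage for one protein
#'
#' Runs feature extraction, normalization and the stage SVM; if a hit table
#' and labelled database are supplied, best-hit transfer is attempted and
#' takes precedence. The SVM score is the coupled probability of the
#' winning class.
#'
#' @param record A [protein_record].
#' @param tracks Its per-residue tracks bundle.
#' @param model An `ion_stage_model`.
#' @param hits Optional BLAST tabular hit table (query rows for this
#'   protein are selected by id).
#' @param db_labels Optional named label vector for the hit database.
#' @param threshold E-value threshold for transfer (required with `hits`).
#' @param scales Property scales for feature extraction.
#' @return A `prediction_result`.
#' @export
predict_stage <- function(record, tracks, model, hits = NULL,
                          db_labels = NULL, threshold = NULL,
                          scales = default_property_scales()) {
  v <- extract_features(record, tracks, scales)
  out <- predict(model, v)
  lab <- as.character(out$label)
  svm_res <- prediction_result(record$id, model$stage, lab,
                               max(out$prob[1, ]), "SVM")
  blast_res <- NULL
  if (!is.null(hits)) {
    if (is.null(db_labels) || is.null(threshold))
      stop("hits require db_labels and threshold")
    blast_res <- transfer_annotation(record$id, hits, db_labels, threshold,
                                     stage = model$stage)
  }
  combine_predictions(svm_res, blast_res)
}

#' Predict the full hierarchy for one protein
#'
#' @param record A [protein_record].
#' @param tracks Its per-residue tracks bundle.
#' @param stages Named list with elements `ION`, `VLG`, `VGS`, each a list
#'   with components `model` and optionally `hits`, `db_labels`,
#'   `threshold`.
#' @param mode `"flat"` (default; all stages always run, matching per-stage
#'   evaluation) or `"cascade"` (type only for predicted channels, subtype
#'   only for predicted voltage-gated).
#' @param scales Property scales.
#' @return Named list of `prediction_result`s; in cascade mode gated stages
#'   are `NULL`.
#' @export
predict_hierarchy <- function(record, tracks, stages,
                              mode = c("flat", "cascade"),
                              scales = default_property_scales()) {
  mode <- match.arg(mode)
  run <- function(stg) {
    b <- stages[[stg]]
    predict_stage(record, tracks, b$model, hits = b$hits,
                  db_labels = b$db_labels, threshold = b$threshold,
                  scales = scales)
  }
  out <- list(ION = run("ION"), VLG = NULL, VGS = NULL)
  if (mode == "flat" || out$ION$label == "ion") out$VLG <- run("VLG")
  if (mode == "flat" || (!is.null(out$VLG) && out$VLG$label == "voltage"))
    out$VGS <- run("VGS")
  out
}

#' Cross-validated hybrid predictions
#'
#' Evaluates the combined SVM + BLAST predictor under the same fold
#' protocol used everywhere else: per fold, the SVM is trained on the
#' training portion (normalizer refitted) and the BLAST database is
#' restricted to the training portion; the BLAST label wins where a
#' qualifying hit exists.
#'
#' @param X Raw feature matrix with protein-id row names.
#' @param y Named stage labels.
#' @param folds Named fold assignment.
#' @param features Selected feature names.
#' @param C,gamma SVM parameters.
#' @param hits Optional all-vs-all BLAST hit table; `NULL` disables the
#'   BLAST path (pure SVM cross-validation).
#' @param threshold E-value threshold for transfer.
#' @param seed Seed for the SVM fits.
#' @return Data frame with columns `id`, `truth`, `pred`, `score`,
#'   `source`, `fold`.
#' @export
cross_validate_hybrid <- function(X, y, folds, features, C, gamma,
                                  hits = NULL, threshold = NULL, seed = 1) {
  ids <- rownames(X)
  y <- stats::setNames(as.character(y), ids)
  cvr <- cross_validate(X[, features, drop = FALSE], y, folds, C, gamma,
                        seed = seed)
  pred <- as.character(cvr$pred)
  score <- apply(cvr$prob, 1, max)
  source <- rep("SVM", length(ids))
  if (!is.null(hits)) {
    if (is.null(threshold)) stop("hits require a threshold")
    for (i in seq_along(ids)) {
      db <- ids[folds != folds[i]]
      r <- transfer_annotation(ids[i], hits, y, threshold, db_ids = db)
      if (!is.null(r)) {
        pred[i] <- r$label
        score[i] <- r$score
        source[i] <- "BLAST"
      }
    }
  }
  data.frame(id = ids, truth = unname(y), pred = pred, score = unname(score),
             source = source, fold = unname(folds), stringsAsFactors = FALSE)
}
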