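# Annotation transfer from the best BLAST hit against the labelled training
# set. Hits are consumed from precomputed 12-column tabular files (the
# outfmt-6 dialect), so the pipeline is testable without a BLAST binary.
# The similarity score reported for a transferred label is
#   score = threshold / (threshold + e-value)
# which is 1 at e-value 0, 0.5 at the threshold, and decreases with
# decreasing similarity. "Sufficiently similar" is e-value <= threshold
# (inclusive).

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Parse tabular BLAST output (12-column outfmt-6 dialect)
#'
#' @param path Path to the tabular file; an empty file yields zero hits.
#' @return Data frame with the standard 12 columns, in file order.
#' @export
parse_blast_tabular <- function(path) {
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(matrix(ncol = 12, nrow = 0)), BLAST_COLUMNS))
  hits <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", rep("numeric", 10))),
    error = function(e) stop("malformed BLAST tabular file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(hits) != 12)
    stop("expected 12 tab-separated columns in ", path, ", got ", ncol(hits))
  names(hits) <- BLAST_COLUMNS
  if (any(hits$evalue < 0)) stop("negative e-value in ", path)
  hits
}

#' Best qualifying hit for one query
#'
#' Among hits whose subject differs from `self_id` and whose e-value is at
#' most `threshold`: the smallest e-value wins; ties break to the larger bit
#' score, then to the lexicographically smaller subject id.
#'
#' @param hits Data frame of hits for one query (BLAST tabular columns).
#' @param threshold E-value cutoff (inclusive).
#' @param self_id Query's own id, excluded from the database.
#' @param db_ids Optional subject whitelist (e.g. the training-fold portion
#'   during tuning); hits to other subjects are ignored.
#' @return One-row data frame, or `NULL` when no hit qualifies.
#' @export
best_hit <- function(hits, threshold, self_id = NULL, db_ids = NULL) {
  ok <- hits$evalue <= threshold
  if (!is.null(self_id)) ok <- ok & hits$sseqid != self_id
  if (!is.null(db_ids)) ok <- ok & hits$sseqid %in% db_ids
  if (!any(ok)) return(NULL)
  h <- hits[ok, , drop = FALSE]
  h[order(h$evalue, -h$bitscore, h$sseqid)[1], , drop = FALSE]
}

#' Normalized BLAST similarity score
#'
#' threshold / (threshold + e-value): 1 at e-value 0, 0.5 at the threshold,
#' strictly decreasing in the e-value.
#'
#' @param e_value Hit e-value (>= 0).
#' @param threshold E-value threshold (> 0).
#' @return Score in (0, 1].
#' @export
blast_score <- function(e_value, threshold) {
  if (any(threshold <= 0)) stop("threshold must be positive")
  if (any(e_value < 0)) stop("e-value must be non-negative")
  threshold / (threshold + e_value)
}

#' Transfer an annotation from the best qualifying hit
#'
#' @param query_id Query protein id.
#' @param hits Hit table (all queries or just this one's rows).
#' @param labels Named character vector mapping database ids to labels.
#' @param threshold E-value cutoff.
#' @param stage Hierarchy stage recorded on the result; `NULL` (default)
#'   infers it from the transferred label's class vocabulary.
#' @param db_ids Optional subject whitelist.
#' @return A `prediction_result` (list with `id`, `stage`, `label`,
#'   `score`, `source = "BLAST"`), or `NULL` when no hit qualifies.
#' @export
transfer_annotation <- function(query_id, hits, labels, threshold,
                                stage = NULL, db_ids = NULL) {
  h <- best_hit(hits[hits$qseqid == query_id, , drop = FALSE],
                threshold, self_id = query_id, db_ids = db_ids)
  if (is.null(h)) return(NULL)
  if (!h$sseqid %in% names(labels))
    stop("subject ", h$sseqid, " has no label")
  label <- labels[[h$sseqid]]
  if (is.null(stage)) {
    stage <- c("ION", "VLG", "VGS")[vapply(c("ION", "VLG", "VGS"), function(s)
      label %in% stage_classes(s), logical(1))][1]
    if (is.na(stage)) stop("label '", label, "' belongs to no stage")
  }
  prediction_result(query_id, stage, label,
                    blast_score(h$evalue, threshold), "BLAST")
}

#' Tune the e-value threshold by cross-validated MCC
#'
#' For each candidate threshold, every training protein is predicted by
#' best-hit transfer with the searchable database restricted to its
#' training-fold portion (self-hits and same-fold subjects excluded).
#' Queries with no qualifying hit are counted as errors. The threshold with
#' the highest MCC wins; ties break to the more stringent (smaller) value.
#'
#' @param hits All-vs-all hit table over the training set.
#' @param labels Named label vector over all training ids.
#' @param folds Named fold assignment (same stratified folds as the SVM
#'   protocol).
#' @param grid Candidate thresholds, default 10^(-6..1).
#' @return List with `threshold` and `table` (threshold / mcc / coverage).
#' @export
tune_threshold <- function(hits, labels, folds, grid = 10^(-6:1)) {
  ids <- names(folds)
  if (is.null(ids)) stop("folds must be named by protein id")
  classes <- sort(unique(as.character(labels)))
  rows <- lapply(grid, function(th) {
    pred <- rep(NA_character_, length(ids))
    for (i in seq_along(ids)) {
      db <- ids[folds != folds[ids[i]]]
      r <- transfer_annotation(ids[i], hits, labels, th, db_ids = db)
      if (!is.null(r)) pred[i] <- r$label
    }
    truth <- as.character(labels[ids])
    covered <- !is.na(pred)
    # abstentions count as errors: substitute a class different from truth
    pred[!covered] <- vapply(truth[!covered],
                             function(t) setdiff(classes, t)[1], character(1))
    data.frame(threshold = th, mcc = stage_mcc(truth, pred, classes),
               coverage = mean(covered))
  })
  tab <- do.call(rbind, rows)
  best <- order(-tab$mcc, tab$threshold)[1]
  list(threshold = tab$threshold[best], table = tab)
}
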