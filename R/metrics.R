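# Evaluation statistics: confusion counts, accuracy, Matthews correlation,
# F-measure, Q4 multiclass accuracy, sensitivity / false positive rate,
# 50%-subsample confidence intervals, and error-rate reduction arithmetic.

#' Binary confusion counts
#'
#' @param truth,pred Vectors of class labels of equal length.
#' @param positive The label counted as positive.
#' @return List with integer components `TP`, `TN`, `FP`, `FN` and `N`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  list(TP = sum(truth == positive & pred == positive),
       TN = sum(truth != positive & pred != positive),
       FP = sum(truth != positive & pred == positive),
       FN = sum(truth == positive & pred != positive),
       N = length(truth))
}

#' Multiclass confusion matrix
#'
#' @param truth,pred Label vectors.
#' @param classes Class levels (row/column order).
#' @return k x k integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

#' Accuracy from binary confusion counts
#'
#' (TP + TN) / (TP + FP + TN + FN), reported as a percentage.
#'
#' @param counts List from [confusion_counts()].
#' @param percent If `TRUE` (default) return a percentage in [0, 100].
#' @return Numeric scalar.
#' @export
accuracy <- function(counts, percent = TRUE) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("empty confusion counts")
  a <- (counts$TP + counts$TN) / n
  if (percent) 100 * a else a
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); 0 when any
#' denominator factor is zero.
#'
#' @param counts List from [confusion_counts()].
#' @return Numeric scalar in [-1, 1].
#' @export
mcc <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' F-measure
#'
#' 2TP / (2TP + FN + FP), the harmonic mean of precision and recall; 0 when
#' the denominator is zero.
#'
#' @param counts List from [confusion_counts()].
#' @param percent If `TRUE` (default) return a percentage.
#' @return Numeric scalar.
#' @export
f_measure <- function(counts, percent = TRUE) {
  den <- 2 * counts$TP + counts$FN + counts$FP
  f <- if (den == 0) 0 else 2 * counts$TP / den
  if (percent) 100 * f else f
}

#' Q4 multiclass accuracy
#'
#' Sum over classes of true positives divided by the total count, i.e. the
#' trace of the confusion matrix over N. For two classes this equals the
#' accuracy.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param percent If `TRUE` (default) return a percentage.
#' @return Numeric scalar.
#' @export
q4 <- function(cm, percent = TRUE) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  q <- sum(diag(cm)) / n
  if (percent) 100 * q else q
}

#' Sensitivity and false positive rate
#'
#' Sensitivity = TP / (TP + FN); FPR = FP / (FP + TN).
#'
#' @param counts List from [confusion_counts()].
#' @param percent If `TRUE` (default) return percentages.
#' @return Named numeric vector `c(sensitivity, fpr)`.
#' @export
sensitivity_fpr <- function(counts, percent = TRUE) {
  if (counts$TP + counts$FN == 0) stop("no positives: sensitivity undefined")
  if (counts$TN + counts$FP == 0) stop("no negatives: FPR undefined")
  out <- c(sensitivity = counts$TP / (counts$TP + counts$FN),
           fpr = counts$FP / (counts$FP + counts$TN))
  if (percent) 100 * out else out
}

#' Stage-level MCC for binary or multiclass predictions
#'
#' Binary stages use the standard Matthews coefficient. For the four-class
#' subtype stage a single value is formed as the mean of the per-class
#' one-vs-rest coefficients.
#'
#' @param truth,pred Label vectors.
#' @param classes Class levels.
#' @return Numeric scalar in [-1, 1].
#' @export
stage_mcc <- function(truth, pred, classes = sort(unique(as.character(truth)))) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(classes) == 2)
    return(mcc(confusion_counts(truth, pred, positive = classes[1])))
  mean(vapply(classes, function(cl)
    mcc(confusion_counts(truth, pred, positive = cl)), numeric(1)))
}

#' Error-rate reduction between two accuracies
#'
#' 100 * (acc_a - acc_b) / (100 - acc_b), both accuracies in percent.
#'
#' @param acc_a,acc_b Accuracies in percent, `acc_b < 100`.
#' @return Reduction in percent.
#' @export
#' @examples
#' error_rate_reduction(91.6, 89.6)  # 19.2
error_rate_reduction <- function(acc_a, acc_b) {
  if (acc_b >= 100) stop("reference accuracy must be below 100%")
  100 * (acc_a - acc_b) / (100 - acc_b)
}

#' Majority-class baseline accuracy
#'
#' Accuracy of a classifier that always predicts the most frequent class.
#'
#' @param class_counts Named or unnamed vector of per-class counts.
#' @return Accuracy in percent.
#' @export
#' @examples
#' majority_baseline_accuracy(c(ion = 298, `non-ion` = 300))  # 50.1...
majority_baseline_accuracy <- function(class_counts) {
  if (sum(class_counts) == 0) stop("empty class counts")
  100 * max(class_counts) / sum(class_counts)
}

#' Subsample confidence intervals for classification metrics
#'
#' Repeatedly draws a fraction of the predictions without replacement and
#' recomputes accuracy, MCC and F-measure (binary) or accuracy/Q4 and mean
#' one-vs-rest MCC (multiclass); reports the mean and standard deviation
#' over the repetitions. Subsamples missing a truth class are redrawn.
#'
#' @param truth,pred Label vectors.
#' @param classes Class levels; first level is the positive class for
#'   binary metrics.
#' @param fraction Subsample fraction, default 0.5.
#' @param reps Number of repetitions, default 10.
#' @param seed RNG seed.
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
subsample_ci <- function(truth, pred, classes = sort(unique(as.character(truth))),
                         fraction = 0.5, reps = 10, seed = 1) {
  truth <- as.character(truth); pred <- as.character(pred)
  n <- length(truth)
  if (n < 4) stop("need at least 4 predictions")
  m <- max(2L, floor(n * fraction))
  set.seed(seed)
  one_rep <- function() {
    for (tries in 1:100) {
      idx <- sample.int(n, m)
      if (all(classes %in% truth[idx])) break
    }
    tt <- truth[idx]; pp <- pred[idx]
    if (length(classes) == 2) {
      cc <- confusion_counts(tt, pp, positive = classes[1])
      c(accuracy = accuracy(cc), mcc = mcc(cc), f_measure = f_measure(cc))
    } else {
      cm <- confusion_matrix(tt, pp, classes)
      c(q4 = q4(cm), mcc = stage_mcc(tt, pp, classes))
    }
  }
  vals <- t(sapply(seq_len(reps), function(i) one_rep()))
  data.frame(metric = colnames(vals),
             mean = colMeans(vals),
             sd = apply(vals, 2, stats::sd),
             row.names = NULL)
}

#' Full metrics report for one stage's predictions
#'
#' @param truth,pred Label vectors.
#' @param classes Class levels (first = positive for binary stages).
#' @return Data frame with columns `metric`, `class`, `value`; percentages
#'   are reported to full precision (format to one decimal place for
#'   display).
#' @export
metrics_report <- function(truth, pred, classes = sort(unique(as.character(truth)))) {
  truth <- as.character(truth); pred <- as.character(pred)
  rows <- list()
  add <- function(metric, class, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, class = class,
                                            value = value)
  if (length(classes) == 2) {
    cc <- confusion_counts(truth, pred, positive = classes[1])
    add("accuracy", "overall", accuracy(cc))
    add("mcc", "overall", mcc(cc))
    add("f_measure", "overall", f_measure(cc))
    sf <- sensitivity_fpr(cc)
    add("sensitivity", "overall", sf[["sensitivity"]])
    add("fpr", "overall", sf[["fpr"]])
  } else {
    cm <- confusion_matrix(truth, pred, classes)
    add("q4", "overall", q4(cm))
    for (cl in classes) {
      cc <- confusion_counts(truth, pred, positive = cl)
      add("accuracy", cl, accuracy(cc))
      add("mcc", cl, mcc(cc))
      add("f_measure", cl, f_measure(cc))
      sf <- sensitivity_fpr(cc)
      add("sensitivity", cl, sf[["sensitivity"]])
      add("fpr", cl, sf[["fpr"]])
    }
    for (met in c("accuracy", "mcc", "f_measure", "sensitivity", "fpr")) {
      per <- vapply(classes, function(cl) {
        rws <- Reduce(rbind, rows)
        rws$value[rws$metric == met & rws$class == cl]
      }, numeric(1))
      add(met, "average", mean(per))
    }
  }
  do.call(rbind, rows)
}
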