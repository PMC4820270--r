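# The 878-dimensional sequence representation.
#
# Block layout (order is frozen; selection results are name/index based):
#   amino acid composition        20
#   dipeptide composition        400
#   physicochemical stats         12   (6 scales x {avg, sd})
#   secondary structure segments  13
#   disorder segments              9
#   RSA descriptors               24   (4 buried/exposed + 10 windows x {min,max})
#   PSSM profile scores          400
#   total                        878

RSA_WINDOWS <- seq(4, 22, by = 2)

#' Names of the 878 features, in the fixed extraction order
#'
#' @param scales Property scale list; only its length (6) and order matter
#'   for the property block names.
#' @return Character vector of length 878.
#' @export
feature_names <- function(scales = default_property_scales()) {
  aa <- AA_ALPHABET
  dipep <- as.vector(t(outer(aa, aa, paste0)))
  props <- as.vector(vapply(seq_along(scales), function(i)
    paste0("AAproperty_", i, "_", c("avg", "sd")), character(2)))
  ss <- c("Num_SS_Seg",
          paste0("Num_", c("C", "H", "E"), "_Seg"),
          as.vector(vapply(c("C", "H", "E"), function(s)
            paste0("CV_", s, "_Seg_", c("min", "max")), character(2))),
          paste0("Composition_", c("C", "H", "E")))
  dis <- c("Total_DisNonDis_Seg",
           paste0("Num_", c("Dis", "NonDis"), "_Seg"),
           as.vector(vapply(c("Dis", "NonDis"), function(s)
             paste0("CV_", s, "_Seg_", c("min", "max")), character(2))),
           paste0("Composition_", c("Dis", "NonDis")))
  rsa <- c("Bd_0.25", "Ed_0.25", "Bd_0.75", "Ed_0.75",
           as.vector(vapply(RSA_WINDOWS, function(w)
             paste0("RSA_", c("min", "max"), "_Seg", w), character(2))))
  c(paste0("AA_", aa),
    paste0("Dipeptide_", dipep),
    props, ss, dis, rsa,
    paste0("PSSM_", as.vector(t(outer(aa, aa, paste, sep = "_")))))
}

#' Feature group membership
#'
#' Maps each of the seven feature groups to its feature names, mirroring the
#' block layout of [feature_names()].
#'
#' @return Named list of character vectors whose lengths are
#'   20/400/12/13/9/24/400.
#' @export
feature_groups <- function() {
  nm <- feature_names()
  list(
    aa_composition   = nm[1:20],
    dipeptide        = nm[21:420],
    properties       = nm[421:432],
    secondary_structure = nm[433:445],
    disorder         = nm[446:454],
    rsa              = nm[455:478],
    pssm             = nm[479:878]
  )
}

.seq_chars <- function(sequence) strsplit(sequence, "")[[1]]

#' Amino acid composition (20 features)
#'
#' Count of each amino acid type divided by the sequence length.
#'
#' @param sequence Amino acid sequence string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(sequence) {
  ch <- .seq_chars(sequence)
  counts <- table(factor(ch, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(ch), paste0("AA_", AA_ALPHABET))
}

#' Dipeptide composition (400 features)
#'
#' Count of each ordered adjacent residue pair divided by L - 1.
#'
#' @param sequence Amino acid sequence string, length >= 2.
#' @return Named numeric vector of length 400 summing to 1.
#' @export
dipeptide_composition <- function(sequence) {
  ch <- .seq_chars(sequence)
  if (length(ch) < 2) stop("dipeptide composition needs length >= 2")
  pairs <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- table(factor(pairs, levels = lv))
  stats::setNames(as.numeric(counts) / (length(ch) - 1), paste0("Dipeptide_", lv))
}

#' Physicochemical property statistics (12 features)
#'
#' For each of the six scales, the mean and the population standard
#' deviation (divide by L) of the per-residue scale values.
#'
#' @param sequence Amino acid sequence string.
#' @param scales Named list of six per-residue scales;
#'   see [default_property_scales()].
#' @return Named numeric vector of length 12.
#' @export
physicochemical_stats <- function(sequence, scales = default_property_scales()) {
  ch <- .seq_chars(sequence)
  out <- numeric(0)
  for (i in seq_along(scales)) {
    sc <- scales[[i]]
    missing <- setdiff(unique(ch), names(sc))
    if (length(missing) > 0)
      stop("scale ", names(scales)[i] %||% i, " missing residue(s): ",
           paste(missing, collapse = ", "))
    v <- sc[ch]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population convention
    out <- c(out, stats::setNames(c(m, s),
                                  paste0("AAproperty_", i, "_", c("avg", "sd"))))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximal runs of identical symbols in a track
#'
#' @param track Character string or vector of symbols.
#' @return Data frame with columns `symbol`, `start`, `end` (half-open
#'   `[start, end)`), `length`; lengths sum to the track length.
#' @export
segment_runs <- function(track) {
  if (is.character(track) && length(track) == 1) track <- .seq_chars(track)
  if (length(track) == 0) stop("empty track")
  r <- rle(as.character(track))
  end <- cumsum(r$lengths)
  data.frame(symbol = r$values, start = c(1L, head(end, -1) + 1L),
             end = end + 1L, length = r$lengths, stringsAsFactors = FALSE)
}

.run_block <- function(runs, symbols, L, prefix) {
  # counts, min/max run length / L, per symbol; absent symbol -> all zeros
  num <- cvmin <- cvmax <- stats::setNames(numeric(length(symbols)), symbols)
  for (s in symbols) {
    lens <- runs$length[runs$symbol == s]
    if (length(lens) > 0) {
      num[s] <- length(lens)
      cvmin[s] <- min(lens) / L
      cvmax[s] <- max(lens) / L
    }
  }
  list(num = num, cvmin = cvmin, cvmax = cvmax)
}

#' Secondary structure segment features (13 features)
#'
#' Total segment count, per-state segment counts, min/max per-state run
#' length divided by sequence length, and per-state residue composition.
#' A state with no segments contributes zeros.
#'
#' @param ss State string over \{C,H,E\}.
#' @param L Sequence length; must equal `nchar(ss)`.
#' @return Named numeric vector of length 13.
#' @export
ss_features <- function(ss, L) {
  if (nchar(ss) != L) stop("ss track length ", nchar(ss), " != ", L)
  runs <- segment_runs(ss)
  b <- .run_block(runs, c("C", "H", "E"), L, "SS")
  ch <- .seq_chars(ss)
  comp <- vapply(c("C", "H", "E"), function(s) sum(ch == s) / L, numeric(1))
  out <- c(nrow(runs), b$num,
           as.vector(rbind(b$cvmin, b$cvmax)), comp)
  stats::setNames(out, c(
    "Num_SS_Seg", paste0("Num_", c("C", "H", "E"), "_Seg"),
    as.vector(vapply(c("C", "H", "E"), function(s)
      paste0("CV_", s, "_Seg_", c("min", "max")), character(2))),
    paste0("Composition_", c("C", "H", "E"))))
}

#' Disorder segment features (9 features)
#'
#' @param flags Logical vector, `TRUE` = disordered.
#' @param L Sequence length; must equal `length(flags)`.
#' @return Named numeric vector of length 9.
#' @export
disorder_features <- function(flags, L) {
  if (length(flags) != L) stop("disorder track length ", length(flags), " != ", L)
  track <- ifelse(flags, "Dis", "NonDis")
  runs <- segment_runs(track)
  b <- .run_block(runs, c("Dis", "NonDis"), L, "Dis")
  comp <- c(Dis = sum(flags) / L, NonDis = sum(!flags) / L)
  out <- c(nrow(runs), b$num,
           as.vector(rbind(b$cvmin, b$cvmax)), comp)
  stats::setNames(out, c(
    "Total_DisNonDis_Seg", paste0("Num_", c("Dis", "NonDis"), "_Seg"),
    as.vector(vapply(c("Dis", "NonDis"), function(s)
      paste0("CV_", s, "_Seg_", c("min", "max")), character(2))),
    paste0("Composition_", c("Dis", "NonDis"))))
}

#' Relative solvent accessibility features (24 features)
#'
#' Buried/exposed residue compositions at RSA cutoffs 0.25 and 0.75
#' (buried = RSA below the cutoff), and for each window length
#' W in \{4, 6, ..., 22\} the minimum and maximum over all contiguous
#' length-W windows of the window-average RSA. Windows longer than the
#' sequence contribute zeros.
#'
#' @param rsa Numeric RSA vector in [0,1].
#' @param L Sequence length; must equal `length(rsa)`.
#' @return Named numeric vector of length 24.
#' @export
rsa_features <- function(rsa, L) {
  if (length(rsa) != L) stop("rsa track length ", length(rsa), " != ", L)
  out <- numeric(0)
  for (cut in c(0.25, 0.75)) {
    bd <- sum(rsa < cut) / L
    out <- c(out, stats::setNames(c(bd, 1 - bd), paste0(c("Bd_", "Ed_"), cut)))
  }
  cs <- c(0, cumsum(rsa))
  for (w in RSA_WINDOWS) {
    if (L < w) {
      mn <- mx <- 0
    } else {
      avgs <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
      mn <- min(avgs); mx <- max(avgs)
    }
    out <- c(out, stats::setNames(c(mn, mx), paste0("RSA_", c("min", "max"), "_Seg", w)))
  }
  out
}

#' PSSM profile score features (400 features)
#'
#' For each ordered pair (AA1 = residue type in the sequence, AA2 = profile
#' column), the profile rows at all positions holding AA1 are summed, the
#' AA2 entry of the summed row is divided by the sequence length, and the
#' logistic transform 1/(1+exp(-x)) is applied. A residue type absent from
#' the sequence yields 0.5 (the logistic of zero) for all its 20 pairs.
#'
#' @param pssm L x 20 matrix with amino acid column names.
#' @param sequence Amino acid sequence of length L.
#' @return Named numeric vector of length 400, values in (0,1).
#' @export
pssm_features <- function(pssm, sequence) {
  ch <- .seq_chars(sequence)
  L <- length(ch)
  if (nrow(pssm) != L)
    stop("pssm has ", nrow(pssm), " rows, expected ", L)
  if (!all(AA_ALPHABET %in% colnames(pssm)))
    stop("pssm must have all 20 amino acid columns")
  m <- pssm[, AA_ALPHABET, drop = FALSE]
  out <- matrix(0.5, nrow = 20, ncol = 20,
                dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in unique(ch)) {
    sums <- colSums(m[ch == a, , drop = FALSE])
    out[a, ] <- 1 / (1 + exp(-sums / L))
  }
  v <- as.vector(t(out))
  stats::setNames(v, paste0("PSSM_", as.vector(t(outer(AA_ALPHABET, AA_ALPHABET,
                                                       paste, sep = "_")))))
}

#' Extract the full 878-feature vector for one protein
#'
#' Concatenates, in frozen order: amino acid composition (20), dipeptide
#' composition (400), physicochemical statistics (12), secondary structure
#' (13), disorder (9), RSA (24) and PSSM (400) blocks.
#'
#' @param record A [protein_record].
#' @param tracks Its per-residue tracks bundle from [residue_tracks()].
#' @param scales Property scales, see [default_property_scales()].
#' @return Named numeric vector of length 878.
#' @export
extract_features <- function(record, tracks, scales = default_property_scales()) {
  L <- nchar(record$sequence)
  v <- tryCatch(
    c(aa_composition(record$sequence),
      dipeptide_composition(record$sequence),
      physicochemical_stats(record$sequence, scales),
      ss_features(tracks$ss, L),
      disorder_features(tracks$disorder, L),
      rsa_features(tracks$rsa, L),
      pssm_features(tracks$pssm, record$sequence)),
    error = function(e) stop("protein ", record$id, ": ", conditionMessage(e)))
  stopifnot(length(v) == 878, all(is.finite(v)))
  v
}

#' Extract the feature matrix of a dataset
#'
#' @param dataset An `ion_dataset`.
#' @param scales Property scales.
#' @return n x 878 numeric matrix with protein ids as row names.
#' @export
extract_dataset_features <- function(dataset, scales = default_property_scales()) {
  ids <- names(dataset$records)
  X <- t(vapply(ids, function(id)
    extract_features(dataset$records[[id]], dataset$tracks[[id]], scales),
    numeric(878)))
  rownames(X) <- ids
  X
}

#' Fit min-max normalization parameters on a training feature matrix
#'
#' @param X n x d numeric training matrix.
#' @return Object of class `minmax_norm` holding per-feature minima and
#'   maxima.
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max),
                 names = colnames(X)),
            class = "minmax_norm")
}

#' Apply min-max normalization into [-1, 1]
#'
#' Computes (2x - min - max) / (max - min) per feature. Features constant on
#' the training data map to 0; values outside the training range are clamped
#' into [-1, 1].
#'
#' @param X Numeric vector or matrix with the same feature order as used to
#'   fit `params`.
#' @param params A `minmax_norm` object from [fit_normalizer()].
#' @return Normalized vector or matrix in [-1, 1].
#' @export
apply_normalizer <- function(X, params) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  rng <- params$max - params$min
  out <- sweep(sweep(2 * X, 2, params$min + params$max, "-"), 2,
               ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, -1), 1)
  if (vec) out[1, ] else out
}

#' Write / read a feature table as TSV
#'
#' The table carries an `id` column, optional label columns and the 878
#' feature columns in frozen order.
#'
#' @param X Feature matrix with id row names.
#' @param path Output path.
#' @param labels Optional named label vector aligned with `rownames(X)`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(X, path, labels = NULL) {
  df <- data.frame(id = rownames(X), check.names = FALSE)
  if (!is.null(labels)) df$label <- labels[rownames(X)]
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  labels <- if ("label" %in% names(df)) stats::setNames(df$label, df$id) else NULL
  X <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(X) <- df$id
  list(X = X, labels = labels)
}
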