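# Synthetic labelled proteins with complete per-residue tracks and BLAST hit
# tables, so every pipeline stage is testable without external tools or
# downloads. The generator plants class signal in a configurable subset of
# the feature blocks:
#   composition - class-tilted amino acid sampling weights
#   dipeptide   - first-order Markov transitions favouring within-block pairs
#   ss          - class-dependent state frequencies of a run-length process
#   disorder    - class-dependent disordered fraction of a run-length process
#   rsa         - class-dependent mean of clipped autocorrelated noise
#   pssm        - class-dependent column bias on small-integer noise
# Physicochemical property features inherit signal from the composition
# tilt, as they do in real sequences.

#' Simulation configuration
#'
#' @param n_per_class Proteins per class (>= 5).
#' @param length_range Min/max sequence length; the minimum must be at
#'   least 25 so all RSA windows exist.
#' @param signal_strength Non-negative class-separation dial; 0 gives
#'   class-independent generation.
#' @param stage Hierarchy stage whose classes are generated.
#' @param seed Master seed; per-protein substreams derive from it, so a
#'   protein's data is stable under changes of `n_per_class`.
#' @param informative_blocks Which feature blocks carry signal.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = 50, length_range = c(60, 120),
                              signal_strength = 1,
                              stage = c("ION", "VLG", "VGS"), seed = 1,
                              informative_blocks = c("composition", "pssm")) {
  stage <- match.arg(stage)
  stopifnot(n_per_class >= 5, length_range[1] >= 25,
            length_range[2] >= length_range[1], signal_strength >= 0)
  blocks <- c("composition", "dipeptide", "ss", "disorder", "rsa", "pssm")
  informative_blocks <- intersect(informative_blocks, blocks)
  structure(list(n_per_class = n_per_class, length_range = length_range,
                 signal_strength = signal_strength, stage = stage,
                 seed = seed, informative_blocks = informative_blocks),
            class = "simulation_config")
}

.class_aa_block <- function(class_index) {
  # 5 amino acids "owned" by each class, wrapping beyond 4 classes
  idx <- ((class_index - 1) * 5 + 0:4) %% 20 + 1
  AA_ALPHABET[idx]
}

.protein_seed <- function(config, class_index, idx) {
  (config$seed * 10007L + class_index * 1009L + idx) %% 2147483647L
}

#' Simulate one protein with all tracks
#'
#' @param class_index 1-based class index within the stage's class set.
#' @param idx Protein index within its class (drives the RNG substream).
#' @param config A [simulation_config()].
#' @return List with `record` ([protein_record]) and `tracks`
#'   ([residue_tracks()] bundle).
#' @export
simulate_protein <- function(class_index, idx, config) {
  classes <- stage_classes(config$stage)
  k <- length(classes)
  sig <- config$signal_strength
  inf <- function(b) b %in% config$informative_blocks && sig > 0
  set.seed(.protein_seed(config, class_index, idx))
  L <- sample(config$length_range[1]:config$length_range[2], 1)

  # --- sequence ---
  w <- rep(1, 20)
  names(w) <- AA_ALPHABET
  if (inf("composition")) w[.class_aa_block(class_index)] <- exp(0.5 * sig)
  p <- w / sum(w)
  if (inf("dipeptide")) {
    Tm <- matrix(rep(p, times = 20), 20, 20, byrow = TRUE,
                 dimnames = list(AA_ALPHABET, AA_ALPHABET))
    blk <- .class_aa_block(class_index)
    Tm[blk, blk] <- Tm[blk, blk] * exp(0.5 * sig)
    Tm <- Tm / rowSums(Tm)
    ch <- character(L)
    ch[1] <- sample(AA_ALPHABET, 1, prob = p)
    for (i in 2:L) ch[i] <- sample(AA_ALPHABET, 1, prob = Tm[ch[i - 1], ])
  } else {
    ch <- sample(AA_ALPHABET, L, replace = TRUE, prob = p)
  }
  sequence <- paste(ch, collapse = "")

  # --- secondary structure: run-length process ---
  base_ss <- c(C = 0.45, H = 0.35, E = 0.20)
  if (inf("ss")) {
    tilt <- c(C = 0, H = 1, E = -1) * 0.4 * sig * (class_index - (k + 1) / 2)
    base_ss <- exp(log(base_ss) + tilt)
    base_ss <- base_ss / sum(base_ss)
  }
  ss <- character(0)
  while (length(ss) < L) {
    st <- sample(names(base_ss), 1, prob = base_ss)
    ss <- c(ss, rep(st, stats::rgeom(1, 1 / 5) + 1))
  }
  ss <- paste(ss[1:L], collapse = "")

  # --- disorder: two-state run-length process ---
  pdis <- 0.15
  if (inf("disorder"))
    pdis <- stats::plogis(stats::qlogis(0.15) +
                            0.8 * sig * (class_index - (k + 1) / 2))
  flags <- logical(0)
  while (length(flags) < L) {
    d <- stats::runif(1) < pdis
    flags <- c(flags, rep(d, stats::rgeom(1, 1 / 6) + 1))
  }
  flags <- flags[1:L]

  # --- RSA: clipped AR(1) ---
  mu <- 0.45
  if (inf("rsa")) mu <- mu + 0.08 * sig * (class_index - (k + 1) / 2)
  eps <- stats::rnorm(L, 0, 0.15)
  rsa <- numeric(L)
  rsa[1] <- mu + eps[1]
  for (i in 2:L) rsa[i] <- mu + 0.7 * (rsa[i - 1] - mu) + eps[i]
  rsa <- pmin(pmax(rsa, 0), 1)

  # --- PSSM: small-integer noise plus class column bias ---
  m <- matrix(sample(-4:8, L * 20, replace = TRUE), L, 20,
              dimnames = list(ch, AA_ALPHABET))
  if (inf("pssm")) {
    bias_cols <- .class_aa_block(class_index)[1:4]
    m[, bias_cols] <- m[, bias_cols] + round(2 * sig)
  }
  m <- pmin(pmax(m, -8), 12)

  id <- sprintf("%s%02d_%04d", config$stage, class_index, idx)
  labels <- stats::setNames(list(classes[class_index]), config$stage)
  list(record = protein_record(id, sequence, labels),
       tracks = residue_tracks(ss, flags, rsa, m, L))
}

#' Simulate a labelled dataset, optionally writing it to disk
#'
#' Generates `n_per_class` proteins for each of the stage's classes. When
#' `dir` is given, writes the FASTA file, per-protein PSSM (PSI-BLAST ASCII
#' dialect), ss2, disorder and RSA files, and a manifest TSV loadable with
#' [load_dataset()].
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return An `ion_dataset`; when written, the manifest path is attached as
#'   attribute `"manifest"`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  classes <- stage_classes(config$stage)
  records <- list(); tracks <- list()
  for (ci in seq_along(classes)) {
    for (idx in seq_len(config$n_per_class)) {
      p <- simulate_protein(ci, idx, config)
      records[[p$record$id]] <- p$record
      tracks[[p$record$id]] <- p$tracks
    }
  }
  ds <- structure(list(records = records, tracks = tracks,
                       stage = config$stage), class = "ion_dataset")
  if (!is.null(dir)) attr(ds, "manifest") <- write_dataset(ds, dir)
  ds
}

#' Write a dataset in the pipeline's input dialects
#'
#' @param dataset An `ion_dataset`.
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest TSV.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(dataset$records)
  fasta <- file.path(dir, "sequences.fasta")
  writeLines(unlist(lapply(ids, function(id)
    c(paste0(">", id), dataset$records[[id]]$sequence))), fasta)
  rows <- lapply(ids, function(id) {
    rec <- dataset$records[[id]]; trk <- dataset$tracks[[id]]
    write_pssm_ascii(trk$pssm, file.path(dir, paste0(id, ".pssm")))
    write_ss2_file(trk$ss, rec$sequence, file.path(dir, paste0(id, ".ss2")))
    write_disorder_file(trk$disorder, rec$sequence,
                        file.path(dir, paste0(id, ".diso")))
    write_rsa_file(trk$rsa, rec$sequence, file.path(dir, paste0(id, ".rsa")))
    lab_col <- paste0("label_", tolower(dataset$stage))
    row <- data.frame(id = id, fasta = "sequences.fasta",
                      pssm = paste0(id, ".pssm"), ss2 = paste0(id, ".ss2"),
                      disorder = paste0(id, ".diso"), rsa = paste0(id, ".rsa"),
                      stringsAsFactors = FALSE)
    row[[lab_col]] <- rec$labels[[dataset$stage]]
    row
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

#' @rdname write_dataset
#' @param pssm L x 20 integer matrix with residue rownames.
#' @param path Output path.
#' @export
write_pssm_ascii <- function(pssm, path) {
  res <- rownames(pssm)
  cols <- colnames(pssm)
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("    ", paste(sprintf("%3s", c(cols, cols)), collapse = "")))
  body <- vapply(seq_len(nrow(pssm)), function(i) {
    pct <- rep(0L, 20)  # second (percentage) block, ignored by the reader
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%3d", pssm[i, ]), collapse = ""),
           paste(sprintf("%4d", pct), collapse = ""),
           sprintf("  %.2f %.2f", 0, 0))
  }, character(1))
  writeLines(c(header, body, ""), path)
  invisible(path)
}

write_ss2_file <- function(ss, sequence, path) {
  st <- strsplit(ss, "")[[1]]
  ch <- strsplit(sequence, "")[[1]]
  pr <- function(target) ifelse(st == target, 0.9, 0.05)
  lines <- sprintf("%4d %s %s  %5.3f %5.3f %5.3f",
                   seq_along(st), ch, st, pr("C"), pr("H"), pr("E"))
  writeLines(c("# PSIPRED VFORMAT (synthetic)", "", lines), path)
  invisible(path)
}

write_disorder_file <- function(flags, sequence, path) {
  ch <- strsplit(sequence, "")[[1]]
  prob <- ifelse(flags, 0.9, 0.1)
  lines <- sprintf("%5d %s %s %5.2f", seq_along(flags), ch,
                   ifelse(flags, "*", "."), prob)
  writeLines(c("# disorder prediction (synthetic)", lines), path)
  invisible(path)
}

write_rsa_file <- function(rsa, sequence, path) {
  ch <- strsplit(sequence, "")[[1]]
  lines <- sprintf("%d\t%s\t%.10g", seq_along(rsa), ch, rsa)
  writeLines(c("# per-residue RSA (synthetic)", lines), path)
  invisible(path)
}

#' Simulate an all-vs-all BLAST hit table
#'
#' Same-class pairs receive low e-values (log-uniform in
#' `10^same_log10_range`), cross-class pairs high e-values; every query also
#' gets a self-hit at e-value 0, which [best_hit()] must exclude. Each query
#' is "covered" with probability `coverage`; uncovered queries get no
#' same-class hits, so transfer abstains on them at stringent thresholds.
#' With `informative = FALSE` the e-value distribution ignores class,
#' giving a homology-null table.
#'
#' @param dataset An `ion_dataset` with labels at its stage.
#' @param seed RNG seed.
#' @param coverage Per-query probability of having same-class hits.
#' @param informative If `FALSE`, e-values are class-independent.
#' @param same_log10_range log10 e-value range for same-class hits.
#' @param cross_log10_range log10 e-value range for cross-class hits.
#' @param path Optional output path (12-column tabular file).
#' @return Hit data frame with the 12 standard columns.
#' @export
simulate_hit_table <- function(dataset, seed = 1, coverage = 1,
                               informative = TRUE,
                               same_log10_range = c(-30, -8),
                               cross_log10_range = c(1, 4),
                               path = NULL) {
  ids <- names(dataset$records)
  n <- length(ids)
  labs <- dataset_labels(dataset)
  lens <- vapply(dataset$records, function(r) nchar(r$sequence), 0L)
  set.seed(seed)
  covered <- stats::runif(n) < coverage

  qi <- rep(seq_len(n), each = n)
  si <- rep(seq_len(n), times = n)
  is_self <- qi == si
  same <- labs[qi] == labs[si]
  u_inc <- stats::runif(n * n)   # inclusion draws, fixed order
  u_e <- stats::runif(n * n)     # e-value draws, fixed order

  same_branch <- informative & same & !is_self
  keep <- is_self |
    (same_branch & covered[qi]) |
    (!same_branch & !is_self & u_inc < 0.15)
  e <- ifelse(same_branch,
              10^(same_log10_range[1] +
                    u_e * diff(same_log10_range)),
              10^(cross_log10_range[1] +
                    u_e * diff(cross_log10_range)))
  e[is_self] <- 0                # self-hit, must be excluded by best_hit

  qi <- qi[keep]; si <- si[keep]; e <- e[keep]
  bit <- round(-2 * log10(e + 1e-200) + 20, 1)
  pid <- round(pmin(100, pmax(20, 100 + 1.5 * log10(e + 1e-200))), 1)
  Lq <- unname(lens[qi])
  hits <- data.frame(
    qseqid = ids[qi], sseqid = ids[si], pident = pid, length = Lq,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = Lq, sstart = 1L,
    send = Lq, evalue = e, bitscore = bit, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  hits
}
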