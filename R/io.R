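# Parsers for every external format the pipeline consumes, and the dataset
# container tying sequences, labels and per-residue tracks together.
#
# Conventions: positions are 1-based in all file formats; every track for a
# protein must have length equal to its sequence length, asserted at load.

#' Construct a protein record
#'
#' @param id Identifier string.
#' @param sequence Amino acid sequence over the 20 standard letters.
#' @param labels Optional named character vector of class labels keyed by
#'   stage (`ION`, `VLG`, `VGS`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, labels = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2)
    stop("protein ", id, ": sequence must have length >= 2")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0)
    stop("protein ", id, ": non-standard residue(s) ",
         paste(bad, collapse = ", "))
  if (!is.null(labels)) {
    for (stg in names(labels)) {
      if (!labels[[stg]] %in% stage_classes(stg))
        stop("protein ", id, ": invalid ", stg, " label '", labels[[stg]], "'")
    }
  }
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "aa\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param skip_invalid If `TRUE`, records with non-standard residues are
#'   dropped with a warning instead of raising an error.
#' @return List of [protein_record] objects.
#' @export
read_fasta <- function(path, skip_invalid = FALSE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out <- vector("list", length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    rec <- tryCatch(protein_record(ids[i], as.character(seqs[[i]])),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (skip_invalid) {
        warning("skipping record: ", conditionMessage(rec), call. = FALSE)
      } else stop(rec)
    } else {
      out[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  out[keep]
}

.noncomment_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!grepl("^\\s*(#|$)", lines)]
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the checkpoint-ASCII dialect: header lines, a column-letter header
#' row, then one row per residue position carrying the position index, the
#' residue letter, and two 20-column score blocks. Only the first block (the
#' log-odds scores) is used; the column order is taken from the header row.
#'
#' @param path Path to the PSSM file.
#' @param expected_length Sequence length the row count must match.
#' @return L x 20 numeric matrix; `colnames` give the file's column order,
#'   `rownames` the residue letters.
#' @export
read_pssm <- function(path, expected_length) {
  lines <- readLines(path, warn = FALSE)
  header_idx <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20 && all(toks %in% AA_ALPHABET)) {
      header_idx <- i
      col_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_idx)) stop("no PSSM column header found in ", path)
  rows <- list()
  residues <- character()
  for (i in seq((header_idx + 1), length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "") break
    toks <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break
    if (length(toks) < 22)
      stop("malformed PSSM row at line ", i, " in ", path)
    scores <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(scores))
      stop("malformed PSSM row at line ", i, " in ", path)
    rows[[length(rows) + 1]] <- scores
    residues <- c(residues, toks[2])
  }
  if (length(rows) != expected_length)
    stop("PSSM in ", path, " has ", length(rows),
         " rows, expected ", expected_length)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(residues, col_order)
  m
}

#' Read a PSIPRED ss2 secondary structure prediction
#'
#' Data rows carry position index, residue, state letter in \{C,H,E\} and
#' three per-state probabilities; only the state letter is used.
#'
#' @param path Path to the ss2 file.
#' @return Character string of per-residue states over \{C,H,E\}.
#' @export
read_ss2 <- function(path) {
  lines <- .noncomment_lines(path)
  if (length(lines) == 0) stop("no data rows in ss2 file ", path)
  states <- vapply(strsplit(trimws(lines), "\\s+"), function(toks) {
    if (length(toks) < 3) stop("malformed ss2 row: ", paste(toks, collapse = " "))
    toks[3]
  }, character(1))
  bad <- setdiff(unique(states), c("C", "H", "E"))
  if (length(bad) > 0)
    stop("unknown secondary structure state(s): ", paste(bad, collapse = ", "))
  paste(states, collapse = "")
}

#' Read a per-residue disorder prediction
#'
#' Accepts DISOPRED-style rows (index, residue, mark character, probability)
#' or a generic two-column TSV (index, probability). In `"prob"` mode a
#' residue is flagged disordered iff its probability is at least `threshold`;
#' in `"mark"` mode iff its mark character is `*`.
#'
#' @param path Path to the prediction file.
#' @param threshold Disorder probability cutoff, default 0.5.
#' @param mode `"prob"` (default) or `"mark"`.
#' @return Logical vector, `TRUE` = disordered.
#' @export
read_disorder <- function(path, threshold = 0.5, mode = c("prob", "mark")) {
  mode <- match.arg(mode)
  lines <- .noncomment_lines(path)
  if (length(lines) == 0) stop("no data rows in disorder file ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  ncol1 <- length(toks[[1]])
  if (mode == "mark") {
    if (ncol1 < 3) stop("mark mode needs DISOPRED-style rows with a mark column")
    return(vapply(toks, function(t) t[3] == "*", logical(1)))
  }
  probs <- vapply(toks, function(t) {
    p <- suppressWarnings(as.numeric(t[length(t)]))
    if (is.na(p)) stop("malformed disorder row: ", paste(t, collapse = " "))
    p
  }, numeric(1))
  if (any(probs < 0 | probs > 1))
    stop("disorder probabilities must lie in [0,1]")
  probs >= threshold
}

#' Read a per-residue relative solvent accessibility track
#'
#' Per-residue TSV with index, residue and value columns. In `"rsa"` mode
#' values are already relative and are clamped into [0,1]; in `"asa"` mode
#' absolute accessible surface areas are divided by the residue's maximum
#' from `max_asa` first.
#'
#' @param path Path to the file.
#' @param mode `"rsa"` (default) or `"asa"`.
#' @param max_asa Named vector of per-residue maximum accessible surface
#'   areas; required in `"asa"` mode. See [default_max_asa()].
#' @return Numeric vector of RSA values in [0,1].
#' @export
read_rsa <- function(path, mode = c("rsa", "asa"), max_asa = NULL) {
  mode <- match.arg(mode)
  lines <- .noncomment_lines(path)
  if (length(lines) == 0) stop("no data rows in RSA file ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  vals <- vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[length(t)]))
    if (is.na(v)) stop("malformed RSA row: ", paste(t, collapse = " "))
    v
  }, numeric(1))
  if (mode == "asa") {
    if (is.null(max_asa)) stop("asa mode requires a max_asa table")
    res <- vapply(toks, function(t) t[2], character(1))
    missing <- setdiff(unique(res), names(max_asa))
    if (length(missing) > 0)
      stop("residue(s) missing from max_asa table: ",
           paste(missing, collapse = ", "))
    vals <- vals / max_asa[res]
  }
  unname(pmin(pmax(vals, 0), 1))
}

#' Assemble a per-residue tracks bundle
#'
#' @param ss Secondary structure state string over \{C,H,E\}.
#' @param disorder Logical disorder flags.
#' @param rsa Numeric RSA values in [0,1].
#' @param pssm L x 20 PSSM matrix with amino acid column names.
#' @param length Expected sequence length all tracks must match.
#' @return List with components `ss`, `disorder`, `rsa`, `pssm`.
#' @export
residue_tracks <- function(ss, disorder, rsa, pssm, length) {
  if (nchar(ss) != length) stop("ss track length ", nchar(ss), " != ", length)
  if (base::length(disorder) != length)
    stop("disorder track length ", base::length(disorder), " != ", length)
  if (base::length(rsa) != length)
    stop("rsa track length ", base::length(rsa), " != ", length)
  if (nrow(pssm) != length)
    stop("pssm has ", nrow(pssm), " rows, expected ", length)
  if (!all(AA_ALPHABET %in% colnames(pssm)))
    stop("pssm must have all 20 amino acid columns")
  list(ss = ss, disorder = disorder, rsa = rsa, pssm = pssm)
}

#' Load a labelled dataset from a manifest
#'
#' The manifest is a TSV with columns `id`, `fasta`, `pssm`, `ss2`,
#' `disorder`, `rsa` and optional `label_ion`, `label_vlg`, `label_vgs`.
#' Relative paths are resolved against the manifest's directory. Every track
#' is cross-checked against the sequence length.
#'
#' @param manifest Path to the manifest TSV.
#' @param stage Hierarchy stage the dataset's labels refer to (used as the
#'   default label slot; all provided label columns are kept).
#' @return An object of class `ion_dataset` with components `records`
#'   (named list of [protein_record]), `tracks` (named list of track
#'   bundles) and `stage`.
#' @export
load_dataset <- function(manifest, stage = c("ION", "VLG", "VGS")) {
  stage <- match.arg(stage)
  man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("id", "fasta", "pssm", "ss2", "disorder", "rsa")
  if (!all(req %in% names(man)))
    stop("manifest missing column(s): ",
         paste(setdiff(req, names(man)), collapse = ", "))
  root <- dirname(manifest)
  resolve <- function(p) {
    p <- ifelse(grepl("^/", p), p, file.path(root, p))
    if (!file.exists(p)) stop("missing file: ", p)
    p
  }
  fasta_cache <- new.env(parent = emptyenv())
  records <- list()
  tracks <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$id[i]
    ok <- try({
      fp <- resolve(man$fasta[i])
      key <- fp
      if (!exists(key, envir = fasta_cache)) {
        recs <- read_fasta(fp)
        assign(key, stats::setNames(recs, vapply(recs, `[[`, "", "id")),
               envir = fasta_cache)
      }
      recs <- get(key, envir = fasta_cache)
      if (!id %in% names(recs)) stop("id ", id, " not found in ", fp)
      rec <- recs[[id]]
      labels <- c(ION = man$label_ion[i], VLG = man$label_vlg[i],
                  VGS = man$label_vgs[i])
      labels <- labels[!is.na(labels) & labels != ""]
      if (length(labels) > 0) rec <- protein_record(id, rec$sequence, as.list(labels))
      L <- nchar(rec$sequence)
      trk <- residue_tracks(
        ss = read_ss2(resolve(man$ss2[i])),
        disorder = read_disorder(resolve(man$disorder[i])),
        rsa = read_rsa(resolve(man$rsa[i])),
        pssm = read_pssm(resolve(man$pssm[i]), expected_length = L),
        length = L)
      records[[id]] <- rec
      tracks[[id]] <- trk
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to load protein ", id, ": ",
           attr(ok, "condition")$message)
  }
  structure(list(records = records, tracks = tracks, stage = stage),
            class = "ion_dataset")
}

#' @export
print.ion_dataset <- function(x, ...) {
  labs <- dataset_labels(x, x$stage)
  cat("<ion_dataset>", length(x$records), "proteins, stage", x$stage, "\n")
  if (!all(is.na(labs))) print(table(labs, useNA = "ifany"))
  invisible(x)
}

#' Extract the label vector of a dataset at one stage
#'
#' @param dataset An `ion_dataset`.
#' @param stage Hierarchy stage; defaults to the dataset's own stage.
#' @return Named character vector of labels (NA where absent).
#' @export
dataset_labels <- function(dataset, stage = dataset$stage) {
  vapply(dataset$records, function(r) {
    lab <- r$labels[[stage]]
    if (is.null(lab)) NA_character_ else lab
  }, character(1))
}
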