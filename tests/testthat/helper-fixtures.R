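# Shared fixture builders; everything is generated in code at test time.

# random valid amino-acid sequence
random_sequence <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# random tracks bundle consistent with a sequence
random_tracks <- function(sequence, seed = 1) {
  set.seed(seed)
  L <- nchar(sequence)
  ss <- paste(sample(c("C", "H", "E"), L, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)), collapse = "")
  flags <- stats::runif(L) < 0.25
  rsa <- stats::runif(L)
  pssm <- matrix(sample(-8:12, L * 20, replace = TRUE), L, 20,
                 dimnames = list(strsplit(sequence, "")[[1]], AA_ALPHABET))
  residue_tracks(ss, flags, rsa, pssm, L)
}

random_protein <- function(L = 60, seed = 1, id = paste0("p", seed)) {
  seqc <- random_sequence(L, seed)
  list(record = protein_record(id, seqc),
       tracks = random_tracks(seqc, seed + 1000))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny separable 2-class matrix for SVM tests
separable_xy <- function(n_per_class = 20, d = 4, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
             matrix(rnorm(n_per_class * d) + gap, n_per_class, d))
  y <- factor(rep(c("a", "b"), each = n_per_class))
  rownames(X) <- paste0("r", seq_len(2 * n_per_class))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = stats::setNames(y, rownames(X)))
}
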