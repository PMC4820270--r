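# Brute-force oracles, independent of the implementation paths they check.

oracle_aa_comp <- function(seqc) {
  ch <- strsplit(seqc, "")[[1]]
  vapply(AA_ALPHABET, function(a) sum(ch == a), 0) / length(ch)
}

oracle_dipep <- function(seqc) {
  ch <- strsplit(seqc, "")[[1]]
  out <- stats::setNames(numeric(400),
                         as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0))))
  for (i in seq_len(length(ch) - 1))
    out[paste0(ch[i], ch[i + 1])] <- out[paste0(ch[i], ch[i + 1])] + 1
  out / (length(ch) - 1)
}

oracle_pssm <- function(pssm, seqc) {
  ch <- strsplit(seqc, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (a1 in AA_ALPHABET) for (a2 in AA_ALPHABET) {
    s <- 0
    for (i in seq_len(L)) if (ch[i] == a1) s <- s + pssm[i, a2]
    out <- c(out, 1 / (1 + exp(-s / L)))
  }
  unname(out)
}

oracle_window_extrema <- function(rsa, w) {
  L <- length(rsa)
  if (L < w) return(c(0, 0))
  avgs <- vapply(1:(L - w + 1), function(s) mean(rsa[s:(s + w - 1)]), 0)
  c(min(avgs), max(avgs))
}

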