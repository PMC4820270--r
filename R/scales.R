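# Per-residue physicochemical scales and the reference maximum accessible
# surface areas. All tables are keyed by one-letter amino acid code and cover
# exactly the 20 standard residues; user-supplied replacements are accepted
# anywhere a scale table is consumed.

.scale_vec <- function(...) {
  v <- c(...)
  stopifnot(setequal(names(v), AA_ALPHABET))
  v[AA_ALPHABET]
}

#' Default physicochemical property scales
#'
#' Six classical per-residue scales: Hopp-Woods hydrophilicity, Kyte-Doolittle
#' hydrophobicity, Grantham polarity, Bhaskaran-Ponnuswamy average
#' flexibility, Chou-Fasman beta-turn propensity, and Janin transfer free
#' energy (kcal/mol, interior minus exterior). Any named list of six numeric
#' vectors covering the 20 standard residues can be substituted.
#'
#' @return Named list of six numeric vectors, each of length 20.
#' @export
#' @examples
#' default_property_scales()$hydrophobicity[["W"]]
default_property_scales <- function() {
  list(
    hydrophilicity = .scale_vec(
      A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
      G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
      P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
    hydrophobicity = .scale_vec(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
    polarity = .scale_vec(
      A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
      G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
      P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
    flexibility = .scale_vec(
      A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493,
      E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466,
      M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305,
      Y = 0.420, V = 0.386),
    beta_turn = .scale_vec(
      A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98, E = 0.74,
      G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01, M = 0.60, F = 0.60,
      P = 1.52, S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50),
    transfer_energy = .scale_vec(
      A = 0.3, R = -1.4, N = -0.5, D = -0.6, C = 0.9, Q = -0.7, E = -0.7,
      G = 0.3, H = -0.1, I = 0.7, L = 0.5, K = -1.8, M = 0.4, F = 0.5,
      P = -0.3, S = -0.1, T = -0.2, W = 0.3, Y = -0.4, V = 0.6)
  )
}

#' Read property scales from a TSV file
#'
#' Expects columns `aa` plus one column per scale; rows cover the 20 standard
#' residues. Used to swap in alternative AAindex entries without touching
#' code.
#'
#' @param path Path to the TSV file.
#' @return Named list of numeric vectors keyed by amino acid.
#' @export
read_property_scales <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"aa" %in% names(df)) stop("scale table needs an 'aa' column")
  if (!setequal(df$aa, AA_ALPHABET))
    stop("scale table must cover exactly the 20 standard amino acids")
  scales <- lapply(df[setdiff(names(df), "aa")], function(col) {
    .scale_vec(stats::setNames(col, df$aa))
  })
  scales
}

#' Maximum accessible surface areas (theoretical, \eqn{\mbox{\AA}^2})
#'
#' Reference maxima for converting absolute accessible surface areas to
#' relative solvent accessibility (Tien et al. theoretical values for an
#' extended tripeptide context).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
default_max_asa <- function() {
  .scale_vec(
    A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}
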