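test_that("composition blocks match counting oracles and hand examples", {
  expect_equal(unname(aa_composition("AAAA")["AA_A"]), 1)
  expect_equal(sum(aa_composition("AAAA")[-1]), 0)
  expect_equal(unname(aa_composition("ACDE")[paste0("AA_", c("A", "C", "D", "E"))]),
               rep(0.25, 4))

  expect_equal(unname(dipeptide_composition("AAA")["Dipeptide_AA"]), 1)
  dc <- dipeptide_composition("ACAC")
  expect_equal(unname(dc["Dipeptide_AC"]), 2 / 3)
  expect_equal(unname(dc["Dipeptide_CA"]), 1 / 3)
  expect_error(dipeptide_composition("A"), ">= 2")

  for (seed in 1:20) {
    s <- random_sequence(60, seed)
    expect_equal(unname(aa_composition(s)), unname(oracle_aa_comp(s)))
    expect_equal(unname(dipeptide_composition(s)), unname(oracle_dipep(s)))
    expect_equal(sum(aa_composition(s)), 1, tolerance = 1e-9)
    expect_equal(sum(dipeptide_composition(s)), 1, tolerance = 1e-9)
  }
})

test_that("physicochemical stats use the population sd convention", {
  ps <- physicochemical_stats("KKKK")
  expect_equal(unname(ps[grep("_sd$", names(ps))]), rep(0, 6))
  expect_equal(unname(ps["AAproperty_2_avg"]),
               unname(default_property_scales()$hydrophobicity[["K"]]))

  toy <- lapply(1:6, function(i) stats::setNames(rep(0, 20), AA_ALPHABET))
  toy <- lapply(toy, function(s) { s[["A"]] <- 0; s[["C"]] <- 2; s })
  st <- physicochemical_stats("AC", toy)
  expect_equal(unname(st["AAproperty_1_avg"]), 1)
  expect_equal(unname(st["AAproperty_1_sd"]), 1)  # population, not sample

  # two-pass oracle on a random sequence
  s <- random_sequence(60, 33)
  sc <- default_property_scales()
  got <- physicochemical_stats(s, sc)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_along(sc)) {
    v <- sc[[i]][ch]
    expect_equal(unname(got[paste0("AAproperty_", i, "_avg")]), mean(v))
    expect_equal(unname(got[paste0("AAproperty_", i, "_sd")]),
                 sqrt(sum((v - mean(v))^2) / length(v)))
  }

  bad <- lapply(1:6, function(i) c(A = 1))
  expect_error(physicochemical_stats("AC", bad), "missing")
})

test_that("segment runs reconstruct their track", {
  r <- segment_runs("CCHHE")
  expect_equal(r$symbol, c("C", "H", "E"))
  expect_equal(r$length, c(2L, 2L, 1L))
  expect_equal(segment_runs("C")$length, 1L)
  for (seed in 1:10) {
    set.seed(seed)
    trk <- sample(c("C", "H", "E"), 40, replace = TRUE)
    r <- segment_runs(trk)
    expect_equal(sum(r$length), 40)
    expect_equal(unlist(mapply(rep, r$symbol, r$length, SIMPLIFY = FALSE),
                        use.names = FALSE), trk)
  }
})

test_that("secondary structure features match hand enumeration", {
  f <- ss_features("CCHHE", 5)
  expect_equal(unname(f["Num_SS_Seg"]), 3)
  expect_equal(unname(f[c("Num_C_Seg", "Num_H_Seg", "Num_E_Seg")]), c(1, 1, 1))
  expect_equal(unname(f[c("CV_C_Seg_min", "CV_C_Seg_max")]), c(0.4, 0.4))
  expect_equal(unname(f[c("CV_E_Seg_min", "CV_E_Seg_max")]), c(0.2, 0.2))
  expect_equal(unname(f[paste0("Composition_", c("C", "H", "E"))]),
               c(0.4, 0.4, 0.2))

  g <- ss_features("CCCC", 4)
  expect_equal(unname(g["Num_SS_Seg"]), 1)
  expect_equal(unname(g[c("Num_H_Seg", "Num_E_Seg")]), c(0, 0))
  expect_equal(unname(g[c("CV_H_Seg_min", "CV_H_Seg_max",
                          "CV_E_Seg_min", "CV_E_Seg_max")]), rep(0, 4))
  expect_equal(unname(g["Composition_C"]), 1)
  expect_error(ss_features("CCH", 4), "!= 4")
})

test_that("disorder features match hand enumeration", {
  f <- disorder_features(c(TRUE, TRUE, FALSE, FALSE, FALSE), 5)
  expect_equal(unname(f["Total_DisNonDis_Seg"]), 2)
  expect_equal(unname(f[c("Num_Dis_Seg", "Num_NonDis_Seg")]), c(1, 1))
  expect_equal(unname(f[c("CV_Dis_Seg_min", "CV_Dis_Seg_max")]), c(0.4, 0.4))
  expect_equal(unname(f[c("CV_NonDis_Seg_min", "CV_NonDis_Seg_max")]), c(0.6, 0.6))
  expect_equal(unname(f[c("Composition_Dis", "Composition_NonDis")]), c(0.4, 0.6))

  g <- disorder_features(rep(FALSE, 6), 6)
  expect_equal(unname(g["Total_DisNonDis_Seg"]), 1)
  expect_equal(unname(g["Num_Dis_Seg"]), 0)
  expect_equal(unname(g[c("Composition_Dis", "Composition_NonDis")]), c(0, 1))
})

test_that("segment features agree with a run-enumeration oracle", {
  for (seed in 1:15) {
    set.seed(seed)
    L <- sample(20:60, 1)
    ss <- paste(sample(c("C", "H", "E"), L, replace = TRUE), collapse = "")
    f <- ss_features(ss, L)
    runs <- segment_runs(ss)
    expect_equal(unname(f["Num_SS_Seg"]), nrow(runs))
    for (s in c("C", "H", "E")) {
      lens <- runs$length[runs$symbol == s]
      expect_equal(unname(f[paste0("Num_", s, "_Seg")]), length(lens))
      expect_equal(unname(f[paste0("CV_", s, "_Seg_min")]),
                   if (length(lens)) min(lens) / L else 0)
      expect_equal(unname(f[paste0("CV_", s, "_Seg_max")]),
                   if (length(lens)) max(lens) / L else 0)
    }
    expect_equal(sum(f[c("Num_C_Seg", "Num_H_Seg", "Num_E_Seg")]),
                 unname(f["Num_SS_Seg"]))
    expect_equal(sum(f[paste0("Composition_", c("C", "H", "E"))]), 1,
                 tolerance = 1e-9)
    flags <- stats::runif(L) < 0.3
    d <- disorder_features(flags, L)
    expect_equal(sum(d[c("Num_Dis_Seg", "Num_NonDis_Seg")]),
                 unname(d["Total_DisNonDis_Seg"]))
    expect_equal(sum(d[c("Composition_Dis", "Composition_NonDis")]), 1,
                 tolerance = 1e-9)
  }
})

test_that("RSA features: cutoffs, window extrema, degenerate lengths", {
  f <- rsa_features(rep(0.5, 30), 30)
  expect_equal(unname(f[c("Bd_0.25", "Ed_0.25", "Bd_0.75", "Ed_0.75")]),
               c(0, 1, 1, 0))
  expect_true(all(abs(f[grep("^RSA_", names(f))] - 0.5) < 1e-12))

  g <- rsa_features(c(0.1, 0.5, 0.9), 3)
  expect_true(all(g[grep("^RSA_", names(g))] == 0))

  set.seed(21)
  rsa <- stats::runif(40)
  h <- rsa_features(rsa, 40)
  for (w in seq(4, 22, 2)) {
    ex <- oracle_window_extrema(rsa, w)
    expect_equal(unname(h[paste0("RSA_min_Seg", w)]), ex[1])
    expect_equal(unname(h[paste0("RSA_max_Seg", w)]), ex[2])
  }
  expect_equal(unname(h["Bd_0.25"] + h["Ed_0.25"]), 1)
  expect_equal(unname(h["Bd_0.75"] + h["Ed_0.75"]), 1)
})

test_that("PSSM features implement the summed-row logistic score", {
  seqc <- random_sequence(30, 5)
  zero <- matrix(0, 30, 20, dimnames = list(NULL, AA_ALPHABET))
  expect_true(all(pssm_features(zero, seqc) == 0.5))

  m2 <- matrix(0, 2, 20, dimnames = list(NULL, AA_ALPHABET))
  m2[, "D"] <- 4
  f2 <- pssm_features(m2, "AA")
  expect_equal(unname(f2["PSSM_A_D"]), 1 / (1 + exp(-4)))
  expect_true(all(f2[paste0("PSSM_C_", AA_ALPHABET)] == 0.5))

  set.seed(9)
  pm <- matrix(sample(-8:12, 600, replace = TRUE), 30, 20,
               dimnames = list(NULL, AA_ALPHABET))
  expect_equal(unname(pssm_features(pm, seqc)), oracle_pssm(pm, seqc))
  expect_error(pssm_features(pm, random_sequence(31, 6)), "rows")
})

test_that("full extraction is 878-dimensional, deterministic, block-consistent", {
  p <- random_protein(70, seed = 4)
  v1 <- extract_features(p$record, p$tracks)
  v2 <- extract_features(p$record, p$tracks)
  expect_length(v1, 878)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))

  g <- feature_groups()
  expect_equal(unname(vapply(g, length, 0L)), c(20L, 400L, 12L, 13L, 9L, 24L, 400L))
  expect_equal(unname(v1[g$aa_composition]), unname(aa_composition(p$record$sequence)))
  expect_equal(unname(v1[g$pssm]),
               unname(pssm_features(p$tracks$pssm, p$record$sequence)))
  expect_equal(unname(v1[g$rsa]),
               unname(rsa_features(p$tracks$rsa, nchar(p$record$sequence))))
  expect_true(all(v1[g$pssm] > 0 & v1[g$pssm] < 1))
})

test_that("min-max normalization maps into [-1,1] with clamping", {
  X <- rbind(c(0, 5, 3), c(2, 5, 1), c(1, 5, 2))
  colnames(X) <- c("a", "b", "c")
  nm <- fit_normalizer(X)
  expect_equal(unname(nm$min), c(0, 5, 1))
  expect_equal(unname(nm$max), c(2, 5, 3))

  Xn <- apply_normalizer(X, nm)
  expect_equal(unname(Xn[, "a"]), c(-1, 1, 0))
  expect_equal(unname(Xn[, "b"]), c(0, 0, 0))    # constant feature -> 0
  expect_true(all(Xn >= -1 & Xn <= 1))
  expect_equal(unname(apply(Xn[, c("a", "c")], 2, min)), c(-1, -1))
  expect_equal(unname(apply(Xn[, c("a", "c")], 2, max)), c(1, 1))

  v <- apply_normalizer(c(a = 99, b = 7, c = -99), nm)
  expect_equal(unname(v), c(1, 0, -1))           # out-of-range clamps

  set.seed(3)
  R <- matrix(rnorm(60), 12, 5)
  nm2 <- fit_normalizer(R)
  expect_equal(unname(nm2$min), unname(apply(R, 2, min)))
  expect_equal(unname(nm2$max), unname(apply(R, 2, max)))
})

test_that("feature tables round-trip through TSV", {
  cfg <- simulation_config(n_per_class = 5, length_range = c(30, 40),
                           stage = "VLG", seed = 8)
  ds <- simulate_dataset(cfg)
  X <- extract_dataset_features(ds)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(X, path, labels = dataset_labels(ds))
  back <- read_feature_table(path)
  expect_equal(back$X, X, tolerance = 1e-12)
  expect_equal(back$labels, dataset_labels(ds))
})
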