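# Small dense matrices stand in for feature tables; oracles are direct
# re-derivations of each rule.

make_xy <- function(n = 60, d = 10, informative = 2, seed = 1, gap = 2) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(paste0("r", 1:n), paste0("f", 1:d)))
  for (j in seq_len(informative)) X[y == "a", j] <- X[y == "a", j] + gap
  list(X = X, y = stats::setNames(y, rownames(X)))
}

test_that("point-biserial correlation matches a covariance oracle", {
  y <- c(0, 0, 1, 1, 1, 0)
  expect_equal(biserial_correlation(y, y), 1)
  expect_equal(biserial_correlation(rep(2, 6), y), 0)
  expect_error(biserial_correlation(rnorm(4), rep(1, 4)), "both classes")

  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(40)
    yy <- sample(c("a", "b"), 40, replace = TRUE)
    if (length(unique(yy)) < 2) next
    y01 <- as.numeric(yy == "b")
    num <- mean(x * y01) - mean(x) * mean(y01)
    den <- sqrt(mean(x^2) - mean(x)^2) * sqrt(mean(y01^2) - mean(y01)^2)
    expect_equal(biserial_correlation(x, yy), num / den, tolerance = 1e-12)
  }
})

test_that("fold-averaged ranking puts perfect features first, noise low", {
  d <- make_xy(n = 100, d = 8, informative = 1, gap = 50, seed = 2)
  # feature equal to the label encoding separates in every fold
  d$X[, 1] <- as.numeric(d$y == "a")
  folds <- make_folds(d$y, 5, seed = 3)
  ranked <- fold_averaged_bcc(d$X, d$y, folds)
  expect_equal(ranked$feature[1], "f1")
  expect_equal(ranked$avg_bcc[1], 1)

  # pure-noise features stay near zero at n = 500
  set.seed(9)
  Xn <- matrix(rnorm(500 * 5), 500, 5,
               dimnames = list(NULL, paste0("n", 1:5)))
  yn <- factor(rep(c("a", "b"), 250))
  rn <- fold_averaged_bcc(Xn, yn, make_folds(yn, 5, 1))
  expect_lt(max(rn$avg_bcc), 0.15)

  # ranking invariant under column permutation of the input
  perm <- sample(ncol(d$X))
  r2 <- fold_averaged_bcc(d$X[, perm], d$y, folds)
  expect_equal(r2$feature, ranked$feature)
  expect_equal(r2$avg_bcc, ranked$avg_bcc)
})

test_that("BCC cutoff filtering preserves order", {
  ranked <- data.frame(feature = c("x", "y", "z"), avg_bcc = c(0.4, 0.2, 0.1))
  expect_equal(filter_by_bcc(ranked, 0.15)$feature, c("x", "y"))
  expect_equal(filter_by_bcc(ranked, 1e-9)$feature, c("x", "y", "z"))
  expect_equal(nrow(filter_by_bcc(ranked, 0.9)), 0)
})

test_that("greedy redundancy removal admits exactly the low-correlation set", {
  set.seed(4)
  base <- rnorm(80)
  X <- cbind(f1 = base, f2 = base, f3 = rnorm(80), f4 = base + rnorm(80, 0, 3))
  ranked <- data.frame(feature = colnames(X), avg_bcc = c(0.9, 0.8, 0.7, 0.6))
  sel <- remove_redundant(ranked, X, 0.9)
  expect_equal(sel[1], "f1")
  expect_false("f2" %in% sel)  # identical copy rejected at any cutoff < 1
  expect_true("f3" %in% sel)

  # orthogonal features all admitted
  Xo <- diag(4); colnames(Xo) <- paste0("o", 1:4)
  ro <- data.frame(feature = colnames(Xo), avg_bcc = 4:1 / 10)
  expect_equal(remove_redundant(ro, Xo, 0.7), colnames(Xo))

  # independent greedy oracle on correlated blocks
  set.seed(5)
  Z <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("g", 1:8)))
  Z[, 2] <- Z[, 1] + rnorm(60, 0, 0.1)
  Z[, 5] <- Z[, 4] * 0.9 + rnorm(60, 0, 0.2)
  rz <- data.frame(feature = colnames(Z), avg_bcc = 8:1 / 10)
  got <- remove_redundant(rz, Z, 0.8)
  admitted <- rz$feature[1]
  for (f in rz$feature[-1]) {
    ok <- TRUE
    for (a in admitted) if (abs(stats::cor(Z[, f], Z[, a])) >= 0.8) ok <- FALSE
    if (ok) admitted <- c(admitted, f)
  }
  expect_equal(got, admitted)
  # post-hoc invariant: every admitted pair is below the cutoff
  for (i in seq_along(got)) for (j in seq_len(i - 1))
    expect_lt(abs(stats::cor(Z[, got[i]], Z[, got[j]])), 0.8)
})

test_that("wrapper elimination is strict, monotone and removes planted noise", {
  # one informative dimension plus pure-noise dimensions that dilute the
  # RBF kernel distances at this gamma (verified to lower pooled CV MCC)
  set.seed(3)
  n <- 60
  y <- factor(rep(c("a", "b"), length.out = n))
  names(y) <- paste0("r", 1:n)
  X <- cbind(f1 = rnorm(n) + ifelse(y == "a", 2, 0),
             f2 = rnorm(n), f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n))
  rownames(X) <- names(y)
  folds <- make_folds(y, 5, seed = 2)
  base <- cross_validate(X, y, folds, C = 1, gamma = 2, probability = FALSE)
  base_mcc <- stage_mcc(base$truth, base$pred)
  we <- wrapper_eliminate(paste0("f", 1:5), X, y, folds, C = 1, gamma = 2)
  expect_gte(we$mcc, base_mcc)                 # never decreases
  expect_lt(length(we$features), 5)            # harmful noise removed
  expect_gt(we$mcc, base_mcc)                  # and removal actually helped
  expect_true("f1" %in% we$features)           # the signal survives

  # strictness: on perfectly separated data (MCC already 1), nothing moves
  dsep <- make_xy(n = 40, d = 3, informative = 3, gap = 60, seed = 8)
  fsep <- make_folds(dsep$y, 5, seed = 2)
  wsep <- wrapper_eliminate(c("f1", "f2", "f3"), dsep$X, dsep$y, fsep,
                            C = 1, gamma = 0.1)
  expect_equal(wsep$features, c("f1", "f2", "f3"))
  expect_equal(wsep$mcc, 1)
})

test_that("PCA selection honours the variance cutoff", {
  # min-max normalization equalizes feature ranges, so variance dominance
  # must come from correlation: nine noisy copies of one direction plus a
  # single independent column put ~90% of normalized variance on PC1
  set.seed(10)
  n <- 80
  dom <- rnorm(n, 0, 3)
  X <- sapply(1:9, function(j) dom + rnorm(n, 0, 0.2))
  X <- cbind(X, rnorm(n))
  colnames(X) <- paste0("f", 1:10)
  rownames(X) <- paste0("r", 1:n)
  y <- factor(ifelse(dom > 0, "a", "b"))
  folds <- make_folds(y, 5, seed = 1)
  cfg <- selection_config(C_grid = 1, gamma_grid = c(0.1, 1),
                          include_pca = FALSE)

  nm <- fit_normalizer(X)
  pc <- stats::prcomp(apply_normalizer(X, nm))
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_gte(cumvar[1], 0.85)                  # dominant direction

  pr <- pca_select(X, y, 0.85, folds, cfg)
  expect_equal(length(pr$components), 1)       # dominant direction suffices
  expect_gt(pr$mcc, 0.9)
  expect_error(pca_select(X, y, 1.5, folds, cfg), "\\(0, 1\\]")

  # cutoff 1.0 keeps every component before pruning
  pr_full <- pca_select(X, y, 1.0, folds, cfg)
  expect_equal(ncol(pr_full$rotation), ncol(X))
})

test_that("the selection grid evaluates every cell deterministically", {
  d <- make_xy(n = 50, d = 8, informative = 2, gap = 3, seed = 11)
  cfg <- selection_config(bcc_cutoffs = c(0.2, 0.4), pcc_cutoffs = c(0.7, 0.9),
                          pca_variance_cutoffs = c(0.5, 0.9),
                          C_grid = c(1, 4), gamma_grid = c(0.05, 0.5),
                          fold_seed = 3)
  res <- run_selection_grid(d$X, d$y, cfg, seed = 3)
  expect_equal(nrow(res$grid_table), 4)        # 2 x 2 correlation cells
  expect_equal(nrow(res$pca_table), 2)
  expect_true(all(res$selected_features %in% colnames(d$X)))
  expect_true(res$cv_mcc >= max(res$grid_table$mcc, na.rm = TRUE) - 1e-12)

  res2 <- run_selection_grid(d$X, d$y, cfg, seed = 3)
  expect_identical(res$grid_table, res2$grid_table)   # bit-reproducible
  expect_identical(res$selected_features, res2$selected_features)

  # selected set respects the winning cell's BCC cutoff
  ranked <- res$ranked
  min_bcc <- min(ranked$avg_bcc[ranked$feature %in% res$selected_features])
  expect_gte(min_bcc, res$best_cell$bcc_cutoff)

  # report writing round-trips
  path <- tempfile(fileext = ".tsv")
  manifest <- tempfile(fileext = ".txt")
  write_selection_report(res, path, manifest)
  expect_equal(readLines(manifest), res$selected_features)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 4)
})

test_that("selection cells can come up empty without crashing the grid", {
  set.seed(12)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), 20))
  cfg <- selection_config(bcc_cutoffs = c(0.1, 0.95), pcc_cutoffs = 0.9,
                          C_grid = 1, gamma_grid = 0.1, include_pca = FALSE)
  res <- run_selection_grid(X, y, cfg, seed = 1)
  expect_true(any(!res$grid_table$valid))      # 0.95 cell is empty
  expect_true(any(res$grid_table$valid))
})
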