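# PCA scoring, k-means validation of group separation, the forward subset
# search and PC1-correlation splitting.

make_separated_cm <- function(design, n_prot = 20, gap = 3, noise = 0.2,
                              seed = 1) {
  set.seed(seed)
  low <- design$group == "low"
  base <- outer(rep(1, n_prot), ifelse(low, gap, -gap))
  vals <- base + matrix(rnorm(n_prot * nrow(design), 0, noise),
                        nrow = n_prot)
  dimnames(vals) <- list(sprintf("P%03d", seq_len(n_prot)),
                         design$sample_id)
  as_complete(vals)
}

test_that("rank-one data put all variance on PC1", {
  design <- tiny_design()
  pattern <- seq(-2, 2, length.out = 12)
  vals <- outer(c(1, 2, -1, 0.5), pattern)
  dimnames(vals) <- list(sprintf("P%d", 1:4), design$sample_id)
  pca <- pca_scores(as_complete(vals), design)
  expect_equal(unname(pca$var_frac["PC1"]), 1, tolerance = 1e-9)
})

test_that("loadings are orthonormal and scores reproduce the data", {
  design <- tiny_design()
  set.seed(71)
  vals <- matrix(rnorm(20 * 12), nrow = 20,
                 dimnames = list(sprintf("P%02d", 1:20), design$sample_id))
  cm <- as_complete(vals)
  pca <- pca_scores(cm, design)
  L <- pca$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
  Xc <- sweep(t(vals), 2, pca$center)
  expect_equal(unname(Xc %*% L), unname(pca$scores), tolerance = 1e-9)
})

test_that("variance fractions match a covariance eigendecomposition", {
  design <- tiny_design()
  set.seed(72)
  vals <- matrix(rnorm(20 * 12), nrow = 20,
                 dimnames = list(sprintf("P%02d", 1:20), design$sample_id))
  pca <- pca_scores(as_complete(vals), design)
  want <- oracle_pca_var_frac(t(vals))
  expect_equal(unname(pca$var_frac), want[seq_along(pca$var_frac)],
               tolerance = 1e-9)
})

test_that("PC orientation is deterministic under protein permutation", {
  design <- tiny_design()
  set.seed(73)
  vals <- matrix(rnorm(30 * 12), nrow = 30,
                 dimnames = list(sprintf("P%02d", 1:30), design$sample_id))
  pca1 <- pca_scores(as_complete(vals), design)
  perm <- sample(30)
  pca2 <- pca_scores(as_complete(vals[perm, ]), design)
  expect_equal(pca1$scores, pca2$scores, tolerance = 1e-9)
  low <- design$group == "low"
  for (j in colnames(pca1$scores)) {
    expect_gte(mean(pca1$scores[low, j]), mean(pca1$scores[!low, j]) - 1e-12)
  }
  expect_error(pca_scores(as_complete(vals[, 1, drop = FALSE]),
                          design[1, ]), "2 samples")
})

test_that("k-means recovers separated groups and names the stray sample", {
  design <- tiny_design()
  low <- design$group == "low"
  set.seed(74)
  pts <- cbind(PC1 = ifelse(low, 3, -3) + rnorm(12, 0, 0.3),
               PC2 = rnorm(12, 0, 0.3))
  rownames(pts) <- design$sample_id
  km <- kmeans_validate(pts, design, dims = "PC1", seed = 2)
  expect_equal(km$accuracy, 1)
  expect_length(km$misclassified, 0)
  # move one low sample into the moderate cloud
  pts2 <- pts
  pts2["L03", "PC1"] <- -3
  km2 <- kmeans_validate(pts2, design, dims = "PC1", seed = 2)
  expect_equal(km2$accuracy, 11 / 12)
  expect_identical(km2$misclassified, "L03")
})

test_that("k-means matches the exhaustive 2-partition oracle", {
  design <- tiny_design()
  set.seed(75)
  for (rep in 1:8) {
    pts <- cbind(PC1 = rnorm(12, ifelse(design$group == "low", 1, -1)),
                 PC2 = rnorm(12))
    rownames(pts) <- design$sample_id
    km <- kmeans_validate(pts, design, dims = c("PC1", "PC2"),
                          restarts = 100, seed = rep)
    oracle <- oracle_best_2partition(pts)
    expect_equal(km$accuracy,
                 oracle_partition_accuracy(oracle$assign, design$group))
  }
})

test_that("coincident samples degrade gracefully", {
  design <- tiny_design(c(D = 2, E = 1))   # 3 low, 3 moderate
  pts <- matrix(0, nrow = 6, ncol = 2,
                dimnames = list(design$sample_id, c("PC1", "PC2")))
  expect_warning(km <- kmeans_validate(pts, design), "degenerate")
  expect_equal(km$accuracy, 0.5)
  expect_true(km$degenerate)
})

test_that("accuracy is invariant to sample order", {
  design <- tiny_design()
  set.seed(76)
  pts <- cbind(PC1 = rnorm(12, ifelse(design$group == "low", 2, -2)),
               PC2 = rnorm(12))
  rownames(pts) <- design$sample_id
  a <- kmeans_validate(pts, design, seed = 3)
  perm <- sample(12)
  b <- kmeans_validate(pts[perm, ], design, seed = 3)
  expect_equal(a$accuracy, b$accuracy)
  expect_setequal(a$misclassified, b$misclassified)
})

test_that("forward search reports candidates and is grid-order independent", {
  design <- tiny_design()
  cm <- make_separated_cm(design, n_prot = 40, seed = 77)
  det <- run_differential(cm, design)
  single <- forward_search(det, cm, design, size_grid = 40, seed = 5)
  expect_identical(single$metrics$n, 40L)
  expect_equal(single$metrics$accuracy_pc12, 1)
  expect_identical(single$n_star_full, 40L)
  up <- forward_search(det, cm, design, size_grid = c(10, 20, 40), seed = 5)
  down <- forward_search(det, cm, design, size_grid = c(40, 20, 10), seed = 5)
  expect_identical(up$metrics, down$metrics)
  expect_identical(up$members, down$members)
  expect_error(forward_search(det, cm, design, size_grid = integer(0)),
               "non-empty")
  expect_error(forward_search(det, cm, design, size_grid = 1000),
               "size_grid")
})

test_that("the forward search output is deterministic on null data", {
  cfg <- synth_config(n_proteins = 120, n_true_de = 0, seed = 18)
  ds <- generate_lfq_dataset(cfg)
  mat <- suppressMessages(filter_simple(ds$matrix, ds$design, 3))
  cm <- impute_downshift(log2_median_center(mat), seed = 18)
  det <- run_differential(cm, ds$design)
  s1 <- forward_search(det, cm, ds$design, size_grid = c(20, 50), seed = 18)
  s2 <- forward_search(det, cm, ds$design, size_grid = c(20, 50), seed = 18)
  expect_identical(s1$metrics, s2$metrics)
})

test_that("PC1 splitting assigns proteins by correlation sign", {
  design <- tiny_design()
  cm <- make_separated_cm(design, n_prot = 10, seed = 78)
  vals <- cm$values
  pca <- pca_scores(cm, design)
  pc1 <- pca$scores[, "PC1"]
  # craft proteins exactly equal to +/- the PC1 pattern and one flat
  vals <- rbind(vals,
                POS = pc1[colnames(vals)],
                NEG = -pc1[colnames(vals)],
                FLAT = rep(1, ncol(vals)))
  cm2 <- as_complete(vals)
  det <- data.frame(protein_id = rownames(vals),
                    p = 0.01, d = c(rep(1, 10), 1, -1, 0))
  class(det) <- c("de_table", "data.frame")
  expect_warning(sp <- split_by_pc1(det, pca$scores, cm2, p_cut = 0.1),
                 "FLAT")
  expect_true("POS" %in% sp$positive)
  expect_true("NEG" %in% sp$negative)
  expect_identical(sp$excluded, "FLAT")
  expect_equal(unname(sp$pc1_corr["POS"]), 1, tolerance = 1e-9)
  expect_equal(unname(sp$pc1_corr["NEG"]), -1, tolerance = 1e-9)
})

test_that("PC1 split recovers planted up and down regulation", {
  # differential proteins must stay a minority: median centering assumes
  # most of the proteome is unchanged, and an uncorrected p <= 0.1 cut
  # admits ~10% of null proteins into the lists, so the check is on the
  # planted proteins recovered and the side they land on
  up_in_pos <- down_in_neg <- up_rec <- down_rec <- numeric(10)
  for (i in 1:10) {
    cfg <- synth_config(n_proteins = 1000, n_true_de = 150,
                        n_true_de_down = 50, effect_size = 2,
                        noise_sd = 0.5, mcar_rate = 0, seed = 500 + i)
    ds <- generate_lfq_dataset(cfg)
    mat <- suppressMessages(filter_simple(ds$matrix, ds$design, 3))
    cm <- impute_downshift(log2_median_center(mat), seed = i)
    det <- run_differential(cm, ds$design)
    pca <- pca_scores(cm, ds$design, proteins = det$protein_id)
    sp <- split_by_pc1(det, pca$scores, cm, p_cut = 0.1)
    eff <- ds$truth$true_effects
    up <- names(eff)[eff > 0]
    down <- names(eff)[eff < 0]
    in_lists <- c(sp$positive, sp$negative)
    up_rec[i] <- sum(up %in% in_lists)
    down_rec[i] <- sum(down %in% in_lists)
    up_in_pos[i] <- sum(up %in% sp$positive)
    down_in_neg[i] <- sum(down %in% sp$negative)
  }
  # recovered planted proteins land on the correct side of PC1 (within 10%)
  expect_gte(sum(up_in_pos) / sum(up_rec), 0.9)
  expect_gte(sum(down_in_neg) / sum(down_rec), 0.9)
  # and the planted set as a whole is recovered; down-regulated proteins
  # sit lower on the intensity scale, so MNAR dropout erodes them slightly
  # more than the up-regulated ones
  expect_gte(mean(up_rec + down_rec) / 150, 0.9)
})
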