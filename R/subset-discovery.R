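# Forward search over p-value-ranked protein subsets: PCA of the samples on
# each candidate subset, k-means (k = 2) validation of humidity-group
# separation in PC space, and splitting of selected proteins by the sign of
# their correlation with PC1.

#' PCA of samples on a protein subset
#'
#' Samples are observations and proteins variables; variables are centered
#' but not variance-scaled (the data are already log2 and median-centered).
#' Each principal component is sign-oriented so that the mean score of the
#' low-humidity group is at least that of the moderate group, which makes
#' downstream correlation signs deterministic.
#'
#' @param cm a `complete_matrix`.
#' @param design a [sample_design()].
#' @param proteins optional character vector restricting the matrix to a
#'   protein subset (default: all proteins).
#' @param scale_proteins if `TRUE`, variables are also scaled to unit
#'   variance before decomposition.
#' @return list with `scores` (samples x PCs), `loadings` (proteins x PCs,
#'   orthonormal columns), `var_frac` (fraction of variance per PC) and
#'   `center` (per-protein means removed).
#' @export
pca_scores <- function(cm, design, proteins = NULL, scale_proteins = FALSE) {
  stopifnot(inherits(cm, "complete_matrix"))
  vals <- cm$values
  if (!is.null(proteins)) {
    missing_p <- setdiff(proteins, rownames(vals))
    if (length(missing_p)) {
      stop("unknown protein id(s): ", paste(missing_p, collapse = ", "))
    }
    vals <- vals[proteins, , drop = FALSE]
  }
  if (ncol(vals) < 2) stop("PCA requires at least 2 samples")
  if (nrow(vals) < 1) stop("PCA requires at least 1 protein")
  design <- align_design(design, colnames(vals))
  X <- t(vals)                       # samples x proteins
  pr <- prcomp(X, center = TRUE, scale. = scale_proteins)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x
  loadings <- pr$rotation
  low <- design$group == "low"
  for (j in seq_len(ncol(scores))) {
    if (mean(scores[low, j]) < mean(scores[!low, j])) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       var_frac = setNames(var_frac, colnames(scores)),
       center = pr$center)
}

#' Validate group separation by k-means (k = 2)
#'
#' Clusters the sample scores on the selected principal components with
#' k-means (k = 2, Euclidean, best of `restarts` seeded initialisations by
#' within-cluster sum of squares) and measures agreement with the humidity
#' groups as the best accuracy over the two cluster-to-group label
#' assignments.
#'
#' @param scores samples x PCs score matrix (rownames = sample ids).
#' @param design a [sample_design()].
#' @param dims character vector of score columns to use (e.g. `"PC1"` or
#'   `c("PC1", "PC2")`).
#' @param restarts number of random initialisations.
#' @param seed integer master seed (a k-means substream is derived from it).
#' @return list with `accuracy` (fraction of samples matched),
#'   `misclassified` (sample ids under the best assignment) and `degenerate`
#'   (`TRUE` when fewer than two distinct points were available).
#' @export
kmeans_validate <- function(scores, design, dims = c("PC1", "PC2"),
                            restarts = 50, seed = 1L) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  design <- align_design(design, rownames(scores))
  if (nrow(scores) < 2) stop("k = 2 exceeds the sample count")
  missing_d <- setdiff(dims, colnames(scores))
  if (length(missing_d)) {
    stop("score matrix lacks dimension(s): ",
         paste(missing_d, collapse = ", "))
  }
  pts <- scores[, dims, drop = FALSE]
  grp <- design$group
  if (nrow(unique(pts)) < 2) {
    warning("all samples coincide in the selected dimensions; ",
            "k-means clustering is degenerate")
    maj <- names(which.max(table(grp)))[1]
    return(list(accuracy = max(table(grp)) / length(grp),
                misclassified = rownames(pts)[grp != maj],
                degenerate = TRUE))
  }
  set.seed(derive_seed(seed, "kmeans"))
  km <- kmeans(pts, centers = 2, nstart = restarts, iter.max = 100)
  cl <- km$cluster
  acc1 <- mean((cl == 1) == (grp == "low"))
  acc2 <- mean((cl == 2) == (grp == "low"))
  if (acc1 >= acc2) {
    mis <- rownames(pts)[(cl == 1) != (grp == "low")]
    acc <- acc1
  } else {
    mis <- rownames(pts)[(cl == 2) != (grp == "low")]
    acc <- acc2
  }
  list(accuracy = acc, misclassified = mis, degenerate = FALSE)
}

#' Forward search for the largest discriminating protein subset
#'
#' For each candidate size `N`, the top-`N` proteins by ascending p-value
#' are analysed by [pca_scores()] and the sample scores are clustered by
#' [kmeans_validate()] on PC1 alone and on (PC1, PC2).  The result records
#' the largest `N` whose (PC1, PC2) clustering reproduces the humidity
#' groups perfectly.
#'
#' @param det a `de_table` from [run_differential()].
#' @param cm the `complete_matrix` the table was computed from.
#' @param design a [sample_design()].
#' @param size_grid integer vector of candidate subset sizes (each in
#'   `[2, nrow(det)]`); the result is independent of its order.
#' @param restarts,seed passed to [kmeans_validate()].
#' @return object of class `subset_search` with `metrics` (one row per `N`:
#'   `n`, `pc1_var`, `pc2_var`, `accuracy_pc1`, `accuracy_pc12`,
#'   `misclassified_pc1`, `misclassified_pc12`), `n_star_full` (largest `N`
#'   with perfect (PC1, PC2) accuracy, `NA` if none) and `members`
#'   (protein ids of the `n_star_full` subset).
#' @export
forward_search <- function(det, cm, design, size_grid = NULL,
                           restarts = 50, seed = 1L) {
  stopifnot(inherits(cm, "complete_matrix"))
  n_total <- nrow(det)
  if (is.null(size_grid)) {
    size_grid <- unique(sort(c(seq(10, n_total, by = 10), 95, 515, n_total)))
    size_grid <- size_grid[size_grid >= 2 & size_grid <= n_total]
  }
  size_grid <- unique(sort(as.integer(size_grid)))
  if (length(size_grid) == 0) stop("size_grid must be non-empty")
  if (any(size_grid < 2 | size_grid > n_total)) {
    stop("size_grid values must lie in [2, ", n_total, "]")
  }
  det_sorted <- det[order(det$rank), , drop = FALSE]
  rows <- lapply(size_grid, function(N) {
    prot <- det_sorted$protein_id[seq_len(N)]
    pca <- pca_scores(cm, design, proteins = prot)
    dims2 <- if ("PC2" %in% colnames(pca$scores)) c("PC1", "PC2") else "PC1"
    k1 <- kmeans_validate(pca$scores, design, dims = "PC1",
                          restarts = restarts, seed = seed)
    k12 <- kmeans_validate(pca$scores, design, dims = dims2,
                           restarts = restarts, seed = seed)
    data.frame(n = N,
               pc1_var = unname(pca$var_frac["PC1"]),
               pc2_var = if ("PC2" %in% names(pca$var_frac)) {
                 unname(pca$var_frac["PC2"])
               } else 0,
               accuracy_pc1 = k1$accuracy,
               accuracy_pc12 = k12$accuracy,
               misclassified_pc1 = paste(k1$misclassified, collapse = ";"),
               misclassified_pc12 = paste(k12$misclassified, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  perfect <- metrics$n[metrics$accuracy_pc12 == 1]
  n_star <- if (length(perfect)) max(perfect) else NA_integer_
  members <- if (!is.na(n_star)) {
    det_sorted$protein_id[seq_len(n_star)]
  } else character(0)
  structure(list(metrics = metrics, n_star_full = n_star, members = members,
                 size_grid = size_grid),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat("<subset_search> ", nrow(x$metrics), " candidate sizes; ",
      "largest perfectly separating subset: ",
      if (is.na(x$n_star_full)) "none" else x$n_star_full, "\n", sep = "")
  invisible(x)
}

#' Split selected proteins by their correlation with PC1
#'
#' Proteins passing the p-value cut are split into a positive and a negative
#' group by the sign of the Pearson correlation between their expression
#' vector and the (orientation-normalised) PC1 sample scores.  With the PC
#' orientation convention of [pca_scores()], the correlation sign agrees
#' with the sign of the mean difference except near zero; disagreements are
#' reported via `message()`.
#'
#' @param det a `de_table`.
#' @param scores score matrix from [pca_scores()] (must contain `"PC1"`).
#' @param cm the `complete_matrix`.
#' @param p_cut inclusive p-value threshold (default `0.1`).
#' @return list with `positive` and `negative` protein id vectors, the
#'   per-protein correlations `pc1_corr` (named, for all selected proteins)
#'   and `excluded` (zero-variance proteins, dropped with a warning).
#' @export
split_by_pc1 <- function(det, scores, cm, p_cut = 0.1) {
  stopifnot(inherits(cm, "complete_matrix"), "PC1" %in% colnames(scores))
  sel <- det$protein_id[det$p <= p_cut]
  pc1 <- scores[, "PC1"]
  vals <- cm$values[, rownames(scores), drop = FALSE]
  corr <- vapply(sel, function(pid) {
    v <- vals[pid, ]
    if (sd(v) == 0) NA_real_ else cor(v, pc1)
  }, numeric(1))
  excluded <- sel[is.na(corr)]
  if (length(excluded)) {
    warning("zero-variance protein(s) excluded from PC1 split: ",
            paste(excluded, collapse = ", "))
  }
  keep <- !is.na(corr)
  sel_k <- sel[keep]
  corr_k <- corr[keep]
  d_sign <- sign(det$d[match(sel_k, det$protein_id)])
  disagree <- sel_k[sign(corr_k) != d_sign & corr_k != 0 & d_sign != 0]
  if (length(disagree)) {
    message("PC1 correlation sign disagrees with mean-difference sign for ",
            length(disagree), " protein(s): ",
            paste(head(disagree, 10), collapse = ", "))
  }
  list(positive = sel_k[corr_k > 0],
       negative = sel_k[corr_k < 0],
       pc1_corr = setNames(corr_k, sel_k),
       excluded = excluded)
}
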