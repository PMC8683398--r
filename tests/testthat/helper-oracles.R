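# Independent oracles used to cross-check the implementation.  Each is a
# deliberately naive, closed-form or exhaustive computation kept separate
# from the package code paths it validates.

# Nested-loop valid-value counter.
oracle_valid_counts <- function(x, design, subset_ids = NULL) {
  n <- nrow(x$intensities)
  out <- data.frame(protein_id = x$annotations$protein_id,
                    n_valid_low = integer(n), n_valid_moderate = integer(n),
                    sub_low = integer(n), sub_moderate = integer(n))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(x$intensities))) {
      sid <- colnames(x$intensities)[j]
      g <- design$group[design$sample_id == sid]
      if (x$intensities[i, j] > 0) {
        col <- paste0("n_valid_", g)
        out[i, col] <- out[i, col] + 1L
        if (!is.null(subset_ids) && sid %in% subset_ids) {
          col <- paste0("sub_", g)
          out[i, col] <- out[i, col] + 1L
        }
      }
    }
  }
  out
}

# Per-protein brute-force application of the simple / compound filter rules.
oracle_filter_simple <- function(x, design, k) {
  cnt <- oracle_valid_counts(x, design)
  cnt$protein_id[cnt$n_valid_low >= k | cnt$n_valid_moderate >= k]
}

oracle_filter_compound <- function(x, design, k_main, k_sub, subset_ids) {
  cnt <- oracle_valid_counts(x, design, subset_ids)
  keep <- (cnt$n_valid_low >= k_main | cnt$n_valid_moderate >= k_main) &
    (cnt$sub_low >= k_sub | cnt$sub_moderate >= k_sub)
  cnt$protein_id[keep]
}

# Textbook Welch formulas, coded independently of stats::t.test.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se <- sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  d <- mean(x) - mean(y)
  tstat <- d / se
  p <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(0.975, df)
  list(p = p, d = d, lcl = d - tcrit * se, ucl = d + tcrit * se)
}

# Eigendecomposition of the sample covariance (samples x variables input).
oracle_pca_var_frac <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

# Exhaustive optimal 2-partition by within-cluster sum of squares.
oracle_best_2partition <- function(pts) {
  n <- nrow(pts)
  best <- NULL
  best_wcss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {       # sample 1 fixed in cluster 0
    assign <- c(0, as.integer(intToBits(code))[1:(n - 1)])
    wcss <- 0
    for (cl in 0:1) {
      sub <- pts[assign == cl, , drop = FALSE]
      if (nrow(sub) == 0) { wcss <- Inf; break }
      ctr <- colMeans(sub)
      wcss <- wcss + sum(sweep(sub, 2, ctr)^2)
    }
    if (wcss < best_wcss) { best_wcss <- wcss; best <- assign }
  }
  list(assign = best, wcss = best_wcss)
}

oracle_partition_accuracy <- function(assign, groups) {
  is_low <- groups == "low"
  max(mean((assign == 0) == is_low), mean((assign == 1) == is_low))
}

# Maximal antichain under set inclusion by pairwise comparison.
oracle_antichain <- function(map) {
  sets <- unique(unname(lapply(map, function(g) sort(unique(g)))))
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  res <- sets[keep]
  res[order(vapply(res, paste, character(1), collapse = "\r"))]
}

canonical_setlist <- function(sets) {
  sets <- unname(lapply(sets, function(g) sort(unique(g))))
  sets[order(vapply(sets, paste, character(1), collapse = "\r"))]
}

# Exact two-sided rank-sum p-value by full enumeration of group splits.
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  splits <- combn(length(pooled), nx)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- nx * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
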