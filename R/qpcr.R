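# RT-qPCR relative quantification by the 2^(-DeltaDeltaCt) method with
# endogenous-control normalization, iterative two-tailed Grubbs outlier
# screening, the signed fold-change convention, and Wilcoxon rank-sum group
# comparisons.

#' Signed fold change
#'
#' Maps an expression ratio to the symmetric reporting convention: a ratio
#' `r >= 1` is reported as `r`, a ratio below one as `-1/r`, so up- and
#' down-regulation have comparable magnitudes (e.g. `1/1.8 -> -1.8`).
#'
#' @param ratio positive numeric vector of expression ratios.
#' @return signed fold changes (same length).
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("ratios must be finite and > 0")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

# Two-sided Grubbs critical value at level alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Two-tailed Grubbs outlier screening
#'
#' Iteratively applies the two-sided Grubbs test: the observation with the
#' largest absolute deviation from the mean is flagged when
#' `G = max|x - mean| / sd` exceeds the t-based critical value at level
#' `alpha`; at most one value is flagged per iteration and the statistic is
#' recomputed on the reduced set until no value is flagged or fewer than
#' three values remain.
#'
#' @param values numeric vector (length >= 3).
#' @param alpha significance level of each Grubbs test.
#' @return integer indices (into `values`) of the flagged outliers, in
#'   removal order; `integer(0)` when none (including the zero-variance
#'   case).
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("Grubbs test requires at least 3 values")
  stopifnot(is.numeric(values), all(is.finite(values)))
  idx <- seq_along(values)
  flagged <- integer(0)
  repeat {
    if (length(idx) < 3) break
    x <- values[idx]
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    if (G <= grubbs_critical(length(x), alpha)) break
    worst <- idx[which.max(dev)]
    flagged <- c(flagged, worst)
    idx <- setdiff(idx, worst)
  }
  flagged
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact enumeration is used when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return the two-sided p-value.
#' @export
wilcoxon_compare <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  unname(ht$p.value)
}

#' Relative quantification by 2^(-DeltaDeltaCt)
#'
#' For every row, `delta_ct = ct_target - ct_reference`; each sample's
#' `delta_delta_ct` subtracts the mean `delta_ct` of the reference
#' (moderate-humidity) group for the same gene, and the relative quantity is
#' `rq = 2^(-delta_delta_ct)`, so the reference group is standardized to 1
#' in expectation.  Outliers are screened per gene within each humidity
#' group by [grubbs_outliers()] (on `rq` by default) before group summaries
#' and the Wilcoxon comparison.
#'
#' @param table data frame with columns `sample_id`, `group`, `gene`,
#'   `ct_target`, `ct_reference` (one row per sample and gene; `group` in
#'   `{"low", "moderate"}`).
#' @param reference_group group whose mean delta-Ct anchors the scale.
#' @param grubbs_alpha level of each Grubbs test; `NA` disables screening.
#' @param screen_on `"rq"` (default) or `"delta_ct"`: the scale on which
#'   outliers are screened.
#' @return list with `per_sample` (input rows plus `delta_ct`,
#'   `delta_delta_ct`, `rq`, `outlier`) and `per_gene` (per gene:
#'   `mean_rq_low`, `sem_low`, `mean_rq_moderate`, `sem_moderate`,
#'   `fold_change` — the signed fold change of the low-group mean rq —
#'   `p_wilcoxon`, `n_outliers_removed`, `outlier_samples`).
#' @export
relative_quantification <- function(table, reference_group = "moderate",
                                    grubbs_alpha = 0.05,
                                    screen_on = c("rq", "delta_ct")) {
  screen_on <- match.arg(screen_on)
  required <- c("sample_id", "group", "gene", "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("qPCR table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(table[, c("sample_id", "gene")])) {
    stop("qPCR table must have one row per (sample, gene)")
  }
  bad_ct <- !is.finite(table$ct_target) | !is.finite(table$ct_reference) |
    table$ct_target <= 0 | table$ct_reference <= 0 |
    table$ct_target > 40 | table$ct_reference > 40
  if (any(bad_ct)) {
    stop("Ct values must lie in (0, 40]; offending row(s): ",
         paste(which(bad_ct), collapse = ", "))
  }
  tab <- table
  tab$delta_ct <- tab$ct_target - tab$ct_reference
  tab$delta_delta_ct <- NA_real_
  tab$rq <- NA_real_
  tab$outlier <- FALSE

  genes <- unique(tab$gene)
  per_gene <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    rows <- which(tab$gene == g)
    ref_rows <- rows[tab$group[rows] == reference_group]
    if (length(ref_rows) == 0) {
      stop("no ", reference_group, "-group samples for gene: ", g)
    }
    ref_mean <- mean(tab$delta_ct[ref_rows])
    tab$delta_delta_ct[rows] <- tab$delta_ct[rows] - ref_mean
    tab$rq[rows] <- 2^(-tab$delta_delta_ct[rows])

    out_rows <- integer(0)
    if (!is.na(grubbs_alpha)) {
      for (grp in unique(tab$group[rows])) {
        grp_rows <- rows[tab$group[rows] == grp]
        if (length(grp_rows) < 3) next
        vals <- switch(screen_on,
                       rq = tab$rq[grp_rows],
                       delta_ct = tab$delta_ct[grp_rows])
        out_rows <- c(out_rows, grp_rows[grubbs_outliers(vals, grubbs_alpha)])
      }
    }
    tab$outlier[out_rows] <- TRUE

    kept <- setdiff(rows, out_rows)
    rq_low <- tab$rq[kept][tab$group[kept] == "low"]
    rq_mod <- tab$rq[kept][tab$group[kept] == reference_group]
    sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    per_gene[[gi]] <- data.frame(
      gene = g,
      mean_rq_low = mean(rq_low),
      sem_low = sem(rq_low),
      mean_rq_moderate = mean(rq_mod),
      sem_moderate = sem(rq_mod),
      fold_change = signed_fold_change(mean(rq_low)),
      p_wilcoxon = if (length(rq_low) >= 1 && length(rq_mod) >= 1) {
        wilcoxon_compare(rq_low, rq_mod)
      } else NA_real_,
      n_outliers_removed = length(out_rows),
      outlier_samples = paste(tab$sample_id[out_rows], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(per_sample = tab, per_gene = do.call(rbind, per_gene))
}
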