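# Per-protein Welch tests on the complete (imputed) matrix, with mean
# differences on the log2 scale (low minus moderate, so positive values mean
# increased abundance under low humidity), 95% confidence intervals,
# ascending-p ranking and threshold summaries.  P-values are reported
# uncorrected; a Benjamini-Hochberg column is provided for reference but is
# never used in downstream selection.

#' Welch's two-sample t-test with mean difference and 95% CI
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `p` (two-sided), `d = mean(x) - mean(y)`, and the 95%
#'   confidence bounds `lcl`, `ucl` based on the Welch-Satterthwaite degrees
#'   of freedom.  When both groups have zero variance the limit behaviour is
#'   used (`p = 1` if `d = 0`, else `p = 0`) with a degenerate CI at `d`,
#'   and a warning is raised.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values for a Welch test")
  }
  d <- mean(x) - mean(y)
  if (var(x) == 0 && var(y) == 0) {
    warning("both groups have zero variance; using limit p-value")
    p <- if (d == 0) 1 else 0
    return(list(p = p, d = d, lcl = d, ucl = d))
  }
  ht <- t.test(x, y, var.equal = FALSE, conf.level = 0.95)
  list(p = unname(ht$p.value), d = d,
       lcl = unname(ht$conf.int[1]), ucl = unname(ht$conf.int[2]))
}

#' Per-protein differential expression table
#'
#' Runs [welch_test()] on every protein of a complete matrix, comparing the
#' low-humidity group against the moderate-humidity group, and returns the
#' records sorted by ascending p-value (ties broken by larger `|d|` first,
#' then protein id) with a contiguous `rank` column.
#'
#' @param cm a `complete_matrix` from [impute_downshift()].
#' @param design a [sample_design()] covering the matrix samples.
#' @param annotations optional annotation data frame (as in an
#'   [lfq_matrix()]) used to attach gene names.
#' @return a `de_table` data frame: `protein_id`, `gene_name`, `p`, `p_bh`,
#'   `d`, `lcl`, `ucl`, `n_low`, `n_moderate`, `rank`.
#' @export
run_differential <- function(cm, design, annotations = NULL) {
  stopifnot(inherits(cm, "complete_matrix"))
  design <- align_design(design, colnames(cm$values))
  low <- design$group == "low"
  ids <- rownames(cm$values)
  res <- lapply(seq_along(ids), function(i) {
    welch_test(cm$values[i, low], cm$values[i, !low])
  })
  tab <- data.frame(
    protein_id = ids,
    gene_name = if (!is.null(annotations)) {
      annotations$gene_name[match(ids, annotations$protein_id)]
    } else NA_character_,
    p = vapply(res, `[[`, numeric(1), "p"),
    d = vapply(res, `[[`, numeric(1), "d"),
    lcl = vapply(res, `[[`, numeric(1), "lcl"),
    ucl = vapply(res, `[[`, numeric(1), "ucl"),
    n_low = sum(low), n_moderate = sum(!low),
    stringsAsFactors = FALSE)
  tab$p_bh <- p.adjust(tab$p, method = "BH")
  ord <- order(tab$p, -abs(tab$d), tab$protein_id, method = "radix")
  tab <- tab[ord, c("protein_id", "gene_name", "p", "p_bh", "d",
                    "lcl", "ucl", "n_low", "n_moderate")]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Threshold summary of a differential table
#'
#' Counts proteins at each p-value cut, split by the sign of the mean
#' difference, and additionally those meeting an absolute mean-difference
#' cut (`0.58` log2 units, i.e. a 1.5-fold change, by default).
#'
#' @param det a `de_table` from [run_differential()].
#' @param p_cuts numeric vector of inclusive p-value thresholds.
#' @param d_cut absolute log2 mean-difference threshold.
#' @return data frame with one row per p cut: `p_cut`, `n`, `n_up`,
#'   `n_down`, `n_up_fc`, `n_down_fc` (the `_fc` columns additionally
#'   require `|d| >= d_cut`).
#' @export
threshold_summary <- function(det, p_cuts = c(0.05, 0.1), d_cut = 0.58) {
  stopifnot(inherits(det, "de_table") || is.data.frame(det))
  do.call(rbind, lapply(p_cuts, function(cut) {
    sel <- det$p <= cut
    data.frame(p_cut = cut,
               n = sum(sel),
               n_up = sum(sel & det$d > 0),
               n_down = sum(sel & det$d < 0),
               n_up_fc = sum(sel & det$d >= d_cut),
               n_down_fc = sum(sel & det$d <= -d_cut))
  }))
}
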