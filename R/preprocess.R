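# Valid-value filtering, log2 transformation with per-sample median
# centering, and sample-wise downshifted-normal imputation of left-censored
# missing values.  A valid value is an LFQ intensity strictly greater than 0.

#' Count valid values per protein, per group and per subset
#'
#' @param x an [lfq_matrix()].
#' @param design a [sample_design()] covering every matrix sample.
#' @param subsets optional named list of subset definitions; each element is
#'   either a character vector of sample ids or a single experiment label
#'   (all samples of that experiment).  Counts are reported per
#'   (subset, group).
#' @return data frame with one row per protein: `protein_id`,
#'   `n_valid_low`, `n_valid_moderate`, and `n_valid_<subset>_<group>`
#'   columns for each requested subset.
#' @export
count_valid <- function(x, design, subsets = NULL) {
  stopifnot(inherits(x, "lfq_matrix"))
  design <- align_design(design, colnames(x$intensities))
  valid <- x$intensities > 0
  out <- data.frame(protein_id = x$annotations$protein_id,
                    stringsAsFactors = FALSE)
  for (g in c("low", "moderate")) {
    out[[paste0("n_valid_", g)]] <-
      as.integer(rowSums(valid[, design$group == g, drop = FALSE]))
  }
  for (nm in names(subsets)) {
    spec <- subsets[[nm]]
    if (length(spec) == 0) stop("subset '", nm, "' selects no samples")
    ids <- if (length(spec) == 1 && spec %in% design$experiment &&
               !spec %in% design$sample_id) {
      design$sample_id[design$experiment == spec]
    } else {
      unknown <- setdiff(spec, design$sample_id)
      if (length(unknown)) {
        stop("subset '", nm, "' references unknown sample(s): ",
             paste(unknown, collapse = ", "))
      }
      spec
    }
    if (length(ids) == 0) stop("subset '", nm, "' selects no samples")
    for (g in c("low", "moderate")) {
      sel <- design$sample_id %in% ids & design$group == g
      out[[paste0("n_valid_", nm, "_", g)]] <-
        as.integer(rowSums(valid[, sel, drop = FALSE]))
    }
  }
  out
}

#' Simple valid-value filter
#'
#' Retains proteins quantified in at least `k` samples of at least one
#' humidity group (the less conservative rule used when all samples come
#' from one experiment).
#'
#' @param x an [lfq_matrix()].
#' @param design a [sample_design()].
#' @param k minimum number of valid values required in some group (>= 1).
#' @return the filtered [lfq_matrix()].
#' @export
filter_simple <- function(x, design, k = 3) {
  if (!is.numeric(k) || k < 1) stop("k must be a count >= 1")
  counts <- count_valid(x, design)
  keep <- counts$n_valid_low >= k | counts$n_valid_moderate >= k
  log_msg("simple valid-value filter (k=", k, "): retained ", sum(keep),
          " of ", nrow(counts), " proteins")
  lfq_matrix(x$intensities[keep, , drop = FALSE],
             x$annotations[keep, , drop = FALSE])
}

#' Compound valid-value filter
#'
#' The conservative rule for a pooled dataset with an under-sampled subset:
#' a protein is retained when it has at least `k_main` valid values in at
#' least one humidity group overall AND at least `k_sub` valid values in at
#' least one humidity group within the `subset` samples (by default the
#' pilot experiment).
#'
#' @param x an [lfq_matrix()].
#' @param design a [sample_design()].
#' @param k_main minimum overall per-group valid count (>= 1).
#' @param k_sub minimum per-group valid count within the subset (>= 1).
#' @param subset experiment label or character vector of sample ids defining
#'   the subset; must select at least one sample.
#' @return the filtered [lfq_matrix()].
#' @export
filter_compound <- function(x, design, k_main = 5, k_sub = 2,
                            subset = "pilot") {
  if (!is.numeric(k_main) || k_main < 1 || !is.numeric(k_sub) || k_sub < 1) {
    stop("k_main and k_sub must be counts >= 1")
  }
  counts <- count_valid(x, design, subsets = list(sub = subset))
  keep <- (counts$n_valid_low >= k_main | counts$n_valid_moderate >= k_main) &
    (counts$n_valid_sub_low >= k_sub | counts$n_valid_sub_moderate >= k_sub)
  log_msg("compound valid-value filter (k_main=", k_main, ", k_sub=", k_sub,
          "): retained ", sum(keep), " of ", nrow(counts), " proteins")
  lfq_matrix(x$intensities[keep, , drop = FALSE],
             x$annotations[keep, , drop = FALSE])
}

#' Log2-transform and median-center an LFQ matrix
#'
#' Observed intensities (`> 0`) are log2-transformed and the per-sample
#' median of the observed log2 values is subtracted (lower-median convention
#' for even counts, computed on observed values only).  Zeros become
#' explicit missing values.
#'
#' @param x an [lfq_matrix()].
#' @return a `norm_matrix` with `values` (centered log2, `NA` = missing) and
#'   the per-sample centering `offsets`.
#' @export
log2_median_center <- function(x) {
  stopifnot(inherits(x, "lfq_matrix"))
  vals <- x$intensities
  vals[vals == 0] <- NA
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("internal error: observed intensity <= 0 after missing-value masking")
  }
  lv <- log2(vals)
  offsets <- apply(lv, 2, lower_median)
  centered <- sweep(lv, 2, offsets, `-`)
  norm_matrix(centered, setNames(offsets, colnames(lv)))
}

#' Sample-wise downshifted-normal imputation
#'
#' For each sample, missing entries are replaced by draws from
#' `Normal(m - shift * s, (width * s)^2)` where `m` and `s` are the mean and
#' SD of that sample's observed (centered log2) values.  This models
#' left-censoring: values missing because the protein fell below the
#' detection limit are assigned plausibly low abundances.  The defaults
#' (`shift = 1.8` SD, `width = 0.3` SD) follow the Perseus convention for
#' downshifted-normal imputation.
#'
#' @param nm a `norm_matrix` from [log2_median_center()].
#' @param width imputation width as a fraction of the sample SD.
#' @param shift downshift in sample SDs.
#' @param seed integer master seed; per-sample substreams are derived from
#'   it by hashing the sample id, so sample order does not change draws.
#' @return a `complete_matrix` (values plus a logical `imputed` mask).
#' @export
impute_downshift <- function(nm, width = 0.3, shift = 1.8, seed = 1L) {
  stopifnot(inherits(nm, "norm_matrix"))
  vals <- nm$values
  imputed <- is.na(vals)
  for (s in colnames(vals)) {
    obs <- vals[!imputed[, s], s]
    if (length(obs) < 2) {
      stop("sample '", s, "' has fewer than 2 observed values; ",
           "cannot estimate an imputation distribution")
    }
    n_miss <- sum(imputed[, s])
    if (n_miss == 0) next
    m <- mean(obs)
    sdev <- sd(obs)
    set.seed(derive_seed(seed, paste0("impute:", s)))
    vals[imputed[, s], s] <- rnorm(n_miss, m - shift * sdev, width * sdev)
  }
  complete_matrix(vals, imputed)
}
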