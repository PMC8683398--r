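# Shared fixtures: tiny matrices and designs built in code.

tiny_annotations <- function(ids, genes = NULL) {
  data.frame(protein_id = ids,
             fasta_header = paste0("sp|", ids, "|TEST"),
             gene_name = genes %||% paste0("G_", ids),
             unique_peptides = 2L, msms_count = 4L,
             contaminant = FALSE, reverse = FALSE, only_site = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n_per_group samples per humidity group over the named cohorts
# (samples per group per cohort); pilot_cohort marks one cohort as pilot.
tiny_design <- function(cohorts = c(D = 3, E = 3), pilot_cohort = NULL) {
  npg <- sum(cohorts)
  cohort_of <- rep(names(cohorts), cohorts)
  exp_of <- ifelse(cohort_of %in% pilot_cohort, "pilot", "comprehensive")
  sample_design(data.frame(
    sample_id = c(sprintf("L%02d", 1:npg), sprintf("M%02d", 1:npg)),
    group = rep(c("low", "moderate"), each = npg),
    cohort = c(cohort_of, cohort_of),
    experiment = c(exp_of, exp_of),
    stringsAsFactors = FALSE))
}

# lfq_matrix with given intensities (proteins x samples).
tiny_lfq <- function(intensities, ids = NULL) {
  ids <- ids %||% sprintf("P%03d", seq_len(nrow(intensities)))
  lfq_matrix(intensities, tiny_annotations(ids))
}

# A complete_matrix built directly from a numeric matrix (no imputation).
as_complete <- function(values) {
  lfqdiscover:::complete_matrix(values,
                                matrix(FALSE, nrow(values), ncol(values)))
}

# Random LFQ matrix with missingness, for filter/count oracles.
random_lfq <- function(n_prot, design, miss_rate = 0.3) {
  n_s <- nrow(design)
  m <- matrix(2^rnorm(n_prot * n_s, 25, 2), nrow = n_prot,
              dimnames = list(NULL, design$sample_id))
  m[runif(length(m)) < miss_rate] <- 0
  tiny_lfq(m)
}
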