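# Core containers.  The package follows the matrix-plus-annotation idiom of
# expression analysis: an `lfq_matrix` couples a proteins x samples intensity
# matrix (0 encodes "not quantified") with per-protein identification
# metadata; downstream stages wrap log2-centered (`norm_matrix`) and imputed
# (`complete_matrix`) views that preserve the missingness provenance.

#' Construct an LFQ matrix object
#'
#' @param intensities numeric matrix, proteins in rows (rownames = protein
#'   ids), samples in columns (colnames = sample ids).  All values must be
#'   `>= 0`; `0` encodes a missing (not quantified) value.
#' @param annotations data frame with one row per protein carrying columns
#'   `protein_id`, `fasta_header`, `gene_name`, `unique_peptides`,
#'   `msms_count`, `contaminant`, `reverse`, `only_site`.
#' @return an object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(intensities, annotations) {
  stopifnot(is.matrix(intensities), is.numeric(intensities),
            is.data.frame(annotations))
  required <- c("protein_id", "fasta_header", "gene_name", "unique_peptides",
                "msms_count", "contaminant", "reverse", "only_site")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols)) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(annotations) != nrow(intensities)) {
    stop("annotations and intensity matrix disagree on protein count")
  }
  ids <- as.character(annotations$protein_id)
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(intensities < 0, na.rm = TRUE) || anyNA(intensities)) {
    stop("intensities must be finite and >= 0 (0 encodes missing)")
  }
  if (is.null(colnames(intensities))) {
    stop("intensity matrix must carry sample ids as column names")
  }
  rownames(intensities) <- ids
  rownames(annotations) <- NULL
  structure(list(intensities = intensities, annotations = annotations),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat("<lfq_matrix> ", nrow(x$intensities), " proteins x ",
      ncol(x$intensities), " samples; ",
      sum(x$intensities == 0), " missing (LFQ = 0) entries\n", sep = "")
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$intensities)

#' Subset an LFQ matrix by protein id
#' @param x an `lfq_matrix`.
#' @param proteins character vector of protein ids to retain (order kept).
#' @return the restricted `lfq_matrix`.
#' @keywords internal
subset_proteins <- function(x, proteins) {
  stopifnot(inherits(x, "lfq_matrix"))
  keep <- match(proteins, x$annotations$protein_id)
  if (anyNA(keep)) {
    stop("unknown protein id(s): ",
         paste(proteins[is.na(keep)], collapse = ", "))
  }
  lfq_matrix(x$intensities[keep, , drop = FALSE],
             x$annotations[keep, , drop = FALSE])
}

#' Validate a sample design table
#'
#' A design assigns every sample to a humidity `group` (`"low"` or
#' `"moderate"`), an exposure `cohort` (a letter), and an `experiment`
#' (`"pilot"`, `"comprehensive"`, or another label).
#'
#' @param design data frame with columns `sample_id`, `group`, `cohort`,
#'   `experiment`.
#' @return the validated design (character columns, class `sample_design`
#'   prepended).
#' @export
sample_design <- function(design) {
  stopifnot(is.data.frame(design))
  required <- c("sample_id", "group", "cohort", "experiment")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  design <- as.data.frame(lapply(design[required], as.character),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample ids in design")
  }
  bad <- setdiff(unique(design$group), c("low", "moderate"))
  if (length(bad)) {
    stop("group labels must be 'low' or 'moderate'; found: ",
         paste(bad, collapse = ", "))
  }
  if (!all(c("low", "moderate") %in% design$group)) {
    stop("both humidity groups must be non-empty")
  }
  class(design) <- c("sample_design", "data.frame")
  design
}

# Check that a design covers exactly the samples of a matrix (by column name)
# and return it ordered to match the matrix columns.
align_design <- function(design, sample_ids) {
  design <- sample_design(design)
  missing_samples <- setdiff(sample_ids, design$sample_id)
  if (length(missing_samples)) {
    stop("design lacks sample(s): ", paste(missing_samples, collapse = ", "))
  }
  design[match(sample_ids, design$sample_id), , drop = FALSE]
}

#' Construct a normalized (log2, median-centered) matrix view
#' @param values numeric matrix of centered log2 intensities, `NA` = missing.
#' @param offsets named numeric vector of per-sample centering offsets
#'   (the subtracted per-sample lower median of the log2 values).
#' @return object of class `norm_matrix`.
#' @keywords internal
norm_matrix <- function(values, offsets) {
  stopifnot(is.matrix(values), identical(names(offsets), colnames(values)))
  structure(list(values = values, offsets = offsets), class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("<norm_matrix> ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples; ", sum(is.na(x$values)), " missing entries\n", sep = "")
  invisible(x)
}

#' Construct a complete (imputed) matrix view
#' @param values numeric matrix with no missing entries.
#' @param imputed logical matrix of the same shape flagging imputed cells.
#' @return object of class `complete_matrix`.
#' @keywords internal
complete_matrix <- function(values, imputed) {
  stopifnot(is.matrix(values), is.logical(imputed),
            identical(dim(values), dim(imputed)), !anyNA(values))
  structure(list(values = values, imputed = imputed),
            class = "complete_matrix")
}

#' @export
print.complete_matrix <- function(x, ...) {
  cat("<complete_matrix> ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples; ", sum(x$imputed), " imputed entries\n", sep = "")
  invisible(x)
}
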