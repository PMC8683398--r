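# Reading and writing the MaxQuant proteinGroups dialect, the sample design
# table, and file-based protein-to-gene mappings, plus identification-level
# prefilters applied before any quantitative analysis.

pg_lfq_col <- function(sample_id) paste0("LFQ intensity ", sample_id)

parse_flag <- function(x) {
  if (is.null(x)) rep(FALSE, 0) else !is.na(x) & trimws(as.character(x)) == "+"
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Consumes the tab-delimited `proteinGroups.txt` produced by MaxQuant.
#' The protein id is taken as the first semicolon-separated accession of
#' "Majority protein IDs".  Contaminant/reverse flags follow the MaxQuant
#' `"+"` convention; if a flag column is absent the flag is treated as
#' all-false with a warning.
#'
#' @param path path to the tab-delimited file.
#' @param sample_ids character vector of samples to load; an
#'   `"LFQ intensity <sample>"` column must exist for each.
#' @return an [lfq_matrix()].
#' @export
read_protein_groups <- function(path, sample_ids) {
  stopifnot(length(sample_ids) >= 1)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = character(0))
  required <- c("Majority protein IDs", "Unique peptides", "MS/MS count",
                pg_lfq_col(sample_ids))
  absent <- setdiff(required, names(tab))
  if (length(absent)) {
    stop("proteinGroups file lacks required column(s): ",
         paste(sprintf('"%s"', absent), collapse = ", "))
  }
  for (flag_col in c("Potential contaminant", "Reverse",
                     "Only identified by site")) {
    if (!flag_col %in% names(tab)) {
      warning(sprintf('column "%s" absent; treating as all-false', flag_col))
      tab[[flag_col]] <- ""
    }
  }
  if (!"Fasta headers" %in% names(tab)) tab[["Fasta headers"]] <- ""
  if (!"Gene names" %in% names(tab)) tab[["Gene names"]] <- NA_character_

  ids <- vapply(strsplit(as.character(tab[["Majority protein IDs"]]), ";",
                         fixed = TRUE),
                function(x) trimws(x[[1]]), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) after taking first majority accession: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  num_col <- function(col) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(trimws(as.character(raw)) %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf('malformed numeric value(s) in "%s" at data row(s) %s',
                   col, paste(bad, collapse = ", ")))
    }
    val[is.na(val)] <- 0
    val
  }
  intens <- vapply(sample_ids, function(s) num_col(pg_lfq_col(s)),
                   numeric(nrow(tab)))
  intens <- matrix(intens, nrow = nrow(tab),
                   dimnames = list(NULL, sample_ids))

  gene <- as.character(tab[["Gene names"]])
  gene[trimws(gene) %in% c("", "NA")] <- NA_character_
  ann <- data.frame(
    protein_id = ids,
    fasta_header = as.character(tab[["Fasta headers"]]),
    gene_name = gene,
    unique_peptides = as.integer(num_col("Unique peptides")),
    msms_count = as.integer(num_col("MS/MS count")),
    contaminant = parse_flag(tab[["Potential contaminant"]]),
    reverse = parse_flag(tab[["Reverse"]]),
    only_site = parse_flag(tab[["Only identified by site"]]),
    stringsAsFactors = FALSE)
  lfq_matrix(intens, ann)
}

#' Write an LFQ matrix in the proteinGroups dialect
#'
#' @param x an [lfq_matrix()].
#' @param path output path (tab-delimited, UTF-8).
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) {
  stopifnot(inherits(x, "lfq_matrix"))
  ann <- x$annotations
  out <- data.frame(
    `Majority protein IDs` = ann$protein_id,
    `Fasta headers` = ann$fasta_header,
    `Gene names` = ifelse(is.na(ann$gene_name), "", ann$gene_name),
    `Unique peptides` = ann$unique_peptides,
    `MS/MS count` = ann$msms_count,
    `Potential contaminant` = ifelse(ann$contaminant, "+", ""),
    Reverse = ifelse(ann$reverse, "+", ""),
    `Only identified by site` = ifelse(ann$only_site, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(x$intensities)) {
    out[[pg_lfq_col(s)]] <- format(x$intensities[, s], digits = 15,
                                   scientific = FALSE, trim = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply identification-level prefilters
#'
#' Removes potential contaminants, reverse (decoy) hits, proteins without at
#' least one unique peptide, proteins with fewer than two MS/MS counts, and
#' proteins with no quantifiable peak (all LFQ values zero).  Rows flagged
#' "Only identified by site" are retained by default.
#'
#' @param x an [lfq_matrix()].
#' @param drop_only_site if `TRUE`, also drop rows flagged
#'   "Only identified by site".
#' @return the filtered [lfq_matrix()]; per-criterion removal counts are
#'   reported via [message()].
#' @export
apply_identification_filters <- function(x, drop_only_site = FALSE) {
  stopifnot(inherits(x, "lfq_matrix"))
  ann <- x$annotations
  crit <- list(
    contaminant = !ann$contaminant,
    reverse = !ann$reverse,
    unique_peptides = ann$unique_peptides >= 1L,
    msms_count = ann$msms_count >= 2L,
    quantified = rowSums(x$intensities > 0) >= 1L)
  if (drop_only_site) crit$only_site <- !ann$only_site
  keep <- Reduce(`&`, crit)
  removed <- vapply(crit, function(ok) sum(!ok), integer(1))
  log_msg("identification filters: ", sum(!keep), " of ", nrow(ann),
          " proteins removed (",
          paste(sprintf("%s=%d", names(removed), removed), collapse = ", "),
          ")")
  if (!any(keep)) warning("identification filters removed every protein")
  lfq_matrix(x$intensities[keep, , drop = FALSE],
             ann[keep, , drop = FALSE])
}

#' Read a protein-to-gene mapping file
#'
#' Two-column tab-delimited file with header `protein_id`, `gene_name`
#' (the offline replacement for an ID-mapping web service).  Proteins absent
#' from the file have no gene name and are excluded from gene-set-based
#' steps.
#'
#' @param path path to the mapping TSV.
#' @return named character vector (`protein_id -> gene_name`) with an
#'   `"unmapped"` attribute reserved for lookups (see
#'   [build_functional_subsets()]).
#' @export
read_gene_mapping <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty gene mapping file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (ncol(tab) < 2) stop("gene mapping must have two columns")
  names(tab)[1:2] <- c("protein_id", "gene_name")
  tab <- unique(tab[, c("protein_id", "gene_name")])
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  if (length(dup)) {
    stop("conflicting gene names for protein id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  setNames(as.character(tab$gene_name), as.character(tab$protein_id))
}

#' Read / write a sample design table
#'
#' Four-column TSV: `sample_id`, `group`, `cohort`, `experiment`.
#'
#' @param path path to the design TSV.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path) {
  sample_design(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_design
#' @param design a [sample_design()] (or coercible data frame).
#' @export
write_sample_design <- function(design, path) {
  design <- sample_design(design)
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
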