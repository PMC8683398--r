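# Consuming enrichment-tool exports (term -> gene sets), collapsing terms
# into their largest unique gene sets (a maximal antichain under set
# inclusion), assembling user-defined functional subsets, and scoring each
# subset's ability to separate the humidity groups.

canonical_set <- function(genes) {
  sort(unique(as.character(genes)), method = "radix")
}

#' Read / write GMT gene-set files
#'
#' @param path path to a GMT file (term id, description, tab-separated
#'   genes per line).
#' @return named list of character gene vectors with a `"description"`
#'   attribute (term id -> description).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- setNames(vapply(lines, function(x) x[2], character(1)),
                   vapply(lines, function(x) x[1], character(1)))
  attr(sets, "description") <- desc[names(sets)]
  sets
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, unname(desc[nm]), sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse enrichment terms into their largest unique gene sets
#'
#' Removes exact duplicates and absorbs any gene set that is a strict
#' subset of another, leaving the maximal sets only; partially overlapping,
#' non-nested sets are both kept.  The result is independent of input term
#' order: output sets are canonically ordered by decreasing size and then
#' lexicographically by content, and each is named after the first input
#' term (in that canonical order) whose gene set equals it.
#'
#' @param map named list of character gene vectors (term id -> genes), as
#'   from [read_gmt()] or [generate_term_gene_map()].
#' @return named list of maximal gene sets (sorted character vectors); the
#'   `"members"` attribute maps each output set to the input term ids whose
#'   gene sets it absorbed (nested terms are assigned to the first
#'   containing output set in canonical order).
#' @export
collapse_terms <- function(map) {
  if (length(map) == 0) stop("term-gene map must be non-empty")
  if (any(lengths(map) == 0)) stop("terms with empty gene sets are invalid")
  sets <- lapply(map, canonical_set)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  # canonical order: larger sets first, then lexicographic content, then id
  ord <- order(-lengths(sets), keys, names(sets), method = "radix")
  sets <- sets[ord]
  keys <- keys[ord]
  # drop duplicates (first occurrence in canonical order is representative)
  first <- !duplicated(keys)
  sets <- sets[first]
  # absorb strict subsets: a set survives iff no earlier (larger or equal
  # size, distinct) set contains it
  n <- length(sets)
  maximal <- rep(TRUE, n)
  for (i in seq_len(n)) {
    gi <- sets[[i]]
    for (j in seq_len(i - 1L)) {
      if (maximal[j] && length(sets[[j]]) > length(gi) &&
          all(gi %in% sets[[j]])) {
        maximal[i] <- FALSE
        break
      }
    }
  }
  out <- sets[maximal]
  # assign every input term to the first output set containing it
  members <- lapply(out, function(g) character(0))
  for (nm in names(map)) {
    g <- canonical_set(map[[nm]])
    for (k in seq_along(out)) {
      if (length(g) <= length(out[[k]]) && all(g %in% out[[k]])) {
        members[[k]] <- c(members[[k]], nm)
        break
      }
    }
  }
  attr(out, "members") <- members
  out
}

#' Assemble functional subsets from collapsed gene sets
#'
#' The grouping of collapsed sets into named functional subsets (chaperone
#' response, glutathione-related, ...) is a curation decision, so it is
#' supplied as configuration rather than inferred: a named list mapping each
#' subset name to the collapsed-set names it aggregates.
#'
#' @param collapsed output of [collapse_terms()].
#' @param grouping named list: subset name -> character vector of collapsed
#'   set names; referencing an unknown set is an error naming it.
#' @param mapping named character vector `protein_id -> gene_name` from
#'   [read_gene_mapping()]; genes without any protein mapping are reported,
#'   not dropped silently.
#' @return list of functional subsets, each a list with `name`, `genes`,
#'   `protein_ids` and `unmapped_genes`.
#' @export
build_functional_subsets <- function(collapsed, grouping, mapping) {
  if (length(grouping) == 0) {
    warning("empty grouping: no functional subsets defined")
    return(list())
  }
  unknown <- setdiff(unique(unlist(grouping)), names(collapsed))
  if (length(unknown)) {
    stop("grouping references unknown collapsed set(s): ",
         paste(unknown, collapse = ", "))
  }
  gene_to_prot <- split(names(mapping), unname(mapping))
  lapply(names(grouping), function(nm) {
    genes <- canonical_set(unlist(collapsed[grouping[[nm]]]))
    prot <- canonical_set(unlist(gene_to_prot[genes]))
    unmapped <- setdiff(genes, names(gene_to_prot))
    if (length(unmapped)) {
      log_msg("subset '", nm, "': ", length(unmapped),
              " gene(s) without protein mapping")
    }
    list(name = nm, genes = genes, protein_ids = prot,
         unmapped_genes = unmapped)
  })
}

#' Per-subset separation report
#'
#' For each functional subset, reports the quantities used to judge whether
#' the subset alone separates the humidity groups: member count (restricted
#' to proteins present in the matrix), number significant at `p <= 0.05`,
#' combined PC1 + PC2 variance fraction, and k-means accuracy on (PC1, PC2).
#' Subsets with fewer than two matrix proteins are marked not computable.
#'
#' @param subsets list of functional subsets from
#'   [build_functional_subsets()] (or any list of lists with `name` and
#'   `protein_ids`).
#' @param cm a `complete_matrix`.
#' @param design a [sample_design()].
#' @param det a `de_table`.
#' @param restarts,seed passed to [kmeans_validate()].
#' @param p_sig significance threshold for the member count.
#' @return data frame: `name`, `n_members`, `n_significant`,
#'   `var_pc12` (fraction), `accuracy_pc12`, `computable`.
#' @export
subset_separation_report <- function(subsets, cm, design, det,
                                     restarts = 50, seed = 1L,
                                     p_sig = 0.05) {
  stopifnot(inherits(cm, "complete_matrix"))
  rows <- lapply(subsets, function(ss) {
    prot <- intersect(ss$protein_ids, rownames(cm$values))
    n_sig <- sum(det$p[match(prot, det$protein_id)] <= p_sig, na.rm = TRUE)
    if (length(prot) < 2) {
      return(data.frame(name = ss$name, n_members = length(prot),
                        n_significant = n_sig, var_pc12 = NA_real_,
                        accuracy_pc12 = NA_real_, computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    pca <- pca_scores(cm, design, proteins = prot)
    dims <- intersect(c("PC1", "PC2"), colnames(pca$scores))
    km <- kmeans_validate(pca$scores, design, dims = dims,
                          restarts = restarts, seed = seed)
    var12 <- sum(pca$var_frac[dims])
    data.frame(name = ss$name, n_members = length(prot),
               n_significant = n_sig, var_pc12 = var12,
               accuracy_pc12 = km$accuracy, computable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
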