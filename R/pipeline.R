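# End-to-end orchestration of the two analysis arms:
#   analysis1 - pooled pilot + comprehensive cohorts, compound valid-value
#               filter; stops after the differential table (the arm used to
#               decide whether a pooled analysis is worthwhile);
#   analysis2 - comprehensive cohorts only, simple valid-value filter,
#               followed by the forward subset search, the PC1 split and
#               (optionally) enrichment-set collapsing with functional
#               subset separation reports.
# One master seed governs imputation and k-means restarts through named
# substreams; all tabular outputs are TSV and the run summary is JSON, with
# no clocks or absolute paths inside any output file so identical runs are
# byte-identical.

#' Assemble a run configuration
#'
#' @param matrix an [lfq_matrix()] or path to a proteinGroups-style TSV.
#' @param design a [sample_design()] or path to a design TSV.
#' @param mode `"analysis2"` (default) or `"analysis1"`.
#' @param sample_ids samples to load when `matrix` is a path (default: all
#'   design samples).
#' @param k,k_main,k_sub,subset valid-value filter parameters (see
#'   [filter_simple()] and [filter_compound()]).
#' @param shift,width downshifted-normal imputation parameters.
#' @param p_sig,p_expand,d_cut significance, expansion and log2
#'   fold-change thresholds.
#' @param size_grid candidate subset sizes for [forward_search()] (`NULL`
#'   for the default grid).
#' @param restarts k-means restarts.
#' @param gene_mapping optional path to a protein-to-gene mapping TSV.
#' @param gmt optional path to a GMT file of enrichment terms.
#' @param grouping optional named list (or path to a YAML file) mapping
#'   functional-subset names to collapsed-set names.
#' @param drop_only_site drop "Only identified by site" rows at ingest.
#' @param seed integer master seed.
#' @param outdir output directory (`NULL` to skip writing files).
#' @return a `run_config` list.
#' @export
run_config <- function(matrix, design, mode = c("analysis2", "analysis1"),
                       sample_ids = NULL,
                       k = 3, k_main = 5, k_sub = 2, subset = "pilot",
                       shift = 1.8, width = 0.3,
                       p_sig = 0.05, p_expand = 0.1, d_cut = 0.58,
                       size_grid = NULL, restarts = 50,
                       gene_mapping = NULL, gmt = NULL, grouping = NULL,
                       drop_only_site = FALSE,
                       seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  structure(list(matrix = matrix, design = design, mode = mode,
                 sample_ids = sample_ids, k = k, k_main = k_main,
                 k_sub = k_sub, subset = subset, shift = shift,
                 width = width, p_sig = p_sig, p_expand = p_expand,
                 d_cut = d_cut, size_grid = size_grid, restarts = restarts,
                 gene_mapping = gene_mapping, gmt = gmt,
                 grouping = grouping, drop_only_site = drop_only_site,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "protein_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Run a full analysis
#'
#' Executes ingest, identification filters, the mode-appropriate
#' valid-value filter, log2/median centering, downshifted-normal
#' imputation and the Welch differential table; in `analysis2` mode it
#' continues with the forward subset search, the PC1 split at `p_expand`,
#' and, when a GMT file plus grouping are configured, enrichment-set
#' collapsing and the functional-subset separation report.  Every stage is
#' logged with counts in and out; outputs are written under
#' `config$outdir` when set.
#'
#' @param config a [run_config()].
#' @return a `run_summary` list recording stage counts, parameters, the
#'   seed, the differential table, search results and (if configured)
#'   enrichment outputs.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  design <- if (is.character(cfg$design)) {
    read_sample_design(cfg$design)
  } else sample_design(cfg$design)

  if (cfg$mode == "analysis1" &&
      !cfg$subset %in% c(design$experiment, design$sample_id)) {
    stop("analysis1 requires '", cfg$subset,
         "' samples in the design (compound filter subset)")
  }

  mat <- if (is.character(cfg$matrix)) {
    ids <- cfg$sample_ids %||% design$sample_id
    read_protein_groups(cfg$matrix, ids)
  } else cfg$matrix
  stopifnot(inherits(mat, "lfq_matrix"))
  design <- align_design(design, colnames(mat$intensities))
  stage_counts <- c(parsed = nrow(mat$intensities))
  log_msg("ingest: ", nrow(mat$intensities), " proteins, ",
          ncol(mat$intensities), " samples (mode ", cfg$mode, ")")

  mat <- apply_identification_filters(mat,
                                      drop_only_site = cfg$drop_only_site)
  stage_counts["id_filtered"] <- nrow(mat$intensities)

  mat <- if (cfg$mode == "analysis1") {
    filter_compound(mat, design, k_main = cfg$k_main, k_sub = cfg$k_sub,
                    subset = cfg$subset)
  } else {
    filter_simple(mat, design, k = cfg$k)
  }
  stage_counts["valid_filtered"] <- nrow(mat$intensities)

  nm <- log2_median_center(mat)
  cm <- impute_downshift(nm, width = cfg$width, shift = cfg$shift,
                         seed = cfg$seed)
  log_msg("imputation: ", sum(cm$imputed), " of ", length(cm$imputed),
          " entries imputed")

  det <- run_differential(cm, design, annotations = mat$annotations)
  stage_counts["de_table"] <- nrow(det)
  thr <- threshold_summary(det, p_cuts = c(cfg$p_sig, cfg$p_expand),
                           d_cut = cfg$d_cut)
  log_msg("differential: ", thr$n[1], " proteins at p <= ", cfg$p_sig,
          ", ", thr$n[2], " at p <= ", cfg$p_expand)

  summary <- list(
    mode = cfg$mode,
    seed = cfg$seed,
    parameters = cfg[c("k", "k_main", "k_sub", "subset", "shift", "width",
                       "p_sig", "p_expand", "d_cut", "restarts",
                       "drop_only_site")],
    group_sizes = as.list(table(design$group)),
    stage_counts = as.list(stage_counts),
    thresholds = thr,
    de_table = det,
    matrix = mat, design = design, normalized = nm, complete = cm)

  if (cfg$mode == "analysis2") {
    search <- forward_search(det, cm, design, size_grid = cfg$size_grid,
                             restarts = cfg$restarts, seed = cfg$seed)
    log_msg("forward search: n_star_full = ",
            if (is.na(search$n_star_full)) "none" else search$n_star_full)
    summary$search <- search
    pca_full <- pca_scores(cm, design,
                           proteins = if (length(search$members)) {
                             search$members
                           } else det$protein_id)
    summary$pca <- pca_full
    split <- split_by_pc1(det, pca_full$scores, cm, p_cut = cfg$p_expand)
    log_msg("PC1 split at p <= ", cfg$p_expand, ": ",
            length(split$positive), " positive, ",
            length(split$negative), " negative")
    summary$split <- split

    if (!is.null(cfg$gmt)) {
      terms <- read_gmt(cfg$gmt)
      collapsed <- collapse_terms(terms)
      log_msg("collapsed ", length(terms), " enrichment terms into ",
              length(collapsed), " maximal unique sets")
      summary$collapsed <- collapsed
      if (!is.null(cfg$grouping) && !is.null(cfg$gene_mapping)) {
        grouping <- if (is.character(cfg$grouping)) {
          yaml::read_yaml(cfg$grouping)
        } else cfg$grouping
        mapping <- read_gene_mapping(cfg$gene_mapping)
        subsets <- build_functional_subsets(collapsed, grouping, mapping)
        summary$subset_report <-
          subset_separation_report(subsets, cm, design, det,
                                   restarts = cfg$restarts, seed = cfg$seed,
                                   p_sig = cfg$p_sig)
      }
    }
  }
  class(summary) <- "run_summary"
  if (!is.null(cfg$outdir)) write_report(summary, cfg$outdir)
  summary
}

#' Write report files for a completed run
#'
#' Emits under `outdir`: the filtered matrix and design, the imputed matrix
#' with its imputation mask, the differential table, forward-search metrics
#' and PC scores, positive/negative protein id lists, heatmap-input
#' matrices for the top 50 proteins by absolute mean difference (from the
#' full table and from the `p_expand` subset), a JSON run summary and a
#' human-readable text summary.
#'
#' @param summary a `run_summary` from [run_analysis()].
#' @param outdir output directory (created if needed).
#' @param top_k number of proteins in the heatmap-input matrices.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(summary, outdir, top_k = 50) {
  stopifnot(inherits(summary, "run_summary"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir)
  }
  p <- function(...) file.path(outdir, ...)
  write_protein_groups(summary$matrix, p("filtered_matrix.tsv"))
  write_sample_design(summary$design, p("design.tsv"))
  write_matrix_tsv(round(summary$complete$values, 9), p("imputed_matrix.tsv"))
  write_matrix_tsv(summary$complete$imputed * 1L, p("imputed_mask.tsv"))
  det <- summary$de_table
  det_out <- det
  write_tsv(det_out, p("de_table.tsv"))
  write_tsv(summary$thresholds, p("threshold_summary.tsv"))

  heat <- function(tab, fname) {
    k <- min(top_k, nrow(tab))
    if (k < top_k) {
      warning("requested top ", top_k, " proteins but only ", nrow(tab),
              " available")
    }
    ids <- tab$protein_id[order(-abs(tab$d))][seq_len(k)]
    write_matrix_tsv(round(summary$complete$values[ids, , drop = FALSE], 9),
                     p(fname))
  }
  heat(det, "heatmap_top_full.tsv")
  det_expand <- det[det$p <= summary$parameters$p_expand, , drop = FALSE]
  if (nrow(det_expand) > 0) heat(det_expand, "heatmap_top_expanded.tsv")

  json <- list(mode = summary$mode, seed = summary$seed,
               parameters = summary$parameters,
               group_sizes = summary$group_sizes,
               stage_counts = summary$stage_counts,
               separation_achieved = FALSE)
  txt <- c(paste0("lfqdiscover run summary (mode ", summary$mode,
                  ", seed ", summary$seed, ")"),
           paste0("stage counts: ",
                  paste(sprintf("%s=%d", names(summary$stage_counts),
                                unlist(summary$stage_counts)),
                        collapse = " -> ")))
  if (!is.null(summary$search)) {
    write_tsv(summary$search$metrics, p("search_metrics.tsv"))
    scores <- summary$pca$scores
    write_matrix_tsv(round(scores, 9), p("pc_scores.tsv"),
                     id_col = "sample_id")
    writeLines(summary$split$positive, p("positive_proteins.txt"))
    writeLines(summary$split$negative, p("negative_proteins.txt"))
    ns <- summary$search$n_star_full
    json$n_star_full <- if (is.na(ns)) NULL else ns
    json$separation_achieved <- !is.na(ns)
    json$n_positive <- length(summary$split$positive)
    json$n_negative <- length(summary$split$negative)
    txt <- c(txt, if (is.na(ns)) {
      "separation: not achieved (no subset gave perfect (PC1,PC2) clustering)"
    } else {
      paste0("separation: achieved by the top ", ns, " proteins")
    })
  }
  if (!is.null(summary$subset_report)) {
    write_tsv(summary$subset_report, p("subset_report.tsv"))
  }
  jsonlite::write_json(json, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(txt, p("summary.txt"))
  invisible(outdir)
}
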