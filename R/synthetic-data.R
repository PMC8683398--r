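# Synthetic data generation.  The generator emulates the statistical
# structure of a small two-group LFQ study: log-normal protein abundances,
# additive cohort batch shifts on the log2 scale, a minority of truly
# differential proteins shifted in the low-humidity group, and missingness
# that is a mixture of intensity-dependent dropout (MNAR, logistic in the
# latent log2 intensity) and a small completely-at-random component.

#' Configuration for the synthetic LFQ generator
#'
#' Defaults mirror the comprehensive arm of the motivating study design: two
#' humidity groups of six rabbits split over two cohorts of three, a grand
#' mean log2 LFQ intensity around 25 with ~2 log2 units of between-protein
#' spread, and a minority of proteins upregulated in the low-humidity group.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per humidity group; must equal `sum(cohorts)`.
#' @param cohorts named integer vector: samples per group contributed by each
#'   cohort (e.g. `c(D = 3, E = 3)`).
#' @param experiments named character vector mapping cohort label to
#'   experiment label; defaults to `"pilot"` for cohort `C` and
#'   `"comprehensive"` otherwise.
#' @param n_true_de number of truly differential proteins.
#' @param n_true_de_down how many of the differential proteins carry the
#'   negated effect (decreased in low humidity); the rest are increased.
#'   Defaults to a third of `n_true_de`, mirroring the roughly 2:1
#'   up/down imbalance typical of these exposures.
#' @param effect_size log2 shift applied to the low-humidity group for
#'   differential proteins (sign encodes direction).
#' @param cohort_sd SD (log2) of the additive cohort offsets shared by all
#'   samples of a cohort.
#' @param noise_sd residual SD (log2) per protein/sample.
#' @param base_mean grand mean of protein baseline log2 intensities.
#' @param base_sd SD of protein baseline log2 intensities.
#' @param mnar_location latent log2 intensity at which the dropout
#'   probability is 0.5.
#' @param mnar_slope logistic steepness of dropout per log2 unit; `0`
#'   disables intensity dependence.
#' @param mcar_rate probability of independent (group- and
#'   intensity-independent) missingness, in `[0, 1]`.
#' @param seed integer master seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_proteins = 1500,
                         n_per_group = 6,
                         cohorts = c(D = 3, E = 3),
                         experiments = NULL,
                         n_true_de = 150,
                         n_true_de_down = round(n_true_de / 3),
                         effect_size = 1,
                         cohort_sd = 0.3,
                         noise_sd = 0.5,
                         base_mean = 25,
                         base_sd = 2,
                         mnar_location = 21.5,
                         mnar_slope = 0.8,
                         mcar_rate = 0.01,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_per_group = as.integer(n_per_group),
              cohorts = cohorts,
              experiments = experiments,
              n_true_de = as.integer(n_true_de),
              n_true_de_down = as.integer(n_true_de_down),
              effect_size = effect_size,
              cohort_sd = cohort_sd,
              noise_sd = noise_sd,
              base_mean = base_mean,
              base_sd = base_sd,
              mnar_location = mnar_location,
              mnar_slope = mnar_slope,
              mcar_rate = mcar_rate,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1 || cfg$n_per_group < 1) {
    stop("n_proteins and n_per_group must be >= 1")
  }
  if (cfg$n_true_de < 0 || cfg$n_true_de > cfg$n_proteins) {
    stop("n_true_de must lie in [0, n_proteins]")
  }
  if (cfg$n_true_de_down < 0 || cfg$n_true_de_down > cfg$n_true_de) {
    stop("n_true_de_down must lie in [0, n_true_de]")
  }
  if (is.null(names(cfg$cohorts)) || any(names(cfg$cohorts) == "")) {
    stop("cohorts must be a named vector (cohort label -> samples per group)")
  }
  if (sum(cfg$cohorts) != cfg$n_per_group) {
    stop("sum(cohorts) must equal n_per_group")
  }
  if (cfg$mcar_rate < 0 || cfg$mcar_rate > 1) {
    stop("mcar_rate must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(cfg$experiments)) {
    labs <- names(cfg$cohorts)
    cfg$experiments <- setNames(
      ifelse(labs == "C", "pilot", "comprehensive"), labs)
  }
  if (!all(names(cfg$cohorts) %in% names(cfg$experiments))) {
    stop("experiments must name every cohort")
  }
  structure(cfg, class = "synth_config")
}

# Sample ids: L01.. for low, M01.. for moderate (M = moderate control),
# assigned to cohorts in blocks in the order given.
synth_design <- function(cfg) {
  cohort_of <- rep(names(cfg$cohorts), cfg$cohorts)
  ids_low <- sprintf("L%02d", seq_len(cfg$n_per_group))
  ids_mod <- sprintf("M%02d", seq_len(cfg$n_per_group))
  sample_design(data.frame(
    sample_id = c(ids_low, ids_mod),
    group = rep(c("low", "moderate"), each = cfg$n_per_group),
    cohort = c(cohort_of, cohort_of),
    experiment = cfg$experiments[c(cohort_of, cohort_of)],
    stringsAsFactors = FALSE))
}

#' Generate a synthetic LFQ dataset with ground truth
#'
#' Latent log2 intensity of protein p in sample s is
#' `base_p + effect_p * [group(s) == low] + cohort_offset(s) + noise`,
#' with `base_p ~ N(base_mean, base_sd^2)` and cohort offsets
#' `~ N(0, cohort_sd^2)` shared by all samples of a cohort.  Dropout is
#' applied to the latent value: `P(MNAR) = plogis(-mnar_slope * (x -
#' mnar_location))`, plus an independent MCAR coin.  Masked entries are
#' stored as `0`; observed entries as `2^x`.
#'
#' @param config a [synth_config()].
#' @return list with elements `matrix` (an [lfq_matrix()]), `design` (a
#'   [sample_design()]) and `truth` (list: `de_protein_ids`, `true_effects`
#'   named by protein, `missing_cause` character matrix with values
#'   `"observed"`, `"mnar"`, `"mcar"`, and `latent` log2 intensity matrix).
#' @export
generate_lfq_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  design <- synth_design(cfg)
  n_samples <- nrow(design)
  prot_ids <- sprintf("SP%04d", seq_len(cfg$n_proteins))

  # Intensity substream: baselines, DE assignment, cohort offsets, noise.
  set.seed(derive_seed(cfg$seed, "intensity"))
  base <- rnorm(cfg$n_proteins, cfg$base_mean, cfg$base_sd)
  de_idx <- if (cfg$n_true_de > 0) {
    sort(sample.int(cfg$n_proteins, cfg$n_true_de))
  } else integer(0)
  effects <- numeric(cfg$n_proteins)
  if (cfg$n_true_de > 0) {
    signs <- rep(1, cfg$n_true_de)
    if (cfg$n_true_de_down > 0) {
      signs[sample.int(cfg$n_true_de, cfg$n_true_de_down)] <- -1
    }
    effects[de_idx] <- cfg$effect_size * signs
  }
  cohort_levels <- names(cfg$cohorts)
  cohort_off <- setNames(rnorm(length(cohort_levels), 0, cfg$cohort_sd),
                         cohort_levels)
  noise <- matrix(rnorm(cfg$n_proteins * n_samples, 0, cfg$noise_sd),
                  nrow = cfg$n_proteins)

  is_low <- design$group == "low"
  latent <- base +
    outer(effects, as.numeric(is_low)) +
    matrix(cohort_off[design$cohort], nrow = cfg$n_proteins,
           ncol = n_samples, byrow = TRUE) +
    noise
  dimnames(latent) <- list(prot_ids, design$sample_id)

  # Independent masking substreams.
  set.seed(derive_seed(cfg$seed, "mnar"))
  u_mnar <- matrix(runif(length(latent)), nrow = nrow(latent))
  p_mnar <- if (cfg$mnar_slope == 0) {
    # degenerate slope: dropout no longer depends on intensity; the limit in
    # the location resolves the 0 * Inf ambiguity
    p0 <- if (cfg$mnar_location == -Inf) 0
          else if (cfg$mnar_location == Inf) 1 else 0.5
    matrix(p0, nrow = nrow(latent), ncol = ncol(latent))
  } else {
    stats::plogis(-cfg$mnar_slope * (latent - cfg$mnar_location))
  }
  mnar_hit <- u_mnar < p_mnar

  set.seed(derive_seed(cfg$seed, "mcar"))
  mcar_hit <- matrix(runif(length(latent)) < cfg$mcar_rate,
                     nrow = nrow(latent))

  cause <- matrix("observed", nrow = nrow(latent), ncol = ncol(latent),
                  dimnames = dimnames(latent))
  cause[mcar_hit] <- "mcar"
  cause[mnar_hit] <- "mnar"   # MNAR takes precedence when both fire

  intens <- 2^latent
  intens[cause != "observed"] <- 0

  ann <- data.frame(
    protein_id = prot_ids,
    fasta_header = sprintf("sp|%s|SYNTH_RABIT synthetic protein %d",
                           prot_ids, seq_len(cfg$n_proteins)),
    gene_name = sprintf("GENE%04d", seq_len(cfg$n_proteins)),
    unique_peptides = 1L + (seq_len(cfg$n_proteins) %% 5L),
    msms_count = 2L + (seq_len(cfg$n_proteins) %% 7L),
    contaminant = FALSE, reverse = FALSE, only_site = FALSE,
    stringsAsFactors = FALSE)

  list(matrix = lfq_matrix(intens, ann),
       design = design,
       truth = list(de_protein_ids = prot_ids[de_idx],
                    true_effects = setNames(effects, prot_ids),
                    missing_cause = cause,
                    latent = latent))
}

#' Generate a term-to-gene map with controlled redundancy
#'
#' Builds `n_terms` gene sets over `gene_pool`.  A `1 - redundancy` fraction
#' of terms are base sets constructed to be pairwise non-nested (each holds a
#' private gene); the remaining terms are exact duplicates or strict subsets
#' of a random base term, which is the redundancy that set collapsing is
#' meant to remove.
#'
#' @param n_terms number of terms (>= 1).
#' @param gene_pool character vector of available gene names.
#' @param redundancy fraction of terms in `[0, 1]` that duplicate or nest
#'   inside another term.
#' @param seed integer seed.
#' @return named list of character gene vectors (names are term ids); the
#'   `"description"` attribute maps term id to a human-readable label.
#' @export
generate_term_gene_map <- function(n_terms, gene_pool, redundancy, seed = 1L) {
  if (length(gene_pool) == 0) stop("gene_pool must be non-empty")
  if (!is.numeric(redundancy) || redundancy < 0 || redundancy > 1) {
    stop("redundancy must lie in [0, 1]")
  }
  n_terms <- as.integer(n_terms)
  stopifnot(n_terms >= 1)
  gene_pool <- unique(as.character(gene_pool))
  set.seed(derive_seed(seed, "term_gene_map"))

  n_red <- min(round(redundancy * n_terms), n_terms - 1L)
  n_base <- n_terms - n_red
  if (n_base > length(gene_pool)) {
    stop("gene_pool too small: need at least one private gene per base term")
  }
  private <- sample(gene_pool, n_base)
  shared_pool <- setdiff(gene_pool, private)
  base_sets <- lapply(seq_len(n_base), function(i) {
    extra <- if (length(shared_pool)) {
      k <- sample.int(min(5L, length(shared_pool)), 1L)
      sample(shared_pool, k)
    } else character(0)
    sort(unique(c(private[i], extra)), method = "radix")
  })
  red_sets <- lapply(seq_len(n_red), function(i) {
    parent <- base_sets[[sample.int(n_base, 1L)]]
    if (length(parent) > 1 && runif(1) < 0.5) {
      # strict non-empty subset
      k <- sample.int(length(parent) - 1L, 1L)
      sort(sample(parent, k), method = "radix")
    } else {
      parent                                   # exact duplicate
    }
  })
  sets <- c(base_sets, red_sets)
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  attr(sets, "description") <- setNames(
    sprintf("synthetic term %d", seq_len(n_terms)), names(sets))
  sets
}

#' Generate a synthetic RT-qPCR Ct table with ground truth
#'
#' Target Ct values are built so that the expected difference in
#' delta-Ct (target minus endogenous control) between the low and moderate
#' groups equals `-true_log2_fc[gene]`; the endogenous control has constant
#' expected Ct across groups.  Independent Gaussian cycle noise with SD
#' `ct_sd` is added to every target and reference Ct.
#'
#' @param genes character vector of target gene names.
#' @param n_per_group samples per humidity group.
#' @param true_log2_fc named numeric vector of planted log2 fold changes
#'   (low vs moderate), one per gene (unnamed scalar recycled).
#' @param ct_sd cycle noise SD (>= 0).
#' @param seed integer seed.
#' @return list with `table` (data frame: `sample_id`, `group`, `gene`,
#'   `ct_target`, `ct_reference`) and `truth` (named log2 fold changes).
#' @export
generate_qpcr_dataset <- function(genes, n_per_group, true_log2_fc,
                                  ct_sd = 0.2, seed = 1L) {
  stopifnot(length(genes) >= 1, n_per_group >= 1, ct_sd >= 0)
  genes <- as.character(genes)
  if (length(true_log2_fc) == 1 && is.null(names(true_log2_fc))) {
    true_log2_fc <- setNames(rep(true_log2_fc, length(genes)), genes)
  }
  if (!all(genes %in% names(true_log2_fc))) {
    stop("true_log2_fc must name every gene")
  }
  set.seed(derive_seed(seed, "qpcr"))
  ids <- c(sprintf("L%d", seq_len(n_per_group)),
           sprintf("M%d", seq_len(n_per_group)))
  grp <- rep(c("low", "moderate"), each = n_per_group)
  rows <- do.call(rbind, lapply(seq_along(genes), function(gi) {
    g <- genes[gi]
    base_target <- 24 + gi              # gene-specific baseline Ct
    ct_ref <- 20 + rnorm(length(ids), 0, ct_sd)
    ct_tar <- base_target -
      ifelse(grp == "low", true_log2_fc[[g]], 0) +
      rnorm(length(ids), 0, ct_sd)
    data.frame(sample_id = ids, group = grp, gene = g,
               ct_target = ct_tar, ct_reference = ct_ref,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(table = rows, truth = true_log2_fc[genes])
}
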