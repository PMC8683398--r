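---
title: "Differential expression and discriminant subset discovery for label-free proteomics"
author: "lfqdiscover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression and discriminant subset discovery for label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqdiscover)
```

## The problem

Small two-group animal exposure studies quantified by label-free
LC--MS/MS (MaxQuant LFQ intensities) pose three linked statistical
problems:

1. **Left-censored missingness.** An LFQ value of 0 means "not
   quantified", and the probability of dropout rises as true abundance
   falls (missing *not* at random, MNAR). Proteins must first pass
   valid-value filters, and the remaining holes must be filled in a way
   that respects the censoring.
2. **Weak per-protein power.** With 3--9 animals per group, per-protein
   Welch tests rarely survive multiple-testing correction, so the
   discovery question is better phrased at the *set* level: how large a
   p-value-ranked protein panel still separates the exposure groups in
   principal-component space?
3. **Redundant annotation.** Enrichment tools return hundreds of
   overlapping term--gene sets; before curating functional panels the
   redundancy has to be collapsed away deterministically.

`lfqdiscover` implements this workflow end to end, together with an
RT-qPCR 2^(-ΔΔCt) arm and a synthetic-data generator that reproduces the
statistical structure of such studies so that every stage can be
benchmarked against known ground truth.

## Pipeline model and conventions

### Identification and valid-value filters

A *valid value* is an LFQ intensity strictly greater than 0. After
removing contaminants, decoys, proteins without a unique peptide,
proteins with fewer than two MS/MS counts, and proteins with no
quantifiable peak, two alternative valid-value rules are provided:

* `filter_simple(k = 3)` keeps proteins with at least `k` valid values
  in **at least one** humidity group — the rule for a single-experiment
  design (6 vs 6: "3 of 6 in either group").
* `filter_compound(k_main = 5, k_sub = 2, subset = "pilot")` keeps
  proteins with at least `k_main` valid values in some group overall
  **and** at least `k_sub` valid values in some group *within the pilot
  subset* — the conservative rule for a pooled design whose pilot arm is
  under-sampled and over-represents missingness.

"Either group" is read as *at least one* group in both rules; both are
validated exactly against brute-force per-protein enumeration in the
test suite.

### Transformation and centering

Observed intensities are log2-transformed and each sample is centered by
subtracting the median of its observed log2 values. The *lower-median*
convention is used for even counts so the subtracted value is always an
observed one; the per-sample offsets are retained. Median centering
assumes the bulk of the proteome is unchanged between groups — see
*Limitations*.

### Downshifted-normal imputation

Missing entries are imputed sample-wise from
`Normal(m - shift * s, (width * s)^2)` where `m` and `s` are the mean
and SD of the sample's observed centered values. Defaults follow the
Perseus convention for left-censored imputation:

| parameter | default | units | role |
|-----------|---------|-------|------|
| `shift`   | 1.8     | sample SDs | how far below the observed mean the imputed distribution sits |
| `width`   | 0.3     | sample SDs | spread of the imputed distribution |

Both are exposed because the downshift strength is a modeling choice,
not an estimate. Observed entries are never altered; imputed positions
are flagged and written out as a sidecar mask. A single user seed drives
per-sample substreams derived by hashing the sample id, so reordering
samples (or toggling another random mechanism) never changes a sample's
draws.

### Differential testing

Per-protein two-sided Welch tests compare low against moderate humidity;
the mean difference `d` is on the log2 scale with *low minus moderate*
orientation, so positive `d` means increased abundance under low
humidity. 95% confidence intervals use the Welch–Satterthwaite degrees
of freedom. P-values are reported **uncorrected**, matching the
reporting convention of small-cohort discovery proteomics; a
Benjamini–Hochberg column is emitted for reference but never used in
downstream selection. Tables are sorted by ascending p, ties broken by
larger `|d|`, then protein id, making the ranking reproducible under
permutation of the input. The default effect-size annotation threshold
is `|d| >= 0.58` log2 units, i.e. a 1.5-fold change.

Degenerate zero-variance pairs (possible only when imputation is
bypassed) use the limit behaviour `p = 0` when `d != 0` and `p = 1` when
`d = 0`, with a warning.

### Forward subset search and k-means validation

For each candidate size `N`, the top-`N` proteins by ascending p-value
are decomposed by PCA (samples as observations, proteins centered but
not variance-scaled — the data are already log2, median-centered;
variance scaling is available as a switch). Sample scores are clustered
by k-means with `k = 2` (Euclidean, best of 50 seeded restarts by
within-cluster sum of squares) on PC1 alone and on (PC1, PC2);
*separation* is operationalised as perfect agreement between the
2-cluster partition and the humidity groups on (PC1, PC2), with the
PC1-only accuracy also reported. The search reports the largest `N`
achieving perfect accuracy. The default size grid is every multiple of
10 up to the table size plus the table size itself (and the sizes 95 and
515, historically interesting panel sizes for this design, when in
range); the grid is configurable and the result is independent of its
order.

Each principal component is sign-oriented so the low-humidity group has
the larger mean score. This makes downstream signs deterministic: the
Pearson correlation of a protein with PC1 then agrees in sign with its
mean difference except in near-zero cases, which are logged.
`split_by_pc1()` splits the proteins passing `p <= 0.1` (inclusive —
the boundary convention adopted here) into positive and negative
PC1-correlation lists; zero-variance proteins are excluded with a
warning.

k-means on 12 samples is validated in the tests against an exhaustive
enumeration of all 2-partitions; PCA variance fractions are validated
against a direct covariance eigendecomposition.

### Enrichment-set collapsing and functional panels

"Collapsing terms into their largest unique sets" is formalised as
computing the maximal antichain under set inclusion: exact duplicate
gene sets are merged and any set that is a strict subset of another is
absorbed; partially overlapping, non-nested sets are all kept. The
output is canonically ordered (decreasing size, then lexicographic
content), which makes the operation idempotent and independent of input
term order; genes are neither invented nor lost. Enrichment p-values and
cluster assignments computed by the external tool are consumed, never
recomputed.

The grouping of collapsed sets into named functional panels (chaperone
response, glutathione-related, ...) is a curation judgement; it is
therefore externalised to a user-edited YAML mapping (see
`inst/extdata/example_grouping.yaml`) rather than inferred. Per panel,
`subset_separation_report()` returns exactly the quantities used to
judge a panel: member count, members significant at `p <= 0.05`,
combined PC1+PC2 variance fraction, and k-means accuracy on (PC1, PC2).
Panels with fewer than two matrix proteins are marked not computable.

### RT-qPCR arm

Relative quantification follows 2^(-ΔΔCt): per sample,
`ΔCt = Ct(target) - Ct(reference)`; each sample's ΔΔCt subtracts the
mean ΔCt of the moderate-humidity (reference) group for that gene, so
the reference group standardises to 1. Group means and SEMs are computed
from individual sample `rq` values. Fold changes use the signed
convention `r >= 1 -> r`, `r < 1 -> -1/r` (a halving is reported as
-2.0). Outliers are screened per gene *within each humidity group* by an
iterative two-tailed Grubbs test (α = 0.05, one removal per iteration,
statistic recomputed on the reduced set) — the most conservative
stratification; the screening scale defaults to `rq` with a `delta_ct`
switch, both choices being defensible since the underlying report does
not fix them. Group comparisons use two-sided Wilcoxon rank-sum tests,
exact by enumeration when the pooled size is at most 20 without ties,
otherwise the tie- and continuity-corrected normal approximation. The
Grubbs critical values follow the t-based closed form and are checked in
the tests against published two-sided tables.

## The synthetic generator

`generate_lfq_dataset()` emulates, on the log2 scale:

* protein baselines `~ N(base_mean = 25, base_sd = 2)` (log-normal
  abundances at a typical LFQ intensity scale);
* a minority of truly differential proteins (`n_true_de = 150` of 1500
  by default) shifted by `effect_size` in the low-humidity group only,
  with a third of them down-regulated by default, mirroring the ~2:1
  up/down imbalance typical of this exposure;
* additive cohort offsets `~ N(0, cohort_sd = 0.3)` shared by every
  sample of a cohort (two cohorts of three per group by default), the
  batch structure that makes cohort stripes visible in PC plots;
* residual noise `~ N(0, noise_sd = 0.5)`;
* MNAR dropout with probability
  `plogis(-mnar_slope * (x - mnar_location))` applied to the latent
  intensity (`mnar_location = 21.5`, `mnar_slope = 0.8`: roughly 11% of
  entries missing overall, concentrated in the low-intensity tail), plus
  an independent `mcar_rate = 0.01` completely-at-random component;
* masked entries stored as LFQ = 0, exactly as consumed by the ingest
  module.

Missingness rates per cohort are deliberately free parameters (no
quantitative rates are available to match), and the defaults above are
one realistic operating point, fixed once. The generator does **not**
simulate peptides, spectra, razor-peptide assignment, protein--protein
correlation, or cohort-by-group confounding; consequently, passing
recovery benchmarks demonstrates that the pipeline recovers planted
effects under the stated noise/missingness model, not that it is robust
to correlated proteomes or confounded batches.

`generate_qpcr_dataset()` plants log2 fold changes as ΔCt shifts with
Gaussian cycle noise on both target and reference Ct values;
`generate_term_gene_map()` produces term--gene maps with a controlled
fraction of duplicate/nested terms (each base set holds a private gene,
guaranteeing non-nestedness at redundancy 0).

## Numerical and design choices

* **Seeding.** One master seed; independent substreams per purpose
  (intensity, MNAR, MCAR, imputation per sample, k-means) derived by a
  stable string hash, so toggling one mechanism never perturbs another
  and identical configurations reproduce every output byte for byte.
* **Tie-breaks.** DE ranking: p, then `|d|` descending, then protein id.
  Collapsed sets: size descending, then lexicographic content (radix
  order, locale-independent). k-means WCSS ties: first found.
* **Degenerate inputs.** Samples with fewer than two observed values
  abort imputation by name; zero observed SD imputes constants;
  coincident sample scores make k-means return the majority-class
  accuracy with a warning; single-protein panels are marked not
  computable.
* **Inclusive thresholds.** `p <= 0.1` and `p <= 0.05` everywhere.
* **Clustering space.** k-means validation operates on PC scores (not
  raw protein space), and only PC1 is used for correlation splitting;
  both choices follow the narrative this workflow reproduces.
* **"Only identified by site".** Retained by default with a switch to
  drop, since their handling is not fixed by the upstream convention.

## Benchmark problem sizes

The test suite sizes were chosen to give tight statistical checks at
interactive runtimes: filter oracles on 200 random 50-protein matrices;
Welch against a closed-form oracle on 100 random pairs plus a
10,000-replicate null calibration (run under a heteroscedastic normal
null — equal means, SD ratio 2 — the regime the Welch test is designed
for); pipeline null calibration over 50 simulated studies of 600
proteins; recovery over 20 studies of 1500 proteins with 100 planted
effects; 500 random term maps against the antichain oracle; 200-seed
qPCR fold-change recovery. `scripts/acceptance.R` recomputes scaled
versions of the same quantities from scratch.

## Limitations

* **Median centering is compositional.** When differential proteins
  stop being a minority, the per-sample median absorbs part of the
  signal: planted +2 log2 effects lose about 1 log2 unit when 75% of a
  200-protein panel is differential (measured in the test suite while
  sizing the recovery scenarios). This is a property of the method, not
  an implementation artifact.
* **MCAR dropout of abundant proteins is poorly handled by downshift
  imputation.** A completely-random dropout of a high-abundance value is
  imputed near the detection floor, inflating within-group variance and
  occasionally destroying a true signal; with the generator defaults
  (1% MCAR) this costs several percentage points of sensitivity. This is
  the known cost of a left-censoring model applied to non-censored
  missingness.
* **Selection bias in the subset search.** Because candidate panels are
  selected on p-values from the same samples they are asked to separate,
  even null data can produce apparent separation; the search therefore
  only *reports* accuracies and never interprets separation as evidence
  by itself.
* **Welch at n = 6/6 is slightly conservative** under an equal-variance
  null (its empirical size sits below the nominal 5%); calibration is
  checked in the heteroscedastic regime the test targets.
* Uncorrected p-value thresholds admit the expected fraction of null
  proteins into the `p <= 0.1` lists; downstream set-level conclusions
  must account for this.

## A worked example

```{r example, eval = FALSE}
library(lfqdiscover)

# synthetic stand-in for a comprehensive two-cohort study
ds <- generate_lfq_dataset(synth_config(seed = 1))

summary <- run_analysis(run_config(
  ds$matrix, ds$design, mode = "analysis2", seed = 1,
  outdir = "results"))

summary$stage_counts
summary$search$n_star_full
head(summary$de_table)
```
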