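# Valid-value counting and filtering, log2 median centering, and
# downshifted-normal imputation.

test_that("valid values are counted with strict positivity", {
  design <- tiny_design(c(D = 3))           # 3 low + 3 moderate
  intens <- rbind(c(0, 0.0, 5.1, 2, 2, 2),
                  c(0, 0, 0, 0, 0, 0))
  colnames(intens) <- design$sample_id
  cnt <- count_valid(tiny_lfq(intens), design)
  expect_identical(cnt$n_valid_low, c(1L, 0L))
  expect_identical(cnt$n_valid_moderate, c(3L, 0L))
})

test_that("count_valid matches a nested-loop enumeration", {
  design <- tiny_design(c(C = 3, D = 3), pilot_cohort = "C")
  set.seed(31)
  m <- random_lfq(20, design)
  pilot_ids <- design$sample_id[design$experiment == "pilot"]
  got <- count_valid(m, design, subsets = list(pilot = "pilot"))
  want <- oracle_valid_counts(m, design, pilot_ids)
  expect_identical(got$n_valid_low, want$n_valid_low)
  expect_identical(got$n_valid_moderate, want$n_valid_moderate)
  expect_identical(got$n_valid_pilot_low, want$sub_low)
  expect_identical(got$n_valid_pilot_moderate, want$sub_moderate)
})

test_that("the simple filter keeps exactly the k-in-either-group proteins", {
  design <- tiny_design(c(D = 3, E = 3))    # 6 per group
  m <- matrix(0, nrow = 2, ncol = 12,
              dimnames = list(NULL, design$sample_id))
  m[1, design$group == "low"][1:3] <- 10    # low=3, moderate=0 -> kept
  m[2, design$group == "low"][1:2] <- 10    # low=2, moderate=2 -> dropped
  m[2, design$group == "moderate"][1:2] <- 10
  got <- suppressMessages(filter_simple(tiny_lfq(m), design, k = 3))
  expect_identical(got$annotations$protein_id, "P001")
  expect_error(filter_simple(tiny_lfq(m), design, k = 0), "count")
})

test_that("the compound filter honours both the main and subset rules", {
  design <- tiny_design(c(C = 3, D = 3, E = 3), pilot_cohort = "C")
  low_ids <- design$sample_id[design$group == "low"]
  mod_ids <- design$sample_id[design$group == "moderate"]
  pilot_low <- design$sample_id[design$group == "low" &
                                  design$experiment == "pilot"]
  m <- matrix(0, nrow = 3, ncol = 18,
              dimnames = list(NULL, design$sample_id))
  # 5 of 9 in low incl. 2 pilot-low -> retained
  m[1, c(pilot_low[1:2], setdiff(low_ids, pilot_low)[1:3])] <- 10
  # low=6, moderate=4 but only 1 pilot id per group -> removed
  m[2, c(pilot_low[1], setdiff(low_ids, pilot_low))] <- 10
  m[2, setdiff(mod_ids, design$sample_id[design$experiment == "pilot"])] <- 10
  # fully observed -> retained
  m[3, ] <- 10
  got <- suppressMessages(
    filter_compound(tiny_lfq(m), design, k_main = 5, k_sub = 2,
                    subset = "pilot"))
  expect_identical(got$annotations$protein_id, c("P001", "P003"))
  expect_error(filter_compound(tiny_lfq(m), design, subset = character(0)),
               "subset")
})

test_that("filters agree with brute-force enumeration on random matrices", {
  d12 <- tiny_design(c(D = 3, E = 3))
  d18 <- tiny_design(c(C = 3, D = 3, E = 3), pilot_cohort = "C")
  pilot_ids <- d18$sample_id[d18$experiment == "pilot"]
  set.seed(77)
  for (rep in 1:20) {
    m12 <- random_lfq(50, d12, miss_rate = runif(1, 0.1, 0.6))
    got <- suppressMessages(filter_simple(m12, d12, k = 3))
    expect_identical(got$annotations$protein_id,
                     oracle_filter_simple(m12, d12, 3))
    m18 <- random_lfq(50, d18, miss_rate = runif(1, 0.1, 0.6))
    got <- suppressMessages(filter_compound(m18, d18, 5, 2, "pilot"))
    expect_identical(got$annotations$protein_id,
                     oracle_filter_compound(m18, d18, 5, 2, pilot_ids))
  }
})

test_that("retention is monotone in the validity threshold", {
  design <- tiny_design()
  set.seed(41)
  m <- random_lfq(80, design, miss_rate = 0.5)
  k3 <- suppressMessages(filter_simple(m, design, 3))$annotations$protein_id
  k4 <- suppressMessages(filter_simple(m, design, 4))$annotations$protein_id
  expect_true(all(k4 %in% k3))
})

test_that("log2 median centering uses the lower-median of observed values", {
  design <- tiny_design(c(D = 1))
  m <- matrix(c(2, 4, 8, 0, 16, 0), ncol = 2,
              dimnames = list(NULL, design$sample_id))
  nm <- log2_median_center(tiny_lfq(m))
  expect_equal(unname(nm$values[, 1]), c(-1, 0, 1))
  # single observed value centers to zero
  expect_equal(nm$values[2, 2], 0)
  expect_true(all(is.na(nm$values[c(1, 3), 2])))
  # even observed count: lower median (an observed value) maps to exactly 0
  set.seed(13)
  d2 <- tiny_design(c(D = 3, E = 3))
  m2 <- random_lfq(40, d2, miss_rate = 0.25)
  keep <- rowSums(m2$intensities > 0) > 0
  m2 <- tiny_lfq(m2$intensities[keep, , drop = FALSE])
  nm2 <- log2_median_center(m2)
  meds <- apply(nm2$values, 2, function(v) {
    v <- v[!is.na(v)]
    sort(v)[floor((length(v) + 1) / 2)]
  })
  expect_equal(unname(meds), rep(0, ncol(nm2$values)), tolerance = 1e-9)
  # missingness pattern untouched
  expect_identical(is.na(nm2$values), m2$intensities == 0)
})

test_that("imputation fills exactly the missing cells and nothing else", {
  design <- tiny_design(c(D = 3))
  set.seed(51)
  m <- random_lfq(50, design, miss_rate = 0.3)
  keep <- rowSums(m$intensities > 0) > 0
  m <- tiny_lfq(m$intensities[keep, , drop = FALSE])
  nm <- log2_median_center(m)
  cm <- impute_downshift(nm, seed = 4)
  expect_identical(cm$imputed, is.na(nm$values))
  obs <- !is.na(nm$values)
  expect_identical(cm$values[obs], nm$values[obs])
  expect_false(anyNA(cm$values))
  # deterministic under the seed, and stable under sample reordering
  cm2 <- impute_downshift(nm, seed = 4)
  expect_identical(cm$values, cm2$values)
  perm <- rev(colnames(nm$values))
  nm_perm <- lfqdiscover:::norm_matrix(nm$values[, perm],
                                       nm$offsets[perm])
  cm3 <- impute_downshift(nm_perm, seed = 4)
  expect_identical(cm3$values[, colnames(cm$values)], cm$values)
})

test_that("complete input and degenerate spread behave as documented", {
  design <- tiny_design(c(D = 1))
  m <- matrix(c(2, 4, 8, 2, 4, 8), ncol = 2,
              dimnames = list(NULL, design$sample_id))
  nm <- log2_median_center(tiny_lfq(m))
  cm <- impute_downshift(nm, seed = 1)
  expect_identical(cm$values, nm$values)
  expect_false(any(cm$imputed))
  # zero observed SD: every imputed value equals the observed mean
  m2 <- matrix(c(4, 4, 4, 0, 4, 4), nrow = 3, ncol = 2,
               dimnames = list(NULL, design$sample_id))
  nm2 <- log2_median_center(tiny_lfq(m2))
  cm2 <- impute_downshift(nm2, seed = 1)
  expect_equal(cm2$values[1, 2], mean(nm2$values[2:3, 2]))
})

test_that("samples with under two observed values are rejected by name", {
  design <- tiny_design(c(D = 1))
  m <- matrix(c(2, 4, 8, 0, 16, 0), ncol = 2,
              dimnames = list(NULL, design$sample_id))
  nm <- log2_median_center(tiny_lfq(m))
  expect_error(impute_downshift(nm, seed = 1), design$sample_id[2],
               fixed = TRUE)
})

test_that("imputed draws follow the downshifted normal", {
  # one sample: 100 observed values standardized to mean 0, SD 1, plus
  # many missing entries; imputed mean ~ -1.8, SD ~ 0.3
  obs <- as.numeric(scale(rnorm(100)))
  n_miss <- 20000
  vals <- matrix(c(obs, rep(NA_real_, n_miss)), ncol = 1,
                 dimnames = list(NULL, "S1"))
  nm <- lfqdiscover:::norm_matrix(vals, c(S1 = 0))
  cm <- impute_downshift(nm, width = 0.3, shift = 1.8, seed = 99)
  imp <- cm$values[cm$imputed]
  expect_lt(abs(mean(imp) + 1.8), 0.02)
  expect_lt(abs(sd(imp) / 0.3 - 1), 0.03)
})
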