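test_that("feature shuffling preserves every per-feature value multiset", {
  sim <- small_sim()
  ds <- sim$dataset

  # fraction 0 is the identity
  same <- shuffle_features(ds, "RNA", 0, seed = 1)
  expect_equal(as.matrix(same$rna), as.matrix(ds$rna))

  # fraction 1: every column is a permutation of the original
  full <- shuffle_features(ds, "RNA", 1, seed = 2)
  orig <- as.matrix(ds$rna)
  shuf <- as.matrix(full$rna)
  expect_false(identical(orig, shuf))
  expect_equal(apply(shuf, 2, sort), apply(orig, 2, sort))

  # grand total conserved at any fraction
  part <- shuffle_features(ds, "ADT", 0.5, seed = 3)
  expect_equal(sum(part$adt), sum(ds$adt))
  expect_equal(sort(as.vector(part$adt)), sort(as.vector(ds$adt)))

  # replayed selection matches the corrupted columns
  ids <- shuffled_feature_ids(ds, "RNA", 0.3, seed = 9)
  corr <- shuffle_features(ds, "RNA", 0.3, seed = 9)
  untouched <- setdiff(ds$gene_ids, ids)
  expect_equal(as.matrix(corr$rna[, untouched]), as.matrix(ds$rna[, untouched]))
  expect_length(ids, ceiling(0.3 * length(ds$gene_ids)))
})

test_that("top-SD feature selection matches a brute-force sort oracle", {
  sim <- simulate_cite_seq(small_config(seed = 6, n_genes = 50,
                                        n_marker_genes_per_cluster = 5,
                                        n_mito_genes = 3))
  ds <- sim$dataset
  m <- as.matrix(ds$rna)
  sds <- apply(m, 2, sd)
  oracle <- colnames(m)[order(-sds, colnames(m))][1:20]
  expect_identical(select_top_sd_features(ds, 20, "RNA"), oracle)
  expect_identical(sort(select_top_sd_features(ds, 50, "RNA")), sort(ds$gene_ids))
  expect_error(select_top_sd_features(ds, 0, "RNA"), "positive")

  # a constant feature is never selected while any feature varies
  m2 <- cbind(m[, 1:10], FLAT = 5L)
  ds2 <- cite_dataset(m2)
  expect_false("FLAT" %in% select_top_sd_features(ds2, 10, "RNA"))
})

test_that("mean correlation decreases strictly with shuffle fraction", {
  sim <- default_sim()
  cfg <- noise_config("RNA", cell_fraction = 0.1,
                      shuffle_fractions = c(0, 0.5, 1.0),
                      n_replicates = 10, seed = 7)
  ex <- correlation_degradation_experiment(sim$dataset, cfg)
  means <- tapply(ex$metrics$rho, ex$metrics$shuffle_fraction, mean)
  expect_true(all(diff(means) < 0))
  expect_true(all(ex$metrics$rho >= -1 & ex$metrics$rho <= 1))
  expect_equal(nrow(ex$metrics), 30)

  # fraction 0 reproduces the uncorrupted rho on the same cell sample
  sub <- subset_cells(sim$dataset,
                      withr::with_seed(7 + 1, sample.int(n_cells(sim$dataset),
                                                         round(0.1 * 2000))))
  st <- per_cell_stats(sub, "RNA")
  direct <- spearman_permutation(st$n_feature, st$n_count, n_permutations = 0)$rho
  expect_equal(ex$metrics$rho[ex$metrics$shuffle_fraction == 0 &
                                ex$metrics$replicate == 1], direct)

  # identical config + seed is bit-identical
  ex2 <- correlation_degradation_experiment(sim$dataset, cfg)
  expect_identical(ex$metrics, ex2$metrics)
})

test_that("entropy distributions shift right as corruption grows", {
  sim <- default_sim()
  cfg <- noise_config("RNA", cell_fraction = 0.1,
                      shuffle_fractions = c(0.1, 0.5, 1.0),
                      n_replicates = 2, n_top_sd_features = 500, seed = 15)
  ex <- suppressWarnings(entropy_shift_experiment(sim$dataset, cfg))
  med <- tapply(ex$metrics$entropy, ex$metrics$shuffle_fraction, median)
  # at one noise seed the extreme contrast is the identifiable signature;
  # pooled-median monotonicity across many seeds is checked elsewhere
  expect_gt(med[["1"]], med[["0.1"]])
  expect_lte(ex$shifts$p_value[2], 0.05)
  expect_lte(compare_entropy_distributions(
    ex$metrics$entropy[ex$metrics$shuffle_fraction == 0.1],
    ex$metrics$entropy[ex$metrics$shuffle_fraction == 1.0]), 0.05)

  # determinism
  ex2 <- suppressWarnings(entropy_shift_experiment(sim$dataset, cfg))
  expect_identical(ex$metrics, ex2$metrics)

  # shuffling nothing of an empty panel errors out
  no_adt <- sim$dataset
  no_adt$adt <- no_adt$adt[, 0, drop = FALSE]
  no_adt$adt_ids <- character(0)
  cfg_adt <- noise_config("ADT", n_replicates = 1, seed = 1)
  expect_error(suppressWarnings(entropy_shift_experiment(no_adt, cfg_adt)),
               "no features")
})

test_that("the rank-sum shift test is directional and calibrated", {
  a <- withr::with_seed(1, rnorm(30))
  expect_lte(compare_entropy_distributions(a, a + 1), 0.001)
  expect_gte(compare_entropy_distributions(a + 1, a), 0.999)
  expect_error(compare_entropy_distributions(a, 1:2), ">= 3")

  # null: p roughly uniform when both samples share one distribution
  ps <- vapply(1:200, function(s) {
    withr::with_seed(4000 + s, {
      compare_entropy_distributions(rnorm(30), rnorm(30))
    })
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_equal(mean(ps), 0.5, tolerance = 0.15)
})

test_that("noise configs reject invalid settings", {
  expect_error(noise_config("RNA", shuffle_fractions = c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(noise_config("RNA", cell_fraction = 0), "cell_fraction")
  expect_error(noise_config("RNA", n_replicates = 0), "n_replicates")
  expect_equal(noise_config("ADT")$n_replicates, 50L)
  expect_equal(noise_config("RNA")$shuffle_fractions, c(0.05, 0.10, 0.20))
})
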