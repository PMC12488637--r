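test_that("pair resolution combines explicit map and naming heuristic", {
  sim <- small_sim()
  ds <- sim$dataset
  pairs <- suppressMessages(resolve_adt_pairs(ds))
  expect_setequal(pairs$adt_id[pairs$source == "map"],
                  names(ds$adt_to_gene))
  expect_setequal(attr(pairs, "unmapped"),
                  grep("^CTRL-", ds$adt_ids, value = TRUE))

  # heuristic: an ADT named <gene>_TotalSeqB matches the gene prefix
  ds2 <- ds
  ds2$adt_ids[6] <- paste0(sim$truth$housekeeping_genes[1], "_TotalSeqB")
  colnames(ds2$adt) <- ds2$adt_ids
  ds2$adt_to_gene <- NULL
  expect_message(p2 <- resolve_adt_pairs(ds2), "heuristic")
  expect_true(sim$truth$housekeeping_genes[1] %in% p2$gene_id)
})

test_that("planted rank coupling is recovered and null pairs stay near zero", {
  sim <- default_sim()
  coupled <- dplyr::filter(sim$truth$coupling, coupling > 0)
  for (i in seq_len(nrow(coupled))) {
    pc <- pair_correlation(sim$dataset, coupled$adt_id[i], coupled$gene_id[i],
                           scale = "raw", n_permutations = 99, seed = i)
    expect_equal(pc$rho, 0.8, tolerance = 0.1 / 0.8)
    expect_lte(pc$p_value, 0.05)
  }

  sim0 <- simulate_cite_seq(synthetic_config(seed = 101, adt_coupling = 0))
  for (i in 1:5) {
    pc0 <- pair_correlation(sim0$dataset, sim0$truth$coupling$adt_id[i],
                            sim0$truth$coupling$gene_id[i],
                            scale = "raw", n_permutations = 0)
    expect_lte(abs(pc0$rho), 0.1)
  }
})

test_that("pair correlations respect scope contracts", {
  sim <- small_sim()
  asn <- new_assignment_from_truth(sim)
  adt <- sim$truth$coupling$adt_id[1]
  gene <- sim$truth$coupling$gene_id[1]

  global <- pair_correlation(sim$dataset, adt, gene, n_permutations = 49, seed = 1)
  per_cl <- pair_correlation(sim$dataset, adt, gene, clusters = asn,
                             n_permutations = 49, seed = 1)
  expect_equal(sum(per_cl$n_cells), global$n_cells)
  expect_true(all(grepl("^cluster:", per_cl$scope)))

  # unmapped pair errors with guidance; tiny scope is skipped
  expect_error(pair_correlation(sim$dataset, adt, "NOT_A_GENE"), "adt_to_gene")
  tiny <- as_cluster_assignment(stats::setNames(
    c("a", "a", rep("b", n_cells(sim$dataset) - 2)), sim$dataset$cell_ids))
  expect_warning(res <- pair_correlation(sim$dataset, adt, gene,
                                         clusters = tiny, n_permutations = 9),
                 "skipped")
  expect_identical(res$scope, "cluster:b")
})

test_that("all-pairs histogram separates coupled from uncoupled tags", {
  for (s in c(42, 19)) {
    sim <- if (s == 42) default_sim() else simulate_cite_seq(synthetic_config(seed = s))
    ds <- sim$dataset
    # map the control tags to housekeeping genes so uncoupled pairs exist
    ctrl <- grep("^CTRL-", ds$adt_ids, value = TRUE)
    ds$adt_to_gene <- c(ds$adt_to_gene,
                        stats::setNames(sim$truth$housekeeping_genes[seq_along(ctrl)],
                                        ctrl))
    pc <- suppressMessages(all_pairs_correlation(ds, n_permutations = 0))
    coupled_rho <- pc$rho[!grepl("^CTRL-", pc$adt_id)]
    uncoupled_rho <- pc$rho[grepl("^CTRL-", pc$adt_id)]
    expect_true(min(coupled_rho) > max(uncoupled_rho))
  }
})

test_that("all-pairs composes with pair_correlation and covers usable clusters", {
  sim <- small_sim()
  ds <- sim$dataset
  ds$adt_to_gene <- ds$adt_to_gene[1]
  # rename the other tags so the heuristic cannot re-map them
  keep <- names(ds$adt_to_gene)
  ds$adt_ids <- ifelse(ds$adt_ids == keep, keep,
                       paste0("ISO-", seq_along(ds$adt_ids)))
  colnames(ds$adt) <- ds$adt_ids
  single <- suppressMessages(all_pairs_correlation(ds, n_permutations = 49, seed = 2))
  direct <- pair_correlation(ds, names(ds$adt_to_gene), ds$adt_to_gene[[1]],
                             n_permutations = 49, seed = 1002)
  expect_equal(single$rho, direct$rho)
  expect_equal(single$p_value, direct$p_value)

  asn <- new_assignment_from_truth(sim)
  both <- suppressMessages(all_pairs_correlation(ds, clusters = asn,
                                                 n_permutations = 9, seed = 1))
  usable <- names(which(table(asn$labels) >= 3))
  expect_setequal(sub("^cluster:", "", setdiff(both$scope, "global")), usable)

  ds$adt_to_gene <- NULL
  ds$adt_ids <- paste0("XX-", seq_along(ds$adt_ids))
  colnames(ds$adt) <- ds$adt_ids
  expect_error(suppressMessages(all_pairs_correlation(ds)), "empty map")
})

test_that("recovered coupling improves with cell count", {
  mae <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_cite_seq(synthetic_config(
        n_cells = n, seed = 500 + s,
        n_genes = 400, n_marker_genes_per_cluster = 10))
      rec <- vapply(1:5, function(i) {
        pair_correlation(sim$dataset, sim$truth$coupling$adt_id[i],
                         sim$truth$coupling$gene_id[i],
                         scale = "raw", n_permutations = 0)$rho
      }, numeric(1))
      mean(abs(rec - 0.8))
    }, numeric(1)))
  }
  expect_lt(mae(2000, 1:3), mae(200, 1:3))
})

test_that("the paired UMAP view is deterministic and shares one embedding", {
  skip_if_not_installed("uwot")
  sim <- small_sim()
  adt <- sim$truth$coupling$adt_id[1]
  u1 <- suppressMessages(umap_pair_plot(sim$dataset, adt, seed = 3))
  u2 <- suppressMessages(umap_pair_plot(sim$dataset, adt, seed = 3))
  expect_equal(u1$embedding$umap_1, u2$embedding$umap_1)
  expect_equal(u1$embedding$umap_2, u2$embedding$umap_2)
  expect_s3_class(u1$plots$adt_umap, "ggplot")
  # both panels are drawn from the same embedding tibble by construction;
  # the statistic is present regardless
  expect_equal(nrow(u1$correlation), 1)
})
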