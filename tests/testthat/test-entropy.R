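# independent one-line oracle: direct evaluation of -sum p log2 p
entropy_oracle <- function(p) {
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

profile_from_p <- function(p, id = "f") {
  # build a cluster_profile realizing exactly the proportions p
  k <- length(p)
  cluster_profile(rep(p, each = 2), rep(seq_len(k), each = 2), feature_id = id)
}

test_that("cluster profiles use means, so cluster size cannot bias them", {
  # equal per-cell expression, 4 equal clusters -> uniform p
  pr <- cluster_profile(rep(1, 8), rep(1:4, each = 2))
  expect_equal(pr$profile$p, rep(0.25, 4))

  # nonzero only in cluster 2 -> one-hot
  expr <- c(0, 0, 3, 5, 0, 0)
  pr2 <- cluster_profile(expr, c(1, 1, 2, 2, 3, 3))
  expect_equal(pr2$profile$p, c(0, 1, 0))

  # unequal cluster sizes (1, 2, 5 cells), equal per-cell expression:
  # hand computation -> means all equal -> p uniform
  pr3 <- cluster_profile(rep(2, 8), factor(rep(1:3, times = c(1, 2, 5))))
  expect_equal(pr3$profile$p, rep(1 / 3, 3))

  # degenerate: zero everywhere
  pr0 <- cluster_profile(rep(0, 6), rep(1:3, 2))
  expect_true(pr0$degenerate)
  expect_error(shannon_entropy(pr0), class = "citeqc_degenerate_profile")
})

test_that("closed-form entropies are exact", {
  # two equal clusters of eight: raw 1 bit, normalized 1/3
  e <- shannon_entropy(profile_from_p(c(0.5, 0.5, 0, 0, 0, 0, 0, 0)))
  expect_equal(e$raw_entropy, 1)
  expect_equal(e$normalized_entropy, 1 / 3)

  # uniform over 10 clusters: normalized exactly 1
  e2 <- shannon_entropy(profile_from_p(rep(0.1, 10)))
  expect_equal(e2$normalized_entropy, 1)

  # (0.7, 0.2, 0.1): agrees with the direct-formula oracle
  e3 <- shannon_entropy(profile_from_p(c(0.7, 0.2, 0.1)))
  expect_equal(e3$raw_entropy, entropy_oracle(c(0.7, 0.2, 0.1)), tolerance = 1e-12)
  expect_equal(e3$raw_entropy, 1.15678, tolerance = 1e-5)
  expect_equal(e3$normalized_entropy, 0.72985, tolerance = 1e-5)

  # single cluster: raw 0, normalized not applicable
  e1 <- shannon_entropy(cluster_profile(c(1, 2), factor(c(1, 1))))
  expect_equal(e1$raw_entropy, 0)
  expect_true(is.na(e1$normalized_entropy))
})

test_that("entropy is non-decreasing when mixing toward the uniform", {
  lambdas <- c(0, 0.25, 0.5, 0.75, 1)
  for (i in 1:100) {
    p <- withr::with_seed(3000 + i, {
      x <- rgamma(sample(2:8, 1), shape = 0.5)
      x / sum(x)
    })
    u <- rep(1 / length(p), length(p))
    h <- vapply(lambdas, function(l) entropy_oracle((1 - l) * p + l * u),
                numeric(1))
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("entropy is invariant to expression scaling and label permutation", {
  sim <- small_sim()
  cl <- set_clusters(sim$dataset, sim$truth$labels)
  norm <- normalize_counts(sim$dataset, "RNA", "library_size")
  g <- sim$truth$marker_genes[[1]][1]
  v <- as.vector(norm[, g])

  base <- shannon_entropy(cluster_profile(v, cl$cluster_labels, g))
  scaled <- shannon_entropy(cluster_profile(v * 37.5, cl$cluster_labels, g))
  expect_equal(scaled$raw_entropy, base$raw_entropy, tolerance = 1e-12)

  relabel <- factor(as.character(cl$cluster_labels),
                    levels = c("2", "3", "1"))
  perm <- shannon_entropy(cluster_profile(v, relabel, g))
  expect_equal(perm$raw_entropy, base$raw_entropy, tolerance = 1e-12)
})

test_that("cluster-specific ADTs separate from uniform ADTs by entropy", {
  for (s in c(42, 13, 77)) {
    sim <- if (s == 42) default_sim() else simulate_cite_seq(synthetic_config(seed = s))
    asn <- new_assignment_from_truth(sim)
    ent <- entropy_set(sim$dataset, sim$dataset$adt_ids, asn, "ADT")
    coupled <- ent$normalized_entropy[grepl("_ADT$", ent$feature_id)]
    uniform <- ent$normalized_entropy[grepl("^CTRL-", ent$feature_id)]
    expect_true(max(coupled) < min(uniform))
  }
})

test_that("marker genes have lower entropy than random non-marker genes", {
  sim <- default_sim()
  asn <- new_assignment_from_truth(sim)
  mk <- suppressWarnings(find_markers(sim$dataset,
                                      define_clusters(sim$dataset, seed = 42),
                                      top_k = 10))
  marker_ent <- entropy_set(sim$dataset, marker_genes(mk), asn, "RNA")
  random_hk <- withr::with_seed(21, sample(sim$truth$housekeeping_genes, 100))
  hk_ent <- entropy_set(sim$dataset, random_hk, asn, "RNA")
  expect_lt(median(marker_ent$normalized_entropy),
            median(hk_ent$normalized_entropy))
})

test_that("entropy_set composes with single-feature computation", {
  sim <- small_sim()
  asn <- new_assignment_from_truth(sim)
  g <- sim$truth$housekeeping_genes[1]
  set_res <- entropy_set(sim$dataset, g, asn, "RNA")
  norm <- normalize_counts(sim$dataset, "RNA", "library_size")
  single <- shannon_entropy(cluster_profile(as.vector(norm[, g]), asn, g))
  expect_equal(set_res$raw_entropy, single$raw_entropy)
  expect_equal(set_res$normalized_entropy, single$normalized_entropy)

  expect_error(entropy_set(sim$dataset, character(0), asn, "RNA"), "empty")
  expect_error(entropy_set(sim$dataset, "NOT_A_GENE", asn, "RNA"), "not in")
})
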