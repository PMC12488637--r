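# fixtures are generated in code and cached for the duration of the run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference conditions: 2000 cells x 1000 genes x 10 ADTs, 4 clusters
default_sim <- function(seed = 42) {
  cached(paste0("default_", seed),
         simulate_cite_seq(synthetic_config(seed = seed)))
}

# desk-scale config for fast structural tests
small_config <- function(seed = 1, n_cells = 300, n_genes = 200,
                         n_marker_genes_per_cluster = 8, n_mito_genes = 5,
                         ...) {
  synthetic_config(
    n_cells = n_cells, n_clusters = 3, cluster_proportions = c(0.5, 0.3, 0.2),
    n_genes = n_genes,
    n_marker_genes_per_cluster = n_marker_genes_per_cluster,
    n_mito_genes = n_mito_genes, n_adts = 6, n_coupled_adts = 3,
    seed = seed, ...)
}

small_sim <- function(seed = 1) {
  cached(paste0("small_", seed), simulate_cite_seq(small_config(seed = seed)))
}

# a tiny hand-built paired dataset (3 cells, 4 genes, 2 ADTs)
toy_dataset <- function() {
  rna <- matrix(c(5, 0, 3, 2,
                  0, 1, 0, 4,
                  7, 2, 1, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("c1", "c2", "c3"),
                                c("GA", "MT-CO1", "GB", "GC")))
  adt <- matrix(c(10, 3,
                  4, 8,
                  0, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("c1", "c2", "c3"), c("A1", "A2")))
  cite_dataset(rna, adt, adt_to_gene = c(A1 = "GA"))
}

# ground-truth labels as a cluster assignment, in dataset cell order
new_assignment_from_truth <- function(sim) {
  as_cluster_assignment(sim$truth$labels[sim$dataset$cell_ids])
}

# independent Spearman (the reference implementation used as an oracle)
spearman_ref <- function(x, y) suppressWarnings(cor(x, y, method = "spearman"))

# adjusted Rand index between two partitions (independent contingency-table
# implementation; used only to score cluster recovery against ground truth)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
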