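#' Configuration for the synthetic CITE-seq generator
#'
#' Describes a dataset with K discrete cell clusters, negative-binomial RNA
#' counts, cluster-restricted marker genes, mitochondrial and housekeeping
#' genes, per-cell depth variation, and a small ADT panel whose coupled tags
#' track their cognate gene at a planted rank correlation. The defaults are
#' the package's reference conditions: 2,000 cells in 4 clusters
#' (40/30/20/10%), 1,000 genes with 20 markers per cluster at 8-fold
#' enrichment, 10 mitochondrial genes carrying 5% of counts on average,
#' lognormal depth (sdlog 0.35), and 10 ADTs — 5 coupled at rank
#' correlation 0.8, 5 background-only.
#'
#' @param n_cells,n_clusters,cluster_proportions cell-level structure;
#'   proportions must sum to 1.
#' @param n_genes,n_marker_genes_per_cluster,marker_fold_change gene panel;
#'   fold change must exceed 1.
#' @param n_mito_genes,mito_fraction_mean mitochondrial genes (named
#'   `MT-1`, ...) and their mean share of per-cell counts.
#' @param mito_depth_exponent exponent linking the mitochondrial share to
#'   per-cell depth (0 = independent, the default; positive values plant a
#'   depth-dependent mitochondrial fraction for power checks).
#' @param nb_dispersion negative-binomial size parameter for RNA counts.
#' @param depth_meanlog,depth_sdlog lognormal per-cell size-factor
#'   parameters.
#' @param n_adts,n_coupled_adts,adt_coupling ADT panel: the first
#'   `n_coupled_adts` tags are Gaussian-copula coupled to cognate marker
#'   genes at rank correlation `adt_coupling` (scalar or vector); the rest
#'   are cluster-uniform background tags.
#' @param adt_signal_mu per-ADT mean signal counts (default: geometric
#'   ladder from 100 down to 0.5 so detection varies across the panel).
#' @param adt_background_level mean of the additive Poisson background.
#' @param ambient_depth_exponent exponent linking ambient-driven ADT signal
#'   (the uncoupled control tags and the additive background) to per-cell
#'   depth; ambient tag capture scales with how much material a droplet
#'   yields, so control-tag counts track depth while antigen-driven signal
#'   does not.
#' @param adt_dispersion negative-binomial size for ADT signal counts.
#' @param capture_exponent exponent of the depth-linked binomial thinning of
#'   ADT counts (protein capture efficiency; mild by default so uncoupled
#'   pairs stay near rho = 0 while cell-level RNA/ADT coverage stays
#'   positively coupled).
#' @param seed integer; generation is fully deterministic given the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 2000, n_clusters = 4,
                             cluster_proportions = c(0.4, 0.3, 0.2, 0.1),
                             n_genes = 1000, n_marker_genes_per_cluster = 20,
                             marker_fold_change = 8,
                             n_mito_genes = 10, mito_fraction_mean = 0.05,
                             mito_depth_exponent = 0,
                             nb_dispersion = 2,
                             depth_meanlog = 0, depth_sdlog = 0.35,
                             n_adts = 10, n_coupled_adts = 5,
                             adt_coupling = 0.8,
                             adt_signal_mu = NULL,
                             adt_background_level = 1,
                             adt_dispersion = 8,
                             ambient_depth_exponent = 0.5,
                             capture_exponent = 0.15,
                             seed = 1) {
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8) {
    abort("cluster_proportions must have length n_clusters and sum to 1")
  }
  if (marker_fold_change <= 1) abort("marker_fold_change must exceed 1")
  n_special <- n_clusters * n_marker_genes_per_cluster + n_mito_genes
  if (n_special >= n_genes) {
    abort(sprintf("n_genes = %d too small for %d marker + %d mito genes",
                  n_genes, n_clusters * n_marker_genes_per_cluster, n_mito_genes))
  }
  if (n_coupled_adts > n_adts) abort("n_coupled_adts exceeds n_adts")
  if (n_coupled_adts > n_clusters * n_marker_genes_per_cluster) {
    abort("not enough marker genes to serve as cognates for the coupled ADTs")
  }
  adt_coupling <- rep_len(adt_coupling, n_coupled_adts)
  if (any(abs(adt_coupling) > 1)) abort("adt_coupling must lie in [-1, 1]")
  adt_signal_mu <- adt_signal_mu %||%
    exp(seq(log(100), log(0.5), length.out = max(n_adts, 2)))[seq_len(n_adts)]
  structure(
    list(n_cells = n_cells, n_clusters = n_clusters,
         cluster_proportions = cluster_proportions, n_genes = n_genes,
         n_marker_genes_per_cluster = n_marker_genes_per_cluster,
         marker_fold_change = marker_fold_change,
         n_mito_genes = n_mito_genes, mito_fraction_mean = mito_fraction_mean,
         mito_depth_exponent = mito_depth_exponent,
         nb_dispersion = nb_dispersion,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         n_adts = n_adts, n_coupled_adts = n_coupled_adts,
         adt_coupling = adt_coupling, adt_signal_mu = adt_signal_mu,
         adt_background_level = adt_background_level,
         adt_dispersion = adt_dispersion,
         ambient_depth_exponent = ambient_depth_exponent,
         capture_exponent = capture_exponent, seed = seed),
    class = "synthetic_config")
}

#' Generate a synthetic CITE-seq dataset with ground truth
#'
#' RNA counts are negative binomial with mean
#' `base_expression x marker_fold (if the gene marks the cell's cluster)
#' x depth factor`; mitochondrial genes are budgeted so their expected share
#' of counts equals `mito_fraction_mean`. Coupled ADTs are built by a
#' Gaussian copula on the cognate gene's realized count ranks, so the
#' planted value is exactly the rank correlation the concordance metrics
#' estimate; a Poisson background and a mild depth-linked binomial thinning
#' (capture efficiency) are then applied.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a [cite_dataset()] including the
#'   `adt_to_gene` map for coupled tags) and `truth`: `labels` (factor),
#'   `marker_genes` (list per cluster), `housekeeping_genes`, `mito_genes`,
#'   `coupling` (tibble `adt_id`, `gene_id`, `coupling`), `depth`.
#' @export
simulate_cite_seq <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed_if(config$seed, simulate_cite_seq_impl(config))
}

simulate_cite_seq_impl <- function(cfg) {
  K <- cfg$n_clusters
  nm <- cfg$n_marker_genes_per_cluster
  n_marker <- K * nm
  n_hk <- cfg$n_genes - n_marker - cfg$n_mito_genes

  gene_ids <- c(sprintf("G%04d", seq_len(n_marker + n_hk)),
                sprintf("MT-%d", seq_len(cfg$n_mito_genes)))
  marker_sets <- split(gene_ids[seq_len(n_marker)], rep(seq_len(K), each = nm))
  names(marker_sets) <- as.character(seq_len(K))
  hk_genes <- gene_ids[(n_marker + 1):(n_marker + n_hk)]
  mito_genes <- gene_ids[grepl("^MT-", gene_ids)]

  # base (cluster-free) expression levels
  base_mu <- stats::setNames(numeric(cfg$n_genes), gene_ids)
  base_mu[unlist(marker_sets)] <- 5
  base_mu[hk_genes] <- pmin(pmax(rlnorm(n_hk, meanlog = log(2), sdlog = 1), 0.1), 50)
  # budget mitochondrial genes to the target mean count share; a marker gene
  # contributes fold x base in 1/K-ish of cells -> use the expected mean
  exp_marker_factor <- 1 + (cfg$marker_fold_change - 1) *
    rep(cfg$cluster_proportions, each = nm)
  nonmito_total <- sum(base_mu[unlist(marker_sets)] * exp_marker_factor) +
    sum(base_mu[hk_genes])
  mito_total <- cfg$mito_fraction_mean / (1 - cfg$mito_fraction_mean) * nonmito_total
  mito_w <- rlnorm(cfg$n_mito_genes, 0, 0.5)
  base_mu[mito_genes] <- mito_total * mito_w / sum(mito_w)

  # cells: cluster memberships and depth factors
  labels <- factor(sample(seq_len(K), cfg$n_cells, replace = TRUE,
                          prob = cfg$cluster_proportions))
  depth <- rlnorm(cfg$n_cells, cfg$depth_meanlog, cfg$depth_sdlog)

  mu <- outer(depth, base_mu)
  for (k in seq_len(K)) {
    in_k <- labels == k
    mu[in_k, marker_sets[[k]]] <- mu[in_k, marker_sets[[k]]] * cfg$marker_fold_change
  }
  if (cfg$mito_depth_exponent != 0) {
    mu[, mito_genes] <- mu[, mito_genes] * depth^cfg$mito_depth_exponent
  }
  rna <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                nrow = cfg$n_cells,
                dimnames = list(sprintf("CELL-%04d", seq_len(cfg$n_cells)),
                                gene_ids))

  # ADT panel: coupled tags copula-tied to the realized ranks of cognate
  # marker genes (the first marker of cluster 1, 2, ..., cycling)
  cognate_idx <- vapply(seq_len(cfg$n_coupled_adts), function(i) {
    k <- ((i - 1) %% K) + 1
    j <- ((i - 1) %/% K) + 1
    marker_sets[[k]][j]
  }, character(1))
  adt_ids <- c(if (cfg$n_coupled_adts > 0) paste0(cognate_idx, "_ADT"),
               if (cfg$n_adts > cfg$n_coupled_adts)
                 sprintf("CTRL-%d", seq_len(cfg$n_adts - cfg$n_coupled_adts)))

  # ambient material (background, and the control tags entirely) scales with
  # per-cell depth; antigen-driven signal does not
  ambient <- depth^cfg$ambient_depth_exponent
  adt <- matrix(0, nrow = cfg$n_cells, ncol = cfg$n_adts,
                dimnames = list(rownames(rna), adt_ids))
  for (i in seq_len(cfg$n_adts)) {
    mu_a <- cfg$adt_signal_mu[i]
    if (i <= cfg$n_coupled_adts) {
      r <- 2 * sin(pi * cfg$adt_coupling[i] / 6)   # copula corr for target Spearman
      u <- qnorm((rank(rna[, cognate_idx[i]]) - 0.5) / cfg$n_cells)
      w <- r * u + sqrt(1 - r^2) * rnorm(cfg$n_cells)
      signal <- qnbinom(pnorm(w), mu = mu_a, size = cfg$adt_dispersion)
    } else {
      signal <- rnbinom(cfg$n_cells, mu = mu_a * ambient,
                        size = cfg$adt_dispersion)
    }
    adt[, i] <- signal + rpois(cfg$n_cells, cfg$adt_background_level * ambient)
  }
  # depth-linked capture efficiency (mild binomial thinning)
  eff <- pmin(1, 0.85 * (depth / exp(cfg$depth_meanlog + cfg$depth_sdlog^2 / 2))^
                cfg$capture_exponent)
  adt[] <- rbinom(length(adt), size = as.integer(adt), prob = rep(eff, cfg$n_adts))

  map <- if (cfg$n_coupled_adts > 0) {
    stats::setNames(cognate_idx, adt_ids[seq_len(cfg$n_coupled_adts)])
  } else NULL

  dataset <- cite_dataset(rna_counts = rna, adt_counts = adt, adt_to_gene = map)
  coupling <- tibble(
    adt_id = adt_ids,
    gene_id = c(cognate_idx, rep(NA_character_, cfg$n_adts - cfg$n_coupled_adts)),
    coupling = c(cfg$adt_coupling, rep(0, cfg$n_adts - cfg$n_coupled_adts)))
  truth <- list(labels = stats::setNames(labels, rownames(rna)),
                marker_genes = marker_sets, housekeeping_genes = hk_genes,
                mito_genes = mito_genes, coupling = coupling, depth = depth)
  list(dataset = dataset, truth = truth)
}

#' Write a dataset as an on-disk fixture
#'
#' @param dataset a [cite_dataset()].
#' @param path output directory (MTX triplet) or, for CSV, the directory in
#'   which `rna.csv` / `adt.csv` are created.
#' @param format `"mtx_triplet"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path, format = c("mtx_triplet", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    write_10x_mtx(dataset, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_csv_dataset(dataset, file.path(path, "rna.csv"),
                      if (length(dataset$adt_ids)) file.path(path, "adt.csv"))
  }
  invisible(path)
}
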