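#' Define cell clusters from RNA expression
#'
#' Standard scRNA-seq graph clustering: log-library-size normalization,
#' selection of the `n_hvgs` most variable genes, PCA (`n_pcs` components,
#' truncated SVD), a k-nearest-neighbour graph on the PC coordinates and
#' Leiden community detection (modularity objective) at the requested
#' resolution. The whole pipeline is deterministic given `seed`. Resulting
#' labels are consecutive integers ordered by decreasing cluster size.
#'
#' Clusters are always defined on RNA; ADT data never enter the clustering.
#'
#' @param dataset a [cite_dataset()] with a nonempty RNA layer.
#' @param resolution Leiden resolution; larger values give more, smaller
#'   clusters. Default 0.8.
#' @param n_hvgs number of highly variable genes kept (default 2000; capped
#'   at the gene count).
#' @param n_pcs number of principal components (default 30; reduced with a
#'   warning when the data are smaller).
#' @param k_neighbors neighbours in the kNN graph (default 20).
#' @param seed integer seed controlling SVD initialisation and Leiden.
#' @return a `cluster_assignment`: labels (factor, cell order), `n_clusters`,
#'   `source = "computed"`, `resolution`, `seed`.
#' @export
define_clusters <- function(dataset, resolution = 0.8, n_hvgs = 2000,
                            n_pcs = 30, k_neighbors = 20, seed = 1) {
  if (length(dataset$gene_ids) == 0) abort("RNA layer is empty")
  if (resolution <= 0) abort("resolution must be positive")
  nc <- n_cells(dataset)

  lognorm <- normalize_counts(dataset, "RNA", "log_library_size")
  gene_var <- col_vars(lognorm)
  n_hvgs <- min(n_hvgs, ncol(lognorm))
  hvgs <- order(gene_var, decreasing = TRUE)[seq_len(n_hvgs)]
  x <- as.matrix(lognorm[, hvgs, drop = FALSE])
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0

  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    warn(sprintf("n_pcs reduced from %d to %d for a %d x %d matrix",
                 n_pcs, max_pcs, nrow(x), ncol(x)))
    n_pcs <- max_pcs
  }

  labels <- with_seed_if(seed, {
    pcs <- irlba::prcomp_irlba(x, n = n_pcs, center = FALSE, scale. = FALSE)$x
    nn <- RANN::nn2(pcs, k = min(k_neighbors + 1L, nc))$nn.idx
    edges <- cbind(rep(seq_len(nc), ncol(nn) - 1L), as.vector(nn[, -1]))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution, n_iterations = 5)
    igraph::membership(comm)
  })

  labels <- relabel_by_size(labels)
  if (nlevels(labels) == 1) {
    warn("clustering produced a single cluster; downstream entropy is degenerate")
  }
  new_cluster_assignment(stats::setNames(labels, dataset$cell_ids),
                         source = "computed", resolution = resolution,
                         seed = seed)
}

# column variances of a (possibly sparse) matrix without densifying
col_vars <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  as.vector(Matrix::colMeans(m^2) - mu^2) * n / (n - 1)
}

relabel_by_size <- function(labels) {
  sizes <- sort(table(labels), decreasing = TRUE)
  factor(match(as.character(labels), names(sizes)))
}

new_cluster_assignment <- function(labels, source, resolution = NULL, seed = NULL) {
  structure(list(labels = labels, n_clusters = nlevels(labels),
                 source = source, resolution = resolution, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d cluster(s) [%s]\n",
              length(x$labels), x$n_clusters, x$source))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(cell_id = names(x$labels), cluster = as.character(x$labels))
}

#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(n_cells = length(x$labels), n_clusters = x$n_clusters,
         source = x$source, resolution = x$resolution %||% NA_real_,
         seed = x$seed %||% NA_integer_)
}

#' Wrap existing labels as a cluster assignment
#'
#' For labels already in memory (e.g. from an external pipeline or a
#' generator's ground truth); equivalent to importing them from a file.
#'
#' @param labels vector of per-cell labels, named by cell barcode (names are
#'   kept) or unnamed.
#' @return a `cluster_assignment` with `source = "imported"`.
#' @export
as_cluster_assignment <- function(labels) {
  new_cluster_assignment(factor(stats::setNames(as.vector(labels),
                                                names(labels))),
                         source = "imported")
}

#' Import cluster labels from a TSV file
#'
#' @param dataset a [cite_dataset()].
#' @param path two-column TSV (barcode, label; header auto-detected).
#' @return a `cluster_assignment` with `source = "imported"`. Every dataset
#'   barcode must appear in the file; file barcodes absent from the dataset
#'   are ignored with a warning.
#' @export
import_clusters <- function(dataset, path) {
  tab <- read_cluster_tsv(path, dataset)
  missing <- setdiff(dataset$cell_ids, tab$cell_id)
  if (length(missing)) {
    abort(sprintf("cluster file lacks %d barcode(s), e.g.: %s", length(missing),
                  paste(head(missing, 10), collapse = ", ")))
  }
  extra <- setdiff(tab$cell_id, dataset$cell_ids)
  if (length(extra)) {
    warn(sprintf("%d barcode(s) in the cluster file are not in the dataset; ignored",
                 length(extra)))
  }
  lab <- stats::setNames(tab$cluster, tab$cell_id)[dataset$cell_ids]
  new_cluster_assignment(factor(stats::setNames(as.vector(lab), dataset$cell_ids)),
                         source = "imported")
}

#' Export cluster labels to TSV
#'
#' @param clusters a `cluster_assignment`.
#' @param path output file; written with a `barcode<TAB>cluster` header.
#' @return `path`, invisibly.
#' @export
export_clusters <- function(clusters, path) {
  readr::write_tsv(tidy(clusters), path)
  invisible(path)
}

#' Per-cluster marker genes by one-vs-rest rank-sum test
#'
#' For every cluster with at least 3 cells, each gene is tested with a
#' Wilcoxon rank-sum test of that cluster's cells against all others, on
#' log-library-size-normalized expression. P-values are Benjamini-Hochberg
#' adjusted within cluster; genes are ranked by ascending raw p-value, ties
#' broken by descending `|log_fc|` then lexicographic gene id; the `top_k`
#' best per cluster are flagged as markers.
#'
#' @param dataset a [cite_dataset()].
#' @param clusters a `cluster_assignment` with at least 2 clusters.
#' @param top_k markers flagged per cluster (default 10; 0 flags none).
#' @return a tibble (one row per cluster x gene) with columns `cluster`,
#'   `gene`, `log_fc` (difference of mean log1p-normalized expression,
#'   cluster minus rest), `p_value`, `p_adjusted`, `rank`, `is_marker`.
#' @export
find_markers <- function(dataset, clusters, top_k = 10) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  if (clusters$n_clusters < 2) abort("marker detection needs >= 2 clusters")
  labels <- clusters$labels[dataset$cell_ids]
  expr <- as.matrix(normalize_counts(dataset, "RNA", "log_library_size"))

  per_cluster <- purrr::map(levels(labels), function(cl) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3) {
      warn(sprintf("cluster '%s' has < 3 cells; skipped in marker detection", cl))
      return(NULL)
    }
    pvals <- apply(expr, 2, function(v) {
      if (all(v[in_cl] == v[in_cl][1]) && all(v == v[1])) return(1)
      suppressWarnings(wilcox.test(v[in_cl], v[!in_cl], exact = FALSE)$p.value)
    })
    lfc <- colMeans(expr[in_cl, , drop = FALSE]) -
      colMeans(expr[!in_cl, , drop = FALSE])
    tibble(cluster = cl, gene = colnames(expr),
           log_fc = unname(lfc), p_value = unname(pvals)) |>
      mutate(p_adjusted = p.adjust(.data$p_value, method = "BH")) |>
      arrange(.data$p_value, desc(abs(.data$log_fc)), .data$gene) |>
      mutate(rank = row_number())
  })

  bind_rows(per_cluster) |>
    mutate(is_marker = .data$rank <= top_k)
}

#' Marker genes flagged in a marker table
#'
#' @param markers tibble from [find_markers()].
#' @param top_k optional override of the flagging depth (uses `rank <= top_k`
#'   instead of the stored `is_marker`).
#' @return character vector of unique marker gene ids across clusters.
#' @export
marker_genes <- function(markers, top_k = NULL) {
  flagged <- if (is.null(top_k)) filter(markers, .data$is_marker)
             else filter(markers, .data$rank <= top_k)
  unique(flagged$gene)
}
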