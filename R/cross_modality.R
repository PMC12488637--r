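#' Resolve ADT-gene pairs
#'
#' The explicit `adt_to_gene` map on the dataset takes precedence. For ADTs
#' it does not cover, a naming heuristic matches tags of the form `"CD14"`
#' or `"CD14_TotalSeqB"` to an identically named gene symbol (the part
#' before the first underscore); every heuristic match is reported.
#' Pairs whose gene is absent from the RNA layer are dropped with a warning.
#'
#' @param dataset a [cite_dataset()].
#' @return tibble with columns `adt_id`, `gene_id`, `source`
#'   (`"map"`/`"heuristic"`); attribute `"unmapped"` lists ADTs without a
#'   usable partner.
#' @export
resolve_adt_pairs <- function(dataset) {
  map <- dataset$adt_to_gene %||% character(0)
  mapped <- tibble(adt_id = names(map) %||% character(0),
                   gene_id = unname(map), source = rep("map", length(map)))

  rest <- setdiff(dataset$adt_ids, mapped$adt_id)
  guess <- sub("_.*$", "", rest)
  hit <- guess %in% dataset$gene_ids
  heur <- tibble(adt_id = rest[hit], gene_id = guess[hit], source = "heuristic")
  if (nrow(heur)) {
    inform(sprintf("heuristic ADT-gene matches: %s",
                   paste(paste0(heur$adt_id, "->", heur$gene_id), collapse = ", ")))
  }

  pairs <- bind_rows(mapped, heur)
  bad <- !(pairs$gene_id %in% dataset$gene_ids)
  if (any(bad)) {
    warn(sprintf("%d mapped gene(s) absent from the RNA layer; pair(s) dropped: %s",
                 sum(bad), paste(head(pairs$adt_id[bad], 5), collapse = ", ")))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  attr(pairs, "unmapped") <- setdiff(dataset$adt_ids, pairs$adt_id)
  pairs
}

# per-cell values for a pair on the default comparison scale
pair_values <- function(dataset, adt_id, gene_id, scale = c("default", "raw")) {
  scale <- match.arg(scale)
  if (!adt_id %in% dataset$adt_ids) {
    abort(sprintf("'%s' is not in the ADT panel", adt_id))
  }
  if (!gene_id %in% dataset$gene_ids) {
    abort(sprintf(
      "gene '%s' not found for ADT '%s'; add an adt_to_gene entry mapping this ADT to a gene present in the RNA layer",
      gene_id, adt_id))
  }
  if (scale == "raw") {
    list(rna = as.vector(dataset$rna[, gene_id]),
         adt = as.vector(dataset$adt[, adt_id]))
  } else {
    list(rna = as.vector(normalize_counts(dataset, "RNA", "log_library_size")[, gene_id]),
         adt = as.vector(normalize_counts(dataset, "ADT", "clr")[, adt_id]))
  }
}

#' RNA-ADT pair correlation, globally or per cluster
#'
#' Spearman correlation (with permutation p-value) between an ADT's
#' abundance and its cognate gene's expression across cells — the core
#' RNA-protein concordance statistic. By default the comparison uses
#' log-library-size RNA and CLR ADT values; Spearman's rho is unaffected by
#' these per-cell-independent monotone transforms of the RNA scale. With a
#' cluster assignment, one correlation per cluster is returned (clusters
#' with fewer than 3 cells are skipped with a warning).
#'
#' @param dataset a [cite_dataset()].
#' @param adt_id,gene_id the pair; `gene_id` defaults to the resolved map
#'   entry for `adt_id`.
#' @param clusters optional `cluster_assignment` for per-cluster scope.
#' @param scale `"default"` (log-libsize RNA vs CLR ADT) or `"raw"` counts.
#' @param n_permutations,seed passed to [spearman_permutation()].
#' @return tibble with columns `adt_id`, `gene_id`, `scope` (`"global"` or
#'   `"cluster:<label>"`), `rho`, `p_value` (two-sided permutation p),
#'   `n_cells`, `degenerate`.
#' @export
pair_correlation <- function(dataset, adt_id, gene_id = NULL, clusters = NULL,
                             scale = c("default", "raw"),
                             n_permutations = 999, seed = NULL) {
  if (is.null(gene_id)) {
    pairs <- suppressMessages(resolve_adt_pairs(dataset))
    gene_id <- pairs$gene_id[match(adt_id, pairs$adt_id)]
    if (is.na(gene_id)) {
      abort(sprintf(
        "no gene mapped for ADT '%s'; supply gene_id or an adt_to_gene entry", adt_id))
    }
  }
  v <- pair_values(dataset, adt_id, gene_id, scale)

  one_scope <- function(idx, scope_label, scope_seed) {
    if (length(idx) < 3) {
      warn(sprintf("scope '%s' has < 3 cells; skipped", scope_label))
      return(NULL)
    }
    perm <- spearman_permutation(v$adt[idx], v$rna[idx],
                                 n_permutations = n_permutations,
                                 seed = scope_seed)
    tibble(adt_id = adt_id, gene_id = gene_id, scope = scope_label,
           rho = perm$rho, p_value = perm$p_two_sided,
           n_cells = perm$n, degenerate = perm$degenerate)
  }

  if (is.null(clusters)) {
    out <- one_scope(seq_len(n_cells(dataset)), "global", seed)
    if (is.null(out)) abort("fewer than 3 cells in scope")
    return(out)
  }
  labels <- clusters$labels
  purrr::imap(split(seq_along(labels), labels), function(idx, cl) {
    one_scope(idx, paste0("cluster:", cl),
              if (is.null(seed)) NULL else seed + match(cl, levels(labels)))
  }) |> bind_rows()
}

#' Correlations for every mapped ADT-gene pair
#'
#' Runs [pair_correlation()] over all pairs from [resolve_adt_pairs()],
#' globally and (optionally) per cluster; the histogram of the resulting
#' coefficients is the panel-wide concordance diagnostic.
#'
#' @inheritParams pair_correlation
#' @return tibble as in [pair_correlation()], one row per pair x scope;
#'   attribute `"unmapped"` carries ADTs without a usable gene.
#' @export
all_pairs_correlation <- function(dataset, clusters = NULL,
                                  scale = c("default", "raw"),
                                  n_permutations = 999, seed = NULL) {
  pairs <- resolve_adt_pairs(dataset)
  if (nrow(pairs) == 0) abort("no usable ADT-gene pairs (empty map)")
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ps <- if (is.null(seed)) NULL else seed + 1000L * i
    global <- pair_correlation(dataset, pairs$adt_id[i], pairs$gene_id[i],
                               scale = scale, n_permutations = n_permutations,
                               seed = ps)
    if (is.null(clusters)) return(global)
    bind_rows(global,
              pair_correlation(dataset, pairs$adt_id[i], pairs$gene_id[i],
                               clusters = clusters, scale = scale,
                               n_permutations = n_permutations, seed = ps))
  }) |> bind_rows()
  attr(out, "unmapped") <- attr(pairs, "unmapped")
  out
}

#' Paired UMAP view of an ADT-gene pair
#'
#' Computes a single 2-D UMAP embedding of the RNA layer (via PCA, seeded)
#' and colours the same coordinates by ADT abundance (CLR) and by gene
#' expression (log-normalized), alongside the pair scatterplot. The
#' embedding is visualization-only: no statistic is derived from it.
#'
#' @param dataset a [cite_dataset()].
#' @param adt_id,gene_id the pair.
#' @param n_pcs,seed embedding parameters; the seed makes coordinates
#'   reproducible.
#' @return list with `embedding` (tibble `cell_id`, `umap_1`, `umap_2`,
#'   `adt_value`, `rna_value`), `correlation` (global [pair_correlation()]
#'   row) and `plots` (list of three ggplots, NULL when the uwot package is
#'   unavailable, with a warning).
#' @export
umap_pair_plot <- function(dataset, adt_id, gene_id = NULL, n_pcs = 30,
                           seed = 1) {
  corr <- pair_correlation(dataset, adt_id, gene_id,
                           n_permutations = 199, seed = seed)
  gene_id <- corr$gene_id[1]
  v <- pair_values(dataset, adt_id, gene_id)

  emb <- tryCatch({
    if (!requireNamespace("uwot", quietly = TRUE)) {
      abort("package 'uwot' not installed")
    }
    lognorm <- normalize_counts(dataset, "RNA", "log_library_size")
    with_seed_if(seed, {
      x <- scale(as.matrix(lognorm))
      x[, attr(x, "scaled:scale") == 0] <- 0
      pcs <- irlba::prcomp_irlba(x, n = min(n_pcs, min(dim(x)) - 1L),
                                 center = FALSE)$x
      uwot::umap(pcs, n_threads = 1, n_sgd_threads = 1)
    })
  }, error = function(e) {
    warn(sprintf("UMAP embedding unavailable (%s); statistic still computed",
                 conditionMessage(e)))
    NULL
  })

  embedding <- NULL
  plots <- NULL
  if (!is.null(emb)) {
    embedding <- tibble(cell_id = dataset$cell_ids,
                        umap_1 = emb[, 1], umap_2 = emb[, 2],
                        adt_value = v$adt, rna_value = v$rna)
    panel <- function(fill, title) {
      ggplot2::ggplot(embedding,
                      ggplot2::aes(.data$umap_1, .data$umap_2,
                                   colour = .data[[fill]])) +
        ggplot2::geom_point(size = 0.4) +
        ggplot2::scale_colour_viridis_c() +
        ggplot2::labs(title = title, colour = NULL) +
        ggplot2::theme_minimal()
    }
    plots <- list(
      adt_umap = panel("adt_value", sprintf("%s (ADT, CLR)", adt_id)),
      rna_umap = panel("rna_value", sprintf("%s (RNA, log-normalized)", gene_id)),
      scatter = ggplot2::ggplot(tibble(adt = v$adt, rna = v$rna),
                                ggplot2::aes(.data$rna, .data$adt)) +
        ggplot2::geom_point(size = 0.4, alpha = 0.5) +
        ggplot2::labs(x = sprintf("%s (RNA)", gene_id),
                      y = sprintf("%s (ADT)", adt_id),
                      title = sprintf("rho = %.3f", corr$rho[1])) +
        ggplot2::theme_minimal())
  }
  list(embedding = embedding, correlation = corr, plots = plots)
}
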