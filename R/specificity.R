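#' Null entropy distribution from expressed, non-differential genes
#'
#' Builds the negative control for marker-specificity calibration: genes
#' that are clearly expressed (mean library-size-normalized expression above
#' `min_mean`) yet not differentially expressed in any cluster (BH-adjusted
#' one-vs-rest p-value at least `alpha` everywhere). Such genes are broadly,
#' non-specifically expressed, so their entropies form a null distribution
#' of non-specific expression. `n` genes are sampled uniformly without
#' replacement (seeded) and scored with the entropy module on the same
#' cluster assignment used for the markers.
#'
#' @param dataset a [cite_dataset()].
#' @param clusters the `cluster_assignment` shared with marker scoring.
#' @param markers full marker table from [find_markers()] (all genes, all
#'   clusters — used for the non-differential criterion).
#' @param n genes to sample (default 1000); reduced with a warning when the
#'   candidate pool is smaller.
#' @param min_mean expression floor on mean library-size-normalized counts
#'   (default 5).
#' @param alpha differential-expression significance level (default 0.05);
#'   a gene is eligible only if `p_adjusted >= alpha` in every cluster.
#' @param scale `"normalized"` or `"raw"` entropy — must match the scale on
#'   which markers will be classified.
#' @param seed integer sampling seed.
#' @return a `null_entropy` object: `gene_ids`, `entropies`, `n`,
#'   `min_mean`, `alpha`, `scale`, `seed`.
#' @export
sample_null_genes <- function(dataset, clusters, markers, n = 1000,
                              min_mean = 5, alpha = 0.05,
                              scale = c("normalized", "raw"), seed = 1) {
  scale <- match.arg(scale)
  norm <- normalize_counts(dataset, "RNA", "library_size")
  mean_expr <- Matrix::colMeans(norm)

  de_anywhere <- markers |>
    group_by(.data$gene) |>
    summarise(de = any(.data$p_adjusted < alpha), .groups = "drop")
  pool <- intersect(names(mean_expr)[mean_expr > min_mean],
                    de_anywhere$gene[!de_anywhere$de])
  if (length(pool) == 0) {
    abort("empty candidate pool: no expressed, non-differential genes")
  }
  if (length(pool) < n) {
    warn(sprintf("candidate pool has only %d gene(s); n reduced from %d",
                 length(pool), n))
    n <- length(pool)
  }

  genes <- with_seed_if(seed, sort(sample(pool, n)))
  ent <- entropy_set(dataset, genes, clusters, "RNA")
  ent <- filter(ent, !.data$degenerate)
  ecol <- if (scale == "normalized") "normalized_entropy" else "raw_entropy"
  structure(list(gene_ids = ent$feature_id, entropies = ent[[ecol]],
                 n = nrow(ent), min_mean = min_mean, alpha = alpha,
                 scale = scale, seed = seed),
            class = "null_entropy")
}

#' @export
print.null_entropy <- function(x, ...) {
  cat(sprintf(
    "<null_entropy> %d gene(s), %s entropy; floor > %g, DE alpha %g\n",
    x$n, x$scale, x$min_mean, x$alpha))
  print(summary(x$entropies))
  invisible(x)
}

#' @export
tidy.null_entropy <- function(x, ...) {
  tibble(gene = x$gene_ids, entropy = x$entropies)
}

#' Empirical entropy cutoff from a null distribution
#'
#' The specificity threshold is a low percentile (default the 5th — the left
#' tail) of the null entropy distribution, computed with the
#' linear-interpolation quantile definition. Markers with entropy strictly
#' below the cutoff are deemed statistically specific.
#'
#' @param null a [sample_null_genes()] result, or a bare numeric vector of
#'   null entropies.
#' @param percentile percentile in (0, 100); default 5.
#' @return the cutoff value (scalar).
#' @export
entropy_cutoff <- function(null, percentile = 5) {
  vals <- if (inherits(null, "null_entropy")) null$entropies else null
  if (length(vals) == 0) abort("null distribution is empty")
  if (percentile <= 0 || percentile >= 100) abort("percentile must be in (0, 100)")
  unname(quantile(vals, percentile / 100, type = 7))
}

#' Classify ranked markers as specific or non-specific
#'
#' Applies an entropy cutoff to the top-k markers per cluster, for each k in
#' `top_k_list`: within each k the unique marker genes across clusters are
#' classified as specific when their entropy is strictly below the cutoff
#' (a value exactly at the cutoff is non-specific). Markers lacking an
#' entropy (degenerate features) are excluded with a warning.
#'
#' @param markers marker table from [find_markers()].
#' @param entropies entropy tibble from [entropy_set()] covering the marker
#'   genes, on the same scale and cluster assignment as the null.
#' @param cutoff entropy threshold from [entropy_cutoff()].
#' @param top_k_list marker depths to evaluate (default `c(10, 20, 30)`).
#' @param scale `"normalized"` or `"raw"` — selects the entropy column;
#'   must match the null's scale.
#' @return a `specificity_call`: `calls` (tibble `top_k`, `gene`, `cluster`,
#'   `rank`, `entropy`, `specific`), `summary` (tibble `top_k`,
#'   `n_markers`, `n_specific`, `fraction_specific`), plus `cutoff`.
#' @export
classify_markers <- function(markers, entropies, cutoff,
                             top_k_list = c(10, 20, 30),
                             scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  ecol <- if (scale == "normalized") "normalized_entropy" else "raw_entropy"
  etab <- tibble(gene = entropies$feature_id, entropy = entropies[[ecol]])

  calls <- purrr::map(sort(top_k_list), function(k) {
    top <- markers |>
      filter(.data$rank <= k) |>
      group_by(.data$gene) |>
      dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
      ungroup() |>
      left_join(etab, by = "gene")
    dropped <- sum(is.na(top$entropy))
    if (dropped > 0) {
      warn(sprintf("%d marker(s) without entropy excluded at top_k = %d",
                   dropped, k))
    }
    top |>
      filter(!is.na(.data$entropy)) |>
      mutate(top_k = k, specific = .data$entropy < cutoff) |>
      select("top_k", "gene", "cluster", "rank", "entropy", "specific")
  }) |> bind_rows()

  summary <- calls |>
    group_by(.data$top_k) |>
    summarise(n_markers = dplyr::n(), n_specific = sum(.data$specific),
              fraction_specific = mean(.data$specific), .groups = "drop")

  structure(list(calls = calls, summary = summary, cutoff = cutoff,
                 scale = scale),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("<specificity_call> cutoff = %.4g (%s entropy; specific iff entropy < cutoff)\n",
              x$cutoff, x$scale))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.specificity_call <- function(x, ...) x$calls

#' @export
glance.specificity_call <- function(x, ...) {
  mutate(x$summary, cutoff = x$cutoff)
}
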