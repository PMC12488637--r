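#' Read-count QC correlations
#'
#' The count diagnostics each correlate two per-cell quantities with
#' Spearman's rho and a permutation p-value, testing a stated directional
#' hypothesis about healthy data:
#'
#' * [count_feature_correlation()] — `n_feature` vs `n_count` within one
#'   modality; in good data more detected features mean more total counts
#'   (hypothesis: positive).
#' * [mito_correlation()] — detected genes vs mitochondrial percentage; in
#'   good data the mitochondrial share does not track depth (hypothesis:
#'   none, two-sided).
#' * [rna_adt_count_correlation()] — RNA `n_feature` vs ADT `n_feature`
#'   across the same cells (hypothesis: positive).
#'
#' Each returns a `qc_correlation` object with [tidy()]/[glance()] and
#' [autoplot()] methods; `p_value` is the p-value matching the recorded
#' hypothesis and `p_two_sided` is always reported alongside.
#'
#' @name qc_correlations
NULL

new_qc_correlation <- function(x, y, x_name, y_name, hypothesis,
                               perm, thresholds = NULL) {
  p_dir <- switch(hypothesis,
                  "positive correlation" = perm$p_greater,
                  "negative correlation" = perm$p_less,
                  perm$p_two_sided)
  structure(
    list(x_name = x_name, y_name = y_name, hypothesis = hypothesis,
         rho = perm$rho, p_value = p_dir, p_two_sided = perm$p_two_sided,
         n_cells = perm$n, n_permutations = perm$n_permutations,
         degenerate = perm$degenerate, thresholds = thresholds,
         data = tibble(x = x, y = y)),
    class = "qc_correlation")
}

#' @export
print.qc_correlation <- function(x, ...) {
  cat(sprintf("<qc_correlation> %s vs %s (n = %d cells)\n",
              x$x_name, x$y_name, x$n_cells))
  cat(sprintf("  hypothesis: %s\n", x$hypothesis))
  if (x$degenerate) {
    cat("  degenerate input (constant values); rho = 0, p = 1\n")
  } else {
    cat(sprintf("  Spearman rho = %.4f; p = %.4g (%d permutations; two-sided %.4g)\n",
                x$rho, x$p_value, x$n_permutations, x$p_two_sided))
  }
  invisible(x)
}

#' @describeIn qc_correlations correlate `n_feature` with `n_count` for one
#'   modality's [per_cell_stats()] tibble.
#' @param stats,stats_rna,stats_adt tibbles from [per_cell_stats()].
#' @param n_permutations,seed passed to [spearman_permutation()].
#' @param thresholds optional [cell_filter_thresholds()] carried along for
#'   plot annotation.
#' @export
count_feature_correlation <- function(stats, n_permutations = 999, seed = NULL,
                                      thresholds = NULL) {
  check_min_cells(stats)
  perm <- spearman_permutation(stats$n_feature, stats$n_count,
                               n_permutations = n_permutations, seed = seed)
  new_qc_correlation(stats$n_feature, stats$n_count,
                     paste0("n_feature_", stats$modality[1]),
                     paste0("n_count_", stats$modality[1]),
                     "positive correlation", perm, thresholds)
}

#' @describeIn qc_correlations correlate detected genes with the
#'   mitochondrial percentage (RNA stats only).
#' @export
mito_correlation <- function(stats, n_permutations = 999, seed = NULL,
                             thresholds = NULL) {
  check_min_cells(stats)
  if (!"percent_mito" %in% names(stats)) {
    abort("mito_correlation needs RNA per_cell_stats with percent_mito")
  }
  perm <- spearman_permutation(stats$n_feature, stats$percent_mito,
                               n_permutations = n_permutations, seed = seed)
  new_qc_correlation(stats$n_feature, stats$percent_mito,
                     "n_feature_RNA", "percent_mito",
                     "no correlation", perm, thresholds)
}

#' @describeIn qc_correlations correlate RNA `n_feature` with ADT
#'   `n_feature` on the shared cells.
#' @export
rna_adt_count_correlation <- function(stats_rna, stats_adt,
                                      n_permutations = 999, seed = NULL) {
  check_min_cells(stats_rna)
  if (!identical(stats_rna$cell_id, stats_adt$cell_id)) {
    abort("RNA and ADT stats must cover the same cells in the same order")
  }
  perm <- spearman_permutation(stats_rna$n_feature, stats_adt$n_feature,
                               n_permutations = n_permutations, seed = seed)
  new_qc_correlation(stats_rna$n_feature, stats_adt$n_feature,
                     "n_feature_RNA", "n_feature_ADT",
                     "positive correlation", perm)
}

check_min_cells <- function(stats, min = 3) {
  if (nrow(stats) < min) abort(sprintf("need at least %d cells", min))
}

#' @export
tidy.qc_correlation <- function(x, ...) {
  tibble(x_name = x$x_name, y_name = x$y_name, hypothesis = x$hypothesis,
         rho = x$rho, p_value = x$p_value, p_two_sided = x$p_two_sided,
         n_cells = x$n_cells, n_permutations = x$n_permutations,
         degenerate = x$degenerate)
}

#' @export
glance.qc_correlation <- function(x, ...) tidy(x)
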