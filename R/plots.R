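#' @export
autoplot.qc_correlation <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      title = sprintf("%s vs %s", object$x_name, object$y_name),
      subtitle = sprintf("Spearman rho = %.3f, p = %.3g (%s)",
                         object$rho, object$p_value, object$hypothesis)) +
    ggplot2::theme_minimal()
  th <- object$thresholds
  if (!is.null(th) && grepl("^n_feature", object$x_name)) {
    p <- p + ggplot2::geom_vline(xintercept = c(th$min_n_feature, th$max_n_feature),
                                 linetype = "dashed", colour = "red")
  }
  if (!is.null(th) && object$y_name == "percent_mito") {
    p <- p + ggplot2::geom_hline(yintercept = th$max_percent_mito,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.cluster_profile <- function(object, ...) {
  df <- object$profile
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = "proportion of mean expression",
                  title = object$feature_id) +
    ggplot2::theme_minimal()
}

#' Histogram of entropy values for a feature set
#'
#' @param entropies tibble from [entropy_set()].
#' @param scale `"normalized"` or `"raw"` — which entropy column to draw.
#' @param cutoff optional vertical cutoff line (e.g. from [entropy_cutoff()]).
#' @param title plot title.
#' @return a ggplot.
#' @export
plot_entropy_histogram <- function(entropies, scale = c("normalized", "raw"),
                                   cutoff = NULL, title = "Entropy distribution") {
  scale <- match.arg(scale)
  ecol <- if (scale == "normalized") "normalized_entropy" else "raw_entropy"
  df <- filter(entropies, !is.na(.data[[ecol]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ecol]])) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = sprintf("%s Shannon entropy", scale), y = "features",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Histogram of ADT-gene pair correlations
#'
#' @param pairs tibble from [all_pairs_correlation()].
#' @param by_cluster facet per-cluster scopes (default: global scope only).
#' @return a ggplot.
#' @export
plot_pair_histogram <- function(pairs, by_cluster = FALSE) {
  df <- if (by_cluster) filter(pairs, .data$scope != "global")
        else filter(pairs, .data$scope == "global")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rho)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Spearman rho (ADT vs cognate gene)", y = "pairs",
                  title = if (by_cluster) "Pair correlations per cluster"
                          else "Pair correlations (all cells)") +
    ggplot2::theme_minimal()
  if (by_cluster) p <- p + ggplot2::facet_wrap(~scope)
  p
}

#' @export
autoplot.noise_experiment <- function(object, ...) {
  if (object$experiment == "correlation_degradation") {
    ggplot2::ggplot(object$metrics,
                    ggplot2::aes(factor(.data$shuffle_fraction), .data$rho)) +
      ggplot2::geom_boxplot(fill = "steelblue") +
      ggplot2::labs(x = "shuffle fraction", y = "nFeature-nCount Spearman rho",
                    title = sprintf("Correlation degradation (%s)",
                                    object$config$modality)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$metrics,
                    ggplot2::aes(.data$entropy,
                                 colour = factor(.data$shuffle_fraction))) +
      ggplot2::geom_density() +
      ggplot2::labs(x = sprintf("%s Shannon entropy", object$scale),
                    colour = "shuffle fraction",
                    title = sprintf("Entropy shift under corruption (%s)",
                                    object$config$modality)) +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.specificity_call <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(.data$entropy, fill = .data$specific)) +
    ggplot2::geom_histogram(bins = 30, colour = "white") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~top_k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = sprintf("%s Shannon entropy", object$scale),
                  y = "markers",
                  title = sprintf("Marker specificity (cutoff %.3g)", object$cutoff)) +
    ggplot2::theme_minimal()
}
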