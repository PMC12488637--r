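#' Configuration for a noise-injection experiment
#'
#' Defaults mirror the reference protocol for the two controlled
#' corruption experiments: 10% of cells sampled per replicate; RNA shuffle
#' fractions 5/10/20% repeated 10 times; ADT shuffle fractions 10/20/30%
#' repeated 50 times (higher fractions and more replicates compensate for
#' the far smaller ADT panel); for the entropy-shift experiment on RNA,
#' the 10,000 features with highest expression standard deviation are
#' retained first. Every field is overridable; desk-scale runs typically
#' reduce replicate and feature counts.
#'
#' @param modality `"RNA"` or `"ADT"`.
#' @param cell_fraction fraction of cells sampled per replicate (default 0.10).
#' @param shuffle_fractions fractions of features to shuffle; defaults
#'   `c(0.05, 0.10, 0.20)` for RNA, `c(0.10, 0.20, 0.30)` for ADT.
#' @param n_replicates replicates per fraction; default 10 (RNA) / 50 (ADT).
#' @param n_top_sd_features features kept (by expression SD) before
#'   corruption in the entropy experiment; default 10000 for RNA, NULL (all)
#'   for ADT.
#' @param seed integer; every replicate's cell sample and shuffle derive
#'   deterministically from it.
#' @return a `noise_config` list.
#' @export
noise_config <- function(modality = c("RNA", "ADT"), cell_fraction = 0.10,
                         shuffle_fractions = NULL, n_replicates = NULL,
                         n_top_sd_features = NULL, seed = 1) {
  modality <- match.arg(modality)
  shuffle_fractions <- shuffle_fractions %||%
    if (modality == "RNA") c(0.05, 0.10, 0.20) else c(0.10, 0.20, 0.30)
  n_replicates <- n_replicates %||% if (modality == "RNA") 10L else 50L
  if (is.null(n_top_sd_features) && modality == "RNA") n_top_sd_features <- 10000L
  if (any(shuffle_fractions < 0 | shuffle_fractions > 1)) {
    abort("shuffle_fractions must lie in [0, 1]")
  }
  if (cell_fraction <= 0 || cell_fraction > 1) abort("cell_fraction must be in (0, 1]")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  structure(list(modality = modality, cell_fraction = cell_fraction,
                 shuffle_fractions = shuffle_fractions,
                 n_replicates = as.integer(n_replicates),
                 n_top_sd_features = n_top_sd_features, seed = seed),
            class = "noise_config")
}

#' Shuffle a fraction of features across cells
#'
#' Selects `ceiling(fraction * n_features)` features at random (seeded) and
#' independently permutes each selected feature's values across cells,
#' leaving other features untouched. Each feature's value multiset — and
#' hence the matrix grand total — is preserved exactly; what is destroyed is
#' the association between a cell's identity and the feature's value, the
#' controlled corruption used to validate the QC metrics.
#'
#' @param dataset a [cite_dataset()].
#' @param modality `"RNA"` or `"ADT"`.
#' @param fraction fraction of features to corrupt, in `[0, 1]`.
#' @param seed integer seed for feature choice and permutations.
#' @return the corrupted copy of `dataset`; an attribute
#'   `"shuffled_features"` on the returned object's count matrix is not
#'   kept — use [shuffled_feature_ids()] to recompute the selection.
#' @export
shuffle_features <- function(dataset, modality = c("RNA", "ADT"), fraction,
                             seed = 1) {
  modality <- match.arg(modality)
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  m <- modality_counts(dataset, modality)
  if (fraction == 0 || ncol(m) == 0) return(dataset)
  with_seed_if(seed, {
    chosen <- sample.int(ncol(m), ceiling(fraction * ncol(m)))
    dense <- as.matrix(m[, chosen, drop = FALSE])
    for (j in seq_along(chosen)) dense[, j] <- dense[sample.int(nrow(dense)), j]
    m[, chosen] <- dense
  })
  modality_counts(dataset, modality) <- m
  dataset
}

#' Feature ids selected by a seeded shuffle
#'
#' Replays the feature selection of [shuffle_features()] for the same
#' `(dataset, modality, fraction, seed)` without corrupting anything.
#'
#' @inheritParams shuffle_features
#' @return character vector of selected feature ids.
#' @export
shuffled_feature_ids <- function(dataset, modality = c("RNA", "ADT"), fraction,
                                 seed = 1) {
  modality <- match.arg(modality)
  ids <- if (match.arg(modality) == "RNA") dataset$gene_ids else dataset$adt_ids
  if (fraction == 0 || length(ids) == 0) return(character(0))
  with_seed_if(seed, ids[sample.int(length(ids), ceiling(fraction * length(ids)))])
}

#' Features with the highest expression standard deviation
#'
#' Ranks features of one modality by the standard deviation of their raw
#' counts across cells and returns the `n` most variable, ties broken
#' lexicographically by feature id.
#'
#' @param dataset a [cite_dataset()].
#' @param n number of features to keep (`1 <= n <= n_features`).
#' @param modality `"RNA"` or `"ADT"`.
#' @return character vector of `n` feature ids.
#' @export
select_top_sd_features <- function(dataset, n, modality = c("RNA", "ADT")) {
  modality <- match.arg(modality)
  m <- modality_counts(dataset, modality)
  if (n <= 0) abort("n must be positive")
  n <- min(n, ncol(m))
  sds <- sqrt(col_vars(m))
  ids <- colnames(m)
  ids[order(-sds, ids)][seq_len(n)]
}

#' Correlation-degradation experiment
#'
#' The first sensitivity check: per replicate, sample `cell_fraction` of the
#' cells; for each shuffle fraction, corrupt that sample with
#' [shuffle_features()], recompute [per_cell_stats()] and record the
#' nFeature-nCount Spearman rho. In sound data the correlation is strongly
#' positive; increasing corruption should drive it down, which is the
#' signature this experiment verifies.
#'
#' @param dataset a [cite_dataset()].
#' @param config a [noise_config()].
#' @return a `noise_experiment` with `metrics`: tibble of
#'   `shuffle_fraction`, `replicate`, `rho`, `n_cells`.
#' @export
correlation_degradation_experiment <- function(dataset, config) {
  stopifnot(inherits(config, "noise_config"))
  nc <- n_cells(dataset)
  n_sample <- max(1L, round(config$cell_fraction * nc))
  if (n_sample < 3) abort("sampled cell count < 3; raise cell_fraction")

  metrics <- purrr::map(seq_len(config$n_replicates), function(rep_i) {
    cells <- with_seed_if(config$seed + rep_i,
                          sample.int(nc, n_sample))
    sub <- subset_cells(dataset, cells)
    purrr::map(seq_along(config$shuffle_fractions), function(fi) {
      frac <- config$shuffle_fractions[fi]
      corrupted <- shuffle_features(sub, config$modality, frac,
                                    seed = config$seed + 1000L * rep_i + fi)
      st <- per_cell_stats(corrupted, config$modality)
      perm <- spearman_permutation(st$n_feature, st$n_count,
                                   n_permutations = 0, seed = 0)
      tibble(shuffle_fraction = frac, replicate = rep_i,
             rho = perm$rho, n_cells = n_sample)
    }) |> bind_rows()
  }) |> bind_rows()

  structure(list(metrics = metrics, config = config,
                 experiment = "correlation_degradation"),
            class = "noise_experiment")
}

#' Entropy-shift experiment
#'
#' The second sensitivity check: per replicate, sample `cell_fraction` of
#' the cells, restrict RNA to the `n_top_sd_features` most variable
#' features, corrupt a fraction of features, re-define clusters on the
#' corrupted sample, and compute cluster-conditional Shannon entropies.
#' As corruption grows, cluster structure erodes and the entropy
#' distribution shifts right (toward uniformity); adjacent fractions are
#' compared with a one-sided rank-sum location test
#' ([compare_entropy_distributions()]), pooling replicates.
#'
#' @param dataset a [cite_dataset()].
#' @param config a [noise_config()].
#' @param resolution clustering resolution passed to [define_clusters()].
#' @param feature_set which features enter the entropy histogram:
#'   `"markers"` (default) uses the top-`top_k`-per-cluster marker genes
#'   identified on the corrupted sample, mirroring the marker-entropy
#'   histogram; `"shuffled"` scores exactly the corrupted features;
#'   `"all"` uses every retained feature.
#' @param top_k markers per cluster when `feature_set = "markers"`.
#' @param scale `"normalized"` (default) or `"raw"` entropy values.
#' @return a `noise_experiment` with `metrics` (tibble of
#'   `shuffle_fraction`, `replicate`, `feature_id`, `entropy`), `shifts`
#'   (tibble of adjacent-fraction one-sided p-values) and `flagged`
#'   (replicates excluded because clustering collapsed to one cluster).
#' @export
entropy_shift_experiment <- function(dataset, config, resolution = 0.8,
                                     feature_set = c("markers", "shuffled", "all"),
                                     top_k = 10,
                                     scale = c("normalized", "raw")) {
  stopifnot(inherits(config, "noise_config"))
  feature_set <- match.arg(feature_set)
  scale <- match.arg(scale)
  ecol <- if (scale == "normalized") "normalized_entropy" else "raw_entropy"
  fractions <- sort(config$shuffle_fractions)
  nc <- n_cells(dataset)
  n_sample <- max(1L, round(config$cell_fraction * nc))
  if (n_sample < 3) abort("sampled cell count < 3; raise cell_fraction")

  keep <- dataset
  if (config$modality == "RNA" && !is.null(config$n_top_sd_features)) {
    ids <- select_top_sd_features(dataset, config$n_top_sd_features, "RNA")
    keep$rna <- dataset$rna[, ids, drop = FALSE]
    keep$gene_ids <- ids
  }
  if ((config$modality == "RNA" && length(keep$gene_ids) == 0) ||
      (config$modality == "ADT" && length(keep$adt_ids) == 0)) {
    abort("no features available to shuffle")
  }

  flagged <- list()
  metrics <- purrr::map(seq_len(config$n_replicates), function(rep_i) {
    cells <- with_seed_if(config$seed + rep_i, sample.int(nc, n_sample))
    sub <- subset_cells(keep, cells)
    purrr::map(seq_along(fractions), function(fi) {
      frac <- fractions[fi]
      corrupted <- shuffle_features(sub, config$modality, frac,
                                    seed = config$seed + 1000L * rep_i + fi)
      cl <- suppressWarnings(
        define_clusters(corrupted, resolution = resolution,
                        seed = config$seed + rep_i))
      if (cl$n_clusters < 2) {
        flagged[[length(flagged) + 1]] <<-
          tibble(shuffle_fraction = frac, replicate = rep_i)
        warn(sprintf(
          "replicate %d at fraction %.2f collapsed to one cluster; excluded",
          rep_i, frac))
        return(NULL)
      }
      feats <- if (feature_set == "shuffled") {
        ids <- shuffled_feature_ids(sub, config$modality, frac,
                                    seed = config$seed + 1000L * rep_i + fi)
        if (length(ids) == 0) abort("empty shuffle set: no features corrupted")
        ids
      } else if (config$modality == "ADT") {
        corrupted$adt_ids
      } else if (feature_set == "markers") {
        marker_genes(suppressWarnings(find_markers(corrupted, cl, top_k = top_k)))
      } else {
        corrupted$gene_ids
      }
      ent <- entropy_set(corrupted, feats, cl, config$modality)
      ent <- filter(ent, !.data$degenerate)
      tibble(shuffle_fraction = frac, replicate = rep_i,
             feature_id = ent$feature_id, entropy = ent[[ecol]])
    }) |> bind_rows()
  }) |> bind_rows()

  shifts <- purrr::map(seq_len(length(fractions) - 1L), function(i) {
    a <- metrics$entropy[metrics$shuffle_fraction == fractions[i]]
    b <- metrics$entropy[metrics$shuffle_fraction == fractions[i + 1]]
    tibble(from_fraction = fractions[i], to_fraction = fractions[i + 1],
           p_value = if (length(a) >= 3 && length(b) >= 3) {
             compare_entropy_distributions(a, b)
           } else NA_real_)
  }) |> bind_rows()

  structure(list(metrics = metrics, shifts = shifts,
                 flagged = bind_rows(flagged), config = config,
                 experiment = "entropy_shift", scale = scale),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat(sprintf("<noise_experiment> %s (%s), %d replicate(s) x fractions {%s}\n",
              x$experiment, x$config$modality, x$config$n_replicates,
              paste(sort(x$config$shuffle_fractions), collapse = ", ")))
  if (x$experiment == "correlation_degradation") {
    print(summarise(group_by(x$metrics, .data$shuffle_fraction),
                    mean_rho = mean(.data$rho), .groups = "drop"))
  } else {
    print(x$shifts)
  }
  invisible(x)
}

#' @export
tidy.noise_experiment <- function(x, ...) x$metrics

#' @export
glance.noise_experiment <- function(x, ...) {
  if (x$experiment == "correlation_degradation") {
    summarise(group_by(x$metrics, .data$shuffle_fraction),
              mean_rho = mean(.data$rho), sd_rho = sd(.data$rho),
              n = dplyr::n(), .groups = "drop")
  } else {
    x$shifts
  }
}

#' One-sided location-shift test between two entropy samples
#'
#' Mann-Whitney rank-sum test of the alternative that `b` is stochastically
#' larger than `a` — the "distribution shifted right" comparison used
#' between adjacent corruption levels.
#'
#' @param a,b numeric entropy samples, each of length >= 3.
#' @return the one-sided p-value.
#' @export
compare_entropy_distributions <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) abort("need >= 3 values per sample")
  suppressWarnings(wilcox.test(b, a, alternative = "greater",
                               exact = FALSE)$p.value)
}
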