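#' Per-cell summary statistics for one modality
#'
#' Computes the standard per-cell QC quantities: `n_count` (total counts),
#' `n_feature` (number of features detected with count > 0) and, for RNA,
#' `percent_mito` (percentage of counts from mitochondrial genes, identified
#' by a gene-symbol regex).
#'
#' @param dataset a [cite_dataset()].
#' @param modality `"RNA"` or `"ADT"`.
#' @param mito_pattern regex identifying mitochondrial gene symbols; default
#'   `"^MT-"` (human HGNC convention). Ignored for ADT.
#' @return a tibble with columns `cell_id`, `modality`, `n_count`,
#'   `n_feature` and (RNA only) `percent_mito`. Cells with `n_count = 0` get
#'   `percent_mito = 0` with a warning; no cell is dropped.
#' @export
per_cell_stats <- function(dataset, modality = c("RNA", "ADT"),
                           mito_pattern = "^MT-") {
  modality <- match.arg(modality)
  m <- modality_counts(dataset, modality)
  if (ncol(m) == 0) abort(sprintf("dataset has no %s features", modality))

  out <- tibble(
    cell_id = dataset$cell_ids,
    modality = modality,
    n_count = as.vector(Matrix::rowSums(m)),
    n_feature = as.vector(Matrix::rowSums(m > 0)))

  if (modality == "RNA") {
    is_mito <- grepl(mito_pattern, dataset$gene_ids)
    mito_counts <- if (any(is_mito)) {
      as.vector(Matrix::rowSums(m[, is_mito, drop = FALSE]))
    } else rep(0, nrow(m))
    zero <- out$n_count == 0
    if (any(zero)) {
      warn(sprintf("%d cell(s) with zero RNA counts; percent_mito set to 0", sum(zero)))
    }
    out$percent_mito <- ifelse(zero, 0, 100 * mito_counts / out$n_count)
  }
  out
}

#' Normalize one modality of a cite_dataset
#'
#' * `library_size`: each cell scaled to sum to `scale_factor` (linear).
#' * `log_library_size`: `log1p` of the library-size values.
#' * `clr`: per-cell centered log-ratio, `log1p(x) - mean(log1p(x))` over
#'   features — the conventional compositional transform for ADT panels.
#'
#' All-zero cells yield a zero row with a warning. Library-size and
#' log-library-size preserve within-cell rank order, so rank statistics are
#' unaffected by the choice between them.
#'
#' @param dataset a [cite_dataset()].
#' @param modality `"RNA"` or `"ADT"`.
#' @param method one of `"library_size"`, `"log_library_size"`, `"clr"`.
#' @param scale_factor target per-cell sum for library-size scaling
#'   (default 1e4; immaterial to rank-based statistics).
#' @return a cells x features matrix (sparse for library-size methods on
#'   sparse input, dense for clr), dimnames preserved.
#' @export
normalize_counts <- function(dataset, modality = c("RNA", "ADT"),
                             method = c("library_size", "log_library_size", "clr"),
                             scale_factor = 1e4) {
  modality <- match.arg(modality)
  method <- match.arg(method)
  m <- modality_counts(dataset, modality)
  if (ncol(m) == 0) abort(sprintf("dataset has no %s features", modality))
  totals <- as.vector(Matrix::rowSums(m))
  if (any(totals == 0)) {
    warn(sprintf("%d all-zero cell(s); normalized rows are zero", sum(totals == 0)))
  }

  if (method == "clr") {
    lg <- log1p(as.matrix(m))
    out <- lg - rowMeans(lg)
    dimnames(out) <- dimnames(m)
    return(out)
  }

  scl <- ifelse(totals == 0, 0, scale_factor / totals)
  out <- Matrix::Diagonal(x = scl) %*% m
  if (method == "log_library_size") out <- log1p(out)
  out <- if (is(m, "sparseMatrix")) {
    methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
  } else as.matrix(out)
  dimnames(out) <- dimnames(m)
  out
}

#' Good-cell thresholds for one modality
#'
#' Holds the cutoffs used to annotate (never remove) cells. RNA defaults are
#' the conventional tutorial values for human PBMC-like data: 200-2500
#' detected genes and at most 5% mitochondrial counts. ADT has no sensible
#' universal default (panel-size dependent), so all bounds are optional.
#'
#' @param min_n_feature,max_n_feature inclusive bounds on `n_feature`.
#' @param max_percent_mito inclusive upper bound on `percent_mito`
#'   (RNA only), in 0-100.
#' @param modality `"RNA"` or `"ADT"`.
#' @return a `cell_filter_thresholds` list.
#' @export
cell_filter_thresholds <- function(min_n_feature = 200, max_n_feature = 2500,
                                   max_percent_mito = 5,
                                   modality = c("RNA", "ADT")) {
  modality <- match.arg(modality)
  if (min_n_feature > max_n_feature) abort("min_n_feature > max_n_feature")
  if (max_percent_mito < 0 || max_percent_mito > 100) {
    abort("max_percent_mito must lie in [0, 100]")
  }
  structure(list(min_n_feature = min_n_feature, max_n_feature = max_n_feature,
                 max_percent_mito = max_percent_mito, modality = modality),
            class = "cell_filter_thresholds")
}

#' Flag cells against quality thresholds
#'
#' A cell passes when `min_n_feature <= n_feature <= max_n_feature` and, for
#' RNA, `percent_mito <= max_percent_mito` (all bounds inclusive). Flags are
#' annotations only; nothing is removed.
#'
#' @param stats tibble from [per_cell_stats()].
#' @param thresholds a [cell_filter_thresholds()].
#' @return `stats` with an added logical column `pass`.
#' @export
flag_cells <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "cell_filter_thresholds"))
  pass <- stats$n_feature >= thresholds$min_n_feature &
    stats$n_feature <= thresholds$max_n_feature
  if (thresholds$modality == "RNA" && "percent_mito" %in% names(stats)) {
    pass <- pass & stats$percent_mito <= thresholds$max_percent_mito
  }
  mutate(stats, pass = pass)
}
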