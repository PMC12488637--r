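#' Construct a paired RNA/ADT CITE-seq dataset
#'
#' The central container: a cell x gene RNA count matrix and a cell x ADT
#' count matrix sharing one cell axis, plus optional ADT-to-gene pairing and
#' cluster labels. RNA counts are stored sparse (`dgCMatrix`), the ADT panel
#' (typically tens of tags) dense; all operations give identical results for
#' either storage.
#'
#' @param rna_counts cells x genes matrix of non-negative integer counts
#'   (base matrix or any Matrix class); must carry row (cell) and column
#'   (gene) names, or supply `cell_ids` / `gene_ids`.
#' @param adt_counts cells x ADTs matrix of non-negative integer counts on
#'   the same cells, in the same order. May have zero columns (no ADT layer).
#' @param cell_ids,gene_ids,adt_ids optional identifier vectors overriding
#'   dimnames. Each must be free of duplicates.
#' @param adt_to_gene optional named character vector mapping ADT name to
#'   cognate gene symbol. Names must be ADT ids; values that are not present
#'   in `gene_ids` are kept but excluded from pair analyses with a warning.
#' @param cluster_labels optional vector of cluster labels, one per cell
#'   (named by cell id or in cell order).
#'
#' @return An object of class `cite_dataset`.
#' @export
cite_dataset <- function(rna_counts, adt_counts = NULL,
                         cell_ids = NULL, gene_ids = NULL, adt_ids = NULL,
                         adt_to_gene = NULL, cluster_labels = NULL) {
  rna <- as_count_matrix(rna_counts, sparse = TRUE)
  cell_ids <- cell_ids %||% rownames(rna)
  gene_ids <- gene_ids %||% colnames(rna)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    abort("rna_counts needs cell and gene identifiers (dimnames or cell_ids/gene_ids).")
  }
  dimnames(rna) <- list(cell_ids, gene_ids)

  if (is.null(adt_counts)) {
    adt_counts <- matrix(0L, nrow = nrow(rna), ncol = 0)
  }
  adt <- as_count_matrix(adt_counts, sparse = FALSE)
  adt_ids <- adt_ids %||% colnames(adt) %||% character(0)
  if (nrow(adt) != nrow(rna)) {
    abort(sprintf("RNA and ADT layers must share the cell axis (%d vs %d cells).",
                  nrow(rna), nrow(adt)))
  }
  dimnames(adt) <- list(cell_ids, adt_ids)

  for (nm in list(c("cell", cell_ids), c("gene", gene_ids), c("ADT", adt_ids))) {
    ids <- nm[-1]
    if (anyDuplicated(ids)) {
      abort(sprintf("duplicate %s identifiers: e.g. '%s'", nm[1],
                    ids[duplicated(ids)][1]))
    }
  }

  if (!is.null(adt_to_gene)) {
    if (is.null(names(adt_to_gene)) || any(names(adt_to_gene) == "")) {
      abort("adt_to_gene must be a named character vector (ADT -> gene).")
    }
    bad <- setdiff(names(adt_to_gene), adt_ids)
    if (length(bad)) {
      abort(sprintf("adt_to_gene keys not in the ADT panel: %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
    unmapped <- setdiff(unname(adt_to_gene), gene_ids)
    if (length(unmapped)) {
      warn(sprintf(
        "%d adt_to_gene target(s) absent from the gene list (excluded from pair analyses): %s",
        length(unmapped), paste(head(unmapped, 5), collapse = ", ")))
    }
  }

  x <- structure(
    list(rna = rna, adt = adt,
         cell_ids = cell_ids, gene_ids = gene_ids, adt_ids = adt_ids,
         adt_to_gene = adt_to_gene, cluster_labels = NULL),
    class = "cite_dataset")
  if (!is.null(cluster_labels)) {
    x <- set_clusters(x, cluster_labels)
  }
  x
}

# coerce to a validated count matrix; sparse => dgCMatrix, else base matrix
as_count_matrix <- function(m, sparse) {
  if (sparse) {
    m <- methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                             "dMatrix"), "generalMatrix"), "CsparseMatrix")
    vals <- m@x
  } else {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    vals <- m
  }
  if (length(vals) && (min(vals) < 0 || any(vals != floor(vals)))) {
    abort("counts must be non-negative integers")
  }
  m
}

#' Attach cluster labels to a dataset
#'
#' @param dataset a [cite_dataset()].
#' @param labels vector of labels, either named by cell barcode or ordered as
#'   the dataset's cells; every cell must receive exactly one label.
#' @return the dataset with `cluster_labels` set (a factor in cell order).
#' @export
set_clusters <- function(dataset, labels) {
  stopifnot(inherits(dataset, "cite_dataset"))
  if (!is.null(names(labels))) {
    missing <- setdiff(dataset$cell_ids, names(labels))
    if (length(missing)) {
      abort(sprintf("cluster labels missing for %d cell(s): %s",
                    length(missing), paste(head(missing, 10), collapse = ", ")))
    }
    labels <- labels[dataset$cell_ids]
  } else if (length(labels) != n_cells(dataset)) {
    abort("unnamed cluster labels must have one entry per cell")
  }
  dataset$cluster_labels <- factor(as.vector(labels))
  dataset
}

#' @export
print.cite_dataset <- function(x, ...) {
  cat(sprintf("<cite_dataset> %d cells; %d genes (RNA), %d ADTs\n",
              n_cells(x), length(x$gene_ids), length(x$adt_ids)))
  if (!is.null(x$cluster_labels)) {
    cat(sprintf("  clusters: %d (%s)\n", nlevels(x$cluster_labels),
                paste(head(levels(x$cluster_labels), 8), collapse = ", ")))
  }
  if (!is.null(x$adt_to_gene)) {
    cat(sprintf("  ADT-gene map: %d pair(s)\n", length(x$adt_to_gene)))
  }
  invisible(x)
}

#' @export
dim.cite_dataset <- function(x) c(n_cells(x), length(x$gene_ids))

#' Number of cells in a dataset
#' @param dataset a [cite_dataset()].
#' @return integer cell count.
#' @export
n_cells <- function(dataset) length(dataset$cell_ids)

# fetch the count matrix of one modality (cells x features)
modality_counts <- function(dataset, modality = c("RNA", "ADT")) {
  modality <- match.arg(modality)
  if (modality == "RNA") dataset$rna else dataset$adt
}

# replace the count matrix of one modality
`modality_counts<-` <- function(dataset, modality, value) {
  if (modality == "RNA") dataset$rna <- value else dataset$adt <- value
  dataset
}

#' Subset a dataset to a set of cells
#'
#' @param dataset a [cite_dataset()].
#' @param cells character barcodes, or integer/logical index on the cell axis.
#' @return a [cite_dataset()] restricted to those cells (labels carried over).
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "cite_dataset"))
  if (is.character(cells)) cells <- match(cells, dataset$cell_ids)
  if (anyNA(cells)) abort("unknown cell barcode(s) in subset")
  out <- dataset
  out$rna <- dataset$rna[cells, , drop = FALSE]
  out$adt <- dataset$adt[cells, , drop = FALSE]
  out$cell_ids <- dataset$cell_ids[cells]
  if (!is.null(dataset$cluster_labels)) {
    out$cluster_labels <- droplevels(dataset$cluster_labels[cells])
  }
  out
}
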