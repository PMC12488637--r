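#' Read a 10x-style MTX triplet into a cite_dataset
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` (each optionally
#' gzipped) in one directory. The matrix is MatrixMarket coordinate format,
#' features x cells; the features file carries columns id, name,
#' feature_type, where rows typed `"Gene Expression"` form the RNA layer and
#' rows typed `"Antibody Capture"` the ADT layer. Cell order follows the
#' barcodes file.
#'
#' @param path directory containing the triplet.
#' @param use_names use the feature `name` column as identifiers when it is
#'   duplicate-free, otherwise fall back to `id` (default TRUE).
#' @return a [cite_dataset()]; if no Antibody Capture rows exist the ADT
#'   layer has zero columns and a warning is raised.
#' @export
read_10x_mtx <- function(path, use_names = TRUE) {
  mtx <- find_triplet_file(path, "matrix.mtx")
  feat <- find_triplet_file(path, "features.tsv")
  bars <- find_triplet_file(path, "barcodes.tsv")

  m <- Matrix::readMM(mtx)                       # features x cells
  barcodes <- readr::read_tsv(bars, col_names = FALSE, show_col_types = FALSE)[[1]]
  if (anyDuplicated(barcodes)) {
    abort(sprintf("duplicate barcodes in %s (e.g. '%s')", bars,
                  barcodes[duplicated(barcodes)][1]))
  }
  features <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE)
  if (ncol(features) < 3) {
    warn("features file has no feature_type column; treating every row as Gene Expression")
    features$X3 <- "Gene Expression"
  }
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m)) {
    abort(sprintf("matrix is %d x %d but features/barcodes have %d / %d rows",
                  nrow(m), ncol(m), nrow(features), length(barcodes)))
  }
  ids <- if (use_names && !anyDuplicated(features$X2)) features$X2 else features$X1

  m <- Matrix::t(m)                              # cells x features
  is_adt <- features$X3 == "Antibody Capture"
  if (!any(is_adt)) {
    warn(sprintf("no 'Antibody Capture' features in %s; ADT layer is empty", feat))
  }
  cite_dataset(
    rna_counts = m[, !is_adt, drop = FALSE],
    adt_counts = as.matrix(m[, is_adt, drop = FALSE]),
    cell_ids = barcodes,
    gene_ids = ids[!is_adt],
    adt_ids = ids[is_adt])
}

find_triplet_file <- function(path, base) {
  if (!dir.exists(path)) abort(sprintf("no such directory: %s", path))
  for (cand in file.path(path, c(base, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  abort(sprintf("missing file: %s (searched %s[.gz])", file.path(path, base), base))
}

#' Write a cite_dataset as a 10x-style MTX triplet
#'
#' Inverse of [read_10x_mtx()]: both modalities are stacked feature-wise with
#' feature_type `"Gene Expression"` / `"Antibody Capture"`.
#'
#' @param dataset a [cite_dataset()].
#' @param path output directory (created if needed).
#' @param gzip compress the three files (default FALSE; plain text).
#' @return `path`, invisibly.
#' @export
write_10x_mtx <- function(dataset, path, gzip = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- c(dataset$gene_ids, dataset$adt_ids)
  type <- rep(c("Gene Expression", "Antibody Capture"),
              c(length(dataset$gene_ids), length(dataset$adt_ids)))
  stacked <- Matrix::t(cbind(dataset$rna, Matrix::Matrix(dataset$adt, sparse = TRUE)))
  maybe_gz <- function(f) if (gzip) gzfile(paste0(f, ".gz")) else f
  Matrix::writeMM(stacked, file.path(path, "matrix.mtx"))
  if (gzip) {
    tmp <- file.path(path, "matrix.mtx")
    writeLines(readLines(tmp), gzfile(paste0(tmp, ".gz")))
    unlink(tmp)
  }
  readr::write_tsv(tibble(id = ids, name = ids, feature_type = type),
                   maybe_gz(file.path(path, "features.tsv")), col_names = FALSE)
  readr::write_tsv(tibble(barcode = dataset$cell_ids),
                   maybe_gz(file.path(path, "barcodes.tsv")), col_names = FALSE)
  invisible(path)
}

#' Read one modality from a dense CSV matrix
#'
#' First column is the cell barcode; remaining columns are features.
#'
#' @param rna_csv,adt_csv file paths; `adt_csv` may be NULL (empty ADT layer).
#' @return a [cite_dataset()]. Cells are matched by barcode; the two files
#'   must cover the same cells.
#' @export
read_csv_dataset <- function(rna_csv, adt_csv = NULL) {
  read_one <- function(f) {
    d <- readr::read_csv(f, show_col_types = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    m
  }
  rna <- read_one(rna_csv)
  adt <- NULL
  if (!is.null(adt_csv)) {
    adt <- read_one(adt_csv)
    if (!setequal(rownames(adt), rownames(rna))) {
      abort("RNA and ADT CSVs cover different barcodes")
    }
    adt <- adt[rownames(rna), , drop = FALSE]
  }
  cite_dataset(rna_counts = rna, adt_counts = adt)
}

#' Write a cite_dataset as dense CSV matrices
#'
#' @param dataset a [cite_dataset()].
#' @param rna_csv,adt_csv output paths; `adt_csv` is skipped when the panel
#'   is empty.
#' @return invisibly, the paths written.
#' @export
write_csv_dataset <- function(dataset, rna_csv, adt_csv = NULL) {
  write_one <- function(m, f) {
    d <- as_tibble(as.matrix(m))
    d <- dplyr::bind_cols(tibble(barcode = dataset$cell_ids), d)
    readr::write_csv(d, f)
  }
  write_one(dataset$rna, rna_csv)
  if (!is.null(adt_csv) && length(dataset$adt_ids)) write_one(dataset$adt, adt_csv)
  invisible(c(rna_csv, adt_csv))
}

#' Read cluster labels from a two-column TSV
#'
#' Column 1 is the barcode, column 2 the label; a header row is auto-detected
#' (present when the first field matches neither a dataset barcode nor, with
#' no dataset given, looks textual).
#'
#' @param path TSV file.
#' @param dataset optional [cite_dataset()] used for header detection.
#' @return tibble with columns `cell_id`, `cluster`.
#' @export
read_cluster_tsv <- function(path, dataset = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 2) abort("cluster TSV needs two columns: barcode, label")
  has_header <- if (!is.null(dataset)) {
    !(raw[[1]][1] %in% dataset$cell_ids)
  } else {
    tolower(raw[[1]][1]) %in% c("barcode", "cell", "cell_id")
  }
  if (has_header) raw <- raw[-1, , drop = FALSE]
  tibble(cell_id = raw[[1]], cluster = raw[[2]])
}
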