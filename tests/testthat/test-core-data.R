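test_that("cite_dataset validates its invariants", {
  ds <- toy_dataset()
  expect_s3_class(ds, "cite_dataset")
  expect_equal(dim(ds$rna), c(3, 4))
  expect_equal(dim(ds$adt), c(3, 2))

  rna <- matrix(1, 2, 2, dimnames = list(c("c1", "c1"), c("g1", "g2")))
  expect_error(cite_dataset(rna), "duplicate cell")
  rna2 <- matrix(c(1, -1, 0, 2), 2, 2,
                 dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(cite_dataset(rna2), "non-negative")
  rna3 <- matrix(c(1, 0.5, 0, 2), 2, 2,
                 dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_error(cite_dataset(rna3), "non-negative")
  expect_error(
    cite_dataset(toy_dataset()$rna, adt_counts = matrix(0L, 2, 0)),
    "cell axis")
  expect_warning(
    cite_dataset(toy_dataset()$rna, toy_dataset()$adt,
                 adt_to_gene = c(A1 = "NOT_A_GENE")),
    "absent from the gene list")
})

test_that("MTX triplet round-trips a synthetic dataset exactly", {
  ds <- small_sim()$dataset
  dir <- withr::local_tempdir()
  write_fixture(ds, dir, format = "mtx_triplet")
  back <- read_10x_mtx(dir)
  expect_equal(as.matrix(back$rna), as.matrix(ds$rna))
  expect_equal(back$adt, ds$adt)
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$adt_ids, ds$adt_ids)
})

test_that("dense CSV round-trips a synthetic dataset exactly", {
  ds <- small_sim()$dataset
  dir <- withr::local_tempdir()
  write_fixture(ds, dir, format = "csv")
  back <- read_csv_dataset(file.path(dir, "rna.csv"), file.path(dir, "adt.csv"))
  expect_equal(as.matrix(back$rna), as.matrix(ds$rna))
  expect_equal(back$adt, ds$adt)
})

test_that("triplet without Antibody Capture rows yields empty ADT layer + warning", {
  ds <- toy_dataset()
  ds$adt <- ds$adt[, 0, drop = FALSE]
  ds$adt_ids <- character(0)
  ds$adt_to_gene <- NULL
  dir <- withr::local_tempdir()
  expect_warning(write_fixture(ds, dir), NA)
  expect_warning(back <- read_10x_mtx(dir), "Antibody Capture")
  expect_equal(length(back$adt_ids), 0)
  expect_equal(ncol(back$adt), 0)
  expect_equal(as.matrix(back$rna), as.matrix(ds$rna))
})

test_that("reader errors name the missing file and reject duplicate barcodes", {
  dir <- withr::local_tempdir()
  expect_error(read_10x_mtx(file.path(dir, "nope")), "no such directory")
  write_fixture(toy_dataset(), dir)
  file.remove(file.path(dir, "features.tsv"))
  expect_error(read_10x_mtx(dir), "features.tsv")

  dir2 <- withr::local_tempdir()
  write_fixture(toy_dataset(), dir2)
  writeLines(c("c1", "c1", "c3"), file.path(dir2, "barcodes.tsv"))
  expect_error(read_10x_mtx(dir2), "duplicate barcodes")
})

test_that("per-cell stats match hand computation, including mito edge cases", {
  rna <- matrix(c(5, 0, 3,
                  5, 5, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("GA", "MT-CO1", "GB")))
  ds <- cite_dataset(rna)
  st <- per_cell_stats(ds, "RNA")
  expect_equal(st$n_count, c(8, 10))
  expect_equal(st$n_feature, c(2, 2))
  expect_equal(st$percent_mito, c(0, 50))   # MT gene has zero counts in c1

  # zero-count cell: retained, percent_mito 0, warning raised
  rna0 <- matrix(c(0, 0,
                   1, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("GA", "MT-CO1")))
  expect_warning(st0 <- per_cell_stats(cite_dataset(rna0), "RNA"),
                 "zero RNA counts")
  expect_equal(st0$percent_mito[1], 0)
  expect_equal(st0$n_count[1], 0)

  # ADT stats carry no percent_mito
  expect_false("percent_mito" %in% names(per_cell_stats(toy_dataset(), "ADT")))
})

test_that("stats respect permutation invariance and count conservation", {
  sim <- small_sim()
  ds <- sim$dataset
  st <- per_cell_stats(ds, "RNA")
  expect_equal(sum(st$n_count), sum(ds$rna))

  perm <- withr::with_seed(7, sample.int(n_cells(ds)))
  st_perm <- per_cell_stats(subset_cells(ds, perm), "RNA")
  expect_equal(st_perm$n_count, st$n_count[perm])
  expect_equal(st_perm$n_feature, st$n_feature[perm])
  expect_equal(st_perm$percent_mito, st$percent_mito[perm])
})

test_that("planted mitochondrial fraction is recovered in the mean", {
  sim <- simulate_cite_seq(small_config(seed = 5, mito_fraction_mean = 0.08,
                                        n_cells = 800))
  st <- per_cell_stats(sim$dataset, "RNA")
  expect_equal(mean(st$percent_mito), 8, tolerance = 0.08)
})

test_that("normalization methods satisfy their contracts", {
  rna <- matrix(c(2, 2, 3, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("g1", "g2")))
  ds <- cite_dataset(rna)
  ls <- normalize_counts(ds, "RNA", "library_size", scale_factor = 10)
  expect_equal(as.vector(ls["c1", ]), c(5, 5))

  # CLR of a constant-count cell is all zeros
  clr <- normalize_counts(ds, "RNA", "clr")
  expect_equal(as.vector(clr["c1", ]), c(0, 0))

  # every row sums to the scale constant on a random fixture
  sim <- small_sim()
  norm <- normalize_counts(sim$dataset, "RNA", "library_size")
  expect_equal(as.vector(Matrix::rowSums(norm)),
               rep(1e4, n_cells(sim$dataset)), tolerance = 1e-9)

  # within-cell rank order preserved by both library-size methods
  lg <- normalize_counts(sim$dataset, "RNA", "log_library_size")
  i <- 17
  expect_equal(rank(as.vector(norm[i, ])), rank(as.vector(lg[i, ])))
  expect_equal(rank(as.vector(norm[i, ])), rank(as.vector(sim$dataset$rna[i, ])))

  # all-zero cell warns and yields zeros
  rna0 <- matrix(c(0, 0,
                   1, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("g1", "g2")))
  expect_warning(n0 <- normalize_counts(cite_dataset(rna0), "RNA", "library_size"),
                 "all-zero")
  expect_equal(as.vector(n0["c1", ]), c(0, 0))
})

test_that("sparse and dense storage give identical results", {
  sim <- small_sim()
  ds <- sim$dataset
  dense <- as.matrix(ds$rna)
  ds_dense <- cite_dataset(dense, ds$adt)
  expect_equal(per_cell_stats(ds_dense, "RNA"), per_cell_stats(ds, "RNA"))
  expect_equal(as.matrix(normalize_counts(ds_dense, "RNA", "log_library_size")),
               as.matrix(normalize_counts(ds, "RNA", "log_library_size")))
})

test_that("cell flagging is inclusive at bounds and matches a brute-force filter", {
  st <- tibble::tibble(cell_id = c("a", "b", "c"), modality = "RNA",
                       n_count = c(500, 900, 1200),
                       n_feature = c(100, 300, 2500),
                       percent_mito = c(1, 4.9, 5.1))
  th <- cell_filter_thresholds(200, 2500, 5, "RNA")
  fl <- flag_cells(st, th)
  expect_equal(fl$pass, c(FALSE, TRUE, FALSE))

  # boundary: n_feature 300, percent_mito 4.9 <= 5 passes; 100 < 200 fails
  sim <- small_sim()
  stats <- per_cell_stats(sim$dataset, "RNA")
  th2 <- cell_filter_thresholds(50, 150, 10, "RNA")
  fl2 <- flag_cells(stats, th2)
  brute <- mapply(function(nf, pm) nf >= 50 && nf <= 150 && pm <= 10,
                  stats$n_feature, stats$percent_mito)
  expect_equal(sum(fl2$pass), sum(brute))
  expect_equal(fl2$pass, unname(brute))
})

test_that("cluster label TSV import/export round-trips", {
  sim <- small_sim()
  ds <- sim$dataset
  cl <- set_clusters(ds, sim$truth$labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  asn <- import_clusters(
    ds, { readr::write_tsv(tibble::tibble(barcode = names(sim$truth$labels),
                                          cluster = as.character(sim$truth$labels)),
                           path); path })
  expect_equal(asn$n_clusters, 3)
  expect_equal(as.character(asn$labels), as.character(sim$truth$labels[ds$cell_ids]))
})
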