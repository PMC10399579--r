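write_mtx_fixture <- function(dir, genes, barcodes, entries) {
  # entries: data.frame(i, j, x)
  dir.create(dir, showWarnings = FALSE)
  header <- c("%%MatrixMarket matrix coordinate integer general",
              paste(length(genes), length(barcodes), nrow(entries)))
  writeLines(c(header, sprintf("%d %d %g", entries$i, entries$j, entries$x)),
             file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

test_that("MTX triplet reads back exactly", {
  d <- write_mtx_fixture(tempfile(), c("gA", "gB", "gC"), c("c1", "c2"),
                         data.frame(i = c(1, 2), j = c(1, 2), x = c(5, 3)))
  m <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
                        file.path(d, "barcodes.tsv"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["gA", "c1"], 5)
  expect_equal(m["gB", "c2"], 3)
  expect_equal(sum(m), 8)
})

test_that("duplicate gene symbols are collapsed by the configured policy at read", {
  d <- write_mtx_fixture(tempfile(), c("A", "B", "A"), c("c1", "c2"),
                         data.frame(i = c(1, 2, 3, 3), j = c(1, 2, 1, 2),
                                    x = c(1, 7, 3, 4)))
  m <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
                        file.path(d, "barcodes.tsv"), collapse = "sum")
  expect_equal(rownames(m), c("A", "B"))
  # row A must equal the elementwise sum of the two A rows: (1,0) + (3,4)
  expect_equal(as.numeric(m["A", ]), c(4, 4))
})

test_that("read errors: duplicated barcodes, dimension mismatch, negative values", {
  d <- write_mtx_fixture(tempfile(), c("gA", "gB"), c("c1", "c1"),
                         data.frame(i = 1, j = 1, x = 2))
  expect_error(read_mtx_triplet(file.path(d, "matrix.mtx"),
                                file.path(d, "features.tsv"),
                                file.path(d, "barcodes.tsv")),
               "duplicate cell barcodes")
  d2 <- write_mtx_fixture(tempfile(), c("gA", "gB", "gC"), c("c1", "c2"),
                          data.frame(i = 1, j = 1, x = 2))
  writeLines(c("gA", "gB"), file.path(d2, "features.tsv"))
  expect_error(read_mtx_triplet(file.path(d2, "matrix.mtx"),
                                file.path(d2, "features.tsv"),
                                file.path(d2, "barcodes.tsv")),
               "features file has")
  d3 <- write_mtx_fixture(tempfile(), c("gA", "gB"), c("c1", "c2"),
                          data.frame(i = 1, j = 1, x = -3))
  expect_error(read_mtx_triplet(file.path(d3, "matrix.mtx"),
                                file.path(d3, "features.tsv"),
                                file.path(d3, "barcodes.tsv")),
               "negative")
})

test_that("two-column features files use the symbol column", {
  d <- write_mtx_fixture(tempfile(), c("ENSG1\tTP53", "ENSG2\tMYC"), c("c1"),
                         data.frame(i = 1:2, j = c(1, 1), x = c(4, 9)))
  m <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
                        file.path(d, "barcodes.tsv"))
  expect_equal(rownames(m), c("TP53", "MYC"))
})

test_that("dense table readback and transpose symmetry", {
  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("gA", "gB"), c("c1", "c2")))
  p_rows <- write_counts_csv(m)
  got <- read_dense_table(p_rows, genes_in = "rows")
  expect_equal(as.matrix(got), m, ignore_attr = FALSE)
  p_cols <- tempfile(fileext = ".csv")
  tm <- t(m)
  utils::write.csv(data.frame(cell = rownames(tm), tm, check.names = FALSE),
                   p_cols, row.names = FALSE, quote = FALSE)
  got2 <- read_dense_table(p_cols, genes_in = "columns")
  expect_equal(as.matrix(got2), as.matrix(got))
})

test_that("dense table rejects non-numeric cells naming the coordinate", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "gA,1,2", "gB,NA,4"), p)
  expect_error(read_dense_table(p), "gB.*c1")
  p2 <- tempfile(fileext = ".csv")
  writeLines("gene,c1", p2)
  expect_error(read_dense_table(p2), "empty")
})

test_that("collapse_duplicate_genes honours all three policies", {
  m <- Matrix::Matrix(matrix(c(1, 3, 2, 4), 2, byrow = FALSE,
                             dimnames = list(c("A", "A"), c("c1", "c2"))),
                      sparse = TRUE)
  expect_equal(as.numeric(collapse_duplicate_genes(m, "sum")["A", ]), c(4, 6))
  expect_equal(as.numeric(collapse_duplicate_genes(m, "max")["A", ]), c(3, 4))
  expect_equal(as.numeric(collapse_duplicate_genes(m, "first")["A", ]), c(1, 2))
  m2 <- random_counts(5, 3)
  expect_identical(collapse_duplicate_genes(m2, "sum"), m2)  # no duplicates
})

test_that("annotation CSV round-trips labels losslessly", {
  set.seed(11)
  h <- two_major_fixture()
  sim <- simulate_dataset(simulation_config(h, cells_per_leaf = 50,
                                            n_background_genes = 50, seed = 3))
  res <- annotate_hierarchical(sim$matrix, h, prescreen = TRUE)
  p <- tempfile(fileext = ".csv")
  write_annotation_csv(res, p)
  back <- read_annotation_csv(p)
  expect_equal(back$barcode, res$barcode)
  expect_equal(back$prescreen_label, res$prescreen_label)
  for (k in 1:3) {
    col <- paste0("layer", k, "_label")
    expect_equal(back[[col]], res[[col]])
  }
  # a non-immune or unassigned cell has empty deeper fields
  lines <- readLines(p)
  expect_true(grepl("layer3_label", lines[1]))
})

test_that("all-zero columns are retained at read time", {
  d <- write_mtx_fixture(tempfile(), c("gA", "gB"), c("c1", "c2"),
                         data.frame(i = 1, j = 1, x = 2))
  m <- read_mtx_triplet(file.path(d, "matrix.mtx"), file.path(d, "features.tsv"),
                        file.path(d, "barcodes.tsv"))
  expect_equal(ncol(m), 2L)
  expect_equal(sum(m[, "c2"]), 0)
})
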