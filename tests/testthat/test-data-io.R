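test_that("MTX read preserves the stored non-zeros and catches dimension mismatches", {
  dir <- withr::local_tempdir()
  # genes x cells, 3 genes x 2 cells, entries (1,1)=4 and (3,2)=7
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(4, 7),
                            dims = c(3, 2))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  cm <- read_matrix(file.path(dir, "matrix.mtx"), "mtx")
  dense <- as.matrix(cm$values)
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(dense[1, 1], 4)
  expect_equal(dense[2, 3], 7)
  expect_equal(sum(dense != 0), 2L)
  expect_equal(cm$gene_ids, c("gA", "gB", "gC"))

  writeLines(c("gA", "gB", "gC", "gD"), file.path(dir, "genes.tsv"))
  expect_error(read_matrix(file.path(dir, "matrix.mtx"), "mtx"),
               "dimension mismatch")
})

test_that("write/read round-trips are lossless across formats", {
  cm <- toy_counts(n = 7, p = 5, seed = 3)
  dir <- withr::local_tempdir()

  write_matrix(cm, file.path(dir, "m.mtx"), "mtx")
  back <- read_matrix(file.path(dir, "m.mtx"), "mtx")
  expect_equal(as.matrix(back$values), unname(as.matrix(cm$values)))
  expect_equal(back$cell_ids, cm$cell_ids)
  expect_equal(back$gene_ids, cm$gene_ids)

  for (fmt in c("tsv", "csv")) {
    path <- file.path(dir, paste0("m.", fmt))
    write_matrix(cm, path, fmt)
    back <- read_matrix(path, fmt)
    expect_equal(unname(as.matrix(back$values)), unname(as.matrix(cm$values)))
    expect_equal(back$gene_ids, cm$gene_ids)
  }
})

test_that("10x-style HDF5 matrices are read correctly", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.h5")
  cm <- toy_counts(n = 6, p = 4, seed = 5)
  sp <- methods::as(methods::as(Matrix::t(Matrix::Matrix(cm$values, sparse = TRUE)),
                                "generalMatrix"), "CsparseMatrix")
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "matrix")
  rhdf5::h5write(sp@x, path, "matrix/data")
  rhdf5::h5write(sp@i, path, "matrix/indices")
  rhdf5::h5write(sp@p, path, "matrix/indptr")
  rhdf5::h5write(dim(sp), path, "matrix/shape")
  rhdf5::h5write(cm$cell_ids, path, "matrix/barcodes")
  rhdf5::h5createGroup(path, "matrix/features")
  rhdf5::h5write(cm$gene_ids, path, "matrix/features/id")
  rhdf5::h5closeAll()
  back <- read_matrix(path, "h5_10x")
  expect_equal(as.matrix(back$values), unname(as.matrix(cm$values)))
  expect_equal(back$cell_ids, cm$cell_ids)
  expect_equal(back$gene_ids, cm$gene_ids)
})

test_that("cell_matrix validates its invariants", {
  m <- matrix(1:6, 2, 3)
  expect_error(cell_matrix(m, cell_ids = c("a", "a")), "duplicates")
  expect_error(cell_matrix(m, gene_ids = c("g1", "g2")), "columns")
  expect_error(cell_matrix(m - 10), "non-negative")
  expect_error(cell_matrix(m, batch = c("b1", "b2", "b3")), "every cell")
})

test_that("concat_datasets intersects genes, prefixes barcodes, errors on disjoint sets", {
  a <- cell_matrix(matrix(1:6, 2, 3), cell_ids = c("x", "y"),
                   gene_ids = c("A", "B", "C"), batch = "b1")
  b <- cell_matrix(matrix(1:6, 2, 3), cell_ids = c("x", "y"),
                   gene_ids = c("A", "B", "D"), batch = "b2")
  cc <- concat_datasets(list(a, b))
  expect_equal(cc$gene_ids, c("A", "B"))
  expect_equal(nrow(cc$values), 4L)
  expect_equal(cc$batch, c("b1", "b1", "b2", "b2"))
  expect_false(anyDuplicated(cc$cell_ids) > 0)

  d <- cell_matrix(matrix(1:4, 2, 2), gene_ids = c("E", "F"), batch = "b3")
  expect_error(concat_datasets(list(a, d)), "empty gene intersection")
})

test_that("cpm_log_normalize matches hand-computed values and handles zero depth", {
  cm <- cell_matrix(matrix(c(1, 1, 2), 1, 3), gene_ids = c("a", "b", "c"))
  out <- cpm_log_normalize(cm)
  expect_equal(as.numeric(out$values),
               c(log(250001), log(250001), log(500001)), tolerance = 1e-12)
  expect_equal(as.numeric(out$values), c(12.4292, 12.4292, 13.1224),
               tolerance = 1e-4)

  single <- cpm_log_normalize(cell_matrix(matrix(5, 1, 1)))
  expect_equal(as.numeric(single$values), log(1 + 1e6), tolerance = 1e-12)

  zero <- cell_matrix(rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_warning(res <- cpm_log_normalize(zero), "zero total depth")
  expect_equal(as.numeric(res$values[1, ]), c(0, 0, 0))
  expect_equal(attr(res, "zero_depth_cells"), zero$cell_ids[1])

  neg <- cell_matrix(matrix(1:4, 2, 2))
  neg$values[1, 1] <- -1
  expect_error(cpm_log_normalize(neg), "negative")
})

test_that("cpm_log_normalize commutes with cell permutation", {
  cm <- toy_counts(n = 12, p = 8, seed = 11)
  perm <- sample(12)
  direct <- as.matrix(cpm_log_normalize(cm)$values)[perm, ]
  permuted <- cell_matrix(as.matrix(cm$values)[perm, ],
                          cell_ids = cm$cell_ids[perm],
                          gene_ids = cm$gene_ids, batch = cm$batch[perm])
  expect_equal(as.matrix(cpm_log_normalize(permuted)$values), direct)
})

test_that("consensus HVG selection favors genes variable in the most batches", {
  # A varies in all 3 batches; B only in batch 1; C in batches 2 and 3;
  # D..F constant everywhere (undefined dispersion, never selected).
  # The two varying genes alternate in antiphase so every cell has the same
  # library size and CPM keeps the constant genes constant.
  make_batch <- function(which_vary) {
    n <- 20
    vals <- matrix(5L, n, 6)
    vals[, match(which_vary[1], LETTERS)] <- rep(c(0L, 30L), n / 2)
    vals[, match(which_vary[2], LETTERS)] <- rep(c(30L, 0L), n / 2)
    cell_matrix(vals, cell_ids = paste0(paste(which_vary, collapse = ""), 1:n),
                gene_ids = LETTERS[1:6])
  }
  batches <- list(make_batch(c("A", "B")), make_batch(c("A", "C")),
                  make_batch(c("A", "C")))
  expect_equal(select_hvg_consensus(batches, n_per_batch = 2, n_final = 1), "A")
  expect_equal(select_hvg_consensus(batches, n_per_batch = 2, n_final = 3),
               c("A", "C", "B"))
  # requesting more genes than were ever selected returns all, with a warning
  expect_warning(all_sel <- select_hvg_consensus(batches, n_per_batch = 2,
                                                 n_final = 10),
                 "exceeds")
  expect_setequal(all_sel, c("A", "B", "C"))
})

test_that("single-dataset HVG selection is that dataset's dispersion ranking", {
  cm <- toy_counts(n = 30, p = 10, seed = 7)
  top <- select_hvg_consensus(list(cm), n_per_batch = 5, n_final = 5)
  expect_length(top, 5)
  expect_true(all(top %in% cm$gene_ids))
})

test_that("all-constant genes yield an empty HVG set with a warning", {
  cm <- cell_matrix(matrix(4, 10, 5))
  expect_warning(res <- select_hvg_consensus(list(cm), n_final = 3),
                 "no gene has a defined dispersion")
  expect_length(res, 0)
})

test_that("HVG consensus is invariant to dataset ordering", {
  set.seed(21)
  batches <- lapply(1:3, function(i) toy_counts(n = 25, p = 12, seed = 30 + i))
  a <- select_hvg_consensus(batches, n_per_batch = 6, n_final = 6)
  b <- select_hvg_consensus(rev(batches), n_per_batch = 6, n_final = 6)
  expect_equal(a, b)
})
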