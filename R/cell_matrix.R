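#' Cell-by-gene expression container
#'
#' Lightweight container for a single-cell expression (or gene-activity)
#' matrix with cells on rows and genes on columns, together with per-cell
#' batch and optional cell-type labels. Values may be a base matrix or a
#' sparse \code{Matrix} object; all downstream functions accept either.
#'
#' @param values numeric matrix (or \code{Matrix} sparse matrix), cells on
#'   rows, genes on columns, all entries non-negative.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   \code{rownames(values)}.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   \code{colnames(values)}.
#' @param batch per-cell dataset/batch label (character or factor); a single
#'   value is recycled. Defaults to \code{"batch1"}.
#' @param type optional per-cell cell-type label.
#' @param layer what the values represent: one of \code{"counts"},
#'   \code{"cpm_log"}, \code{"recovered"}, \code{"activity"}.
#' @return An object of class \code{cell_matrix}: a list with elements
#'   \code{values}, \code{cell_ids}, \code{gene_ids}, \code{batch},
#'   \code{type}, \code{layer}.
#' @export
cell_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values), batch = "batch1",
                        type = NULL, layer = "counts") {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("'values' must be a two-dimensional matrix")
  n <- nrow(values); p <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(p))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n)
    stop("length of cell_ids (", length(cell_ids), ") != number of rows (", n, ")")
  if (length(gene_ids) != p)
    stop("length of gene_ids (", length(gene_ids), ") != number of columns (", p, ")")
  if (anyDuplicated(cell_ids)) stop("cell_ids contain duplicates")
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates")
  if (min_value(values) < 0) stop("values must be non-negative")
  layer <- match.arg(layer, c("counts", "cpm_log", "recovered", "activity"))
  batch <- as.character(batch)
  if (length(batch) == 1L) batch <- rep(batch, n)
  if (length(batch) != n) stop("batch label required for every cell")
  if (anyNA(batch)) stop("batch labels must not contain NA")
  if (!is.null(type)) {
    type <- as.character(type)
    if (length(type) != n) stop("type labels, when given, are required for every cell")
  }
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, type = type, layer = layer),
            class = "cell_matrix")
}

min_value <- function(values) {
  if (inherits(values, "sparseMatrix")) {
    x <- methods::as(values, "generalMatrix")@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else min(values)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  bt <- table(x$batch)
  cat("  batches:", paste(sprintf("%s (%d)", names(bt), bt), collapse = ", "), "\n")
  if (!is.null(x$type))
    cat("  cell types:", length(unique(x$type)), "\n")
  invisible(x)
}

## row/column subsetting helpers used throughout
subset_cells <- function(x, keep) {
  cell_matrix(x$values[keep, , drop = FALSE],
              cell_ids = x$cell_ids[keep], gene_ids = x$gene_ids,
              batch = x$batch[keep],
              type = if (!is.null(x$type)) x$type[keep], layer = x$layer)
}

subset_genes <- function(x, keep) {
  cell_matrix(x$values[, keep, drop = FALSE],
              cell_ids = x$cell_ids, gene_ids = x$gene_ids[keep],
              batch = x$batch, type = x$type, layer = x$layer)
}

as_dense <- function(x) {
  v <- if (inherits(x, "cell_matrix")) x$values else x
  if (is.matrix(v)) v else as.matrix(v)
}

#' Read a cell-by-gene matrix from standard single-cell formats
#'
#' Supported formats: MatrixMarket coordinate (\code{mtx}) with companion
#' barcode and gene id files, dense \code{tsv}/\code{csv} with a header row of
#' gene ids and cell ids in the first column, and the 10x-style HDF5 layout
#' (\code{h5_10x}; group holding \code{data}/\code{indices}/\code{indptr}/
#' \code{shape} in CSC order plus barcode and feature id datasets).
#' MTX and HDF5 inputs are assumed to be genes-by-cells, the 10x convention,
#' and are transposed; dense tables are cells-by-genes.
#'
#' @param path path to the matrix file.
#' @param format one of \code{"mtx"}, \code{"tsv"}, \code{"csv"},
#'   \code{"h5_10x"}.
#' @param barcodes,genes companion file paths for \code{mtx}; default to
#'   \code{barcodes.tsv} and \code{genes.tsv} next to \code{path}.
#' @param batch batch label(s) passed to [cell_matrix()].
#' @param layer layer tag of the stored values (default \code{"counts"}).
#' @return A [cell_matrix()] with cells on rows.
#' @export
read_matrix <- function(path, format = c("mtx", "tsv", "csv", "h5_10x"),
                        barcodes = NULL, genes = NULL, batch = "batch1",
                        layer = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    if (is.null(genes)) genes <- file.path(dir, "genes.tsv")
    if (!file.exists(barcodes)) stop("companion barcode file not found: ", barcodes)
    if (!file.exists(genes)) stop("companion gene file not found: ", genes)
    m <- Matrix::readMM(path)
    bc <- utils::read.table(barcodes, sep = "\t", stringsAsFactors = FALSE)[[1]]
    gn <- utils::read.table(genes, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(gn))
      stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
           length(gn), " gene ids")
    if (ncol(m) != length(bc))
      stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
           length(bc), " barcodes")
    cell_matrix(Matrix::t(m), cell_ids = bc, gene_ids = gn, batch = batch,
                layer = layer)
  } else if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    cell_matrix(as.matrix(tab), cell_ids = rownames(tab),
                gene_ids = colnames(tab), batch = batch, layer = layer)
  } else {
    read_h5_10x(path, batch = batch, layer = layer)
  }
}

read_h5_10x <- function(path, batch = "batch1", layer = "counts") {
  contents <- rhdf5::h5ls(path)
  groups <- unique(contents$group[contents$name == "data"])
  if (length(groups) == 0) stop("malformed 10x HDF5 file: no 'data' dataset")
  grp <- sub("^/", "", groups[[1]])
  rd <- function(name) rhdf5::h5read(path, paste(grp, name, sep = "/"))
  shape <- as.integer(rd("shape"))
  data <- as.numeric(rd("data"))
  indices <- as.integer(rd("indices"))
  indptr <- as.integer(rd("indptr"))
  bc <- as.character(rd("barcodes"))
  gn <- tryCatch(as.character(rhdf5::h5read(path, paste(grp, "features/id", sep = "/"))),
                 error = function(e) as.character(rd("genes")))
  if (length(indptr) != shape[2] + 1L)
    stop("malformed 10x HDF5 file: indptr length does not match shape")
  m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                            dims = shape)
  if (nrow(m) != length(gn)) stop("dimension mismatch between matrix and gene ids")
  if (ncol(m) != length(bc)) stop("dimension mismatch between matrix and barcodes")
  cell_matrix(Matrix::t(m), cell_ids = bc, gene_ids = gn, batch = batch,
              layer = layer)
}

#' Write a cell-by-gene matrix
#'
#' \code{mtx} writes a MatrixMarket file (genes-by-cells, the 10x convention)
#' plus \code{barcodes.tsv} and \code{genes.tsv} in the same directory;
#' \code{tsv}/\code{csv} write a dense table with gene ids as the header and
#' cell ids in the first column.
#'
#' @param x a [cell_matrix()].
#' @param path output path for the matrix file.
#' @param format one of \code{"mtx"}, \code{"tsv"}, \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(x, path, format = c("mtx", "tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cell_matrix"))
  if (format == "mtx") {
    m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(x$values, sparse = TRUE)),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, path)
    dir <- dirname(path)
    writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
    writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- as.data.frame(as_dense(x))
    dimnames(tab) <- list(x$cell_ids, x$gene_ids)
    utils::write.table(tab, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Concatenate datasets over their shared genes
#'
#' Restricts all datasets to the gene intersection (ordered as in the first
#' dataset), stacks cells, records the dataset of origin as the batch label,
#' and prefixes cell ids with the batch name so barcodes repeated across
#' datasets do not collide.
#'
#' @param datasets list of [cell_matrix()] objects on a shared gene namespace.
#' @param batch_names batch label per dataset; defaults to list names or
#'   \code{dataset1, dataset2, ...}.
#' @return A single [cell_matrix()].
#' @export
concat_datasets <- function(datasets, batch_names = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (is.null(batch_names)) {
    own <- lapply(datasets, function(d) unique(d$batch))
    if (all(lengths(own) == 1) && !anyDuplicated(unlist(own))) {
      batch_names <- unlist(own)      # each dataset carries its own label
    } else {
      batch_names <- names(datasets)
      if (is.null(batch_names) || any(batch_names == ""))
        batch_names <- paste0("dataset", seq_along(datasets))
    }
  }
  stopifnot(length(batch_names) == length(datasets))
  shared <- datasets[[1]]$gene_ids
  for (d in datasets[-1]) shared <- shared[shared %in% d$gene_ids]
  if (length(shared) == 0) stop("empty gene intersection across datasets")
  layers <- unique(vapply(datasets, `[[`, "", "layer"))
  pieces <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    v <- d$values[, match(shared, d$gene_ids), drop = FALSE]
    rownames(v) <- NULL
    list(values = v,
         cells = paste0(batch_names[i], "_", d$cell_ids),
         batch = rep(batch_names[i], nrow(v)),
         type = if (!is.null(d$type)) d$type else rep(NA_character_, nrow(v)))
  })
  values <- do.call(rbind, lapply(pieces, `[[`, "values"))
  type <- unlist(lapply(pieces, `[[`, "type"))
  if (all(is.na(type))) type <- NULL
  cell_matrix(values,
              cell_ids = unlist(lapply(pieces, `[[`, "cells")),
              gene_ids = shared,
              batch = unlist(lapply(pieces, `[[`, "batch")),
              type = type,
              layer = if (length(layers) == 1) layers else "counts")
}
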