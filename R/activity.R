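#' Peak-by-cell accessibility container
#'
#' @param counts non-negative integer matrix, peaks on rows, cells on columns
#'   (base or sparse \code{Matrix}).
#' @param chrom,start,end peak coordinates, 1-based inclusive.
#' @param barcodes unique cell barcodes (defaults to column names).
#' @return An object of class \code{peak_matrix}.
#' @export
peak_matrix <- function(counts, chrom, start, end, barcodes = colnames(counts)) {
  np <- nrow(counts)
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(ncol(counts)))
  stopifnot(length(chrom) == np, length(start) == np, length(end) == np,
            length(barcodes) == ncol(counts))
  if (any(end < start)) stop("peak end < start")
  if (any(start < 1)) stop("peak coordinates must be >= 1")
  if (anyDuplicated(barcodes)) stop("barcodes contain duplicates")
  if (min_value(counts) < 0) stop("peak counts must be non-negative")
  structure(list(counts = counts, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 barcodes = as.character(barcodes)),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d peaks x %d cells on %d chromosome(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$chrom))))
  invisible(x)
}

#' Read peak coordinates from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention used internally.
#'
#' @param path BED file (at least 3 columns).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive), in file order.
#' @export
read_peak_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read gene annotation from a GTF file
#'
#' Collapses all records sharing a \code{gene_id} to the union span
#' (minimum start, maximum end); the strand is taken from the first record.
#'
#' @param path GTF file.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tx_start}, \code{tx_end} (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gid <- gr$gene_id
  if (is.null(gid)) stop("GTF attributes do not contain gene_id")
  keep <- !is.na(gid)
  gr <- gr[keep]; gid <- gid[keep]
  sp <- split(seq_along(gr), gid)
  ann <- do.call(rbind, lapply(names(sp), function(g) {
    idx <- sp[[g]]
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(gr[idx[1]])),
               strand = as.character(GenomicRanges::strand(gr[idx[1]])),
               tx_start = min(GenomicRanges::start(gr[idx])),
               tx_end = max(GenomicRanges::end(gr[idx])),
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  ann
}

gene_window <- function(ann, upstream) {
  up <- ann$strand == "+" | ann$strand == "*"
  ws <- ifelse(up, pmax(1L, ann$tx_start - upstream), ann$tx_start)
  we <- ifelse(up, ann$tx_end, ann$tx_end + upstream)
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = as.integer(ws), end = as.integer(we),
             stringsAsFactors = FALSE)
}

#' Convert a peak matrix to gene activity
#'
#' For every gene, sums the counts of all peaks overlapping (by at least 1 bp)
#' the window from 2 kb upstream of the transcription start site to the
#' transcript end. For plus-strand genes the window is
#' \code{[max(1, tx_start - upstream), tx_end]}; for minus-strand genes it is
#' \code{[tx_start, tx_end + upstream]}. A peak contributes its full count to
#' every gene window it overlaps.
#'
#' @param pm a [peak_matrix()].
#' @param ann gene annotation data.frame as returned by
#'   [read_gene_annotation()] (columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{tx_start}, \code{tx_end}; one row per gene).
#' @param upstream bases added upstream of the TSS (default 2000).
#' @return A [cell_matrix()] with cells on rows, genes on columns and
#'   \code{layer == "activity"}.
#' @export
gene_activity <- function(pm, ann, upstream = 2000) {
  stopifnot(inherits(pm, "peak_matrix"))
  if (is.null(ann) || nrow(ann) == 0) stop("empty gene annotation")
  if (anyDuplicated(ann$gene_id)) stop("annotation must have one record per gene_id")
  if (any(ann$tx_end < ann$tx_start)) stop("annotation tx_end < tx_start")
  win <- gene_window(ann, upstream)
  peaks_gr <- GenomicRanges::GRanges(pm$chrom, IRanges::IRanges(pm$start, pm$end))
  genes_gr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
  hits <- GenomicRanges::findOverlaps(peaks_gr, genes_gr, minoverlap = 1L)
  if (length(hits) == 0)
    warning("no peak overlaps any gene window; activity matrix is all zero")
  ## peaks x genes indicator, then cells x genes = t(counts) %*% indicator
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(nrow(pm$counts), nrow(win)))
  act <- Matrix::t(Matrix::Matrix(pm$counts, sparse = TRUE)) %*% ind
  act <- as.matrix(act)
  dimnames(act) <- NULL
  cell_matrix(act, cell_ids = pm$barcodes, gene_ids = win$gene_id,
              layer = "activity")
}

#' Filter a gene-activity matrix
#'
#' Drops cells whose raw total peak count is below \code{min_total}
#' (strictly fewer than the threshold; cells exactly at it are kept), then
#' keeps only genes that are in \code{hvg} and have non-zero activity in at
#' least one retained cell.
#'
#' @param m a [cell_matrix()] with \code{layer == "activity"}.
#' @param raw_peak_totals numeric vector of per-cell total raw peak counts,
#'   aligned with \code{m$cell_ids}.
#' @param min_total minimum raw peak total (default 5000).
#' @param hvg character vector of genes to retain (e.g. the scRNA-seq HVG
#'   list); \code{NULL} keeps all genes with non-zero activity.
#' @return The filtered [cell_matrix()].
#' @export
filter_atac <- function(m, raw_peak_totals, min_total = 5000, hvg = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  if (length(raw_peak_totals) != length(m$cell_ids))
    stop("raw_peak_totals must be given for every cell")
  keep_cells <- raw_peak_totals >= min_total
  if (!any(keep_cells))
    stop("all cells filtered out at min_total = ", min_total)
  m <- subset_cells(m, keep_cells)
  nonzero <- colSums(as_dense(m) > 0) > 0
  keep_genes <- if (is.null(hvg)) nonzero else nonzero & m$gene_ids %in% hvg
  if (!any(keep_genes))
    stop("no gene passes the HVG/non-zero-activity filter")
  subset_genes(m, keep_genes)
}
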