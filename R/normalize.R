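#' CPM-log normalization
#'
#' Per cell, divides counts by the cell's total, scales to counts per million,
#' adds a pseudo-count of 1 and takes the natural logarithm:
#' \code{ln(1 + 1e6 * count / total)}. Cells with zero total depth are kept as
#' all-zero rows and reported in the \code{zero_depth_cells} attribute (with a
#' warning); dropping them is left to the caller.
#'
#' @param x a [cell_matrix()] with \code{layer == "counts"}.
#' @return A [cell_matrix()] with \code{layer == "cpm_log"} and attribute
#'   \code{zero_depth_cells} (character vector of affected cell ids).
#' @export
cpm_log_normalize <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  if (x$layer != "counts")
    stop("cpm_log_normalize expects a counts layer, got '", x$layer, "'")
  v <- as_dense(x)
  if (min(v) < 0) stop("negative values in count matrix")
  totals <- rowSums(v)
  zero <- totals == 0
  scale <- ifelse(zero, 0, 1e6 / totals)
  out <- log1p(v * scale)
  if (any(zero))
    warning(sum(zero), " cell(s) with zero total depth kept as all-zero rows")
  res <- cell_matrix(out, cell_ids = x$cell_ids, gene_ids = x$gene_ids,
                     batch = x$batch, type = x$type, layer = "cpm_log")
  attr(res, "zero_depth_cells") <- x$cell_ids[zero]
  res
}

## Per-batch dispersion score in the binned-dispersion style: work on
## expm1(normalized expression), bin genes into ~20 equal-count bins by mean,
## and z-score the variance/mean dispersion within each bin. Genes with
## undefined dispersion (zero mean, or a degenerate bin) get -Inf.
hvg_dispersion_z <- function(counts_cm, n_bins = 20) {
  norm <- suppressWarnings(cpm_log_normalize(counts_cm))
  e <- expm1(as_dense(norm))
  mu <- colMeans(e)
  v <- apply(e, 2, stats::var)
  ## constant genes (zero variance) carry no dispersion signal: undefined
  disp <- ifelse(mu > 0 & v > 0, v / mu, NA_real_)
  z <- rep(-Inf, length(mu))
  ok <- is.finite(disp)
  if (any(ok)) {
    qs <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- if (length(qs) < 2) factor(rep(1, sum(ok)))
            else cut(mu[ok], breaks = qs, include.lowest = TRUE)
    zok <- stats::ave(disp[ok], bins, FUN = function(d) {
      s <- stats::sd(d)
      if (!is.finite(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
    })
    ## a gene alone in its bin, or in an all-equal bin, scores 0 but is kept
    z[ok] <- zok
  }
  names(z) <- counts_cm$gene_ids
  z
}

#' Consensus highly variable gene selection across batches
#'
#' In each dataset separately, genes are ranked by binned normalized
#' dispersion (variance/mean of \code{expm1}-transformed CPM-log values,
#' z-scored within 20 equal-count mean-expression bins) and the top
#' \code{n_per_batch} are selected. The union of the per-batch selections is
#' then ordered by the number of datasets in which a gene was selected
#' (descending), breaking ties by the mean within-batch dispersion rank
#' (ascending) and then by gene id, and the first \code{n_final} genes are
#' returned.
#'
#' @param datasets list of [cell_matrix()] count matrices on a shared gene
#'   namespace (a single dataset is allowed).
#' @param n_per_batch genes selected per dataset (default 2000).
#' @param n_final size of the consensus list (default 2000).
#' @return Character vector of gene ids, most-consistently-variable first.
#'   If fewer than \code{n_final} genes are ever selected, all selected genes
#'   are returned with a warning.
#' @export
select_hvg_consensus <- function(datasets, n_per_batch = 2000, n_final = 2000) {
  if (inherits(datasets, "cell_matrix")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  genes <- datasets[[1]]$gene_ids
  for (d in datasets[-1])
    if (!identical(sort(d$gene_ids), sort(genes)))
      stop("datasets must share a common gene namespace")
  zs <- lapply(datasets, function(d) hvg_dispersion_z(d)[genes])
  n_sel <- integer(length(genes)); names(n_sel) <- genes
  rank_sum <- numeric(length(genes)); names(rank_sum) <- genes
  for (z in zs) {
    ## rank 1 = most dispersed; -Inf (undefined) ranks last
    r <- rank(-z, ties.method = "average")
    rank_sum <- rank_sum + r
    ok <- names(sort(r))[seq_len(min(n_per_batch, sum(is.finite(z))))]
    n_sel[ok] <- n_sel[ok] + 1L
  }
  mean_rank <- rank_sum / length(zs)
  cand <- genes[n_sel > 0]
  if (length(cand) == 0) {
    warning("no gene has a defined dispersion in any batch; returning empty set")
    return(character(0))
  }
  ord <- cand[order(-n_sel[cand], mean_rank[cand], cand)]
  if (n_final > length(ord)) {
    warning("n_final (", n_final, ") exceeds the number of selected genes (",
            length(ord), "); returning all")
    return(ord)
  }
  ord[seq_len(n_final)]
}
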