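#' Simulate multi-batch single-cell count data with known structure
#'
#' Poisson counts with log-normal per-gene base means, disjoint per-type
#' marker sets (multiplicative effect \code{2^marker_log2fc}), per-(batch,
#' gene) multiplicative batch effects (log-normal with log-sd
#' \code{batch_sd}), and per-cell library-size factors (log-normal with
#' log-sd \code{libsize_sd}). Cell types are assigned i.i.d. uniformly within
#' each batch. Regeneration with the same parameters and seed is
#' bit-identical.
#'
#' @param n_per_batch cells per batch (scalar, or vector of length
#'   \code{n_batches}).
#' @param n_batches number of batches (default 2).
#' @param n_types number of cell types (default 3).
#' @param n_genes number of genes (default 500).
#' @param marker_frac fraction of genes that are markers of each type
#'   (default 0.1; marker sets are disjoint across types).
#' @param marker_log2fc log2 fold change of marker genes in their type
#'   (default 2).
#' @param batch_sd log-sd of the per-(batch, gene) batch multiplier (default
#'   0.5; 0 disables batch effects).
#' @param libsize_sd log-sd of the per-cell library factor (default 0.3).
#' @param seed integer seed.
#' @return List with \code{batches} (list of count [cell_matrix()] objects
#'   with batch and type labels) and \code{truth} (class
#'   \code{synthetic_truth}: base means \code{lambda}, \code{type_mult},
#'   \code{batch_mult}, library factors, labels, marker sets, and all
#'   generator parameters including the seed).
#' @export
simulate_multibatch <- function(n_per_batch, n_batches = 2, n_types = 3,
                                n_genes = 500, marker_frac = 0.1,
                                marker_log2fc = 2.0, batch_sd = 0.5,
                                libsize_sd = 0.3, seed = 1) {
  stopifnot(n_batches >= 1, n_types >= 1, n_genes >= 1, batch_sd >= 0,
            libsize_sd >= 0, all(n_per_batch >= 1))
  n_per_batch <- rep_len(as.integer(n_per_batch), n_batches)
  n_marker <- round(marker_frac * n_genes)
  if (n_types * n_marker > n_genes)
    stop("disjoint marker sets exceed the gene count")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  genes <- sprintf("gene%03d", seq_len(n_genes))
  lambda <- stats::rlnorm(n_genes, meanlog = log(0.5), sdlog = 1)
  type_mult <- matrix(1, n_types, n_genes)
  markers <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    idx <- ((t - 1) * n_marker + 1):(t * n_marker)
    if (n_marker > 0) type_mult[t, idx] <- 2^marker_log2fc
    markers[[t]] <- genes[idx]
  }
  batch_mult <- matrix(stats::rlnorm(n_batches * n_genes, 0, batch_sd),
                       n_batches, n_genes)
  batch_names <- paste0("batch", seq_len(n_batches))
  batches <- vector("list", n_batches)
  type_of_cell <- list(); lib_of_cell <- list()
  for (b in seq_len(n_batches)) {
    nb <- n_per_batch[b]
    ty <- sample.int(n_types, nb, replace = TRUE)
    lib <- stats::rlnorm(nb, 0, libsize_sd)
    mu <- (lib * type_mult[ty, , drop = FALSE]) *
      rep(lambda * batch_mult[b, ], each = nb)
    counts <- matrix(stats::rpois(length(mu), mu), nb, n_genes)
    batches[[b]] <- cell_matrix(counts,
                                cell_ids = sprintf("%s_c%04d", batch_names[b], seq_len(nb)),
                                gene_ids = genes,
                                batch = batch_names[b],
                                type = paste0("type", ty),
                                layer = "counts")
    type_of_cell[[b]] <- ty
    lib_of_cell[[b]] <- lib
  }
  truth <- structure(list(lambda = lambda, type_mult = type_mult,
                          batch_mult = batch_mult,
                          markers = stats::setNames(markers, paste0("type", seq_len(n_types))),
                          type_of_cell = unlist(type_of_cell),
                          batch_of_cell = rep(batch_names, n_per_batch),
                          lib_of_cell = unlist(lib_of_cell),
                          params = list(n_per_batch = n_per_batch,
                                        n_batches = n_batches,
                                        n_types = n_types, n_genes = n_genes,
                                        marker_frac = marker_frac,
                                        marker_log2fc = marker_log2fc,
                                        batch_sd = batch_sd,
                                        libsize_sd = libsize_sd, seed = seed)),
                     class = "synthetic_truth")
  list(batches = batches, truth = truth)
}

#' Simulate a query modality from known cell-type means
#'
#' Draws fresh cells from the same per-type expected expression as the
#' original simulation (fresh batch multipliers at the configured batch-effect
#' strength, fresh library factors) and applies additional independent
#' zero-inflation at rate \code{dropout_extra}, emulating the sparser
#' gene-activity modality for label-transfer tests. Cells get the batch label
#' \code{"query"}.
#'
#' @param truth a \code{synthetic_truth} from [simulate_multibatch()].
#' @param dropout_extra probability of zeroing each entry (default 0.3).
#' @param n_cells number of query cells (defaults to the first batch's size).
#' @param seed integer seed.
#' @return A count [cell_matrix()] with type labels and batch "query".
#' @export
make_split_modality <- function(truth, dropout_extra = 0.3, n_cells = NULL,
                                seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (dropout_extra < 0 || dropout_extra > 1)
    stop("dropout_extra must be in [0, 1]")
  p <- truth$params
  if (is.null(n_cells)) n_cells <- p$n_per_batch[1]
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  ty <- sample.int(p$n_types, n_cells, replace = TRUE)
  lib <- stats::rlnorm(n_cells, 0, p$libsize_sd)
  bmult <- stats::rlnorm(p$n_genes, 0, p$batch_sd)
  mu <- (lib * truth$type_mult[ty, , drop = FALSE]) *
    rep(truth$lambda * bmult, each = n_cells)
  counts <- matrix(stats::rpois(length(mu), mu), n_cells, p$n_genes)
  if (dropout_extra > 0) {
    keep <- matrix(stats::rbinom(length(counts), 1, 1 - dropout_extra),
                   n_cells)
    counts <- counts * keep
  }
  cell_matrix(counts,
              cell_ids = sprintf("query_c%04d", seq_len(n_cells)),
              gene_ids = sprintf("gene%03d", seq_len(p$n_genes)),
              batch = "query", type = paste0("type", ty), layer = "counts")
}
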