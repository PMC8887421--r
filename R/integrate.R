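#' Latent embedding of cells
#'
#' Returns the posterior means of the variational distribution — the model's
#' point estimates of the latent factors — row-aligned with the input cells.
#'
#' @param params a \code{generative_params} object or fitted \code{ccalign}
#'   model.
#' @param data normalized [cell_matrix()] or matrix on the training gene set.
#' @return n x d numeric matrix (rownames = cell ids when available).
#' @export
get_embedding <- function(params, data) {
  emb <- encode(params, data)$mean
  if (inherits(data, "cell_matrix")) rownames(emb) <- data$cell_ids
  emb
}

#' Recover batch-free expression
#'
#' Decodes every cell's latent embedding with one shared reference batch
#' code, so dataset-specific effects (carried by the code, not the latent
#' factors) are removed. Values are on the normalized-expression scale and
#' non-negative.
#'
#' @param object a fitted \code{ccalign} model, or a \code{generative_params}
#'   object (then \code{codes} and \code{data} are required).
#' @param data optional [cell_matrix()] to recover (defaults to the model's
#'   training data).
#' @param reference_batch index or name of the batch code used for all cells
#'   (default 1).
#' @param codes list of batch codes (taken from the fitted model when
#'   omitted).
#' @return A [cell_matrix()] with \code{layer == "recovered"}.
#' @export
recover_expression <- function(object, data = NULL, reference_batch = 1,
                               codes = NULL) {
  if (inherits(object, "ccalign")) {
    params <- object$params
    if (is.null(codes)) codes <- object$codes
    if (is.null(data)) data <- object$data
  } else {
    params <- as_params(object)
    if (is.null(codes) || is.null(data))
      stop("codes and data are required when not passing a fitted model")
  }
  ref <- if (is.character(reference_batch)) {
    if (!reference_batch %in% names(codes))
      stop("reference batch '", reference_batch, "' not among batch codes")
    reference_batch
  } else {
    if (reference_batch < 1 || reference_batch > length(codes))
      stop("reference_batch out of range")
    as.integer(reference_batch)
  }
  emb <- get_embedding(params, data)
  vals <- decode(params, emb, codes[[ref]])
  if (inherits(data, "cell_matrix"))
    cell_matrix(vals, cell_ids = data$cell_ids, gene_ids = data$gene_ids,
                batch = data$batch, type = data$type, layer = "recovered")
  else cell_matrix(vals, layer = "recovered")
}

#' Nearest neighbors in the joint latent space
#'
#' For each query cell, finds the \code{n_neighbors} nearest cells by
#' Euclidean distance among the joint set of reference and query cells
#' (self excluded). Reference members of a query cell's neighborhood are the
#' candidates for label transfer; a neighborhood may contain none.
#'
#' @param reference_embedding,query_embedding matrices with the same number
#'   of columns.
#' @param n_neighbors neighborhood size (default 50). When it exceeds the
#'   number of available cells, all cells are used with a warning.
#' @return List with \code{idx} (n_query x k matrix of joint indices;
#'   reference cells come first), \code{dist} (matching distances),
#'   \code{is_ref} (logical matrix), and \code{n_ref}.
#' @export
knn_latent <- function(reference_embedding, query_embedding, n_neighbors = 50) {
  ref <- as.matrix(reference_embedding)
  qry <- as.matrix(query_embedding)
  stopifnot(ncol(ref) == ncol(qry))
  joint <- rbind(ref, qry)
  n_ref <- nrow(ref)
  n_total <- nrow(joint)
  k <- n_neighbors
  if (k > n_total - 1) {
    warning("n_neighbors (", k, ") exceeds available cells; using ", n_total - 1)
    k <- n_total - 1
  }
  nn <- RANN::nn2(joint, qry, k = min(k + 1L, n_total))
  idx <- matrix(0L, nrow(qry), k)
  dst <- matrix(0, nrow(qry), k)
  for (i in seq_len(nrow(qry))) {
    self <- n_ref + i
    row <- nn$nn.idx[i, ]
    drop <- match(self, row)
    if (is.na(drop)) drop <- length(row)   # self pushed out by ties
    keep <- setdiff(seq_along(row), drop)[seq_len(k)]
    idx[i, ] <- row[keep]
    dst[i, ] <- nn$nn.dists[i, keep]
  }
  list(idx = idx, dist = dst, is_ref = idx <= n_ref, n_ref = n_ref)
}

#' Transfer reference cell-type labels to query cells
#'
#' For each query cell, reference cells among its \code{n_neighbors} nearest
#' neighbors in the joint latent space vote with a Gaussian kernel: the
#' confidence for cell type \code{c} is
#' \deqn{S_{ic} = \sum_{j \in N_{ic}} \exp(-dist(i,j)^2 / (2 w_c)),}
#' where \code{N_ic} is the set of reference neighbors of type \code{c} and
#' the bandwidth \code{w_c} is the global proportion of type \code{c} in the
#' reference. The cell is assigned the type with maximal confidence (ties
#' broken by larger \code{w_c}, then lexicographically); a query cell with no
#' reference neighbor at all is assigned \code{"unknown"}.
#'
#' @param reference_embedding,query_embedding latent coordinate matrices.
#' @param reference_labels cell-type label per reference cell.
#' @param n_neighbors neighborhood size (default 50).
#' @return An object of class \code{transfer_result}: data.frame with columns
#'   \code{cell}, \code{label}, \code{score} (confidence of the assigned
#'   label; NA for unknown) and \code{n_ref_neighbors}; the full per-type
#'   score matrix is in \code{attr(, "scores")}.
#' @export
transfer_labels <- function(reference_embedding, reference_labels,
                            query_embedding, n_neighbors = 50) {
  ref <- as.matrix(reference_embedding)
  if (nrow(ref) == 0) stop("empty reference")
  reference_labels <- as.character(reference_labels)
  stopifnot(length(reference_labels) == nrow(ref))
  qry <- as.matrix(query_embedding)
  nn <- knn_latent(ref, qry, n_neighbors)
  types <- sort(unique(reference_labels))
  w <- table(factor(reference_labels, levels = types)) / length(reference_labels)
  w <- as.numeric(w); names(w) <- types
  scores <- matrix(0, nrow(qry), length(types),
                   dimnames = list(NULL, types))
  label <- character(nrow(qry))
  best <- rep(NA_real_, nrow(qry))
  n_ref_nb <- integer(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    ref_nb <- which(nn$is_ref[i, ])
    n_ref_nb[i] <- length(ref_nb)
    if (length(ref_nb) == 0) {
      label[i] <- "unknown"
      next
    }
    labs <- reference_labels[nn$idx[i, ref_nb]]
    d2 <- nn$dist[i, ref_nb]^2
    for (ty in unique(labs)) {
      sel <- labs == ty
      scores[i, ty] <- sum(exp(-d2[sel] / (2 * w[ty])))
    }
    cand <- unique(labs)
    s <- scores[i, cand]
    ord <- cand[order(-s, -w[cand], cand)]
    label[i] <- ord[1]
    best[i] <- scores[i, ord[1]]
  }
  qids <- rownames(qry)
  if (is.null(qids)) qids <- paste0("query", seq_len(nrow(qry)))
  res <- data.frame(cell = qids, label = label, score = best,
                    n_ref_neighbors = n_ref_nb, stringsAsFactors = FALSE)
  attr(res, "scores") <- scores
  class(res) <- c("transfer_result", "data.frame")
  res
}
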