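#' kBET-style acceptance rate
#'
#' For each cell type, repeatedly samples a focal cell, takes its k nearest
#' same-type neighbors in the embedding, and tests the neighborhood's batch
#' composition against the global within-type batch proportions with a
#' Pearson chi-squared test (df = number of batches - 1). The neighborhood
#' size k sweeps \code{size_fracs} of the type's cell count (at least twice
#' the number of batches), with \code{reps} replicates per size. The
#' acceptance rate is the fraction of tests with p >= \code{alpha}: near
#' \code{1 - alpha} for perfectly mixed batches, near 0 for separated ones.
#'
#' @param embedding n x d latent coordinates.
#' @param batch per-cell batch labels (>= 2 distinct values required overall).
#' @param type optional per-cell type labels; when NULL all cells form one
#'   group. A type present in fewer than two batches is reported as NA and
#'   excluded from the mean.
#' @param size_fracs neighborhood sizes as fractions of the per-type cell
#'   count (default 9 evenly spaced values in 5-25%).
#' @param reps replicates per neighborhood size (default 100).
#' @param alpha test level (default 0.05).
#' @param seed integer seed for focal-cell sampling.
#' @param max_cells_per_batch optional subsampling cap per batch, applied
#'   before testing (seed-controlled), for very large inputs.
#' @return List with \code{per_type} (named acceptance rates), \code{mean}
#'   (unweighted over non-NA types) and \code{n_tests}.
#' @export
kbet_acceptance <- function(embedding, batch, type = NULL,
                            size_fracs = seq(0.05, 0.25, length.out = 9),
                            reps = 100, alpha = 0.05, seed = 1,
                            max_cells_per_batch = NULL) {
  emb <- as.matrix(embedding)
  batch <- as.character(batch)
  stopifnot(nrow(emb) == length(batch))
  if (length(unique(batch)) < 2) stop("kBET requires at least 2 batches")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  if (!is.null(max_cells_per_batch)) {
    keep <- unlist(lapply(unique(batch), function(b) {
      ib <- which(batch == b)
      if (length(ib) > max_cells_per_batch) sample(ib, max_cells_per_batch) else ib
    }))
    keep <- sort(keep)
    emb <- emb[keep, , drop = FALSE]
    batch <- batch[keep]
    if (!is.null(type)) type <- as.character(type)[keep]
  }
  if (is.null(type)) type <- rep("all", nrow(emb)) else type <- as.character(type)
  types <- sort(unique(type))
  per_type <- stats::setNames(rep(NA_real_, length(types)), types)
  n_tests <- 0L
  for (ty in types) {
    sel <- which(type == ty)
    b <- factor(batch[sel])
    if (nlevels(b) < 2) next  # type confined to one batch: NA
    props <- as.numeric(table(b)) / length(sel)
    e <- emb[sel, , drop = FALSE]
    d2 <- as.matrix(stats::dist(e))^2
    nc <- length(sel)
    nb <- nlevels(b)
    accept <- 0L; total <- 0L
    for (frac in size_fracs) {
      k <- max(round(frac * nc), 2L * nb)
      k <- min(k, nc - 1L)
      for (r in seq_len(reps)) {
        focal <- sample.int(nc, 1)
        nbrs <- order(d2[focal, ])[-1][seq_len(k)]   # self first at distance 0
        obs <- tabulate(b[nbrs], nbins = nb)
        expd <- k * props
        stat <- sum((obs - expd)^2 / expd)
        p <- stats::pchisq(stat, df = nb - 1, lower.tail = FALSE)
        accept <- accept + (p >= alpha)
        total <- total + 1L
      }
    }
    per_type[ty] <- accept / total
    n_tests <- n_tests + total
  }
  list(per_type = per_type,
       mean = mean(per_type, na.rm = TRUE),
       n_tests = n_tests)
}

#' Mixing metric
#'
#' For every cell, ranks its \code{k_max} nearest neighbors (self excluded)
#' and records, for each batch, the 1-based rank at which that batch's k-th
#' member appears (capped at \code{k_max} when fewer than k occur). The
#' per-cell score is \code{k_max} minus the median of those ranks; the metric
#' is the median over cells. Higher means better mixing: the score is
#' \code{k_max - k} when every batch supplies its k-th neighbor immediately,
#' 147.5 at the two-batch fully-separated floor (k = 5, k_max = 300) and 0 at
#' the three-batch floor.
#'
#' @param embedding n x d latent coordinates.
#' @param batch per-cell batch labels.
#' @param k neighbor depth per batch (default 5).
#' @param k_max neighborhood size (default 300; capped at n - 1 with a
#'   warning).
#' @return A single number in \code{[0, k_max]}.
#' @export
mixing_metric <- function(embedding, batch, k = 5, k_max = 300) {
  emb <- as.matrix(embedding)
  batch <- factor(batch)
  n <- nrow(emb)
  stopifnot(length(batch) == n)
  if (nlevels(batch) < 2)
    warning("single batch: mixing metric is k_max - k by construction")
  if (k_max > n - 1) {
    warning("k_max (", k_max, ") exceeds n - 1; using ", n - 1)
    k_max <- n - 1
  }
  nn <- RANN::nn2(emb, emb, k = k_max + 1L)
  scores <- numeric(n)
  bint <- as.integer(batch)
  for (i in seq_len(n)) {
    row <- nn$nn.idx[i, ]
    row <- row[row != i]
    if (length(row) > k_max) row <- row[seq_len(k_max)]
    nb <- bint[row]
    ranks <- vapply(seq_len(nlevels(batch)), function(m) {
      pos <- which(nb == m)
      if (length(pos) >= k) pos[k] else k_max
    }, numeric(1))
    scores[i] <- k_max - stats::median(ranks)
  }
  stats::median(scores)
}

#' Louvain clustering of a latent embedding
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances, weights edges by
#' the Jaccard similarity of the two endpoints' neighbor sets (shared nearest
#' neighbors), and runs Louvain modularity optimization. Deterministic for a
#' fixed seed.
#'
#' @param embedding n x d latent coordinates.
#' @param knn neighbors per cell for the graph (default 20; lowered to n - 1
#'   with a warning when too large).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @return Integer vector of cluster labels (1-based).
#' @export
cluster_embedding <- function(embedding, knn = 20, resolution = 1.0, seed = 1) {
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (n < 2) return(rep(1L, n))
  if (all(apply(emb, 2, function(col) length(unique(col)) == 1)))
    return(rep(1L, n))
  if (knn > n - 1) {
    warning("knn (", knn, ") exceeds n - 1; using ", n - 1)
    knn <- n - 1
  }
  nn <- RANN::nn2(emb, emb, k = knn + 1L)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), knn), j = as.vector(idx),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * knn - jac@x)
  jac <- (jac + Matrix::t(jac)) / 2
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, computed from the
#' contingency table; invariant to label renaming. 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A single number in \code{[-1, 1]}.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  ## max == expected only when both partitions are all-singleton or both are
  ## one lump, i.e. identical up to labels: perfect agreement
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## exact two-sided rank-sum p-value by enumeration of all C(n, n_a)
## assignments of the pooled (tied) ranks
rank_sum_exact_p <- function(r_a, r_all) {
  n_a <- length(r_a)
  W <- sum(r_a)
  mu <- n_a * (length(r_all) + 1) / 2
  dev <- abs(W - mu)
  combos <- utils::combn(r_all, n_a)
  sums <- colSums(combos)
  mean(abs(sums - mu) >= dev - 1e-9)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between two cell groups on
#' normalized (or recovered) expression, with a tie-corrected normal
#' approximation (continuity corrected) or exact enumeration over all group
#' assignments when both groups have at most 10 cells. Following the standard
#' single-cell marker-detection convention, only genes detected (value > 0)
#' in at least \code{min_pct} of either group and with
#' \code{|avg_log2FC| >= logfc_threshold} are tested; the Bonferroni
#' adjustment is over the tested genes. Set both to 0 to test every gene.
#' The average log2 fold change is
#' \code{log2(mean(expm1(a)) + 1) - log2(mean(expm1(b)) + 1)}.
#'
#' @param expr a [cell_matrix()] (normalized or recovered layer) or matrix.
#' @param cells_a,cells_b disjoint, non-empty cell selections: indices,
#'   logical masks, or cell ids.
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param logfc_threshold minimum absolute average log2 fold change
#'   (default 0.25).
#' @param exact_max exact enumeration is used when both group sizes are at
#'   most this (default 10).
#' @return An object of class \code{de_result}: data.frame with columns
#'   \code{gene}, \code{p}, \code{p_adj} (NA for untested genes),
#'   \code{avg_log2FC}, \code{pct_a}, \code{pct_b}, \code{mean_a},
#'   \code{mean_b} and \code{tested}, in input gene order.
#' @export
wilcoxon_de <- function(expr, cells_a, cells_b, min_pct = 0.1,
                        logfc_threshold = 0.25, exact_max = 10) {
  if (inherits(expr, "cell_matrix")) {
    genes <- expr$gene_ids
    ids <- expr$cell_ids
    v <- as_dense(expr)
  } else {
    v <- as.matrix(expr)
    genes <- colnames(v)
    if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(v)))
    ids <- rownames(v)
  }
  resolve <- function(sel) {
    if (is.character(sel)) {
      if (is.null(ids)) stop("cell ids not available")
      m <- match(sel, ids)
      if (anyNA(m)) stop("unknown cell id(s) in selection")
      m
    } else if (is.logical(sel)) which(sel) else as.integer(sel)
  }
  ia <- resolve(cells_a); ib <- resolve(cells_b)
  if (length(ia) == 0 || length(ib) == 0) stop("both groups must be non-empty")
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  n_a <- length(ia); n_b <- length(ib); n <- n_a + n_b
  exact <- n_a <= exact_max && n_b <= exact_max
  pct_a <- colMeans(v[ia, , drop = FALSE] > 0)
  pct_b <- colMeans(v[ib, , drop = FALSE] > 0)
  lfc <- log2(colMeans(expm1(v[ia, , drop = FALSE])) + 1) -
    log2(colMeans(expm1(v[ib, , drop = FALSE])) + 1)
  tested <- pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= logfc_threshold
  p <- rep(NA_real_, ncol(v))
  for (g in which(tested)) {
    vals <- c(v[ia, g], v[ib, g])
    r <- rank(vals)
    r_a <- r[seq_len(n_a)]
    if (exact) {
      p[g] <- rank_sum_exact_p(r_a, r)
    } else {
      W <- sum(r_a)
      mu <- n_a * (n + 1) / 2
      ties <- table(vals)
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      sig2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
      if (sig2 <= 0) { p[g] <- 1; next }
      z <- (abs(W - mu) - 0.5) / sqrt(sig2)
      p[g] <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  res <- data.frame(gene = genes, p = p,
                    p_adj = pmin(1, p * sum(tested)),
                    avg_log2FC = lfc,
                    pct_a = pct_a, pct_b = pct_b,
                    mean_a = colMeans(v[ia, , drop = FALSE]),
                    mean_b = colMeans(v[ib, , drop = FALSE]),
                    tested = tested,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Top differentially expressed genes
#'
#' Stable sort by adjusted p-value (ascending), then by decreasing absolute
#' average log2 fold change, then by gene id; truncated to \code{n}. Genes
#' that were not tested (NA adjusted p) are excluded.
#'
#' @param res a \code{de_result} from [wilcoxon_de()].
#' @param n list length (default 100; the full table when shorter).
#' @return Character vector of gene ids.
#' @export
top_de_genes <- function(res, n = 100) {
  stopifnot(nrow(res) >= 1)
  res <- res[!is.na(res$p_adj), , drop = FALSE]
  ord <- order(res$p_adj, -abs(res$avg_log2FC), res$gene)
  res$gene[ord][seq_len(min(n, nrow(res)))]
}

#' Jaccard index of two gene lists
#'
#' Set overlap |A n B| / |A u B|. Two empty lists give 1 by convention, with
#' a warning.
#'
#' @param list_a,list_b character vectors (treated as sets).
#' @return A single number in \code{[0, 1]}.
#' @export
jaccard_index <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(a) == 0 && length(b) == 0) {
    warning("both lists empty; Jaccard index 1 by convention")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}
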