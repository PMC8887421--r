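# Shared fixtures, built in code at test time.

# small count cell_matrix with reproducible Poisson counts
toy_counts <- function(n = 10, p = 6, seed = 1, batch = "batch1") {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = 3), n, p)
  cell_matrix(m, cell_ids = paste0(batch, "c", seq_len(n)),
              gene_ids = paste0("g", seq_len(p)), batch = batch)
}

# well-separated Gaussian clusters in d dimensions; returns embedding + labels
separated_clusters <- function(n_per, centers, d = 2, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  emb <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      rep(centers[i, ], each = n_per)))
  list(embedding = emb, label = rep(paste0("c", seq_len(k)), each = n_per))
}

# independent exhaustive permutation oracle for the two-sided rank-sum p-value
perm_ranksum_p <- function(a, b) {
  vals <- c(a, b)
  n_a <- length(a)
  r <- rank(vals)
  mu <- n_a * (length(vals) + 1) / 2
  obs <- abs(sum(r[seq_len(n_a)]) - mu)
  idx <- utils::combn(length(vals), n_a)
  devs <- abs(apply(idx, 2, function(ii) sum(r[ii])) - mu)
  mean(devs >= obs - 1e-9)
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(codes) {
    if (length(codes) == n) {
      out[[length(out) + 1]] <<- codes
      return(invisible())
    }
    m <- if (length(codes)) max(codes) else 0
    for (v in seq_len(m + 1)) grow(c(codes, v))
  }
  grow(integer(0))
  out
}

# synthetic two-batch fixture run end to end; returns everything the
# integration battery needs
run_integration_fixture <- function(seed, epochs = 300, n_per_batch = 600,
                                    n_genes = 500, n_hvg = 200) {
  sim <- simulate_multibatch(n_per_batch, n_batches = 2, n_types = 3,
                             n_genes = n_genes, batch_sd = 0.5, seed = seed)
  hvg <- select_hvg_consensus(sim$batches, n_per_batch = n_hvg, n_final = n_hvg)
  fit <- ccalign(sim$batches, spec = network_spec(),
                 config = train_config(epochs = epochs, seed = seed),
                 hvg = hvg)
  list(sim = sim, fit = fit, type = fit$data$type, batch = fit$data$batch)
}
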