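test_that("mixing metric hits its analytic floors for separated batches", {
  centers2 <- matrix(c(0, 0, 1000, 1000), 2, 2, byrow = TRUE)
  fix2 <- separated_clusters(310, centers2, d = 2, sd = 1, seed = 1)
  # two batches: per-cell ranks {5, 300}, median 152.5 -> score 147.5
  expect_equal(mixing_metric(fix2$embedding, fix2$label, k = 5, k_max = 300),
               147.5)
  centers3 <- matrix(c(0, 0, 1000, 0, 0, 1000), 3, 2, byrow = TRUE)
  fix3 <- separated_clusters(310, centers3, d = 2, sd = 1, seed = 2)
  # three batches: ranks {5, 300, 300}, median 300 -> score 0
  expect_equal(mixing_metric(fix3$embedding, fix3$label, k = 5, k_max = 300), 0)
})

test_that("mixing metric is bounded, rotation/translation invariant, and maximal for mixed batches", {
  set.seed(4)
  emb <- matrix(rnorm(400 * 2), 400, 2)
  batch <- rep(c("a", "b"), 200)
  m <- mixing_metric(emb, batch, k = 5, k_max = 100)
  # i.i.d. batches: each batch's 5th neighbor arrives around rank 10
  expect_gte(m, 0.8 * (100 - 5))
  expect_lte(m, 100 - 5)
  th <- 0.7
  rot <- emb %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) + 5
  expect_equal(mixing_metric(rot, batch, k = 5, k_max = 100), m)
  expect_warning(s <- mixing_metric(emb, rep("a", 400), k = 5, k_max = 100),
                 "single batch")
  expect_equal(s, 95)
  expect_warning(mixing_metric(emb[1:50, ], batch[1:50], k = 5, k_max = 300),
                 "exceeds n - 1")
})

test_that("kBET acceptance is calibrated under the permutation null", {
  set.seed(10)
  emb <- matrix(rnorm(600 * 4), 600, 4)
  batch <- sample(c("a", "b"), 600, replace = TRUE)   # i.i.d. labels
  res <- kbet_acceptance(emb, batch, seed = 42)
  expect_gte(res$n_tests, 900)
  expect_gte(res$mean, 1 - 0.05 - 0.05)
  expect_lte(res$mean, 1)
})

test_that("kBET rejects fully separated batches and handles degenerate types", {
  centers <- matrix(c(0, 0, 50, 50), 2, 2, byrow = TRUE)
  fix <- separated_clusters(150, centers, d = 2, sd = 1, seed = 3)
  res <- kbet_acceptance(fix$embedding, fix$label, seed = 7)
  expect_lte(res$mean, 0.02)

  expect_error(kbet_acceptance(fix$embedding, rep("a", 300)), "at least 2")

  # a cell type confined to one batch is NA and excluded from the mean
  type <- c(rep("t1", 150), rep("t2", 150))
  set.seed(5)
  mixed <- matrix(rnorm(300 * 2), 300, 2)
  batch <- c(rep("a", 150), sample(c("a", "b"), 150, replace = TRUE))
  res2 <- kbet_acceptance(mixed, batch, type, seed = 1)
  expect_true(is.na(res2$per_type[["t1"]]))
  expect_false(is.na(res2$per_type[["t2"]]))
  expect_equal(res2$mean, res2$per_type[["t2"]])
})

test_that("Louvain clustering on the SNN graph recovers well-separated blobs", {
  # blobs in a latent-like dimensionality (centroids 10 sd apart)
  centers <- rbind(rep(0, 10), c(10, rep(0, 9)))
  fix <- separated_clusters(100, centers, d = 10, sd = 1, seed = 6)
  cl <- cluster_embedding(fix$embedding, knn = 20, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(adjusted_rand_index(cl, fix$label), 1)

  # determinism under permutation: unpermuting restores the same partition
  set.seed(2)
  perm <- sample(200)
  cl_perm <- cluster_embedding(fix$embedding[perm, ], knn = 20, seed = 1)
  expect_equal(adjusted_rand_index(cl_perm[order(perm)], cl), 1)

  expect_warning(cluster_embedding(fix$embedding[1:10, ], knn = 20, seed = 1),
                 "exceeds n - 1")
  expect_equal(cluster_embedding(matrix(1, 30, 2)), rep(1L, 30))
})

test_that("adjusted Rand index matches its closed form and brute force over partitions of 5", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")

  skip_if_not_installed("mclust")
  parts <- all_partitions(5)               # all 52 set partitions
  for (i in seq_along(parts)) {
    for (j in c(1, 7, 23, length(parts))) {
      ref <- mclust::adjustedRandIndex(parts[[i]], parts[[j]])
      if (is.nan(ref)) next   # both-all-singleton: reference is indeterminate
      expect_equal(adjusted_rand_index(parts[[i]], parts[[j]]), ref,
                   tolerance = 1e-12)
    }
  }
  # identical degenerate partitions agree perfectly
  expect_equal(adjusted_rand_index(1:5, 5:1), 1)   # both all-singleton
})

test_that("rank-sum p-values match exhaustive permutation enumeration for small groups", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  de <- wilcoxon_de(x, 1:3, 4:6, min_pct = 0, logfc_threshold = 0)
  expect_equal(de$p, 0.1)                  # 2 of C(6,3)=20 assignments as extreme

  set.seed(44)
  for (sizes in list(c(3, 3), c(4, 6), c(5, 5), c(8, 10))) {
    vals <- matrix(c(rpois(sizes[1], 3), rpois(sizes[2], 5)), ncol = 1)  # ties likely
    de <- wilcoxon_de(vals, seq_len(sizes[1]), sizes[1] + seq_len(sizes[2]),
                      min_pct = 0, logfc_threshold = 0)
    oracle <- perm_ranksum_p(vals[seq_len(sizes[1]), 1],
                             vals[sizes[1] + seq_len(sizes[2]), 1])
    expect_equal(de$p, oracle, tolerance = 1e-12)
  }

  # no ties: exact path must agree with the reference implementation
  set.seed(45)
  a <- rnorm(6); b <- rnorm(7) + 1
  de <- wilcoxon_de(matrix(c(a, b), ncol = 1), 1:6, 7:13,
                    min_pct = 0, logfc_threshold = 0)
  expect_equal(de$p, wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("the large-sample rank-sum approximation tracks the reference implementation", {
  set.seed(46)
  a <- rpois(40, 4); b <- rpois(55, 5)
  de <- wilcoxon_de(matrix(c(a, b), ncol = 1), 1:40, 41:95,
                    min_pct = 0, logfc_threshold = 0)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(de$p, ref, tolerance = 1e-9)
})

test_that("DE table carries fold changes, Bonferroni adjustment and filters", {
  set.seed(47)
  v <- cbind(g1 = c(rep(2, 12), rep(0.2, 12)),       # strong DE
             g2 = rep(c(1, 1.01), 12),               # null, tiny fold change
             g3 = c(rep(1.6, 12), rep(1.0, 12)))     # moderate DE
  rownames(v) <- paste0("c", 1:24)
  de <- wilcoxon_de(v, 1:12, 13:24)
  expect_true(de$tested[1] && de$tested[3])
  expect_false(de$tested[2])                         # |log2FC| below threshold
  expect_true(is.na(de$p[2]))
  expect_equal(de$p_adj[de$tested], pmin(1, de$p[de$tested] * sum(de$tested)))
  expect_equal(de$avg_log2FC[1],
               log2(mean(expm1(v[1:12, 1])) + 1) -
                 log2(mean(expm1(v[13:24, 1])) + 1))

  # identical multisets: p = 1, zero fold change (filters off)
  w <- matrix(rep(c(3, 1, 2), 4), ncol = 1)
  de0 <- wilcoxon_de(w, 1:6, 7:12, min_pct = 0, logfc_threshold = 0)
  expect_equal(de0$p, 1)
  expect_equal(de0$avg_log2FC, 0)

  # Bonferroni arithmetic: raw 0.01 over 10 tested genes -> 0.1
  expect_equal(min(1, 0.01 * 10), 0.1)
  expect_error(wilcoxon_de(v, 1:12, integer(0)), "non-empty")
  expect_error(wilcoxon_de(v, 1:12, 12:24), "disjoint")
})

test_that("top DE genes sort by adjusted p, then absolute fold change, then id", {
  res <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                    p = c(0.001, 0.002, 0.002, NA),
                    p_adj = c(0.01, 0.02, 0.02, NA),
                    avg_log2FC = c(0.5, 1, 2, 9),
                    tested = c(TRUE, TRUE, TRUE, FALSE))
  class(res) <- c("de_result", "data.frame")
  expect_equal(top_de_genes(res, 1), "gA")            # primary key wins
  expect_equal(top_de_genes(res, 3), c("gA", "gC", "gB"))  # |2| before |1|
  expect_equal(top_de_genes(res, 100), c("gA", "gC", "gB"))  # untested excluded
})

test_that("Jaccard index follows set arithmetic", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  a <- paste0("g", 1:100); b <- c(paste0("g", 1:50), paste0("h", 1:50))
  expect_equal(jaccard_index(a, b), 50 / 150)
  expect_warning(j <- jaccard_index(character(0), character(0)), "empty")
  expect_equal(j, 1)
})
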