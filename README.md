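# ccalign

Single-cell data alignment with non-linear probabilistic canonical
correlation analysis.

`ccalign` integrates multiple single-cell datasets — scRNA-seq count
matrices and/or scATAC-seq gene-activity matrices — into a shared
low-dimensional latent space, removes batch effects, reconstructs batch-free
expression values for downstream differential expression, and transfers
cell-type labels across modalities. It is aimed at analysts who need to
align datasets from different samples, platforms or assays and then quantify
how well the alignment worked.

## The model

Each cell's normalized expression vector $X_i^{(m)}$ (dataset $m$, $p$
genes) is modeled as a non-linear function of a shared latent factor and a
dataset-specific code:

$$X_i^{(m)} = f\big(Z_i^{(m)},\, b^{(m)} \mid \theta\big) + E_i^{(m)},
\qquad Z_i^{(m)} \sim \mathcal{N}(0, I_d), \qquad
E_{ij}^{(m)} \sim \mathcal{N}(0, \sigma^2).$$

$f$ is a decoder network shared by all datasets; $b^{(m)}$ is a fixed random
code (entries uniform on $0..10$) that lets the decoder express
dataset-specific distortions. With a linear $f$ and no code this is exactly
probabilistic CCA/PCA. An encoder network parameterizes a Gaussian
variational posterior $q(Z_i) = \mathcal{N}(\mu_i, \mathrm{diag}(\sigma_i^2))$,
trained by minimizing the reparameterized evidence-lower-bound loss
(reconstruction + KL to the standard-normal prior) with mini-batch Adam.
Because only the decoder sees $b^{(m)}$, the posterior means $\mu_i$ form a
batch-free embedding; decoding every cell with one common reference code
$b^{(1)}$ yields recovered, batch-corrected expression
$\hat{X}_i = f(\hat{Z}_i, b^{(1)} \mid \hat\theta)$.

The package also implements the surrounding pipeline: MTX / dense TSV / CSV /
10x-HDF5 readers, CPM-log normalization, consensus highly-variable-gene
selection across batches, scATAC peak-to-gene-activity conversion
(TSS − 2 kb to transcript end), Gaussian-kernel label transfer with an
"unknown" rule, and an integration-quality battery: kBET-style acceptance
rate, the mixing metric (k = 5, k.max = 300), Louvain clustering + adjusted
Rand index, and Wilcoxon rank-sum differential expression with Bonferroni
control. A multi-batch synthetic count generator with known ground truth
makes the whole pipeline testable offline.

## Worked example

Simulate two batches with strong gene-specific batch effects and three cell
types, align them, and check the result:

```r
library(ccalign)

sim <- simulate_multibatch(n_per_batch = 300, n_batches = 2, n_types = 3,
                           n_genes = 300, batch_sd = 0.5, seed = 1)
hvg <- select_hvg_consensus(sim$batches, n_per_batch = 150, n_final = 150)
fit <- ccalign(sim$batches, config = train_config(epochs = 150, seed = 1),
               hvg = hvg)
fit
#> Conditional VAE alignment of single-cell datasets
#> Call:  ccalign(datasets = sim$batches, config = train_config(epochs = 150,      seed = 1), hvg = hvg)
#>
#>   600 cells, 150 genes, 2 batch(es): batch1 (300), batch2 (300)
#>   latent dimension 16, code dimension 16
#>   trained 150 epoch(s), final loss 784.4458 (recon 762.5384, KL 21.9074), stop: max_epochs

clusters <- cluster_embedding(fit$embedding, seed = 1)
adjusted_rand_index(clusters, fit$data$type)
#> [1] 0.9803693
mixing_metric(fit$embedding, fit$data$batch, k = 5, k_max = 100)
#> [1] 90
kbet_acceptance(fit$embedding, fit$data$batch, fit$data$type, seed = 1)$mean
#> [1] 0.9640741
```

The clustering of the latent embedding recovers the three simulated cell
types almost perfectly (ARI 0.98), batches are thoroughly mixed (mixing 90
out of a maximum 95; kBET acceptance 0.96, against ~0.01 for the
unintegrated data), and differential expression on the recovered values
behaves as it should — no spurious between-batch genes, while real
between-type markers remain:

```r
ty <- fit$data$type; bt <- fit$data$batch
de_null <- wilcoxon_de(fit$recovered, which(ty == "type1" & bt == "batch1"),
                       which(ty == "type1" & bt == "batch2"))
sum(de_null$p_adj < 0.05, na.rm = TRUE)   # same type across batches
#> [1] 0
de_alt <- wilcoxon_de(fit$recovered, which(ty == "type1" & bt == "batch1"),
                      which(ty == "type2" & bt == "batch1"))
sum(de_alt$p_adj < 0.05, na.rm = TRUE)    # different types, same batch
#> [1] 74
```

`predict()` embeds or recovers new data, `simulate()` draws cells from the
fitted generative model, and `plot()` shows the loss history or the
embedding. `transfer_labels()` moves reference annotations onto query cells
(e.g. scATAC gene-activity profiles embedded alongside scRNA-seq).

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
ccalign simulate  --n-per-batch 600 --batches 2 --genes 500 --seed 7 --o sim/
ccalign integrate --inputs sim/batch1/matrix.mtx --inputs sim/batch2/matrix.mtx \
                  --batch-names batch1 --batch-names batch2 --epochs 100 \
                  --seed 7 --o run/
ccalign evaluate  --embedding run/embedding.tsv --types types.tsv --o eval/
ccalign activity  --peaks peaks.mtx --peak-bed peaks.bed --gtf genes.gtf \
                  --upstream 2000 --min-peak-total 5000 --o act/
ccalign transfer  --ref-embedding ref.tsv --ref-labels labels.tsv \
                  --query-embedding query.tsv --o assign/
```

Every run writes a `manifest.json` (resolved options, seed, input checksums,
outputs) and outputs are staged and renamed atomically.

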