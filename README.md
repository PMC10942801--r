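# bermad

Batch-effect removal for single-cell RNA-seq data with a multi-layer
adaptation, dual-channel autoencoder.

## What it does and for whom

When scRNA-seq batches from different platforms or experiments are analysed
jointly, systematic technical differences (batch effect) separate same-type
cells and corrupt downstream clustering. Existing correctors tend to fail in
one of two directions: *under-correction* (residual separation of same-type
cells) or *over-correction* (merging biologically distinct populations,
including cell types present in only one batch). This package is for
computational biologists who need a correction that addresses both at once
and returns a low-dimensional corrected embedding with full determinism and
ground-truth-backed evaluation tools.

## The model

One deep autoencoder per batch ("channel"), architecture
`D → 200 → 20 → 200 → D` with intermediate outputs `h1` (200-d), code `z`
(20-d) and `h2` (200-d). Channels share the architecture, never the
weights. The training loss is

    L = L_rec + λ(p) · L_tran,          λ(p) = 2 / (1 + exp(−10 p/n)) − 1
    L_tran = α·L_h1 + β·L_h2 + γ·L_z

where each per-layer term sums the multi-scale Gaussian-kernel squared MMD
over *similar* cross-batch cluster pairs. Similarity is a MetaNeighbor-style
neighbour-voting AUROC between per-batch Louvain clusters, binarized at a
threshold (`thr = 0.85` by default, inclusive). Batch-exclusive cell types
match nothing, so nothing ever pulls them into foreign clusters. The
corrected embedding is the row-concatenation of the per-batch codes.

Evaluation metrics: a symmetric kNN Kullback–Leibler **divergence** between
batches (lower = better mixing), the mean **silhouette** on true cell-type
labels (higher = better separation of distinct types), and the **ARI**
between a Louvain clustering of the corrected embedding and ground truth.

## Worked example

```r
library(bermad)

# a two-batch world with 3 shared cell types and a clear batch effect
sim <- simulate_batches(simulation_params(
  n_genes = 300, batch_sizes = c(150L, 120L), n_groups = 3,
  de_prob = 0.2, de_factor = 8, batch_factor_scale = 0.4,
  library_size_mean = 2000, seed = 1))

cfg <- bermad_config(epochs = 60, learning_rate = 2e-3, num_hvg = 150,
                     seed = 1, knn_k = 10)
fit <- bermad_run(sim$batches, cfg, verbose = TRUE)

labs <- setNames(unlist(lapply(sim$batches, function(b) b$labels)),
                 unlist(lapply(sim$batches, function(b) b$cell_ids)))
evaluate_embedding(fit$embedding, labs, cfg)
```

prints (this exact run):

```
MetricsReport (3 clustering runs)
  Divergence: 0.30±0.00
  Silhouette: 0.23±0.00
  ARI:        0.99±0.01
```

meaning: after correction the two batches' shared-type cells are nearly
indistinguishable in distribution (divergence 0.30, versus 2.03 on the
uncorrected PCA embedding of the same data), the three true types remain
separated (positive silhouette), and clustering the corrected embedding
recovers the true types almost perfectly (ARI 0.99). `fit$similarity` shows which
cluster pairs were matched; `fit$history` holds the per-epoch loss
breakdown; `write_embedding(fit$embedding, "z.csv")` exports the embedding.

## Command line

```sh
exec/bermad simulate --scenario two_batch_same --out data/
exec/bermad run --batches data/two_batch_same_batch1.csv,data/two_batch_same_batch2.csv \
                --thr 0.85 --epochs 400 --seed 1 --out out/
exec/bermad evaluate --embedding out/embedding.csv --labels data/two_batch_same_batch1_labels.csv
```

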