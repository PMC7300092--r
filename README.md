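# scDiffVAE

Unsupervised modelling of cell differentiation from single-cell RNA-seq
expression matrices with MMD-regularized variational autoencoders.

## The problem

Single-cell RNA-seq measures the expression of thousands of genes in
thousands of individual cells. Two recurring questions are:

1. **Which cell types are present, and which genes define them?**
   Clustering cells needs a low-dimensional representation that keeps
   the biological structure, and the representation is only useful if
   it can be traced back to marker genes.
2. **What drives differentiation, and can we steer it?** If a latent
   representation disentangles the axes along which cell types differ,
   moving a progenitor cell along those axes *in silico* predicts which
   gene changes would convert it into a mature type.

`scDiffVAE` addresses both with **DiffVAE**, a variational autoencoder
that replaces the usual per-sample KL penalty with a **maximum mean
discrepancy (MMD)** term matching the aggregate latent distribution to
a standard-normal prior. The MMD objective regularizes less aggressively
per cell, which in practice yields latent dimensions that specialize to
cell types — the property the rest of the pipeline exploits. The package
also implements **Graph-DiffVAE**, a graph convolutional VAE that takes
an initial cell-cell graph plus expression and predicts novel links
between cells (e.g. shared-state relationships).

## The model in brief

- **Encoder** `x -> (mu, log_var)`: two ReLU hidden layers (512, 256)
  with batch normalization; latent size 50 by default; sampling via the
  reparameterization `z = mu + eps * exp(log_var / 2)`.
- **Decoder** `z -> x'`: mirror architecture with a logistic output, so
  reconstructions live in `(0, 1)` and the reconstruction term is a
  Bernoulli cross-entropy over min-max scaled expression.
- **Loss**: batch-averaged cross-entropy plus `mmd_weight *`
  squared MMD between the latent batch and a fresh prior batch, under a
  multi-bandwidth RBF kernel. Optimized with Adam; all gradients are
  analytic and finite-difference tested.
- **Downstream**: t-SNE + k-means/DBSCAN clustering; latent dimension
  relevance via *extreme-cell sets* (cells at least one standard
  deviation from a dimension's mean); marker genes via the composed
  decoder weight matrix `omega = W0 W1 W2`; cell-state conversion by
  shifting relevant latent dimensions `lambda` standard deviations and
  re-classifying the decoded profiles; minimal flipping gene sets.
- **Baselines**: a standard VAE, a plain autoencoder and PCA, compared
  by the adjusted Rand index of repeated clusterings.

See `vignette("diffvae-methods")` for exact formulas and conventions.

## Worked example

Everything below is runnable offline: the package ships a synthetic
generator that plants marker-gene blocks for a known number of
clusters, so recovery can be verified against ground truth.

```r
library(scDiffVAE)

# 300 cells, 120 genes, 4 clusters, 8 planted markers each
spec <- synthetic_spec(n_cells = 300, n_genes = 120, n_clusters = 4,
                       markers_per_cluster = 8, seed = 7)
ds   <- generate_expression(spec)
expr <- minmax_scale(ds$expression, verbose = FALSE)

model <- train_diffvae(expr, diffvae_config(m = 10, epochs = 30, seed = 1))
round(c(first = model$loss_history[1], final = tail(model$loss_history, 1)), 2)
#> first final
#> 83.33 76.01
```

(The loss cannot approach zero: cross-entropy against continuous
targets has an irreducible entropy floor; see the vignette.)

Cluster the latent space and compare with the ground truth:

```r
lat <- get_latent(model, expr)
emb <- tsne_embed(lat, perplexity = 30, seed = 1)
cl  <- cluster_cells(emb, "kmeans", k = 4, seed = 1)
adjusted_rand_index(ds$labels, cl$labels)
#> [1] 1
```

Find which latent dimensions encode cluster 1 and extract its marker
genes from the composed decoder weights (a gene is called when it is a
top-weight gene of at least two of the cluster's relevant dimensions):

```r
rel   <- dimension_relevance(lat, cl$labels, top_n = 3)
rel$top_dims$cluster_1
#> [1] 3 8 7

omega  <- gene_weights(model)
hw     <- high_weight_genes(omega, rel$top_dims$cluster_1, top_g = 8)
called <- names(hw$counts)[hw$counts >= 2]
sort(called)
#> [1] "gene_0001" "gene_0002" "gene_0003" "gene_0004" "gene_0005"
#> [6] "gene_0006" "gene_0007" "gene_0008"

ds$marker_map$cluster_1   # the genes actually planted for this cluster
#> [1] "gene_0001" "gene_0002" "gene_0003" "gene_0004" "gene_0005"
#> [6] "gene_0006" "gene_0007" "gene_0008"
```

All eight planted markers are recovered with no false positives
(precision and recall 1.0 on this seed; precision is typically
0.5–1.0 per cluster across seeds).

### Link prediction with Graph-DiffVAE

```r
ds    <- generate_expression(synthetic_spec(n_cells = 100, n_genes = 60,
                                            n_clusters = 4,
                                            markers_per_cluster = 10,
                                            seed = 19))
graph <- generate_labeled_graph(ds, k = 3, seed = 19)   # within-cluster edges
expr  <- minmax_scale(ds$expression, verbose = FALSE)
fit   <- train_graph_diffvae(expr, graph,
                             graphvae_config(hidden_features = 64,
                                             latent_features = 16,
                                             epochs = 150, seed = 19))
top <- predict_links(fit$predicted, top_q = 50, input_graph = graph)$novel
mean(ds$labels[top$from] == ds$labels[top$to])
#> [1] 1
head(top, 3)
#>   from to     score
#> 1   40 92 0.8281818
#> 2   48 92 0.8113855
#> 3   40 84 0.8058377
```

All 50 top-scoring novel links connect cells of the same (held-out)
cluster: the model generalizes the training edges to unseen
within-cluster pairs.

### Command line

The same workflows are scriptable via `exec/scdiffvae`:

```sh
scdiffvae simulate --preset small --seed 3 --out runs/sim
scdiffvae train    --input runs/sim/expression.csv --m 20 --epochs 40 --out runs/model
scdiffvae cluster  --input runs/sim/expression.csv --model runs/model/model.rds \
                   --method kmeans --k 4 --out runs/clusters
scdiffvae markers  --input runs/sim/expression.csv --model runs/model/model.rds \
                   --clusters runs/clusters/clusters.csv --out runs/markers
```

Every subcommand writes a `manifest.json` (resolved options, seed,
package version, input checksums) next to its outputs.

## Scope and limitations

- Training is plain R on dense matrices: designed for datasets in the
  hundreds-to-thousands of cells, not atlas scale.
- The synthetic generator does not model library size, dropout or
  count overdispersion; results on it validate the machinery, not
  biology.
- Checkpoints are `.rds` files (`save_model()` / `load_model()`).
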