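# Cell-type identification pipeline: embed the latent representation with
# t-SNE, cluster, score which latent dimensions encode each cluster's
# differentiation via the extreme-cell rule, and pull marker genes out of
# the composed decoder weight matrix.

#' t-SNE embedding of a latent representation
#'
#' Established t-SNE (via Rtsne), seeded for reproducibility.
#'
#' @param latent A [latent_matrix()] or numeric matrix.
#' @param perplexity t-SNE perplexity (requires `N > 3 * perplexity`).
#' @param seed Integer seed.
#' @return `N x 2` embedding matrix.
#' @export
tsne_embed <- function(latent, perplexity = 30, seed = 1) {
  Z <- if (inherits(latent, "latent_matrix")) latent$z_means else as.matrix(latent)
  .assert(nrow(Z) > 3 * perplexity,
          sprintf("perplexity %g too large for %d cells", perplexity, nrow(Z)))
  emb <- .with_seed(seed, {
    Rtsne::Rtsne(Z, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE)$Y
  })
  rownames(emb) <- rownames(Z)
  emb
}

#' Cluster cells in an embedding
#'
#' K-means (seeded, `nstart = 10`) or DBSCAN on the rows of `embedding`.
#' DBSCAN labels unassigned cells `-1` (noise).
#'
#' @param embedding Numeric matrix (cells in rows): a latent matrix or a 2-D
#'   t-SNE embedding.
#' @param method `"kmeans"` or `"dbscan"`.
#' @param k Number of clusters (k-means).
#' @param eps Neighbourhood radius (DBSCAN).
#' @param min_pts Core-point threshold (DBSCAN).
#' @param seed Seed for k-means initialization.
#' @return An object of class `cluster_assignment`: list with integer
#'   `labels` (noise = -1), `method` and `params`.
#' @export
cluster_cells <- function(embedding, method = c("kmeans", "dbscan"), k = NULL,
                          eps = NULL, min_pts = 5, seed = 1) {
  method <- match.arg(method)
  X <- if (inherits(embedding, "latent_matrix")) embedding$z_means else as.matrix(embedding)
  if (method == "kmeans") {
    .assert(!is.null(k), "kmeans needs k")
    labels <- .with_seed(seed, stats::kmeans(X, centers = k, nstart = 10)$cluster)
    params <- list(k = k, seed = seed)
  } else {
    .assert(!is.null(eps), "dbscan needs eps")
    labels <- .dbscan(X, eps = eps, min_pts = min_pts)
    params <- list(eps = eps, min_pts = min_pts)
    if (all(labels == -1L)) {
      warning("DBSCAN labelled every cell as noise; consider a larger eps")
    }
  }
  structure(list(labels = as.integer(labels), method = method, params = params),
            class = "cluster_assignment")
}

# Plain DBSCAN on a dense distance matrix; adequate for the few thousand
# cells this package targets. Border points join the first core cluster
# that reaches them; unreached points get label -1.
.dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  is_core <- vapply(neighbours, length, integer(1)) >= min_pts
  labels <- rep(0L, n) # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue) > 0L) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cl # noise becomes border point
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (is_core[j]) queue <- union(queue, setdiff(neighbours[[j]], j))
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Cells at least one standard deviation from a latent dimension's mean
#'
#' The extreme-cell set of dimension `k`:
#' `D_k = { i : z_k(i) >= mu_k + sigma_k  or  z_k(i) <= mu_k - sigma_k }`
#' (boundaries inclusive). Mean and standard deviation use the population
#' convention (divide by `N`) over all cells. A constant dimension
#' (`sigma_k = 0`) would select every cell under the literal rule; it is
#' instead flagged degenerate and returns the empty set.
#'
#' @param z_k Latent coordinates of all cells in one dimension.
#' @param mu_k,sigma_k Optional precomputed statistics; defaults are the
#'   population mean and sd of `z_k`.
#' @return Integer vector of cell indices, with attribute `"degenerate"`.
#' @export
extreme_cells <- function(z_k, mu_k = NULL, sigma_k = NULL) {
  z_k <- as.numeric(z_k)
  if (is.null(mu_k)) mu_k <- mean(z_k)
  if (is.null(sigma_k)) sigma_k <- sqrt(mean((z_k - mu_k)^2))
  if (sigma_k == 0) {
    return(structure(integer(0), degenerate = TRUE))
  }
  idx <- which(z_k >= mu_k + sigma_k | z_k <= mu_k - sigma_k)
  structure(idx, degenerate = FALSE)
}

#' Rank latent dimensions by their relevance to each cluster
#'
#' For every latent dimension `k`, the extreme-cell set `D_k` is computed
#' and its membership distributed across clusters as percentages (summing to
#' 100 for non-empty `D_k`). For each cluster the dimensions are ranked by
#' the percentage of `D_k` cells belonging to it; the `top_n` dimensions are
#' the ones taken to encode that cluster's differentiation. Ties break by
#' ascending dimension index; noise cells (label -1) are excluded from the
#' cluster percentages but still count toward `|D_k|`.
#'
#' @param latent A [latent_matrix()].
#' @param clusters A `cluster_assignment` or an integer label vector.
#' @param top_n Number of dimensions kept per cluster.
#' @return An object of class `dimension_relevance`: list with `percentages`
#'   (clusters x dimensions matrix), `top_dims` (named list of ordered
#'   dimension indices per cluster), `extreme_sets` and `degenerate_dims`.
#' @export
dimension_relevance <- function(latent, clusters, top_n = 10) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels else as.integer(clusters)
  Z <- latent$z_means
  .assert(length(labels) == nrow(Z), "labels length must match latent rows")
  cl_ids <- sort(unique(labels[labels != -1L]))
  .assert(length(cl_ids) >= 1, "need at least one non-noise cluster")
  m <- ncol(Z)
  pct <- matrix(0, length(cl_ids), m,
                dimnames = list(paste0("cluster_", cl_ids), paste0("dim_", seq_len(m))))
  sets <- vector("list", m)
  degenerate <- logical(m)
  for (k in seq_len(m)) {
    dk <- extreme_cells(Z[, k], latent$dim_means[k], latent$dim_sds[k])
    degenerate[k] <- isTRUE(attr(dk, "degenerate"))
    sets[[k]] <- as.integer(dk)
    if (length(dk) > 0L) {
      tab <- table(factor(labels[dk], levels = cl_ids))
      pct[, k] <- 100 * as.numeric(tab) / length(dk)
    }
  }
  top_dims <- lapply(seq_along(cl_ids), function(ci) {
    ord <- order(-pct[ci, ], seq_len(m))
    ord[seq_len(min(top_n, m))]
  })
  names(top_dims) <- rownames(pct)
  structure(list(percentages = pct, top_dims = top_dims, extreme_sets = sets,
                 degenerate_dims = which(degenerate), clusters = cl_ids),
            class = "dimension_relevance")
}

#' Composed decoder gene-weight matrix
#'
#' Multiplies the decoder's weight matrices,
#' `omega = W0 %*% W1 %*% W2` (latent -> hidden1 -> hidden2 -> genes),
#' deliberately ignoring biases and ReLU nonlinearities: `omega[i, j]` is
#' the weight of latent dimension `i` on gene `j` under this linearization
#' of the decoder.
#'
#' @param decoder A trained autoencoder model, or a list with elements
#'   `W0` (m x h1), `W1` (h1 x h2), `W2` (h2 x k).
#' @return An object of class `gene_weight_matrix`: list with `omega`
#'   (m x k) and `gene_names`.
#' @export
gene_weights <- function(decoder) {
  if (inherits(decoder, "sc_autoencoder")) {
    W0 <- decoder$params$dec_W1
    W1 <- decoder$params$dec_W2
    W2 <- decoder$params$W_out
    gene_names <- decoder$gene_names
  } else {
    W0 <- decoder$W0; W1 <- decoder$W1; W2 <- decoder$W2
    gene_names <- decoder$gene_names
  }
  .assert(ncol(W0) == nrow(W1) && ncol(W1) == nrow(W2),
          "decoder weight shapes are not conformable")
  omega <- W0 %*% W1 %*% W2
  if (is.null(gene_names)) gene_names <- sprintf("gene_%d", seq_len(ncol(omega)))
  colnames(omega) <- gene_names
  structure(list(omega = omega, gene_names = gene_names),
            class = "gene_weight_matrix")
}

#' High-weight genes of selected latent dimensions
#'
#' For each requested dimension, genes are sorted by the absolute value of
#' their composed decoder weight (descending; ties broken by ascending gene
#' index) and the top `top_g` are reported, together with the genes common
#' to all selected dimensions and per-gene occurrence counts across them.
#'
#' @param omega A [gene_weights()] result or a numeric `m x k` matrix.
#' @param dims Latent dimension indices to inspect.
#' @param top_g Number of genes per dimension (clipped to the gene count,
#'   with a warning).
#' @return List with `per_dim` (named list of character vectors), `common`
#'   (genes present in every per-dimension list) and `counts` (named table
#'   of occurrences across dimensions).
#' @export
high_weight_genes <- function(omega, dims, top_g = 3) {
  W <- if (inherits(omega, "gene_weight_matrix")) omega$omega else as.matrix(omega)
  genes <- colnames(W)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(ncol(W)))
  .assert(all(dims >= 1 & dims <= nrow(W)), "dims out of range")
  if (top_g > ncol(W)) {
    warning(sprintf("top_g = %d exceeds gene count %d; clipped", top_g, ncol(W)))
    top_g <- ncol(W)
  }
  per_dim <- lapply(dims, function(d) {
    ord <- order(-abs(W[d, ]), seq_len(ncol(W)))
    genes[ord[seq_len(top_g)]]
  })
  names(per_dim) <- paste0("dim_", dims)
  common <- Reduce(intersect, per_dim)
  counts <- sort(table(unlist(per_dim)), decreasing = TRUE)
  list(per_dim = per_dim, common = common, counts = counts)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to label permutation), about 0 for independent ones. By default the
#' DBSCAN noise label (-1) is treated as one extra cluster; with
#' `drop_noise = TRUE` cells labelled -1 in either labeling are discarded
#' first.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @param drop_noise Drop cells labelled -1 before computing the index.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b, drop_noise = FALSE) {
  .assert(length(labels_a) == length(labels_b),
          "labelings must have equal length")
  if (drop_noise) {
    keep <- labels_a != -1L & labels_b != -1L
    labels_a <- labels_a[keep]
    labels_b <- labels_b[keep]
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Benchmark embeddings by clustering performance
#'
#' For every combination of model, latent size, clustering algorithm and
#' embedding space (the latent representation itself, or its 2-D t-SNE
#' embedding recomputed per repeat), clusters the cells `repeats` times with
#' fresh seeds and reports the ARI against the true labels.
#'
#' @param expr Unit-scaled [expression_matrix()] with labels attached (or
#'   pass `labels`).
#' @param models Character subset of `c("diffvae", "vae", "ae", "pca")`.
#' @param m_values Latent sizes to evaluate.
#' @param clusterers Subset of `c("kmeans", "dbscan")`.
#' @param embeddings Subset of `c("latent", "tsne")`.
#' @param repeats Repetitions per setting.
#' @param labels True labels (default: `expr$labels`).
#' @param config Base [diffvae_config()] for the trained models.
#' @param dbscan_eps,dbscan_min_pts DBSCAN parameters.
#' @param perplexity t-SNE perplexity.
#' @param seed Base seed; repeat `r` of each setting uses `seed + r`.
#' @return List with `runs` (long data.frame: model, m, clusterer, embedding,
#'   repeat, ari) and `table` (mean ARI per setting).
#' @export
benchmark_embeddings <- function(expr, models = c("diffvae", "vae", "ae", "pca"),
                                 m_values = c(20, 50, 100),
                                 clusterers = c("kmeans", "dbscan"),
                                 embeddings = c("latent", "tsne"),
                                 repeats = 50, labels = NULL,
                                 config = diffvae_config(),
                                 dbscan_eps = 3, dbscan_min_pts = 5,
                                 perplexity = 30, seed = 1) {
  if (is.null(labels)) labels <- expr$labels
  .assert(!is.null(labels), "benchmark needs true labels")
  k_true <- length(unique(labels[labels != -1]))
  runs <- list()
  for (model in models) {
    for (m in m_values) {
      lat <- embed_cells(expr, model, m = m, config = config, seed = seed)
      for (embedding in embeddings) {
        for (clusterer in clusterers) {
          for (r in seq_len(repeats)) {
            rs <- seed + r
            space <- if (embedding == "tsne") {
              tsne_embed(lat, perplexity = perplexity, seed = rs)
            } else {
              lat$z_means
            }
            ca <- cluster_cells(space, method = clusterer, k = k_true,
                                eps = dbscan_eps, min_pts = dbscan_min_pts,
                                seed = rs)
            runs[[length(runs) + 1L]] <- data.frame(
              model = model, m = m, clusterer = clusterer,
              embedding = embedding, rep = r,
              ari = adjusted_rand_index(labels, ca$labels))
          }
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  tab <- stats::aggregate(ari ~ model + m + clusterer + embedding, runs, mean)
  list(runs = runs, table = tab)
}
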