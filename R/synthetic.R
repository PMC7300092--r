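# Synthetic single-cell expression data with planted cluster markers.
#
# The generator emulates the statistical structure the downstream methods
# assume: nonnegative log-scale expression, a handful of well-separated cell
# clusters each carrying a block of marker genes, and (optionally) one
# "progenitor" population whose centroid is the average of the mature
# centroids, i.e. a population lying between the differentiated cell types.

#' Specification for a synthetic expression dataset
#'
#' Defaults describe a small but realistic benchmark: 500 cells, 200 genes,
#' 4 clusters each with 10 marker genes shifted upwards by 3 log-units over a
#' baseline of 1, Gaussian noise with sd 0.5 truncated at zero.
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of genes.
#' @param n_clusters Number of clusters (including the progenitor cluster
#'   when `progenitor_fraction > 0`).
#' @param markers_per_cluster Marker genes planted per mature cluster.
#' @param marker_effect Log-scale mean shift of marker genes inside their
#'   cluster (positive).
#' @param base_scale Baseline log-scale mean for all genes (nonnegative).
#' @param noise_sd Standard deviation of the Gaussian noise (positive);
#'   values are truncated at zero to keep the log-scale matrix nonnegative.
#' @param progenitor_fraction Fraction of cells assigned to a progenitor
#'   population positioned between the mature clusters; 0 disables it.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec including this seed.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 500, n_genes = 200, n_clusters = 4,
                           markers_per_cluster = 10, marker_effect = 3,
                           base_scale = 1, noise_sd = 0.5,
                           progenitor_fraction = 0, seed = 1) {
  spec <- structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters),
         markers_per_cluster = as.integer(markers_per_cluster),
         marker_effect = marker_effect, base_scale = base_scale,
         noise_sd = noise_sd, progenitor_fraction = progenitor_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  .validate_synthetic_spec(spec)
  spec
}

.validate_synthetic_spec <- function(spec) {
  with(spec, {
    .assert(n_cells >= 1 && n_genes >= 1 && n_clusters >= 1 &&
              markers_per_cluster >= 1, "all counts must be positive")
    .assert(n_clusters * markers_per_cluster <= n_genes,
            "n_clusters * markers_per_cluster must not exceed n_genes")
    .assert(n_cells >= n_clusters, "need at least one cell per cluster")
    .assert(marker_effect > 0, "marker_effect must be positive")
    .assert(base_scale >= 0, "base_scale must be nonnegative")
    .assert(noise_sd > 0, "noise_sd must be positive")
    .assert(progenitor_fraction >= 0 && progenitor_fraction < 1,
            "progenitor_fraction must lie in [0, 1)")
    if (progenitor_fraction > 0) {
      .assert(n_clusters >= 3,
              "a progenitor population needs at least 2 mature clusters")
    }
  })
  invisible(spec)
}

#' Generate a synthetic expression dataset with planted markers
#'
#' Each mature cluster `c` receives `markers_per_cluster` dedicated genes
#' whose within-cluster mean is `base_scale + marker_effect` while all other
#' cells express them at `base_scale`; non-marker genes share the baseline
#' mean in every cluster. Noise is Gaussian with sd `noise_sd`, truncated at
#' zero. When `progenitor_fraction > 0` the last cluster is a progenitor
#' population whose centroid is the average of the mature centroids. Cluster
#' labels are assigned deterministically by cell index.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_dataset` with fields `expression`
#'   (an [expression_matrix()] with labels attached), `labels` (integer
#'   cluster per cell), `marker_map` (named list: cluster -> marker gene
#'   names), `progenitor_cluster` (integer or `NA`), and `centroids`.
#' @export
generate_expression <- function(spec) {
  .validate_synthetic_spec(spec)
  n_mature <- if (spec$progenitor_fraction > 0) spec$n_clusters - 1L else spec$n_clusters

  gene_names <- sprintf("gene_%04d", seq_len(spec$n_genes))
  cell_ids <- sprintf("cell_%04d", seq_len(spec$n_cells))

  # deterministic label layout: progenitor cells (if any) first block sizes
  n_prog <- if (spec$progenitor_fraction > 0)
    as.integer(round(spec$progenitor_fraction * spec$n_cells)) else 0L
  n_rest <- spec$n_cells - n_prog
  mature_labels <- rep(seq_len(n_mature), length.out = n_rest)
  labels <- c(mature_labels,
              rep(spec$n_clusters, n_prog))

  # marker blocks: cluster c owns genes ((c-1)*mpc + 1) .. c*mpc
  mpc <- spec$markers_per_cluster
  marker_map <- stats::setNames(
    lapply(seq_len(n_mature), function(c) gene_names[((c - 1L) * mpc + 1L):(c * mpc)]),
    paste0("cluster_", seq_len(n_mature))
  )

  centroids <- matrix(spec$base_scale, nrow = spec$n_clusters, ncol = spec$n_genes)
  for (c in seq_len(n_mature)) {
    idx <- ((c - 1L) * mpc + 1L):(c * mpc)
    centroids[c, idx] <- spec$base_scale + spec$marker_effect
  }
  if (n_prog > 0L) {
    centroids[spec$n_clusters, ] <- colMeans(centroids[seq_len(n_mature), , drop = FALSE])
  }

  values <- .with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(spec$n_cells * spec$n_genes, sd = spec$noise_sd),
                    nrow = spec$n_cells)
    pmax(centroids[labels, , drop = FALSE] + noise, 0)
  })

  expr <- expression_matrix(values, gene_names = gene_names, cell_ids = cell_ids,
                            labels = labels, scale_state = "log_normalized")
  structure(
    list(expression = expr, labels = labels, marker_map = marker_map,
         progenitor_cluster = if (n_prog > 0L) spec$n_clusters else NA_integer_,
         centroids = centroids, spec = spec),
    class = "synthetic_dataset"
  )
}

#' Ground-truth cell graph over a synthetic dataset
#'
#' Links each cell to `k` randomly chosen cells of the same cluster, then
#' symmetrizes. Edges never cross cluster boundaries, which makes the graph
#' a clean target for link-prediction tests. A cell in a singleton cluster
#' gets no edges (with a warning).
#'
#' @param dataset A `synthetic_dataset`.
#' @param k Number of within-cluster neighbours drawn per cell.
#' @param seed Integer seed for the neighbour draws.
#' @return A [cell_graph()] without self-loops.
#' @export
generate_labeled_graph <- function(dataset, k = 3, seed = 1) {
  .assert(inherits(dataset, "synthetic_dataset"), "dataset must be a synthetic_dataset")
  labels <- dataset$labels
  .assert(length(unique(labels)) >= 2, "need at least 2 clusters")
  n <- length(labels)
  A <- matrix(0, n, n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      peers <- setdiff(which(labels == labels[i]), i)
      if (length(peers) == 0L) {
        warning(sprintf("cell %d is in a singleton cluster; no edges added", i))
        next
      }
      kk <- min(k, length(peers))
      nb <- if (length(peers) == 1L) peers else sample(peers, kk)
      A[i, nb] <- 1
      A[nb, i] <- 1
    }
  })
  cell_graph(A, cell_ids = dataset$expression$cell_ids)
}
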