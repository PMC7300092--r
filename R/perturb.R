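# In-silico cell-state conversion: a softmax classifier over mature cell
# types, latent shifts of lambda * sigma along cluster-relevant dimensions,
# and gene-level analysis of the converted reconstructions.

#' Classifier configuration
#'
#' Defaults: three hidden layers of 256, 512 and
#' 256 ReLU neurons, softmax output, Adam with learning rate 0.001, batch
#' size 128, 300 epochs.
#'
#' @param hidden Hidden layer sizes.
#' @param learning_rate,batch_size,epochs Adam training parameters.
#' @param seed Integer seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(hidden = c(256, 512, 256), learning_rate = 0.001,
                              batch_size = 128, epochs = 300, seed = 1) {
  .assert(all(hidden >= 1) && batch_size >= 1 && epochs >= 0,
          "invalid classifier configuration")
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

.mlp_fwd <- function(params, X) {
  L <- length(params$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    A <- .add_bias(acts[[l]] %*% params$W[[l]], params$b[[l]])
    acts[[l + 1L]] <- if (l < L) .relu(A) else A # last layer: logits
  }
  logits <- acts[[L + 1L]]
  # row-wise softmax, stabilised
  e <- exp(logits - apply(logits, 1L, max))
  list(probs = e / rowSums(e), acts = acts)
}

.mlp_bwd <- function(params, acts, dlogits) {
  L <- length(params$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- dlogits
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], d)
    gb[[l]] <- colSums(d)
    if (l > 1L) {
      d <- (d %*% t(params$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train a softmax cell-type classifier on full gene expression
#'
#' @param expr Unit-scaled [expression_matrix()] of the training cells
#'   (typically the mature cell types only).
#' @param labels Class label per cell (at least two distinct classes).
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `cell_classifier` with `params`, `classes`,
#'   `config` and `train_accuracy`.
#' @export
train_classifier <- function(expr, labels, config = classifier_config(),
                             verbose = FALSE) {
  X <- .unit_values(expr)
  .assert(length(labels) == nrow(X), "labels length must match cell count")
  classes <- sort(unique(as.character(labels)))
  .assert(length(classes) >= 2, "classifier needs at least 2 classes")
  y <- match(as.character(labels), classes)
  Y <- diag(length(classes))[y, , drop = FALSE]
  sizes <- c(ncol(X), config$hidden, length(classes))

  fit <- .with_seed(config$seed, {
    params <- list(
      W = lapply(seq_len(length(sizes) - 1L),
                 function(l) .glorot(sizes[l], sizes[l + 1L])),
      b = lapply(seq_len(length(sizes) - 1L), function(l) rep(0, sizes[l + 1L]))
    )
    flat <- c(stats::setNames(params$W, paste0("W", seq_along(params$W))),
              stats::setNames(params$b, paste0("b", seq_along(params$b))))
    opt <- .adam_init(flat)
    N <- nrow(X)
    history <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(N)
      epoch_loss <- 0
      for (s in seq(1L, N, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1L, N)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fwd <- .mlp_fwd(params, Xb)
        loss <- -sum(Yb * log(pmax(fwd$probs, 1e-12))) / length(idx)
        if (!is.finite(loss)) stop("non-finite classifier loss", call. = FALSE)
        g <- .mlp_bwd(params, fwd$acts, (fwd$probs - Yb) / length(idx))
        gflat <- c(stats::setNames(g$W, paste0("W", seq_along(g$W))),
                   stats::setNames(g$b, paste0("b", seq_along(g$b))))
        step <- .adam_update(flat, gflat, opt, config$learning_rate)
        flat <- step$params
        opt <- step$state
        nl <- length(params$W)
        params$W <- unname(flat[paste0("W", seq_len(nl))])
        params$b <- unname(flat[paste0("b", seq_len(nl))])
        epoch_loss <- epoch_loss + loss * length(idx)
      }
      history <- c(history, epoch_loss / N)
      .msg(sprintf("classifier epoch %3d loss %.5f", epoch, history[epoch]),
           verbose = verbose)
    }
    list(params = params, history = history)
  })

  model <- structure(
    list(params = fit$params, classes = classes, config = config,
         loss_history = fit$history),
    class = "cell_classifier"
  )
  pred <- classify_cells(model, X)
  model$train_accuracy <- mean(pred == as.character(labels))
  model
}

#' Class probabilities from a trained classifier
#'
#' @param classifier A `cell_classifier`.
#' @param x Unit-scaled expression: matrix, vector, or [expression_matrix()].
#' @return `N x n_classes` matrix of probabilities (rows sum to 1).
#' @export
predict_classifier <- function(classifier, x) {
  X <- if (inherits(x, "expression_matrix")) .unit_values(x) else .as_row_matrix(x)
  p <- .mlp_fwd(classifier$params, X)$probs
  colnames(p) <- classifier$classes
  p
}

#' Hard class assignments (argmax of the class probabilities)
#' @inheritParams predict_classifier
#' @return Character vector of predicted classes.
#' @export
classify_cells <- function(classifier, x) {
  p <- predict_classifier(classifier, x)
  classifier$classes[max.col(p, ties.method = "first")]
}

#' Shift selected latent dimensions by lambda times their standard deviation
#'
#' `z'[, j] = z[, j] + direction[j] * lambda * sigma[j]` for the selected
#' dimensions `j`; all other coordinates are unchanged. The identity at
#' `lambda = 0`, linear in `lambda`.
#'
#' @param z Latent codes (vector or matrix).
#' @param dims Dimension indices to shift.
#' @param lambda Nonnegative shift factor.
#' @param sigma_dims Standard deviation of each shifted dimension (dataset
#'   level, from a [latent_matrix()]).
#' @param directions Sign per shifted dimension (default `+1`).
#' @return Shifted latent codes, same shape as `z`.
#' @export
perturb_latent <- function(z, dims, lambda, sigma_dims, directions = NULL) {
  .assert(lambda >= 0, "lambda must be nonnegative")
  .assert(length(dims) >= 1, "dims must be non-empty")
  .assert(length(sigma_dims) == length(dims),
          "sigma_dims must align with dims")
  if (is.null(directions)) directions <- rep(1, length(dims))
  Z <- .as_row_matrix(z)
  shift <- directions * lambda * sigma_dims
  Z[, dims] <- sweep(Z[, dims, drop = FALSE], 2L, shift, "+")
  if (is.null(dim(z))) drop(Z) else Z
}

# Direction rule: shift each selected dimension toward the side where the
# target cluster's cells sit relative to the dataset mean.
.target_directions <- function(latent, cluster_labels, target, dims) {
  Z <- latent$z_means
  in_target <- cluster_labels == target
  .assert(any(in_target), "no cells carry the target label")
  d <- sign(colMeans(Z[in_target, dims, drop = FALSE]) - latent$dim_means[dims])
  d[d == 0] <- 1
  d
}

#' Convert source cells toward a target cell type via latent perturbation
#'
#' Encodes each source cell, shifts the latent dimensions that encode the
#' target cluster's differentiation by `lambda` times their dataset-level
#' standard deviation (toward the target cluster's side of the latent mean),
#' decodes, and classifies the reconstruction. A cell counts as converted
#' when the classifier assigns the target class.
#'
#' @param model A trained `diffvae_model`.
#' @param classifier A `cell_classifier` whose classes include `target`.
#' @param source_expr Unit-scaled [expression_matrix()] of the source cells
#'   (e.g. the progenitor population).
#' @param target Target class label.
#' @param dims Latent dimensions to shift (e.g. the top 5 from
#'   [dimension_relevance()] for the target cluster).
#' @param lambda Shift factor (may be a vector; one result per value).
#' @param latent [latent_matrix()] over the full dataset, providing the
#'   per-dimension statistics.
#' @param cluster_labels Cluster label per cell of `latent` (used for the
#'   shift direction rule).
#' @param directions Optional explicit shift signs, overriding the
#'   target-side rule.
#' @return For scalar `lambda`, an object of class `perturbation_result`:
#'   list with `converted` (logical), `predicted` (classes), `fraction`,
#'   `reconstruction` (y), `z_shifted`, `lambda`, `dims`, `directions`.
#'   For vector `lambda`, a list of such objects (named by lambda).
#' @export
convert_cells <- function(model, classifier, source_expr, target, dims,
                          lambda, latent, cluster_labels, directions = NULL) {
  .assert(target %in% classifier$classes,
          "target is not one of the classifier's classes")
  if (is.null(directions)) {
    directions <- .target_directions(latent, cluster_labels, target, dims)
  }
  Zsrc <- encode(model, source_expr)$mu
  sigma_dims <- latent$dim_sds[dims]
  one <- function(lam) {
    Zp <- perturb_latent(Zsrc, dims, lam, sigma_dims, directions)
    Y <- decode(model, Zp)
    pred <- classify_cells(classifier, Y)
    converted <- pred == as.character(target)
    structure(list(converted = converted, predicted = pred,
                   fraction = mean(converted), reconstruction = Y,
                   z_shifted = Zp, lambda = lam, dims = dims,
                   directions = directions,
                   cell_ids = source_expr$cell_ids),
              class = "perturbation_result")
  }
  if (length(lambda) == 1L) one(lambda) else {
    stats::setNames(lapply(lambda, one), paste0("lambda_", lambda))
  }
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> lambda=%g: %d/%d cells converted (%.1f%%)\n",
              x$lambda, sum(x$converted), length(x$converted), 100 * x$fraction))
  invisible(x)
}

#' Per-gene expression change between a cell and its converted reconstruction
#'
#' @param x Original expression vector.
#' @param y Reconstructed (converted) expression vector.
#' @return Data frame with columns `gene`, `delta` (`y - x`) and `direction`
#'   (`"up"`/`"down"`/`"unchanged"`), ordered by decreasing `|delta|` with
#'   ties broken by gene index.
#' @export
gene_delta <- function(x, y) {
  .assert(length(x) == length(y), "x and y must share the gene space")
  delta <- as.numeric(y) - as.numeric(x)
  genes <- names(x)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_along(delta))
  ord <- order(-abs(delta), seq_along(delta))
  data.frame(gene = genes[ord], delta = delta[ord],
             direction = ifelse(delta[ord] > 0, "up",
                                ifelse(delta[ord] < 0, "down", "unchanged")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimal gene set that flips a cell's predicted class
#'
#' Genes are ranked by the magnitude of their change `|y - x|`. For
#' `g = 0, 1, ..., k` a hybrid profile takes the top-`g` genes from the
#' converted reconstruction `y` and the rest from the original `x`; the
#' result is the smallest `g` whose hybrid the classifier assigns to
#' `target` (at `g = k` the hybrid equals `y`, so a solution always exists
#' when the precondition holds).
#'
#' @param x Original expression vector.
#' @param y Converted reconstruction; must already classify as `target`.
#' @param classifier A `cell_classifier`.
#' @param target Target class label.
#' @return List with `g_star` (smallest flipping prefix size) and `genes`
#'   (the `g_star` genes changed, in rank order).
#' @export
minimal_gene_set <- function(x, y, classifier, target) {
  gene_names <- names(x)
  x <- as.numeric(x); y <- as.numeric(y)
  .assert(length(x) == length(y), "x and y must share the gene space")
  .assert(classify_cells(classifier, y) == as.character(target),
          "precondition violated: classifier(y) must equal target")
  ranked <- order(-abs(y - x), seq_along(x))
  k <- length(x)
  hybrids <- matrix(rep(x, k + 1L), nrow = k + 1L, byrow = TRUE)
  for (g in seq_len(k)) {
    hybrids[(g + 1L):(k + 1L), ranked[g]] <- y[ranked[g]]
  }
  pred <- classify_cells(classifier, hybrids)
  g_star <- which(pred == as.character(target))[1L] - 1L
  list(g_star = g_star,
       genes = if (g_star > 0L) {
         gn <- gene_names
         if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(k))
         gn[ranked[seq_len(g_star)]]
       } else character(0))
}
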