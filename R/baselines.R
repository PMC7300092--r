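# Baseline embeddings used in the clustering benchmark: a standard VAE
# (same architecture as DiffVAE but with the closed-form Gaussian KL term),
# a plain autoencoder trained on mean squared error, and PCA.

#' Train a standard variational autoencoder baseline
#'
#' Identical architecture to DiffVAE; the objective is the Bernoulli
#' reconstruction NLL plus the closed-form Gaussian KL divergence
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` to the standard-normal
#' prior, averaged over the batch. The latent representation is the
#' posterior mean.
#'
#' @inheritParams train_diffvae
#' @return A `vae_model` with a `latent` field holding the [latent_matrix()]
#'   of the training cells.
#' @export
train_vae <- function(expr, config = diffvae_config(), verbose = FALSE) {
  X <- .unit_values(expr)
  fit <- .train_autoencoder(X, config, kind = "vae", verbose = verbose)
  model <- structure(
    list(params = fit$params, bn = fit$bn, config = config, kind = "vae",
         loss_history = fit$history, gene_names = expr$gene_names),
    class = c("vae_model", "sc_autoencoder")
  )
  model$latent <- get_latent(model, expr)
  model
}

#' Train a plain autoencoder baseline
#'
#' Deterministic encoder-decoder with the same layer sizes as DiffVAE,
#' trained on the squared reconstruction error `||x - dec(enc(x))||^2`.
#' The logistic output activation is retained since inputs live in `[0, 1]`.
#' The latent representation is the bottleneck activation.
#'
#' @inheritParams train_diffvae
#' @return An `ae_model` with a `latent` field.
#' @export
train_ae <- function(expr, config = diffvae_config(), verbose = FALSE) {
  X <- .unit_values(expr)
  fit <- .train_autoencoder(X, config, kind = "ae", verbose = verbose)
  model <- structure(
    list(params = fit$params, bn = fit$bn, config = config, kind = "ae",
         loss_history = fit$history, gene_names = expr$gene_names),
    class = c("ae_model", "sc_autoencoder")
  )
  model$latent <- get_latent(model, expr)
  model
}

#' Gaussian KL divergence to the standard-normal prior
#'
#' Closed form `0.5 * sum_d (mu_d^2 + sigma_d^2 - 1 - log sigma_d^2)` per
#' row, averaged over rows. Nonnegative, zero iff `mu = 0` and `sigma = 1`.
#'
#' @param mu,log_var Posterior parameters (vectors or matrices).
#' @return Scalar KL value.
#' @export
gaussian_kl <- function(mu, log_var) {
  mu <- .as_batch(mu); log_var <- .as_batch(log_var)
  0.5 * sum(mu^2 + exp(log_var) - 1 - log_var) / nrow(mu)
}

#' PCA embedding baseline
#'
#' Top-`m` principal-component scores of the gene-centred (not re-scaled)
#' unit-scaled matrix. Each component's sign is fixed so that its largest
#' absolute loading is positive.
#'
#' @param expr Unit-scaled [expression_matrix()].
#' @param m Number of components; must not exceed `min(N, k)`.
#' @return A [latent_matrix()] of scores, with loadings and explained
#'   variances attached as attributes `"rotation"` and `"variance"`.
#' @export
pca_embed <- function(expr, m) {
  X <- .unit_values(expr)
  .assert(m >= 1 && m <= min(dim(X)),
          sprintf("m must lie in [1, %d]", min(dim(X))))
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = m)
  rot <- fit$rotation[, seq_len(m), drop = FALSE]
  scores <- fit$x[, seq_len(m), drop = FALSE]
  flip <- vapply(seq_len(m), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip]
  scores[, flip] <- -scores[, flip]
  out <- latent_matrix(scores, cell_ids = expr$cell_ids)
  attr(out, "rotation") <- rot
  attr(out, "variance") <- fit$sdev[seq_len(m)]^2
  out
}

#' Embed an expression matrix with any of the benchmark models
#'
#' Convenience dispatcher used by [benchmark_embeddings()].
#'
#' @param expr Unit-scaled [expression_matrix()].
#' @param kind One of `"diffvae"`, `"vae"`, `"ae"`, `"pca"`.
#' @param m Latent size.
#' @param config Optional [diffvae_config()]; `m` and the seed override its
#'   fields. Ignored for PCA.
#' @param seed Seed for the trained models.
#' @return A [latent_matrix()].
#' @export
embed_cells <- function(expr, kind = c("diffvae", "vae", "ae", "pca"), m = 50,
                        config = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "pca") return(pca_embed(expr, m))
  if (is.null(config)) config <- diffvae_config()
  config$m <- as.integer(m)
  config$seed <- as.integer(seed)
  model <- switch(kind,
                  diffvae = train_diffvae(expr, config),
                  vae = train_vae(expr, config),
                  ae = train_ae(expr, config))
  get_latent(model, expr)
}
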