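# DiffVAE: a fully connected variational autoencoder with a Gaussian
# encoder, a Bernoulli (logistic-output) decoder, and a training objective
# that replaces the usual KL term with the maximum mean discrepancy between
# the aggregate latent posterior and the standard-normal prior (the
# MMD-VAE / InfoVAE family). The latent representation used downstream is
# the posterior mean.

#' DiffVAE configuration
#'
#' Defaults are the published training setup for a hematopoiesis-scale
#' dataset: hidden layers of 256 and 512 neurons (`h2 = 2 * h1`), a
#' 50-dimensional latent space, Adam with learning rate 0.001, batch size
#' 128 and 100 epochs.
#'
#' @param h1 Neurons in the inner hidden layer (encoder layer 2 / decoder
#'   layer 1).
#' @param h2 Neurons in the outer hidden layer; defaults to `2 * h1`.
#' @param m Latent dimensionality.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (the final partial batch is kept).
#' @param epochs Training epochs.
#' @param mmd_weight Nonnegative weight of the MMD term in the loss.
#' @param kernel_bandwidths RBF length-scales for the MMD kernel mixture;
#'   `NULL` uses `sqrt(m/2) * c(0.1, 0.5, 1, 2, 10)`.
#' @param head_activation Activation of the posterior-mean and log-variance
#'   heads: `"relu"` (as printed in the model equations, constraining the
#'   mean to be nonnegative and the variance to be at least 1) or
#'   `"linear"` (the conventional unconstrained heads).
#' @param use_batchnorm Apply batch normalization after each encoder hidden
#'   affine transform (before the ReLU).
#' @param seed Integer seed controlling weight initialization, shuffling
#'   and all noise draws.
#' @return An object of class `diffvae_config`.
#' @export
diffvae_config <- function(h1 = 256, h2 = NULL, m = 50, learning_rate = 0.001,
                           batch_size = 128, epochs = 100, mmd_weight = 1.0,
                           kernel_bandwidths = NULL,
                           head_activation = c("relu", "linear"),
                           use_batchnorm = TRUE, seed = 1) {
  if (is.null(h2)) h2 <- 2L * h1
  head_activation <- match.arg(head_activation)
  .assert(h1 >= 1 && h2 >= 1 && m >= 1 && batch_size >= 1 && epochs >= 0,
          "all sizes must be positive (epochs may be 0)")
  .assert(mmd_weight >= 0, "mmd_weight must be nonnegative")
  .assert(learning_rate > 0, "learning_rate must be positive")
  structure(
    list(h1 = as.integer(h1), h2 = as.integer(h2), m = as.integer(m),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), mmd_weight = mmd_weight,
         kernel_bandwidths = kernel_bandwidths,
         head_activation = head_activation,
         use_batchnorm = isTRUE(use_batchnorm), seed = as.integer(seed)),
    class = "diffvae_config"
  )
}

# ---- parameter initialization ------------------------------------------

# `kind`: "diffvae"/"vae" carry a log-variance head; "ae" does not.
.init_autoencoder_params <- function(k, config, kind) {
  h1 <- config$h1; h2 <- config$h2; m <- config$m
  p <- list(
    enc_W1 = .glorot(k, h2), enc_b1 = rep(0, h2),
    enc_W2 = .glorot(h2, h1), enc_b2 = rep(0, h1),
    W_mu = .glorot(h1, m), b_mu = rep(0, m),
    dec_W1 = .glorot(m, h1), dec_b1 = rep(0, h1),
    dec_W2 = .glorot(h1, h2), dec_b2 = rep(0, h2),
    W_out = .glorot(h2, k), b_out = rep(0, k)
  )
  if (kind != "ae") {
    p$W_sig <- .glorot(h1, m)
    p$b_sig <- rep(0, m)
  }
  bn <- if (config$use_batchnorm) list(bn1 = .bn_init(h2), bn2 = .bn_init(h1)) else NULL
  list(params = p, bn = bn)
}

.head_act <- function(x, head_activation) {
  if (head_activation == "relu") .relu(x) else x
}

# ---- forward / backward -------------------------------------------------

.enc_fwd <- function(params, bn, X, config, training, kind) {
  A1 <- .add_bias(X %*% params$enc_W1, params$enc_b1)
  if (config$use_batchnorm) {
    r1 <- .bn_fwd(A1, bn$bn1, training)
    P1 <- r1$Y
  } else {
    r1 <- NULL; P1 <- A1
  }
  H1 <- .relu(P1)
  A2 <- .add_bias(H1 %*% params$enc_W2, params$enc_b2)
  if (config$use_batchnorm) {
    r2 <- .bn_fwd(A2, bn$bn2, training)
    P2 <- r2$Y
  } else {
    r2 <- NULL; P2 <- A2
  }
  H2 <- .relu(P2)
  mu_pre <- .add_bias(H2 %*% params$W_mu, params$b_mu)
  mu <- .head_act(mu_pre, config$head_activation)
  out <- list(mu = mu, cache = list(X = X, P1 = P1, H1 = H1, P2 = P2, H2 = H2,
                                    mu_pre = mu_pre, r1 = r1, r2 = r2))
  if (kind != "ae") {
    lv_pre <- .add_bias(H2 %*% params$W_sig, params$b_sig)
    out$log_var <- .head_act(lv_pre, config$head_activation)
    out$cache$lv_pre <- lv_pre
  }
  if (training && config$use_batchnorm) {
    out$bn <- list(bn1 = r1$bn, bn2 = r2$bn)
  }
  out
}

.enc_bwd <- function(params, config, cache, dmu, dlv, kind) {
  g <- list()
  if (config$head_activation == "relu") {
    dmu <- dmu * (cache$mu_pre > 0)
    if (!is.null(dlv)) dlv <- dlv * (cache$lv_pre > 0)
  }
  g$W_mu <- crossprod(cache$H2, dmu)
  g$b_mu <- colSums(dmu)
  dH2 <- dmu %*% t(params$W_mu)
  if (kind != "ae") {
    g$W_sig <- crossprod(cache$H2, dlv)
    g$b_sig <- colSums(dlv)
    dH2 <- dH2 + dlv %*% t(params$W_sig)
  }
  dP2 <- dH2 * (cache$P2 > 0)
  if (config$use_batchnorm) {
    b2 <- .bn_bwd(dP2, cache$r2$cache, cache$r2$bn$gamma)
    g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta
    dA2 <- b2$dA
  } else {
    dA2 <- dP2
  }
  g$enc_W2 <- crossprod(cache$H1, dA2)
  g$enc_b2 <- colSums(dA2)
  dH1 <- dA2 %*% t(params$enc_W2)
  dP1 <- dH1 * (cache$P1 > 0)
  if (config$use_batchnorm) {
    b1 <- .bn_bwd(dP1, cache$r1$cache, cache$r1$bn$gamma)
    g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
    dA1 <- b1$dA
  } else {
    dA1 <- dP1
  }
  g$enc_W1 <- crossprod(cache$X, dA1)
  g$enc_b1 <- colSums(dA1)
  g
}

.dec_fwd <- function(params, Z) {
  A1 <- .add_bias(Z %*% params$dec_W1, params$dec_b1)
  H1 <- .relu(A1)
  A2 <- .add_bias(H1 %*% params$dec_W2, params$dec_b2)
  H2 <- .relu(A2)
  logits <- .add_bias(H2 %*% params$W_out, params$b_out)
  Xp <- .sigmoid(logits)
  list(Xp = Xp, cache = list(Z = Z, A1 = A1, H1 = H1, A2 = A2, H2 = H2))
}

.dec_bwd <- function(params, cache, dlogits) {
  g <- list()
  g$W_out <- crossprod(cache$H2, dlogits)
  g$b_out <- colSums(dlogits)
  dH2 <- dlogits %*% t(params$W_out)
  dA2 <- dH2 * (cache$A2 > 0)
  g$dec_W2 <- crossprod(cache$H1, dA2)
  g$dec_b2 <- colSums(dA2)
  dH1 <- dA2 %*% t(params$dec_W2)
  dA1 <- dH1 * (cache$A1 > 0)
  g$dec_W1 <- crossprod(cache$Z, dA1)
  g$dec_b1 <- colSums(dA1)
  dZ <- dA1 %*% t(params$dec_W1)
  list(grads = g, dZ = dZ)
}

# Fold batch-norm parameters into/out of the flat parameter list so Adam
# treats them like any other trainable tensor.
.flatten_bn <- function(params, bn) {
  if (is.null(bn)) return(params)
  params$bn1_gamma <- bn$bn1$gamma; params$bn1_beta <- bn$bn1$beta
  params$bn2_gamma <- bn$bn2$gamma; params$bn2_beta <- bn$bn2$beta
  params
}

.sync_bn <- function(params, bn) {
  if (is.null(bn)) return(bn)
  bn$bn1$gamma <- params$bn1_gamma; bn$bn1$beta <- params$bn1_beta
  bn$bn2$gamma <- params$bn2_gamma; bn$bn2$beta <- params$bn2_beta
  bn
}

# ---- shared training loop ----------------------------------------------

.unit_values <- function(expr) {
  .assert(inherits(expr, "expression_matrix"), "expected an expression_matrix")
  .assert(expr$scale_state == "unit_scaled",
          "input must be unit_scaled (run minmax_scale first)")
  expr$values
}

# One trainer backs DiffVAE ("mmd"), the standard VAE ("kl") and the plain
# autoencoder ("mse" objective, deterministic bottleneck).
.train_autoencoder <- function(X, config, kind = c("diffvae", "vae", "ae"),
                               verbose = FALSE) {
  kind <- match.arg(kind)
  N <- nrow(X); k <- ncol(X)
  bandwidths <- config$kernel_bandwidths
  if (is.null(bandwidths)) bandwidths <- .default_bandwidths(config$m)

  .with_seed(config$seed, {
    init <- .init_autoencoder_params(k, config, kind)
    params <- .flatten_bn(init$params, init$bn)
    bn <- init$bn
    opt <- .adam_init(params)
    history <- numeric(0)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(N)
      starts <- seq(1L, N, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, N)]
        Xb <- X[idx, , drop = FALSE]
        B <- length(idx)

        enc <- .enc_fwd(params, bn, Xb, config, training = TRUE, kind = kind)
        if (config$use_batchnorm) bn <- enc$bn
        if (kind == "ae") {
          Z <- enc$mu
          eps <- NULL
        } else {
          eps <- matrix(stats::rnorm(B * config$m), B, config$m)
          sig <- exp(enc$log_var / 2)
          Z <- enc$mu + eps * sig
        }
        dec <- .dec_fwd(params, Z)

        if (kind == "ae") {
          loss <- sum((Xb - dec$Xp)^2) / B
          dlogits <- 2 * (dec$Xp - Xb) * dec$Xp * (1 - dec$Xp) / B
        } else {
          loss <- .bce(Xb, dec$Xp)
          dlogits <- (dec$Xp - Xb) / B
        }

        back <- .dec_bwd(params, dec$cache, dlogits)
        dZ <- back$dZ

        if (kind == "diffvae") {
          prior <- matrix(stats::rnorm(B * config$m), B, config$m)
          loss <- loss + config$mmd_weight * mmd(Z, prior, bandwidths)
          dZ <- dZ + config$mmd_weight * .mmd_grad_q(Z, prior, bandwidths)
        }

        if (kind == "ae") {
          dmu <- dZ
          dlv <- NULL
        } else {
          dmu <- dZ
          dlv <- dZ * eps * 0.5 * exp(enc$log_var / 2)
          if (kind == "vae") {
            # closed-form Gaussian KL to N(0, I), averaged over the batch
            loss <- loss +
              0.5 * sum(enc$mu^2 + exp(enc$log_var) - 1 - enc$log_var) / B
            dmu <- dmu + enc$mu / B
            dlv <- dlv + 0.5 * (exp(enc$log_var) - 1) / B
          }
        }

        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (%.4g); try a smaller learning rate",
                       epoch, loss), call. = FALSE)
        }

        genc <- .enc_bwd(params, config, enc$cache, dmu, dlv, kind)
        grads <- c(back$grads, genc)
        step <- .adam_update(params, grads, opt, config$learning_rate)
        params <- step$params
        opt <- step$state
        bn <- .sync_bn(params, bn)
        epoch_loss <- epoch_loss + loss * B
      }
      history <- c(history, epoch_loss / N)
      .msg(sprintf("epoch %3d/%d  loss %.5f", epoch, config$epochs,
                   history[epoch]), verbose = verbose)
    }
    list(params = params, bn = bn, history = history)
  })
}

#' Train DiffVAE on a unit-scaled expression matrix
#'
#' Minimizes the Bernoulli reconstruction negative log-likelihood plus
#' `mmd_weight` times the MMD between the sampled latent batch and a fresh
#' standard-normal batch, using Adam on minibatches. All randomness (weight
#' initialization, shuffling, reparameterisation noise, prior draws) flows
#' from `config$seed`, so reruns are bit-identical.
#'
#' @param expr A unit-scaled [expression_matrix()] (see [minmax_scale()]).
#' @param config A [diffvae_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `diffvae_model` with elements `params`, `bn`
#'   (batch-norm statistics), `config`, `loss_history` and `gene_names`.
#' @export
train_diffvae <- function(expr, config = diffvae_config(), verbose = FALSE) {
  X <- .unit_values(expr)
  fit <- .train_autoencoder(X, config, kind = "diffvae", verbose = verbose)
  structure(
    list(params = fit$params, bn = fit$bn, config = config, kind = "diffvae",
         loss_history = fit$history, gene_names = expr$gene_names),
    class = c("diffvae_model", "sc_autoencoder")
  )
}

#' @export
print.sc_autoencoder <- function(x, ...) {
  cat(sprintf("<%s> k=%d genes, m=%d latent, %d epoch(s) trained\n",
              class(x)[1], nrow(x$params$enc_W1), x$config$m,
              length(x$loss_history)))
  invisible(x)
}

#' Encode expression profiles to the latent posterior parameters
#'
#' @param model A trained `diffvae_model` or `vae_model` (autoencoder models
#'   return only `mu`, the bottleneck activations).
#' @param x Unit-scaled expression: an [expression_matrix()] or a numeric
#'   matrix/vector of width `k`.
#' @return List with `mu` and (for variational models) `log_var`, each
#'   `N x m`. Batch normalization runs in inference mode (running statistics).
#' @export
encode <- function(model, x) {
  X <- if (inherits(x, "expression_matrix")) .unit_values(x) else .as_row_matrix(x)
  .assert(ncol(X) == nrow(model$params$enc_W1),
          sprintf("input width %d does not match model gene count %d",
                  ncol(X), nrow(model$params$enc_W1)))
  enc <- .enc_fwd(model$params, model$bn, X, model$config, training = FALSE,
                  kind = model$kind)
  if (model$kind == "ae") list(mu = enc$mu) else list(mu = enc$mu, log_var = enc$log_var)
}

.as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Reparameterisation trick
#'
#' `z = mu + eps * exp(log_var / 2)`, turning the sampling of a Gaussian
#' latent code into a differentiable transformation of a standard-normal
#' draw `eps`.
#'
#' @param mu,log_var Posterior mean and log-variance (vectors or matrices of
#'   equal shape).
#' @param eps Standard-normal draw of the same shape.
#' @return The latent sample `z`.
#' @export
reparameterize <- function(mu, log_var, eps) {
  .assert(all(is.finite(mu)) && all(is.finite(log_var)) && all(is.finite(eps)),
          "reparameterize: inputs must be finite")
  mu + eps * exp(log_var / 2)
}

#' Decode latent codes to reconstructed expression
#'
#' Two ReLU layers followed by a logistic output; the returned values are
#' the Bernoulli means (maximum-likelihood reconstruction, no sampling) and
#' lie strictly in (0, 1).
#'
#' @param model A trained autoencoder model.
#' @param z Latent codes, `N x m` matrix or length-`m` vector.
#' @return `N x k` matrix of reconstructions.
#' @export
decode <- function(model, z) {
  Z <- .as_row_matrix(z)
  .assert(ncol(Z) == model$config$m,
          sprintf("latent width %d does not match model m=%d", ncol(Z), model$config$m))
  out <- .dec_fwd(model$params, Z)$Xp
  colnames(out) <- model$gene_names
  out
}

#' DiffVAE training loss for a single batch
#'
#' Bernoulli negative log-likelihood (binary cross-entropy summed over genes,
#' averaged over the batch; decoder outputs clamped to
#' `[1e-7, 1 - 1e-7]`) plus `mmd_weight` times the MMD between the latent
#' batch and a prior batch.
#'
#' @param x Input batch in `[0, 1]`.
#' @param x_prime Reconstructed batch in `(0, 1)`.
#' @param z_batch Latent sample for the batch.
#' @param prior_batch Standard-normal sample of the same width.
#' @param mmd_weight Weight of the MMD term.
#' @param bandwidths RBF length-scales (default as in [mmd()]).
#' @return Scalar loss (to minimize).
#' @export
diffvae_loss <- function(x, x_prime, z_batch, prior_batch, mmd_weight = 1.0,
                         bandwidths = NULL) {
  X <- .as_batch(x); Xp <- .as_batch(x_prime)
  .assert(all(dim(X) == dim(Xp)), "x and x_prime must have the same shape")
  .bce(X, Xp) + mmd_weight * mmd(z_batch, prior_batch, bandwidths)
}

#' Latent matrix container
#'
#' Stores per-cell latent coordinates along with per-dimension means and
#' standard deviations (population convention, dividing by `N`), which feed
#' the extreme-cell rule and the latent perturbation machinery.
#'
#' @param z_means `N x m` matrix of per-cell latent coordinates.
#' @param cell_ids Optional cell identifiers.
#' @return An object of class `latent_matrix` with `z_means`, `dim_means`
#'   and `dim_sds`.
#' @export
latent_matrix <- function(z_means, cell_ids = NULL) {
  z_means <- as.matrix(z_means)
  dim_means <- colMeans(z_means)
  dim_sds <- sqrt(colMeans(sweep(z_means, 2L, dim_means)^2))
  if (!is.null(cell_ids)) rownames(z_means) <- cell_ids
  structure(list(z_means = z_means, dim_means = dim_means, dim_sds = dim_sds),
            class = "latent_matrix")
}

#' @export
print.latent_matrix <- function(x, ...) {
  cat(sprintf("<latent_matrix> %d cells x %d dimensions\n",
              nrow(x$z_means), ncol(x$z_means)))
  invisible(x)
}

#' Extract the latent representation of every cell
#'
#' Uses the posterior mean (no sampling) as the latent representation, the
#' maximum-likelihood point in the learnt latent distribution.
#'
#' @param model A trained autoencoder model.
#' @param expr Unit-scaled [expression_matrix()].
#' @return A [latent_matrix()].
#' @export
get_latent <- function(model, expr) {
  latent_matrix(encode(model, expr)$mu, cell_ids = expr$cell_ids)
}

#' Grid search over DiffVAE hyperparameters
#'
#' Splits cells 80/20 into training and validation (seeded), trains one
#' model per grid entry and returns the configuration with the smallest
#' validation loss (reconstruction NLL plus weighted MMD on the validation
#' set). Ties are broken by smaller `m`, then smaller `h1`.
#'
#' @param expr Unit-scaled [expression_matrix()].
#' @param grid A list of [diffvae_config()] objects.
#' @param seed Seed for the train/validation split.
#' @return The winning `diffvae_config`, with the per-entry validation
#'   losses attached as attribute `"validation_loss"`.
#' @export
hyperparameter_search <- function(expr, grid, seed = 1) {
  .assert(length(grid) >= 1, "grid must be non-empty")
  X <- .unit_values(expr)
  N <- nrow(X)
  idx_train <- .with_seed(seed, sample.int(N, size = floor(0.8 * N)))
  Xtr <- expression_matrix(X[idx_train, , drop = FALSE], scale_state = "unit_scaled")
  Xval <- X[-idx_train, , drop = FALSE]
  losses <- vapply(grid, function(cfg) {
    model <- train_diffvae(Xtr, cfg)
    enc <- encode(model, Xval)
    z <- enc$mu
    xp <- decode(model, z)
    prior <- .with_seed(seed + 1L, matrix(stats::rnorm(length(z)), nrow(z), ncol(z)))
    diffvae_loss(Xval, xp, z, prior, cfg$mmd_weight, cfg$kernel_bandwidths)
  }, numeric(1))
  ord <- order(losses,
               vapply(grid, `[[`, integer(1), "m"),
               vapply(grid, `[[`, integer(1), "h1"))
  best <- grid[[ord[1]]]
  attr(best, "validation_loss") <- losses
  best
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding all weight matrices,
#' batch-norm statistics and the configuration (including the seed), so a
#' reloaded model encodes bit-identically.
#'
#' @param model A model object from this package.
#' @param path Checkpoint path.
#' @return `path` (save) or the model object (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
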