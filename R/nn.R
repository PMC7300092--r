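# Minimal dense-network machinery: Glorot initialization, batch
# normalization, analytic backpropagation and Adam. Written directly in
# matrix algebra; every training loop in the package builds on these
# primitives.

.glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.bn_init <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       running_mean = rep(0, n), running_var = rep(1, n))
}

# Batch normalization over the batch dimension (rows).
.bn_fwd <- function(A, bn, training) {
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(sweep(A, 2L, mu)^2)
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  inv_sd <- 1 / sqrt(v + .BN_EPS)
  xhat <- sweep(sweep(A, 2L, mu), 2L, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  new_bn <- bn
  if (training) {
    new_bn$running_mean <- .BN_MOMENTUM * bn$running_mean + (1 - .BN_MOMENTUM) * mu
    new_bn$running_var <- .BN_MOMENTUM * bn$running_var + (1 - .BN_MOMENTUM) * v
  }
  list(Y = Y, cache = list(xhat = xhat, inv_sd = inv_sd), bn = new_bn)
}

.bn_bwd <- function(dY, cache, gamma) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  # dA = inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per column
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dA <- sweep(sweep(dxhat, 2L, m1) - sweep(cache$xhat, 2L, m2, "*"),
              2L, cache$inv_sd, "*")
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# ---- Adam -------------------------------------------------------------

.adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

.adam_update <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- Maximum mean discrepancy -----------------------------------------

.sqdist <- function(A, B) {
  # squared Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

.default_bandwidths <- function(m) sqrt(m / 2) * c(0.1, 0.5, 1, 2, 10)

.as_batch <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
}

#' Maximum mean discrepancy between two samples
#'
#' Biased (V-statistic) estimate of the squared MMD under a mixture of RBF
#' kernels `k(a, b) = exp(-||a - b||^2 / l^2)`, summed over the bandwidths
#' `l`. The biased estimator is nonnegative by construction and zero when
#' the two samples coincide.
#'
#' @param sample_q,sample_p Numeric matrices (rows = points) or vectors
#'   (treated as 1-D points); must have the same width.
#' @param bandwidths Positive length-scales `l` of the RBF kernels. Default:
#'   `sqrt(m/2) * c(0.1, 0.5, 1, 2, 10)` for latent width `m`.
#' @return A single nonnegative number.
#' @export
mmd <- function(sample_q, sample_p, bandwidths = NULL) {
  q <- .as_batch(sample_q)
  p <- .as_batch(sample_p)
  .assert(nrow(q) > 0 && nrow(p) > 0, "mmd: empty sample")
  .assert(ncol(q) == ncol(p), "mmd: samples must have the same width")
  if (is.null(bandwidths)) bandwidths <- .default_bandwidths(ncol(q))
  .assert(all(bandwidths > 0), "mmd: bandwidths must be positive")
  Dqq <- .sqdist(q, q)
  Dpp <- .sqdist(p, p)
  Dqp <- .sqdist(q, p)
  total <- 0
  for (l in bandwidths) {
    total <- total + mean(exp(-Dqq / l^2)) + mean(exp(-Dpp / l^2)) -
      2 * mean(exp(-Dqp / l^2))
  }
  max(total, 0)
}

# Gradient of mmd(q, p) with respect to the rows of q.
.mmd_grad_q <- function(q, p, bandwidths) {
  B <- nrow(q)
  Bp <- nrow(p)
  Dqq <- .sqdist(q, q)
  Dqp <- .sqdist(q, p)
  grad <- matrix(0, nrow(q), ncol(q))
  for (l in bandwidths) {
    Kqq <- exp(-Dqq / l^2)
    Kqp <- exp(-Dqp / l^2)
    # d/dq_i mean(Kqq): rows and columns both contain q_i
    g_qq <- (Kqq %*% q - rowSums(Kqq) * q) * (4 / (B^2 * l^2))
    g_qp <- (Kqp %*% p - rowSums(Kqp) * q) * (2 / (B * Bp * l^2))
    grad <- grad + g_qq - 2 * g_qp
  }
  grad
}

# ---- Bernoulli reconstruction loss ------------------------------------

.NLL_EPS <- 1e-7

# Binary cross-entropy summed over genes, averaged over the batch.
.bce <- function(X, Xp) {
  Xp <- pmin(pmax(Xp, .NLL_EPS), 1 - .NLL_EPS)
  sum(-(X * log(Xp) + (1 - X) * log(1 - Xp))) / nrow(X)
}
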