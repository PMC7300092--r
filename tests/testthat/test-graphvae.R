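test_that("correlation graph matches a hand-worked three-cell case", {
  # c1 and c2 strongly positively correlated; c3 anticorrelated with both
  X <- rbind(c1 = c(1, 2, 3, 4),
             c2 = c(2, 4, 6, 9),
             c3 = c(4, 3, 2, 1))
  g <- suppressWarnings(correlation_graph(X))
  # c1 picks c2 and vice versa; c3's best correlation is negative -> isolated
  expect_equal(unname(g$A),
               rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
})

test_that("correlation graph agrees with a brute-force scan", {
  set.seed(61)
  e <- generate_expression(synthetic_spec(n_cells = 30, n_genes = 15,
                                          n_clusters = 3, markers_per_cluster = 4,
                                          seed = 13))$expression
  g <- correlation_graph(e)
  X <- e$values
  A <- matrix(0, 30, 30)
  for (i in 1:30) {
    best <- -Inf; bj <- 0L
    for (j in 1:30) {
      if (j == i) next
      r <- cor(X[i, ], X[j, ])
      if (r > best) { best <- r; bj <- j }
    }
    if (best > 0) { A[i, bj] <- 1; A[bj, i] <- 1 }
  }
  expect_equal(unname(g$A), A)
  expect_identical(g$A, t(g$A))
  expect_true(all(diag(g$A) == 0))
})

test_that("correlation graph is invariant to per-cell affine rescaling", {
  set.seed(62)
  X <- matrix(runif(40), 8, 5)
  Y <- X * 3 + 2 # Pearson correlation is affine-invariant
  g1 <- correlation_graph(X)
  g2 <- correlation_graph(Y)
  expect_equal(g1$A, g2$A)
})

test_that("adjacency normalization reproduces hand values", {
  # two isolated nodes: A + I = I, degrees 1 -> identity
  g0 <- cell_graph(matrix(0, 2, 2))
  expect_equal(unname(normalize_adjacency(g0)), diag(2))
  # single edge between 2 nodes: degrees 2, all entries 0.5
  g1 <- cell_graph(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(normalize_adjacency(g1)), matrix(0.5, 2, 2))
  # path 1-2-3 with self-loops: degrees (2, 3, 2)
  g2 <- cell_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  An <- normalize_adjacency(g2)
  expect_equal(unname(An),
               rbind(c(1 / 2, 1 / sqrt(6), 0),
                     c(1 / sqrt(6), 1 / 3, 1 / sqrt(6)),
                     c(0, 1 / sqrt(6), 1 / 2)),
               tolerance = 1e-12)
})

test_that("normalized adjacency eigenvalues lie in [-1, 1]", {
  set.seed(63)
  for (rep in 1:5) {
    A <- matrix(rbinom(64, 1, 0.3), 8, 8)
    A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    ev <- eigen(normalize_adjacency(cell_graph(A)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("gcn layer is the propagation rule A_norm X W", {
  An <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  X <- rbind(c(1, -1), c(3, 1))
  W <- rbind(c(1, 0), c(0, 1))
  # A_norm X = [[2, 0], [2, 0]]; relu leaves it unchanged
  expect_equal(unname(gcn_layer(An, X, W)), rbind(c(2, 0), c(2, 0)))
  expect_equal(unname(gcn_layer(An, X, -W, "linear")),
               rbind(c(-2, 0), c(-2, 0)))
  # with A_norm = I the layer is a plain dense layer
  set.seed(64)
  X2 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(6), 3, 2)
  expect_equal(gcn_layer(diag(4), X2, W2, "linear"), X2 %*% W2)
  expect_error(gcn_layer(An, X, matrix(1, 3, 2)), "conformable")
})

test_that("graph encoder and decoder honour shapes and zero-weight limits", {
  cfg <- graphvae_config(hidden_features = 4, latent_features = 3, epochs = 0)
  X <- matrix(runif(5 * 6), 5, 6)
  g <- cell_graph(1 * (as.matrix(dist(X)) < 0.9), self_loop_state = "without")
  model <- list(params = list(Wg1 = matrix(0, 6, 4), W_mu = matrix(0, 4, 3),
                              W_sig = matrix(0, 4, 3),
                              Wd1 = matrix(0, 9, 4), Wd2 = matrix(0, 4, 3)),
                config = cfg)
  enc <- graph_encode(model, g, X)
  expect_equal(dim(enc$mu), c(5, 3))
  expect_true(all(enc$mu == 0) && all(enc$log_var == 0))
  dec <- graph_decode(model, g, X, enc$mu)
  # Z* = 0 -> every predicted edge probability is exactly 0.5
  expect_equal(unname(dec$A_hat), matrix(0.5, 5, 5))
  expect_equal(dim(dec$Z_prime), c(5, 3))
  expect_equal(dec$Z_star, (dec$Z_prime + enc$mu) / 2)
})

test_that("graph decoder inner product matches hand arithmetic", {
  # choose weights so Z' = 0; then Z* = Z/2 and A_hat = sigmoid(Z Z^T / 4)
  cfg <- graphvae_config(hidden_features = 2, latent_features = 2, epochs = 0)
  model <- list(params = list(Wd1 = matrix(0, 4, 2), Wd2 = matrix(0, 2, 2)),
                config = cfg)
  g <- cell_graph(matrix(c(0, 1, 1, 0), 2))
  X <- matrix(0, 2, 2)
  Z <- rbind(c(2, 0), c(0, 2))
  dec <- graph_decode(model, g, X, Z)
  S <- tcrossprod(Z / 2)
  expect_equal(unname(dec$A_hat), 1 / (1 + exp(-S)), tolerance = 1e-12)
})

test_that("graphvae loss reproduces hand values", {
  # perfect prediction of the 2-node loop-only graph, prior posterior
  A <- diag(2)
  mu <- matrix(0, 2, 2)
  lv <- matrix(0, 2, 2)
  eps <- scDiffVAE:::.NLL_EPS
  almost <- matrix(eps, 2, 2); diag(almost) <- 1 - eps
  expect_equal(graphvae_loss(A, almost, mu, lv), -2 * log(1 - eps) * 2 / 2,
               tolerance = 1e-9)
  # uniform 0.5 prediction: every entry contributes log 2
  half <- matrix(0.5, 2, 2)
  expect_equal(graphvae_loss(A, half, mu, lv), 4 * log(2) / 2, tolerance = 1e-12)
  # KL term: mu = 1 everywhere adds 0.5 * N * M / N = M / 2 per node
  expect_equal(graphvae_loss(A, half, matrix(1, 2, 3), matrix(0, 2, 3)),
               2 * log(2) + 0.5 * 3, tolerance = 1e-12)
  # positive-edge weighting scales only the edge terms
  expect_equal(graphvae_loss(A, half, mu, lv, edge_pos_weight = 2),
               (2 * 2 + 2) * log(2) / 2, tolerance = 1e-12)
})

test_that("graphvae loss matches an element-wise oracle", {
  set.seed(65)
  n <- 4
  A <- 1 * (matrix(runif(16), 4) > 0.5)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
  P <- matrix(runif(16, 0.05, 0.95), 4)
  mu <- matrix(rnorm(8), 4, 2)
  lv <- matrix(rnorm(8, sd = 0.3), 4, 2)
  w <- 2.5
  acc <- 0
  for (i in 1:4) for (j in 1:4) {
    acc <- acc - (w * A[i, j] * log(P[i, j]) + (1 - A[i, j]) * log(1 - P[i, j]))
  }
  kl <- 0
  for (i in 1:4) for (d in 1:2) {
    kl <- kl + 0.5 * (mu[i, d]^2 + exp(lv[i, d]) - 1 - lv[i, d])
  }
  expect_equal(graphvae_loss(A, P, mu, lv, edge_pos_weight = w),
               (acc + kl) / 4, tolerance = 1e-10)
})

test_that("training is deterministic and separates edges from non-edges", {
  ds <- generate_expression(synthetic_spec(n_cells = 60, n_genes = 30,
                                           n_clusters = 3, markers_per_cluster = 5,
                                           seed = 17))
  g <- generate_labeled_graph(ds, k = 3, seed = 2)
  expr <- minmax_scale(ds$expression, verbose = FALSE)
  cfg <- graphvae_config(hidden_features = 32, latent_features = 8,
                         epochs = 60, seed = 9)
  fit1 <- train_graph_diffvae(expr, g, cfg)
  fit2 <- train_graph_diffvae(expr, g, cfg)
  expect_identical(fit1$predicted$A_hat, fit2$predicted$A_hat)
  expect_lt(fit1$loss_history[60], fit1$loss_history[1])
  A_hat <- fit1$predicted$A_hat
  expect_identical(A_hat, t(A_hat))
  expect_true(all(A_hat > 0 & A_hat < 1))
  At <- g$A; diag(At) <- 1
  expect_gt(mean(A_hat[At == 1]), mean(A_hat[At == 0]))
  # epochs = 0 contract: still returns a prediction from the initial weights
  fit0 <- train_graph_diffvae(expr, g, graphvae_config(hidden_features = 8,
                                                       latent_features = 4,
                                                       epochs = 0, seed = 9))
  expect_length(fit0$loss_history, 0)
  expect_equal(dim(fit0$predicted$A_hat), c(60, 60))
})

test_that("training gradient matches finite differences", {
  set.seed(66)
  n <- 5; f <- 4
  X <- matrix(runif(n * f), n, f)
  A <- rbind(c(0, 1, 0, 0, 1), c(1, 0, 1, 0, 0), c(0, 1, 0, 1, 0),
             c(0, 0, 1, 0, 1), c(1, 0, 0, 1, 0))
  g <- cell_graph(A)
  cfg <- graphvae_config(hidden_features = 3, latent_features = 2,
                         epochs = 1, seed = 7)
  An <- normalize_adjacency(g)
  At <- A; diag(At) <- 1
  w <- 1.5
  params <- withr::with_seed(7, scDiffVAE:::.graphvae_init(f, cfg))
  eps <- matrix(rnorm(n * 2), n, 2)

  loss_at <- function(p) {
    H <- pmax(An %*% X %*% p$Wg1, 0)
    mu <- An %*% H %*% p$W_mu
    lv <- An %*% H %*% p$W_sig
    Z <- mu + eps * exp(lv / 2)
    D1 <- pmax(An %*% cbind(Z, X) %*% p$Wd1, 0)
    Zp <- pmax(An %*% D1 %*% p$Wd2, 0)
    Zs <- (Zp + Z) / 2
    P <- 1 / (1 + exp(-tcrossprod(Zs)))
    P <- pmin(pmax(P, scDiffVAE:::.NLL_EPS), 1 - scDiffVAE:::.NLL_EPS)
    -sum(w * At * log(P) + (1 - At) * log(1 - P)) / n +
      gaussian_kl_total(mu, lv) / n
  }

  # analytic gradients, mirroring the training loop
  AX <- An %*% X
  H <- pmax(AX %*% params$Wg1, 0)
  AH <- An %*% H
  mu <- AH %*% params$W_mu
  lv <- AH %*% params$W_sig
  sig <- exp(lv / 2)
  Z <- mu + eps * sig
  C <- cbind(Z, X)
  AC <- An %*% C
  P1 <- AC %*% params$Wd1
  D1 <- pmax(P1, 0)
  AD1 <- An %*% D1
  P2 <- AD1 %*% params$Wd2
  Zp <- pmax(P2, 0)
  Zs <- (Zp + Z) / 2
  A_hat <- 1 / (1 + exp(-tcrossprod(Zs)))
  G <- (A_hat * (1 - At) - w * At * (1 - A_hat)) / n
  dZs <- (G + t(G)) %*% Zs
  dP2 <- (dZs / 2) * (P2 > 0)
  gWd2 <- crossprod(AD1, dP2)
  dD1 <- (An %*% dP2) %*% t(params$Wd2)
  dP1 <- dD1 * (P1 > 0)
  gWd1 <- crossprod(AC, dP1)
  dC <- (An %*% dP1) %*% t(params$Wd1)
  dZ <- dZs / 2 + dC[, 1:2, drop = FALSE]
  dmu <- dZ + mu / n
  dlv <- dZ * eps * 0.5 * sig + 0.5 * (exp(lv) - 1) / n
  gWmu <- crossprod(AH, dmu)
  gWsig <- crossprod(AH, dlv)
  dH <- (An %*% (dmu %*% t(params$W_mu) + dlv %*% t(params$W_sig))) * (H > 0)
  gWg1 <- crossprod(AX, dH)
  grads <- list(Wg1 = gWg1, W_mu = gWmu, W_sig = gWsig, Wd1 = gWd1, Wd2 = gWd2)

  h <- 1e-6
  for (nm in names(grads)) {
    for (ii in 1:2) {
      p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + h
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - h
      num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("link calling thresholds, tops and separates input pairs", {
  P <- rbind(c(0.0, 0.9, 0.2, 0.7),
             c(0.9, 0.0, 0.6, 0.1),
             c(0.2, 0.6, 0.0, 0.8),
             c(0.7, 0.1, 0.8, 0.0))
  g <- cell_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                        c(0, 0, 0, 0), c(0, 0, 0, 0)))
  res <- predict_links(P, threshold = 0.5, input_graph = g)
  # pair (1,2) is a training edge; novel >= 0.5 are (3,4)=0.8, (1,4)=0.7, (2,3)=0.6
  expect_equal(res$input$from, 1)
  expect_equal(res$input$to, 2)
  expect_equal(res$novel$score, c(0.8, 0.7, 0.6))
  expect_equal(res$novel$from, c(3, 1, 2))
  expect_equal(res$novel$to, c(4, 4, 3))
  top <- predict_links(P, top_q = 2, input_graph = g)
  expect_equal(nrow(top$novel), 2)
  expect_equal(top$novel$score, c(0.8, 0.7))
  # without an input graph everything is novel
  all_novel <- predict_links(P, threshold = 0)
  expect_equal(nrow(all_novel$novel), 6)
  expect_equal(all_novel$novel$score, sort(P[upper.tri(P)], decreasing = TRUE))
})

test_that("graph TSV round-trip preserves the adjacency", {
  set.seed(67)
  A <- matrix(rbinom(36, 1, 0.3), 6)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  ids <- sprintf("c%02d", 1:6)
  g <- cell_graph(A, cell_ids = ids)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, path)
  back <- read_graph(path, ids)
  expect_equal(back$A, g$A)
  expect_error(read_graph(path, ids[1:3]), "unknown")
})

test_that("self-loop bookkeeping is explicit", {
  g <- cell_graph(matrix(c(0, 1, 1, 0), 2))
  expect_equal(g$self_loop_state, "without")
  gl <- add_self_loops(g)
  expect_equal(gl$self_loop_state, "with")
  expect_equal(unname(diag(gl$A)), c(1, 1))
  # graph_edges never reports self-loops
  expect_equal(nrow(graph_edges(gl)), 1)
  expect_error(cell_graph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(cell_graph(matrix(c(0, 2, 2, 0), 2)), "binary")
})
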