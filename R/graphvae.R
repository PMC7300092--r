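# Graph-DiffVAE: a variational autoencoder whose encoder and decoder are
# graph convolutional networks over a cell-cell graph. The encoder maps
# (adjacency, expression) to per-node Gaussian latent features; the decoder
# concatenates latent and input features, builds its own latent
# representation Z', and scores every cell pair with the inner product of
# Z* = (Z + Z') / 2 through a logistic link.

#' Cell graph container
#'
#' Symmetric binary adjacency over cells. Self-loops are not stored; they
#' are added only for GCN propagation (see [add_self_loops()] and
#' [normalize_adjacency()]).
#'
#' @param A Square binary matrix (or object coercible to one); symmetrized
#'   entries must match.
#' @param cell_ids Optional node identifiers.
#' @param self_loop_state `"without"` (default, diagonal zeroed) or `"with"`.
#' @return An object of class `cell_graph` with fields `A`, `self_loop_state`,
#'   `cell_ids`, `degrees`.
#' @export
cell_graph <- function(A, cell_ids = NULL, self_loop_state = c("without", "with")) {
  self_loop_state <- match.arg(self_loop_state)
  A <- as.matrix(A)
  .assert(nrow(A) == ncol(A), "adjacency must be square")
  .assert(all(A %in% c(0, 1)), "adjacency must be binary")
  .assert(isTRUE(all.equal(A, t(A))), "adjacency must be symmetric")
  if (self_loop_state == "without") {
    diag(A) <- 0
  } else {
    .assert(all(diag(A) == 1), "self_loop_state 'with' requires a unit diagonal")
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(A)))
  dimnames(A) <- list(cell_ids, cell_ids)
  structure(list(A = A, self_loop_state = self_loop_state,
                 cell_ids = cell_ids, degrees = rowSums(A)),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d undirected edges (%s self-loops)\n",
              nrow(x$A), sum(x$A[upper.tri(x$A)] > 0) ,
              x$self_loop_state))
  invisible(x)
}

#' Add self-loops to a cell graph
#' @param graph A [cell_graph()].
#' @return A `cell_graph` with unit diagonal.
#' @export
add_self_loops <- function(graph) {
  A <- graph$A
  diag(A) <- 1
  cell_graph(A, cell_ids = graph$cell_ids, self_loop_state = "with")
}

#' Edge list of a cell graph
#' @param graph A [cell_graph()].
#' @return Data frame with columns `from`, `to` (indices, `from < to`).
#' @export
graph_edges <- function(graph) {
  idx <- which(upper.tri(graph$A) & graph$A == 1, arr.ind = TRUE)
  data.frame(from = idx[, 1L], to = idx[, 2L])
}

#' Build the correlation-based initial cell graph
#'
#' For every cell, the Pearson correlation between its expression vector and
#' every other cell's is computed, and an edge is added to the most
#' positively correlated cell (only if that correlation is positive). The
#' union of these per-cell picks is symmetrized into an undirected binary
#' graph. Zero-variance cells have undefined correlations and are left
#' isolated with a warning. Ties go to the lowest cell index.
#'
#' @param expr An [expression_matrix()] (any scale state).
#' @return A [cell_graph()] without self-loops.
#' @export
correlation_graph <- function(expr) {
  X <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  n <- nrow(X)
  .assert(n >= 2, "need at least two cells")
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance cell(s) left isolated", sum(sds == 0)))
  }
  C <- suppressWarnings(stats::cor(t(X)))
  diag(C) <- -Inf
  C[!is.finite(C)] <- -Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    best <- which.max(C[i, ]) # ties: lowest index
    if (is.finite(C[i, best]) && C[i, best] > 0) {
      A[i, best] <- 1
      A[best, i] <- 1
    }
  }
  ids <- if (inherits(expr, "expression_matrix")) expr$cell_ids else rownames(X)
  cell_graph(A, cell_ids = ids)
}

#' Symmetric adjacency normalization
#'
#' Adds self-loops if absent, then returns
#' `D^(-1/2) A D^(-1/2)` with `D` the diagonal degree matrix. All
#' eigenvalues of the result lie in `[-1, 1]`.
#'
#' @param graph A [cell_graph()] (or square adjacency matrix).
#' @return The normalized adjacency matrix.
#' @export
normalize_adjacency <- function(graph) {
  A <- if (inherits(graph, "cell_graph")) graph$A else as.matrix(graph)
  diag(A) <- 1
  d <- rowSums(A)
  inv_sqrt <- 1 / sqrt(d)
  A * outer(inv_sqrt, inv_sqrt)
}

#' One graph convolution layer
#'
#' `X' = activation(A_norm %*% X %*% W)` - the layer-wise propagation rule,
#' with no bias term.
#'
#' @param A_norm Normalized adjacency ([normalize_adjacency()]).
#' @param X Node feature matrix (`N x F`).
#' @param W Weight matrix (`F x F'`).
#' @param activation `"relu"` or `"linear"`.
#' @return `N x F'` matrix of updated node features.
#' @export
gcn_layer <- function(A_norm, X, W, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  .assert(ncol(A_norm) == nrow(X) && ncol(X) == nrow(W),
          "non-conformable shapes in gcn_layer")
  out <- A_norm %*% X %*% W
  if (activation == "relu") .relu(out) else out
}

#' Graph-DiffVAE configuration
#'
#' Defaults: 512 hidden node features, 50 latent
#' node features, Adam with learning rate 0.0001 for 200 epochs of
#' full-graph training.
#'
#' @param hidden_features Hidden GCN width.
#' @param latent_features Latent node-feature width `M`.
#' @param learning_rate,epochs Adam training parameters.
#' @param edge_pos_weight Weight of positive entries in the adjacency
#'   cross-entropy; `NULL` (default) uses `#zeros / #ones` of the training
#'   adjacency to counter edge sparsity, `1` reproduces the unweighted
#'   objective.
#' @param seed Integer seed.
#' @return An object of class `graphvae_config`.
#' @export
graphvae_config <- function(hidden_features = 512, latent_features = 50,
                            learning_rate = 1e-4, epochs = 200,
                            edge_pos_weight = NULL, seed = 1) {
  .assert(hidden_features >= 1 && latent_features >= 1 && epochs >= 0,
          "sizes must be positive")
  structure(list(hidden_features = as.integer(hidden_features),
                 latent_features = as.integer(latent_features),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 edge_pos_weight = edge_pos_weight, seed = as.integer(seed)),
            class = "graphvae_config")
}

.graphvae_init <- function(F_in, config) {
  h <- config$hidden_features
  M <- config$latent_features
  list(Wg1 = .glorot(F_in, h),
       W_mu = .glorot(h, M),
       W_sig = .glorot(h, M),
       Wd1 = .glorot(M + F_in, h),
       Wd2 = .glorot(h, M))
}

#' Graph encoder: per-node Gaussian posterior
#'
#' One shared ReLU GCN layer followed by two linear GCN heads for the mean
#' and log-variance of each node's latent features.
#'
#' @param model A trained `graphvae_model` (or a list with `params` and
#'   `config`).
#' @param graph A [cell_graph()].
#' @param X Node feature matrix (cells x genes).
#' @return List with `mu` and `log_var`, each `N x M`.
#' @export
graph_encode <- function(model, graph, X) {
  An <- normalize_adjacency(graph)
  p <- model$params
  H <- gcn_layer(An, X, p$Wg1, "relu")
  list(mu = gcn_layer(An, H, p$W_mu, "linear"),
       log_var = gcn_layer(An, H, p$W_sig, "linear"))
}

#' Graph decoder: predicted edge probabilities
#'
#' A ReLU GCN layer on the concatenation `[Z | X]`, a second ReLU GCN layer
#' producing the decoder's own latent features `Z'`, then
#' `Z* = (Z' + Z) / 2` and `A_hat = sigmoid(Z* %*% t(Z*))` - a symmetric
#' matrix of pairwise edge probabilities in `(0, 1)`.
#'
#' @inheritParams graph_encode
#' @param Z Latent node features (`N x M`).
#' @return An object of class `predicted_graph`: list with `A_hat`, `Z`,
#'   `Z_prime`, `Z_star` and `cell_ids`.
#' @export
graph_decode <- function(model, graph, X, Z) {
  An <- normalize_adjacency(graph)
  p <- model$params
  C <- cbind(Z, X)
  D1 <- gcn_layer(An, C, p$Wd1, "relu")
  Zp <- gcn_layer(An, D1, p$Wd2, "relu")
  Zs <- (Zp + Z) / 2
  A_hat <- .sigmoid(tcrossprod(Zs))
  structure(list(A_hat = A_hat, Z = Z, Z_prime = Zp, Z_star = Zs,
                 cell_ids = graph$cell_ids),
            class = "predicted_graph")
}

#' Graph-DiffVAE training loss
#'
#' Edge-weighted Bernoulli negative log-likelihood of the target adjacency
#' under the predicted edge probabilities, plus the closed-form Gaussian KL
#' of the per-node posteriors to the standard-normal prior; both terms are
#' averaged per node.
#'
#' @param A_target Target adjacency (with self-loops, as propagated).
#' @param A_hat Predicted edge probabilities in `(0, 1)`.
#' @param mu,log_var Encoder outputs.
#' @param edge_pos_weight Weight of the positive (edge) entries.
#' @return Scalar loss (to minimize).
#' @export
graphvae_loss <- function(A_target, A_hat, mu, log_var, edge_pos_weight = 1) {
  N <- nrow(A_target)
  P <- pmin(pmax(A_hat, .NLL_EPS), 1 - .NLL_EPS)
  nll <- -sum(edge_pos_weight * A_target * log(P) +
                (1 - A_target) * log(1 - P)) / N
  nll + gaussian_kl_total(mu, log_var) / N
}

# Summed (not averaged) Gaussian KL, internal helper for per-node averaging.
gaussian_kl_total <- function(mu, log_var) {
  0.5 * sum(mu^2 + exp(log_var) - 1 - log_var)
}

#' Train Graph-DiffVAE
#'
#' Full-graph (non-minibatched) Adam optimization of [graphvae_loss()]. The
#' reconstruction target is the propagated adjacency (input graph plus
#' self-loops). One reparameterised latent sample is drawn per epoch. All
#' randomness flows from `config$seed`.
#'
#' @param expr An [expression_matrix()] providing node features.
#' @param graph A [cell_graph()] over the same cells.
#' @param config A [graphvae_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (class `graphvae_model`), `predicted` (a
#'   `predicted_graph` from the posterior mean) and `loss_history`.
#' @export
train_graph_diffvae <- function(expr, graph, config = graphvae_config(),
                                verbose = FALSE) {
  X <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  .assert(nrow(X) == nrow(graph$A), "graph and expression cover different cells")
  An <- normalize_adjacency(graph)
  A_target <- graph$A
  diag(A_target) <- 1
  w <- config$edge_pos_weight
  if (is.null(w)) w <- sum(A_target == 0) / sum(A_target == 1)
  N <- nrow(X)
  M <- config$latent_features

  fit <- .with_seed(config$seed, {
    params <- .graphvae_init(ncol(X), config)
    opt <- .adam_init(params)
    history <- numeric(0)
    AX <- An %*% X
    for (epoch in seq_len(config$epochs)) {
      # encoder forward
      H <- .relu(AX %*% params$Wg1)
      AH <- An %*% H
      mu <- AH %*% params$W_mu
      lv <- AH %*% params$W_sig
      eps <- matrix(stats::rnorm(N * M), N, M)
      sig <- exp(lv / 2)
      Z <- mu + eps * sig
      # decoder forward
      C <- cbind(Z, X)
      AC <- An %*% C
      P1 <- AC %*% params$Wd1
      D1 <- .relu(P1)
      AD1 <- An %*% D1
      P2 <- AD1 %*% params$Wd2
      Zp <- .relu(P2)
      Zs <- (Zp + Z) / 2
      S <- tcrossprod(Zs)
      A_hat <- .sigmoid(S)

      Pc <- pmin(pmax(A_hat, .NLL_EPS), 1 - .NLL_EPS)
      loss <- -sum(w * A_target * log(Pc) + (1 - A_target) * log(1 - Pc)) / N +
        gaussian_kl_total(mu, lv) / N
      if (!is.finite(loss)) {
        stop(sprintf("non-finite Graph-DiffVAE loss at epoch %d", epoch),
             call. = FALSE)
      }

      # backward
      G <- (A_hat * (1 - A_target) - w * A_target * (1 - A_hat)) / N
      dZs <- (G + t(G)) %*% Zs
      dP2 <- (dZs / 2) * (P2 > 0)
      gWd2 <- crossprod(AD1, dP2)
      dD1 <- (An %*% dP2) %*% t(params$Wd2)
      dP1 <- dD1 * (P1 > 0)
      gWd1 <- crossprod(AC, dP1)
      dC <- (An %*% dP1) %*% t(params$Wd1)
      dZ <- dZs / 2 + dC[, seq_len(M), drop = FALSE]
      dmu <- dZ + mu / N
      dlv <- dZ * eps * 0.5 * sig + 0.5 * (exp(lv) - 1) / N
      gWmu <- crossprod(AH, dmu)
      gWsig <- crossprod(AH, dlv)
      dH <- (An %*% (dmu %*% t(params$W_mu) + dlv %*% t(params$W_sig))) * (H > 0)
      gWg1 <- crossprod(AX, dH)

      grads <- list(Wg1 = gWg1, W_mu = gWmu, W_sig = gWsig,
                    Wd1 = gWd1, Wd2 = gWd2)
      step <- .adam_update(params, grads, opt, config$learning_rate)
      params <- step$params
      opt <- step$state
      history <- c(history, loss)
      .msg(sprintf("graph epoch %3d loss %.5f", epoch, loss), verbose = verbose)
    }
    list(params = params, history = history)
  })

  model <- structure(
    list(params = fit$params, config = config, edge_pos_weight = w,
         cell_ids = graph$cell_ids),
    class = "graphvae_model"
  )
  post <- graph_encode(model, graph, X)
  predicted <- graph_decode(model, graph, X, post$mu)
  list(model = model, predicted = predicted, loss_history = fit$history)
}

#' Call predicted links from an edge-probability matrix
#'
#' Returns undirected pairs (`i < j`, diagonal excluded) either with
#' probability at least `threshold`, or the `top_q` highest-scoring pairs.
#' Pairs present in `input_graph` are reported separately from novel ones.
#'
#' @param predicted A `predicted_graph` or a square probability matrix.
#' @param threshold Probability cutoff (default 0.5; ignored when `top_q`
#'   is given).
#' @param top_q Return the `top_q` highest-scoring non-input pairs instead
#'   of thresholding.
#' @param input_graph Optional [cell_graph()] of training edges.
#' @return List of data frames `novel` and `input`, each with columns
#'   `from`, `to`, `score` (novel pairs sorted by decreasing score).
#' @export
predict_links <- function(predicted, threshold = 0.5, top_q = NULL,
                          input_graph = NULL) {
  A_hat <- if (inherits(predicted, "predicted_graph")) predicted$A_hat else as.matrix(predicted)
  n <- nrow(A_hat)
  ut <- which(upper.tri(A_hat), arr.ind = TRUE)
  scores <- A_hat[upper.tri(A_hat)]
  df <- data.frame(from = ut[, 1L], to = ut[, 2L], score = scores)
  is_input <- rep(FALSE, nrow(df))
  if (!is.null(input_graph)) {
    is_input <- input_graph$A[cbind(df$from, df$to)] == 1
  }
  input <- df[is_input, , drop = FALSE]
  novel <- df[!is_input, , drop = FALSE]
  novel <- novel[order(-novel$score, novel$from, novel$to), , drop = FALSE]
  if (!is.null(top_q)) {
    novel <- utils::head(novel, top_q)
  } else {
    novel <- novel[novel$score >= threshold, , drop = FALSE]
  }
  rownames(novel) <- NULL
  rownames(input) <- NULL
  list(novel = novel, input = input)
}

#' Write / read a graph as a two-column edge-list TSV
#' @param graph A [cell_graph()].
#' @param path Output path.
#' @export
write_graph <- function(graph, path) {
  e <- graph_edges(graph)
  utils::write.table(
    data.frame(cell_id_a = graph$cell_ids[e$from], cell_id_b = graph$cell_ids[e$to]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @param cell_ids Node universe (needed to size the adjacency).
#' @export
read_graph <- function(path, cell_ids) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  n <- length(cell_ids)
  A <- matrix(0, n, n)
  i <- match(df[[1L]], cell_ids)
  j <- match(df[[2L]], cell_ids)
  .assert(!anyNA(i) && !anyNA(j), "edge list refers to unknown cell ids")
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  cell_graph(A, cell_ids = cell_ids)
}
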