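# Shared fixtures, memoized so expensive objects (trained models) are built
# once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(name, value) {
  if (is.null(.fix[[name]])) .fix[[name]] <- value
  .fix[[name]]
}

# The 4-cluster benchmark fixture: 500 cells x 200 genes, 10 markers per
# cluster with a 3 log-unit effect over baseline 1, noise sd 0.5.
fixture_dataset <- function() memo("ds", generate_expression(synthetic_spec(seed = 7)))

fixture_scaled <- function() memo("scaled", minmax_scale(fixture_dataset()$expression,
                                                         verbose = FALSE))

fixture_model <- function() {
  memo("model", train_diffvae(fixture_scaled(), diffvae_config(m = 20, epochs = 40,
                                                               seed = 11)))
}

fixture_latent <- function() memo("latent", get_latent(fixture_model(), fixture_scaled()))

# Progenitor fixture: 4 mature clusters plus a progenitor population whose
# centroid is the average of the mature centroids.
fixture_prog <- function() {
  memo("prog", {
    ds <- generate_expression(synthetic_spec(n_clusters = 5,
                                             progenitor_fraction = 0.2, seed = 21))
    expr <- minmax_scale(ds$expression, verbose = FALSE)
    list(ds = ds, expr = expr)
  })
}

fixture_prog_model <- function() {
  memo("prog_model",
       train_diffvae(fixture_prog()$expr, diffvae_config(m = 20, epochs = 40, seed = 5)))
}

fixture_prog_classifier <- function() {
  memo("prog_clf", {
    p <- fixture_prog()
    mature <- p$ds$labels != p$ds$progenitor_cluster
    train_classifier(
      expression_matrix(p$expr$values[mature, , drop = FALSE],
                        scale_state = "unit_scaled"),
      p$ds$labels[mature], classifier_config(epochs = 60, seed = 6))
  })
}

# A small model with every weight set to `fill` and zero biases; batch norm
# disabled so layer outputs can be hand-evaluated.
toy_model <- function(k = 1, h1 = 1, h2 = 1, m = 1, fill = 1,
                      head_activation = "relu", kind = "diffvae") {
  config <- diffvae_config(h1 = h1, h2 = h2, m = m, use_batchnorm = FALSE,
                           head_activation = head_activation, epochs = 0)
  const <- function(a, b) matrix(fill, a, b)
  params <- list(
    enc_W1 = const(k, h2), enc_b1 = rep(0, h2),
    enc_W2 = const(h2, h1), enc_b2 = rep(0, h1),
    W_mu = const(h1, m), b_mu = rep(0, m),
    W_sig = const(h1, m), b_sig = rep(0, m),
    dec_W1 = const(m, h1), dec_b1 = rep(0, h1),
    dec_W2 = const(h1, h2), dec_b2 = rep(0, h2),
    W_out = const(h2, k), b_out = rep(0, k)
  )
  structure(list(params = params, bn = NULL, config = config, kind = kind,
                 loss_history = numeric(0),
                 gene_names = sprintf("gene_%d", seq_len(k))),
            class = c("diffvae_model", "sc_autoencoder"))
}

# Hand-built linear softmax classifier: class scores = X %*% W + b.
toy_classifier <- function(W, b = NULL, classes = NULL) {
  W <- as.matrix(W)
  if (is.null(b)) b <- rep(0, ncol(W))
  if (is.null(classes)) classes <- paste0("class_", seq_len(ncol(W)))
  structure(list(params = list(W = list(W), b = list(b)),
                 classes = classes,
                 config = classifier_config(epochs = 0)),
            class = "cell_classifier")
}

expect_same_matrix <- function(a, b, tol = 0) {
  expect_true(max(abs(a - b)) <= tol)
}
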