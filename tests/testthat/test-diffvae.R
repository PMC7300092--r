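test_that("encoder matches hand evaluation on a 1-unit toy network", {
  m <- toy_model(fill = 1)
  # x = 0.5 -> each affine step multiplies by 1: hidden 0.5, 0.5; mu = ReLU(0.5)
  out <- encode(m, 0.5)
  expect_equal(drop(out$mu), 0.5)
  expect_equal(drop(out$log_var), 0.5)

  zero <- toy_model(k = 3, h1 = 2, h2 = 4, m = 2, fill = 0)
  out0 <- encode(zero, matrix(runif(6), 2, 3))
  expect_true(all(out0$mu == 0) && all(out0$log_var == 0))
})

test_that("encode output shapes follow the batch and latent sizes", {
  m <- toy_model(k = 5, h1 = 3, h2 = 4, m = 50, fill = 0.01)
  out <- encode(m, matrix(runif(35), 7, 5))
  expect_equal(dim(out$mu), c(7, 50))
  expect_equal(dim(out$log_var), c(7, 50))
  expect_error(encode(m, matrix(1, 2, 4)), "width")
})

test_that("reparameterisation is the documented affine transform", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(0, 0, 1), 1)
  expect_equal(reparameterize(2, log(4), 0.5), 3)
})

test_that("decoder matches hand evaluation and stays in (0, 1)", {
  zero <- toy_model(k = 4, h1 = 2, h2 = 3, m = 2, fill = 0)
  expect_equal(unname(decode(zero, c(0.3, -0.2))), matrix(0.5, 1, 4))

  one <- toy_model(fill = 1)
  expect_equal(unname(drop(decode(one, 1))), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  set.seed(4)
  model <- train_diffvae(
    minmax_scale(expression_matrix(matrix(runif(80), 20, 4)), verbose = FALSE),
    diffvae_config(h1 = 4, m = 2, batch_size = 10, epochs = 1, seed = 2))
  out <- decode(model, matrix(rnorm(10), 5, 2))
  expect_true(all(out > 0 & out < 1))
})

test_that("mmd reproduces the 1-D closed form and basic identities", {
  # q = {0}, p = {1}, kernel exp(-(a-b)^2): k(0,0)+k(1,1)-2k(0,1)
  expect_equal(mmd(0, 1, bandwidths = 1), 2 - 2 * exp(-1), tolerance = 1e-12)
  set.seed(11)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(15), 5, 3)
  expect_equal(mmd(A, A), 0, tolerance = 1e-12)
  expect_equal(mmd(A, B), mmd(B, A), tolerance = 1e-12)
  expect_gte(mmd(A, B), 0)
  expect_error(mmd(A[0, , drop = FALSE], B), "empty")
})

test_that("mmd agrees with a brute-force double-loop kernel sum", {
  brute_mmd <- function(q, p, bws) {
    kf <- function(a, b, l) exp(-sum((a - b)^2) / l^2)
    tot <- 0
    for (l in bws) {
      s1 <- 0; s2 <- 0; s3 <- 0
      for (i in seq_len(nrow(q))) for (j in seq_len(nrow(q)))
        s1 <- s1 + kf(q[i, ], q[j, ], l)
      for (i in seq_len(nrow(p))) for (j in seq_len(nrow(p)))
        s2 <- s2 + kf(p[i, ], p[j, ], l)
      for (i in seq_len(nrow(q))) for (j in seq_len(nrow(p)))
        s3 <- s3 + kf(q[i, ], p[j, ], l)
      tot <- tot + s1 / nrow(q)^2 + s2 / nrow(p)^2 - 2 * s3 / (nrow(q) * nrow(p))
    }
    tot
  }
  set.seed(12)
  for (rep in 1:3) {
    q <- matrix(rnorm(5 * 2), 5, 2)
    p <- matrix(rnorm(4 * 2), 4, 2)
    bws <- c(0.5, 1, 2)
    expect_equal(mmd(q, p, bws), brute_mmd(q, p, bws), tolerance = 1e-10)
  }
})

test_that("diffvae loss reproduces hand values and entropy lower bound", {
  z <- matrix(0, 2, 2)
  expect_equal(diffvae_loss(matrix(c(0, 1), 1), matrix(c(0, 1), 1),
                            z, z, mmd_weight = 1), 0, tolerance = 1e-5)
  expect_equal(diffvae_loss(matrix(0.5, 1, 1), matrix(0.5, 1, 1), z, z,
                            mmd_weight = 0), log(2), tolerance = 1e-12)
  # cross-entropy >= binary entropy of the targets
  set.seed(13)
  x <- matrix(runif(20), 4, 5)
  xp <- matrix(runif(20), 4, 5)
  entropy <- -sum(x * log(x) + (1 - x) * log(1 - x)) / 4
  expect_gte(diffvae_loss(x, xp, z, z, mmd_weight = 0), entropy)
})

test_that("analytic training gradient matches finite differences", {
  set.seed(42)
  k <- 6
  cfg <- diffvae_config(h1 = 4, h2 = 5, m = 3, batch_size = 4, epochs = 1,
                        seed = 3, use_batchnorm = TRUE, head_activation = "relu")
  X <- matrix(runif(4 * k), 4, k)
  init <- scDiffVAE:::.init_autoencoder_params(k, cfg, "diffvae")
  params <- scDiffVAE:::.flatten_bn(init$params, init$bn)
  bn <- init$bn
  eps <- matrix(rnorm(12), 4, 3)
  prior <- matrix(rnorm(12), 4, 3)
  bws <- scDiffVAE:::.default_bandwidths(cfg$m)

  loss_at <- function(p) {
    b <- scDiffVAE:::.sync_bn(p, bn)
    enc <- scDiffVAE:::.enc_fwd(p, b, X, cfg, training = TRUE, kind = "diffvae")
    Z <- enc$mu + eps * exp(enc$log_var / 2)
    dec <- scDiffVAE:::.dec_fwd(p, Z)
    scDiffVAE:::.bce(X, dec$Xp) + mmd(Z, prior, bws)
  }

  enc <- scDiffVAE:::.enc_fwd(params, bn, X, cfg, training = TRUE, kind = "diffvae")
  Z <- enc$mu + eps * exp(enc$log_var / 2)
  dec <- scDiffVAE:::.dec_fwd(params, Z)
  back <- scDiffVAE:::.dec_bwd(params, dec$cache, (dec$Xp - X) / 4)
  dZ <- back$dZ + scDiffVAE:::.mmd_grad_q(Z, prior, bws)
  genc <- scDiffVAE:::.enc_bwd(params, cfg, enc$cache, dZ,
                               dZ * eps * 0.5 * exp(enc$log_var / 2), "diffvae")
  grads <- c(back$grads, genc)

  h <- 1e-6
  for (nm in c("enc_W1", "W_mu", "W_sig", "dec_W1", "W_out", "bn1_gamma")) {
    for (ii in 1:2) {
      p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + h
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - h
      num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-3)
    }
  }
})

test_that("training runs, reduces the loss, and is seed-deterministic", {
  expr <- minmax_scale(
    generate_expression(synthetic_spec(n_cells = 120, n_genes = 40,
                                       n_clusters = 3, markers_per_cluster = 5,
                                       seed = 2))$expression, verbose = FALSE)
  cfg <- diffvae_config(h1 = 16, m = 5, batch_size = 32, epochs = 8, seed = 4)

  m0 <- train_diffvae(expr, diffvae_config(h1 = 16, m = 5, epochs = 0, seed = 4))
  expect_length(m0$loss_history, 0)

  m1 <- train_diffvae(expr, cfg)
  expect_lt(m1$loss_history[8], m1$loss_history[1])

  m2 <- train_diffvae(expr, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("latent extraction matches independent column statistics", {
  lat <- get_latent(fixture_model(), fixture_scaled())
  expect_equal(dim(lat$z_means), c(500, 20))
  k <- 7
  expect_equal(lat$dim_means[k], mean(lat$z_means[, k]), tolerance = 1e-12)
  sd_pop <- sqrt(mean((lat$z_means[, k] - mean(lat$z_means[, k]))^2))
  expect_equal(lat$dim_sds[k], sd_pop, tolerance = 1e-12)

  zero <- toy_model(k = 4, h1 = 2, h2 = 3, m = 2, fill = 0)
  expr <- expression_matrix(matrix(runif(12), 3, 4), scale_state = "unit_scaled")
  lat0 <- get_latent(zero, expr)
  expect_true(all(lat0$z_means == 0) && all(lat0$dim_sds == 0))
})

test_that("checkpoint round-trip reproduces encodings bit for bit", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  x <- fixture_scaled()$values[1:5, , drop = FALSE]
  expect_identical(encode(model, x), encode(back, x))
})

test_that("hyperparameter search picks the trained configuration", {
  expr <- minmax_scale(
    generate_expression(synthetic_spec(n_cells = 100, n_genes = 30,
                                       n_clusters = 2, markers_per_cluster = 5,
                                       seed = 3))$expression, verbose = FALSE)
  untrained <- diffvae_config(h1 = 8, m = 4, batch_size = 32, epochs = 0, seed = 1)
  trained <- diffvae_config(h1 = 8, m = 4, batch_size = 32, epochs = 10, seed = 1)
  best <- hyperparameter_search(expr, list(untrained, trained), seed = 5)
  expect_equal(best$epochs, 10L)
  single <- hyperparameter_search(expr, list(untrained), seed = 5)
  expect_equal(single$epochs, 0L)
})
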