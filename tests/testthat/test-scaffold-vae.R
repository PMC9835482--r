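# The scaffold VAE: embedding, gated convolutions, latent heads,
# reparameterization, decoder, KL.

test_that("embedding equals the explicit matrix product for one-hot input", {
  set.seed(1)
  v <- 7; d <- 5; l <- 4
  E1 <- matrix(rnorm(v * d), v, d)
  P1 <- matrix(rnorm(128 * d), 128, d)
  X <- matrix(0, l, v)
  X[cbind(1:l, c(2, 5, 1, 7))] <- 1
  out <- embed_source(X, E1, P1)
  expect_equal(out, X %*% E1 + P1[1:l, ])        # brute-force product
  expect_equal(out, E1[c(2, 5, 1, 7), ] + P1[1:l, ])  # lookup view
  expect_error(embed_source(X, E1[1:3, ]), "shape mismatch")
})

test_that("gated conv block reduces to the residual for zero kernels and saturates", {
  set.seed(2)
  l <- 5; d <- 3; k <- 3
  A <- matrix(rnorm(l * d), l, d)
  zero <- array(0, c(k, d, d))
  expect_equal(gated_conv_block(A, zero, rep(0, d), zero, rep(0, d)), A)
  # gate saturation: huge c2 makes the gate 1, so out = A + (A*U1 + c1)
  U1 <- array(rnorm(k * d * d, sd = 0.3), c(k, d, d))
  big <- gated_conv_block(A, U1, rep(0.5, d), zero, rep(50, d))
  lin <- gated_conv_block(A, U1, rep(0.5, d), zero, rep(0, d))  # gate = 1/2
  expect_equal(big - A, 2 * (lin - A), tolerance = 1e-6)
})

test_that("gated conv block matches a nested-loop convolution oracle", {
  set.seed(3)
  l <- 5; d <- 3; k <- 3
  A <- matrix(rnorm(l * d), l, d)
  U1 <- array(rnorm(k * d * d), c(k, d, d))
  U2 <- array(rnorm(k * d * d), c(k, d, d))
  c1 <- rnorm(d); c2 <- rnorm(d)
  conv_loop <- function(A, U, cc) {
    half <- (k - 1) / 2
    out <- matrix(0, l, d)
    for (t in 1:l) for (f_out in 1:d) {
      acc <- cc[f_out]
      for (j in 1:k) {
        tt <- t + (j - 1 - half)
        if (tt >= 1 && tt <= l)
          for (f_in in 1:d) acc <- acc + A[tt, f_in] * U[j, f_in, f_out]
      }
      out[t, f_out] <- acc
    }
    out
  }
  expected <- A + conv_loop(A, U1, c1) * plogis(conv_loop(A, U2, c2))
  expect_equal(gated_conv_block(A, U1, c1, U2, c2), expected,
               tolerance = 1e-6)
})

test_that("latent heads have dimension dz and zero weights give the biases", {
  vocab <- build_vocabulary(fixture_smiles())
  cfg <- fixture_config()
  params <- scaffdec:::init_params(cfg, vocab$v, seed = 8)$vae
  X <- encode_onehot("CCO", vocab, cfg$L_max)
  lat <- encode_to_latent(X, params)
  expect_length(lat$mu, cfg$dz)
  expect_length(lat$log_var, cfg$dz)
  zp <- rapply(params, function(x) x * 0, how = "replace")
  zp$b1 <- seq_len(cfg$dz) * 1.0
  zp$b2 <- -seq_len(cfg$dz) * 1.0
  lat0 <- encode_to_latent(X, zp)
  expect_equal(lat0$mu, zp$b1)
  expect_equal(lat0$log_var, zp$b2)
})

test_that("pad content cannot leak through the masked max-pooling", {
  vocab <- build_vocabulary(fixture_smiles())
  cfg <- fixture_config()
  params <- scaffdec:::init_params(cfg, vocab$v, seed = 8)$vae
  X <- encode_onehot("CCO", vocab, cfg$L_max)
  lat <- encode_to_latent(X, params)
  # rewrite the pad tail with arbitrary tokens; mask means same posterior
  X2 <- X
  X2$ids[(X$length + 1):cfg$L_max] <- 5L
  lat2 <- encode_to_latent(X2, params)
  expect_equal(lat2$mu, lat$mu)
  expect_equal(lat2$log_var, lat$log_var)
})

test_that("reparameterization is the componentwise affine transform", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(c(0, 0), c(0, 0), c(1.3, -0.2)), c(1.3, -0.2))
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(1, -1)), c(2, 1))
  expect_error(reparameterize(1:2, 1:3, 1:2), "length mismatch")
})

test_that("decoder output is row-stochastic, deterministic, uniform at zero weights", {
  vocab <- build_vocabulary(fixture_smiles())
  cfg <- fixture_config()
  params <- scaffdec:::init_params(cfg, vocab$v, seed = 8)$vae
  z <- rnorm(cfg$dz)
  P <- decode_from_latent(z, params)
  expect_equal(dim(P), c(cfg$L_max, vocab$v))
  expect_equal(rowSums(P), rep(1, cfg$L_max), tolerance = 1e-6)
  expect_identical(P, decode_from_latent(z, params))
  zp <- rapply(params, function(x) x * 0, how = "replace")
  expect_equal(decode_from_latent(z, zp),
               matrix(1 / vocab$v, cfg$L_max, vocab$v))
  expect_error(decode_from_latent(rnorm(cfg$dz + 1), params), "expected dz")
})

test_that("KL divergence matches the closed form and its zero point", {
  expect_equal(kl_divergence(rep(0, 64), rep(0, 64)), 0)
  expect_equal(kl_divergence(rep(1, 64), rep(0, 64)), 32)
  expect_equal(kl_divergence(0, 1), (exp(1) - 2) / 2)
  expect_error(kl_divergence(1:3, 1:2), "length mismatch")
  # non-negative and monotone in |mu|
  set.seed(4)
  for (i in 1:20) {
    mu <- rnorm(8); lv <- rnorm(8)
    expect_gte(kl_divergence(mu, lv), 0)
    expect_gt(kl_divergence(mu * 2, lv), kl_divergence(mu, lv))
  }
})
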