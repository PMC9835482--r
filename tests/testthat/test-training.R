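# Schedules, loss composition, and the optimization loop.

test_that("the KL-weight schedule has the printed plateau, staircase and cap", {
  expect_equal(gamma_schedule(0), 0.001)
  expect_equal(gamma_schedule(40000), 0.001)
  expect_equal(gamma_schedule(44999), 0.001)
  expect_equal(gamma_schedule(45000), 0.0011)
  expect_equal(gamma_schedule(1e6), 0.01)
  steps <- seq(0, 6e5, by = 1000)
  g <- gamma_schedule(steps)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0.001 & g <= 0.01))
  expect_error(gamma_schedule(-1), "negative")
})

test_that("the warm-up learning rate peaks at step 10000 for any d", {
  expect_equal(lr_schedule(10000, 256), 0.000625)
  expect_equal(lr_schedule(2500, 256), 0.00015625)
  for (d in c(32, 64, 256)) {
    lr <- lr_schedule(1:50000, d)
    expect_equal(which.max(lr), 10000)
    # unimodal: rising before the peak, falling after
    expect_true(all(diff(lr[1:10000]) > 0))
    expect_true(all(diff(lr[10000:50000]) < 0))
  }
  expect_error(lr_schedule(0, 256), "step")
})

test_that("the joint loss decomposes as gamma*KL + vae CE + transformer CE", {
  v <- build_vocabulary("CCO", include_scaffolds = FALSE)
  X <- encode_onehot("CCC", v, 6)  # reuse C-only string for both sides
  perfect <- X$X + 1e-15           # row-stochastic, prob ~1 on the truth
  uniform <- matrix(1 / v$v, 6, v$v)
  mu0 <- rep(0, 4); lv0 <- rep(0, 4)
  l0 <- joint_loss(X, perfect, X, perfect, mu0, lv0, step_num = 1)
  expect_equal(l0$total, 0, tolerance = 1e-9)
  lu <- joint_loss(X, uniform, X, perfect, mu0, lv0, step_num = 1)
  expect_equal(lu$l_vr, log(v$v), tolerance = 1e-9)
  mu <- c(1, -1, 2, 0); lv <- c(0.3, -0.2, 0, 0.1)
  lj <- joint_loss(X, uniform, X, uniform, mu, lv, step_num = 50000)
  expect_equal(lj$gamma, gamma_schedule(50000))
  expect_equal(lj$l_kl, kl_divergence(mu, lv))
  expect_equal(lj$total, lj$gamma * lj$l_kl + lj$l_vr + lj$l_tr,
               tolerance = 1e-9)
  bad <- uniform; bad[2, ] <- bad[2, ] * 2
  expect_error(joint_loss(X, bad, X, uniform, mu, lv, 1), "row-stochastic")
})

test_that("analytic training gradients match finite differences on a tiny instance", {
  cfg <- model_config(d = 8, dz = 4, m = 1, k = 3, heads = 2, dff = 8,
                      n_layers = 1, dropout = 0, L_max = 8)
  v <- 6
  params <- scaffdec:::init_params(cfg, v, seed = 5)
  set.seed(31)
  B <- 2; L <- cfg$L_max
  src <- rbind(c(2L, 4L, 5L, 4L, 3L, 1L, 1L, 1L),
               c(2L, 5L, 5L, 3L, 1L, 1L, 1L, 1L))
  tgt <- rbind(c(2L, 6L, 4L, 6L, 3L, 1L, 1L, 1L),
               c(2L, 4L, 6L, 3L, 1L, 1L, 1L, 1L))
  eps <- matrix(rnorm(B * cfg$dz), B, cfg$dz)
  gamma <- 0.3
  loss_fn <- function(p) {
    src_mask <- src != 1L
    enc <- scaffdec:::vae_encode_fwd(src, src_mask, p$vae, cfg, FALSE)
    z <- enc$mu + exp(0.5 * enc$log_var) * eps
    dec <- scaffdec:::vae_decode_fwd(z, p$vae, cfg, FALSE)
    vr <- scaffdec:::ce_masked(dec$probs, src, src_mask, B, L, want_grad = FALSE)
    l_kl <- mean(-0.5 * rowSums(1 + enc$log_var - enc$mu^2 - exp(enc$log_var)))
    tgt_out <- cbind(tgt[, -1, drop = FALSE], matrix(1L, B, 1))
    fw <- scaffdec:::transformer_fwd(src, src_mask, tgt, tgt != 1L, p$tr,
                                     cfg, FALSE)
    tr <- scaffdec:::ce_masked(fw$probs, tgt_out, tgt_out != 1L, B, L,
                               want_grad = FALSE)
    gamma * l_kl + vr$loss + tr$loss
  }
  grads <- local({
    src_mask <- src != 1L
    enc <- scaffdec:::vae_encode_fwd(src, src_mask, params$vae, cfg, FALSE)
    z <- enc$mu + exp(0.5 * enc$log_var) * eps
    dec <- scaffdec:::vae_decode_fwd(z, params$vae, cfg, FALSE)
    vr <- scaffdec:::ce_masked(dec$probs, src, src_mask, B, L)
    g_vae <- scaffdec:::vae_bwd(vr$dLogits, enc, dec, eps,
                                gamma * enc$mu / B,
                                gamma * 0.5 * (exp(enc$log_var) - 1) / B,
                                src, params$vae, cfg)
    tgt_out <- cbind(tgt[, -1, drop = FALSE], matrix(1L, B, 1))
    fw <- scaffdec:::transformer_fwd(src, src_mask, tgt, tgt != 1L,
                                     params$tr, cfg, FALSE)
    tr <- scaffdec:::ce_masked(fw$probs, tgt_out, tgt_out != 1L, B, L)
    g_tr <- scaffdec:::transformer_bwd(tr$dLogits, fw, src, tgt, params$tr, cfg)
    list(vae = g_vae, tr = g_tr)
  })
  getp <- function(obj, path) { for (k in path) obj <- obj[[k]]; obj }
  setp <- function(obj, path, i, val) {
    if (length(path) == 0) { obj[i] <- val; return(obj) }
    obj[[path[[1]]]] <- setp(obj[[path[[1]]]], path[-1], i, val); obj
  }
  paths <- list(list("vae", "E1"), list("vae", "enc", 1L, "U1"),
                list("vae", "W3"), list("vae", "W4"),
                list("tr", "E2"), list("tr", "enc", 1L, "attn", "Wq"),
                list("tr", "dec", 1L, "cross", "Wv"),
                list("tr", "dec", 1L, "ln3", "g"), list("tr", "Wout"))
  for (path in paths) {
    arr <- getp(params, path); garr <- getp(grads, path)
    for (i in sample(length(arr), 2)) {
      h <- 1e-5
      num <- (loss_fn(setp(params, path, i, arr[i] + h)) -
              loss_fn(setp(params, path, i, arr[i] - h))) / (2 * h)
      expect_equal(garr[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seed-deterministic, schedule-consistent, and reduces the loss", {
  corpus <- fixture_smiles()
  cfg <- fixture_config()
  ck1 <- fit_generator(corpus, cfg, epochs = 6, batch_size = 10, seed = 21,
                       log_every = 1)
  ck2 <- fit_generator(corpus, cfg, epochs = 6, batch_size = 10, seed = 21,
                       log_every = 1)
  expect_identical(ck1$loss_log, ck2$loss_log)
  expect_identical(ck1$params, ck2$params)
  lg <- ck1$loss_log
  expect_equal(lg$gamma, gamma_schedule(lg$step))
  expect_equal(lg$lr, lr_schedule(lg$step, cfg$d))
  expect_lt(mean(tail(lg$total, 3)), lg$total[1])
  expect_true(all(lg$l_kl >= 0 & lg$l_vr >= 0 & lg$l_tr >= 0))
})

test_that("m2m mode trains on identical source and target sides", {
  ck <- fit_generator(fixture_smiles()[1:8], fixture_config(), epochs = 2,
                      batch_size = 8, seed = 2, mode = "m2m")
  expect_identical(ck$mode, "m2m")
  acc <- teacher_forced_accuracy(ck, fixture_smiles()[1:8])
  expect_gte(acc, 0); expect_lte(acc, 1)
})

test_that("checkpoints save and reload bit-exactly", {
  ck <- fixture_checkpoint()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, ck$params)
  expect_identical(back$vocab$tokens, ck$vocab$tokens)
  expect_error(load_checkpoint(file.path(tempdir(), "none.rds")),
               "no such checkpoint")
})
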