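# The decorating transformer: input switch, teacher forcing, causality,
# attention correctness, autoregressive decoding.

test_that("the input switch passes truth in training and argmaxes at inference", {
  v <- build_vocabulary("CCO", include_scaffolds = FALSE)
  X <- encode_onehot("CCO", v, 6)
  expect_identical(select_transformer_input("training", X_truth = X), X$X)
  expect_identical(select_transformer_input("inference", X_hat = X$X), X$X)
  # uniform rows collapse to the lowest token index per row
  U <- matrix(1 / v$v, 3, v$v)
  oh <- select_transformer_input("inference", X_hat = U)
  expect_equal(oh[, 1], rep(1, 3))
  expect_equal(rowSums(oh), rep(1, 3))
  expect_error(select_transformer_input("training"), "missing input")
  expect_error(select_transformer_input("inference"), "missing input")
})

test_that("teacher-forced output is row-stochastic and causally masked", {
  ck <- fixture_checkpoint()
  vocab <- ck$vocab; cfg <- ck$config
  scaf <- encode_onehot(to_generic_scaffold("CC(C)O"), vocab, cfg$L_max)
  tgt <- encode_onehot("CC(C)O", vocab, cfg$L_max)
  P <- decorate_teacher_forced(scaf, tgt, ck$params$tr, heads = cfg$heads)
  expect_equal(dim(P), c(cfg$L_max, vocab$v))
  expect_equal(rowSums(P), rep(1, cfg$L_max), tolerance = 1e-6)
  # perturbing the target at position j leaves output rows < j unchanged
  for (j in c(3L, 5L)) {
    tgt2 <- tgt
    tgt2$ids[j] <- if (tgt$ids[j] == 4L) 5L else 4L
    P2 <- decorate_teacher_forced(scaf, tgt2, ck$params$tr, heads = cfg$heads)
    expect_equal(P2[seq_len(j - 1), ], P[seq_len(j - 1), ], tolerance = 1e-10)
    expect_gt(max(abs(P2[j, ] - P[j, ])), 0)
  }
})

test_that("compiled attention matches a brute-force QK^T/softmax/V oracle", {
  set.seed(5)
  B <- 2; L <- 4; d <- 6; H <- 2; dh <- d / H
  Q <- matrix(rnorm(B * L * d), B * L, d)
  K <- matrix(rnorm(B * L * d), B * L, d)
  V <- matrix(rnorm(B * L * d), B * L, d)
  mask <- matrix(1, B, L); mask[1, 4] <- 0
  for (causal in c(FALSE, TRUE)) {
    res <- scaffdec:::.nn_attn_fwd(Q, K, V, mask, B, L, H, causal, 1 / sqrt(dh))
    # explicit loops over batch, head, query, key
    O_exp <- matrix(0, B * L, d)
    for (b in 1:B) for (h in 1:H) {
      rows <- b + B * (0:(L - 1))
      cols <- (h - 1) * dh + 1:dh
      S <- matrix(-Inf, L, L)
      for (i in 1:L) for (j in 1:L) {
        if (mask[b, j] == 0) next
        if (causal && j > i) next
        S[i, j] <- sum(Q[rows[i], cols] * K[rows[j], cols]) / sqrt(dh)
      }
      A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
      for (i in 1:L) O_exp[rows[i], cols] <- colSums(A[i, ] * V[rows, cols])
    }
    expect_equal(res$O, O_exp, tolerance = 1e-6)
  }
})

test_that("autoregressive decoding is deterministic and bounded", {
  ck <- fixture_checkpoint()
  scaf <- encode_onehot("CCC", ck$vocab, ck$config$L_max)
  out1 <- decorate_autoregressive(scaf, ck$params$tr, ck$vocab,
                                  heads = ck$config$heads)
  out2 <- decorate_autoregressive(scaf, ck$params$tr, ck$vocab,
                                  heads = ck$config$heads)
  expect_identical(out1, out2)
  short <- decorate_autoregressive(scaf, ck$params$tr, ck$vocab,
                                   heads = ck$config$heads, max_len = 3)
  expect_lte(length(tokenize_smiles(short)), 3)
})

test_that("greedy decoding agrees with one-step teacher-forced continuation", {
  ck <- fixture_checkpoint()
  vocab <- ck$vocab; cfg <- ck$config
  scaf <- encode_onehot("CCC", vocab, cfg$L_max)
  L <- cfg$L_max
  ids <- scaffdec:::decode_autoregressive_batch(
    matrix(scaf$ids, 1), matrix(seq_len(L) <= scaf$length, 1),
    ck$params$tr, list(heads = cfg$heads, dropout = 0), vocab, L - 1L)[1, ]
  stop_at <- c(which(ids == vocab$end_id), L)[1]
  # feeding the generated prefix teacher-forced must reproduce each token
  tgt <- structure(list(ids = ids, length = stop_at), class = "sd_encseq")
  P <- decorate_teacher_forced(scaf, tgt, ck$params$tr, heads = cfg$heads)
  for (t in seq_len(stop_at - 1L)) {
    expect_identical(which.max(P[t, ]), as.integer(ids[t + 1L]))
  }
})
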