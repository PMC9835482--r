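# Low-level neural-network layers with explicit forward/backward passes.
#
# Batches of sequences travel as flat (B*L) x d matrices with row index
# r = b + B*(t-1) (batch fastest), so every position block is a contiguous
# row range; the hot kernels (linear+bias, convolution, layer norm,
# softmax, attention) are compiled (see src/nn_kernels.cpp) and the
# backward passes here were verified against finite differences.

linear_fwd <- function(M, W, b) .nn_linear(M, W, b)
linear_bwd <- function(dY, M, W) {
  list(dX = dY %*% t(W), dW = crossprod(M, dY), db = colSums(dY))
}

conv_fwd <- function(M, U, bias, B, L) .nn_conv_fwd(M, U, bias, B, L)
conv_bwd <- function(dY, M, U, B, L) .nn_conv_bwd(dY, M, U, B, L)

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) (x > 0) * x

# Gated convolution with residual connection:
# out = A + (A * U1 + c1) (.) sigmoid(A * U2 + c2)    ("*" = convolution)
gated_fwd <- function(M, blk, B, L) {
  G <- conv_fwd(M, blk$U1, blk$c1, B, L)
  S <- sigmoid(conv_fwd(M, blk$U2, blk$c2, B, L))
  list(out = M + G * S, A = M, G = G, S = S)
}
gated_bwd <- function(dOut, cache, blk, B, L) {
  d1 <- conv_bwd(dOut * cache$S, cache$A, blk$U1, B, L)
  d2 <- conv_bwd(dOut * cache$G * cache$S * (1 - cache$S), cache$A, blk$U2, B, L)
  list(dA = dOut + d1$dX + d2$dX,
       grads = list(U1 = d1$dU, c1 = as.numeric(d1$db),
                    U2 = d2$dU, c2 = as.numeric(d2$db)))
}

softmax_rows <- function(M) .nn_softmax_rows(M)

layernorm_fwd <- function(M, g, b) .nn_ln_fwd(M, g, b, 1e-5)
layernorm_bwd <- function(dY, cache, g) {
  out <- .nn_ln_bwd(dY, cache$xhat, cache$inv, g)
  out$dg <- as.numeric(out$dg); out$db <- as.numeric(out$db)
  out
}

# multi-head attention; key_mask is B x L with 1 = attend
mha_fwd <- function(Mq, Mkv, p, heads, key_mask, B, L, causal = FALSE) {
  d <- ncol(Mq); dh <- d %/% heads
  Q <- linear_fwd(Mq, p$Wq, p$bq)
  K <- linear_fwd(Mkv, p$Wk, p$bk)
  V <- linear_fwd(Mkv, p$Wv, p$bv)
  res <- .nn_attn_fwd(Q, K, V, key_mask * 1, B, L, heads, causal, 1 / sqrt(dh))
  out <- linear_fwd(res$O, p$Wo, p$bo)
  list(out = out, cache = list(Mq = Mq, Mkv = Mkv, Q = Q, K = K, V = V,
                               A = res$A, O = res$O))
}

mha_bwd <- function(dOut, cache, p, heads, B, L) {
  d <- ncol(cache$Mq); dh <- d %/% heads
  lo <- linear_bwd(dOut, cache$O, p$Wo)
  g <- .nn_attn_bwd(lo$dX, cache$A, cache$Q, cache$K, cache$V, B, L, heads,
                    1 / sqrt(dh))
  lq <- linear_bwd(g$dQ, cache$Mq, p$Wq)
  lk <- linear_bwd(g$dK, cache$Mkv, p$Wk)
  lv <- linear_bwd(g$dV, cache$Mkv, p$Wv)
  list(dMq = lq$dX, dMkv = lk$dX + lv$dX,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

# Max pooling over positions with a validity mask (B x L); masked
# positions are -Inf so padding can never leak into the pooled vector.
maxpool_fwd <- function(M, mask, B, L) {
  d <- ncol(M)
  h <- matrix(-Inf, B, d)
  idx <- matrix(1L, B, d)
  for (t in seq_len(L)) {
    Mt <- M[(t - 1L) * B + seq_len(B), , drop = FALSE]
    Mt[!mask[, t], ] <- -Inf
    upd <- Mt > h
    h[upd] <- Mt[upd]
    idx[upd] <- t
  }
  list(h = h, idx = idx)
}
maxpool_bwd <- function(dh, idx, B, L, d) {
  dM <- matrix(0, B * L, d)
  bi <- rep(seq_len(B), times = d)
  fi <- rep(seq_len(d), each = B)
  dM[cbind(bi + B * (as.vector(idx) - 1L), fi)] <- as.vector(dh)
  dM
}

# inverted dropout; the mask is drawn from the current RNG stream
dropout_fwd <- function(M, rate, training) {
  if (!training || rate <= 0) return(list(out = M, mask = NULL))
  mask <- matrix((runif(length(M)) >= rate) / (1 - rate), nrow(M), ncol(M))
  list(out = M * mask, mask = mask)
}
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# fixed sinusoidal positional encoding (L_max x d)
positional_encoding <- function(L_max, d) {
  pos <- seq_len(L_max) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i - i %% 2) / d))
  P <- matrix(0, L_max, d)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  P[, even] <- sin(angle[, even])
  P[, odd] <- cos(angle[, odd])
  P
}

# expand a positional encoding to the flat batch layout (rows b + B*(t-1))
posenc_flat <- function(L, d, B) {
  P <- positional_encoding(L, d)
  P[rep(seq_len(L), each = B), , drop = FALSE]
}

# Glorot-uniform initialization drawn from the current RNG stream
glorot <- function(dims) {
  fan <- if (length(dims) == 2) dims else c(dims[1], dims[2])
  lim <- sqrt(6 / sum(fan))
  array(runif(prod(dims), -lim, lim), dims)
}

zeros <- function(dims) array(0, dims)
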