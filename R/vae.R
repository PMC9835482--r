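# The scaffold VAE: embedding + positional encoding, stacked gated-conv
# residual blocks, masked max-pooling, Gaussian latent heads,
# reparameterization, and the one-shot convolutional decoder.
#
# Internally sequences travel as token-id matrices (B x L) and flat
# (B*L) x d activations; the exported single-sequence operations accept
# one-hot matrices to mirror the mathematical formulation.

# --- exported single-instance operations ---------------------------------

#' Embed a one-hot sequence
#'
#' `X1 = X E1 + P1`: one-hot rows select embedding rows (lookup ==
#' matrix multiplication for one-hot input) and the fixed sinusoidal
#' positional encoding is added.
#'
#' @param X Binary (or row-stochastic) matrix `l x v`, or an `sd_encseq`.
#' @param E1 Embedding matrix `v x d`.
#' @param P1 Positional encoding matrix with at least `l` rows, or NULL for
#'   the standard sinusoidal encoding.
#' @return Real matrix `l x d`.
#' @export
embed_source <- function(X, E1, P1 = NULL) {
  if (inherits(X, "sd_encseq")) X <- X$X
  if (ncol(X) != nrow(E1)) stopf("shape mismatch: X has %d columns, E1 has %d rows",
                                 ncol(X), nrow(E1))
  if (is.null(P1)) P1 <- positional_encoding(nrow(X), ncol(E1))
  X %*% E1 + P1[seq_len(nrow(X)), , drop = FALSE]
}

#' Gated convolution block with residual connection
#'
#' `A + (A * U1 + c1) (.) sigmoid(A * U2 + c2)` where `*` is a
#' length-preserving 1-D convolution (stride 1, symmetric zero padding).
#'
#' @param A Real matrix `l x d`.
#' @param U1,U2 Convolution kernels `k x d x d` (k odd).
#' @param c1,c2 Bias vectors of length `d`.
#' @return Real matrix `l x d` (same shape as the input).
#' @export
gated_conv_block <- function(A, U1, c1, U2, c2) {
  if (ncol(A) != dim(U1)[2]) stopf("shape mismatch between A and U1")
  # kernels come in as k x d_in x d_out; internally slices are per tap
  blk <- list(U1 = aperm(U1, c(2, 3, 1)), c1 = c1,
              U2 = aperm(U2, c(2, 3, 1)), c2 = c2)
  gated_fwd(A, blk, B = 1L, L = nrow(A))$out
}

#' Encode a sequence to its Gaussian posterior parameters
#'
#' Embedding, `m` gated-conv blocks, masked max-pooling over positions
#' (pad rows are masked to -Inf so padding never leaks into the pooled
#' vector), then two independent affine heads.
#'
#' @param X An `sd_encseq` (from [encode_onehot()]).
#' @param params VAE parameter list (element `params$vae` of a
#'   checkpoint's parameters).
#' @return List with `mu` and `log_var`, both length `dz`.
#' @export
encode_to_latent <- function(X, params) {
  stopifnot(inherits(X, "sd_encseq"))
  ids <- matrix(X$ids, 1)
  mask <- matrix(seq_len(ncol(ids)) <= X$length, 1)
  fw <- vae_encode_fwd(ids, mask, params, cfg_from_params(params), training = FALSE)
  list(mu = as.numeric(fw$mu), log_var = as.numeric(fw$log_var))
}

#' Reparameterization trick
#'
#' `z = mu + exp(log_var / 2) * eps`, differentiable in `mu` and
#' `log_var`; all stochasticity enters through the caller-supplied `eps`.
#'
#' @param mu,log_var,eps Equal-length numeric vectors.
#' @return The latent sample `z`.
#' @export
reparameterize <- function(mu, log_var, eps) {
  if (length(mu) != length(log_var) || length(mu) != length(eps))
    stopf("length mismatch among mu, log_var, eps")
  mu + exp(0.5 * log_var) * eps
}

#' Decode a latent vector to a row-stochastic sequence matrix
#'
#' `z' = z W3 + b3` reshaped row-major to `L_max x d`, passed through `m`
#' residual gated-conv blocks and a position-wise softmax projection onto
#' the vocabulary. Deterministic given `z` and parameters.
#'
#' @param z Latent vector of length `dz`.
#' @param params VAE parameter list.
#' @return Row-stochastic matrix `L_max x v` (rows sum to 1).
#' @export
decode_from_latent <- function(z, params) {
  cfg <- cfg_from_params(params)
  if (length(z) != cfg$dz) stopf("z has length %d, expected dz = %d",
                                 length(z), cfg$dz)
  vae_decode_fwd(matrix(z, 1), params, cfg)$probs
}

#' KL divergence of the diagonal Gaussian posterior from the standard normal
#'
#' `-1/2 * sum(1 + log_var - mu^2 - exp(log_var))`, the closed form of
#' `D_KL(N(mu, sigma^2 I) || N(0, I))`; non-negative, zero iff `mu = 0`
#' and `log_var = 0`.
#'
#' @param mu,log_var Equal-length numeric vectors (length `dz`).
#' @return Scalar KL divergence.
#' @export
kl_divergence <- function(mu, log_var) {
  if (length(mu) != length(log_var)) stopf("length mismatch between mu and log_var")
  -0.5 * sum(1 + log_var - mu^2 - exp(log_var))
}

# infer shape info from a VAE parameter list
cfg_from_params <- function(params) {
  d <- ncol(params$E1)
  list(d = d, dz = ncol(params$W1), m = length(params$enc),
       k = dim(params$enc[[1]]$U1)[3], L_max = length(params$b3) %/% d,
       dropout = 0)
}

# --- batched forward/backward --------------------------------------------

# ids: B x L token-id matrix; mask: B x L (TRUE up to and including end).
vae_encode_fwd <- function(ids, mask, p, cfg, training = FALSE) {
  B <- nrow(ids); L <- ncol(ids); d <- ncol(p$E1)
  X <- p$E1[as.vector(ids), , drop = FALSE] + posenc_flat(L, d, B)
  # zero pad positions before the conv stack: with kernel reach k-1 they
  # could otherwise leak into positions inside the mask
  X <- X * as.vector(mask)
  drop_in <- dropout_fwd(X, cfg$dropout, training)
  X <- drop_in$out
  blocks <- vector("list", length(p$enc))
  for (i in seq_along(p$enc)) {
    res <- gated_fwd(X, p$enc[[i]], B, L)
    blocks[[i]] <- res
    X <- res$out
  }
  pool <- maxpool_fwd(X, mask, B, L)
  mu <- .nn_linear(pool$h, p$W1, p$b1)
  log_var <- .nn_linear(pool$h, p$W2, p$b2)
  list(mu = mu, log_var = log_var, h = pool$h, pool_idx = pool$idx,
       blocks = blocks, drop_in = drop_in, mask = mask, B = B, L = L, d = d)
}

# z: B x dz. Returns flat probabilities ((B*L) x v) and caches.
vae_decode_fwd <- function(z, p, cfg, training = FALSE) {
  B <- nrow(z); d <- cfg$d; L <- length(p$b3) %/% d
  zp <- .nn_linear(z, p$W3, p$b3)
  # zp[b, (t-1)*d + f] -> flat row b + B*(t-1), column f (row-major unpack)
  Z <- matrix(aperm(array(zp, c(B, d, L)), c(1, 3, 2)), B * L, d)
  blocks <- vector("list", length(p$dec))
  X <- Z
  for (i in seq_along(p$dec)) {
    res <- gated_fwd(X, p$dec[[i]], B, L)
    blocks[[i]] <- res
    X <- res$out
  }
  drop_out <- dropout_fwd(X, cfg$dropout, training)
  logits <- linear_fwd(drop_out$out, p$W4, p$b4)
  probs <- softmax_rows(logits)
  list(probs = probs, Zfinal = drop_out$out, drop_out = drop_out,
       blocks = blocks, z = z, B = B, L = L, d = d)
}

# Backward through the whole VAE given dLogits ((B*L) x v) from the masked
# cross-entropy, plus the (gamma-weighted) KL gradients. eps is the
# reparameterization noise of the forward pass.
vae_bwd <- function(dLogits, enc_cache, dec_cache, eps, dKL_dmu, dKL_dlv,
                    ids, p, cfg) {
  B <- dec_cache$B; L <- dec_cache$L; d <- dec_cache$d
  g <- list(E1 = array(0, dim(p$E1)), enc = vector("list", length(p$enc)),
            W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL, W3 = NULL, b3 = NULL,
            dec = vector("list", length(p$dec)), W4 = NULL, b4 = NULL)
  lo <- linear_bwd(dLogits, dec_cache$Zfinal, p$W4)
  g$W4 <- lo$dW; g$b4 <- lo$db
  dX <- dropout_bwd(lo$dX, dec_cache$drop_out$mask)
  for (i in rev(seq_along(p$dec))) {
    gb <- gated_bwd(dX, dec_cache$blocks[[i]], p$dec[[i]], B, L)
    g$dec[[i]] <- gb$grads
    dX <- gb$dA
  }
  dzp <- matrix(aperm(array(dX, c(B, L, d)), c(1, 3, 2)), B, L * d)
  g$W3 <- crossprod(dec_cache$z, dzp)
  g$b3 <- colSums(dzp)
  dz <- dzp %*% t(p$W3)
  dmu <- dz + dKL_dmu
  dlv <- dz * eps * 0.5 * exp(0.5 * enc_cache$log_var) + dKL_dlv
  g$W1 <- crossprod(enc_cache$h, dmu); g$b1 <- colSums(dmu)
  g$W2 <- crossprod(enc_cache$h, dlv); g$b2 <- colSums(dlv)
  dh <- dmu %*% t(p$W1) + dlv %*% t(p$W2)
  dXe <- maxpool_bwd(dh, enc_cache$pool_idx, B, L, d)
  for (i in rev(seq_along(p$enc))) {
    gb <- gated_bwd(dXe, enc_cache$blocks[[i]], p$enc[[i]], B, L)
    g$enc[[i]] <- gb$grads
    dXe <- gb$dA
  }
  dXe <- dropout_bwd(dXe, enc_cache$drop_in$mask)
  dXe <- dXe * as.vector(enc_cache$mask)
  agg <- rowsum(dXe, as.vector(ids))
  g$E1[as.integer(rownames(agg)), ] <- g$E1[as.integer(rownames(agg)), ] + agg
  g
}
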