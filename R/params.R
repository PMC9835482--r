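# Model configuration, parameter initialization, parameter-tree utilities
# and checkpoints.

#' Model configuration
#'
#' Hyperparameters shared by the scaffold VAE and the decorating
#' transformer. The defaults are the full-scale settings (model dimension
#' 256, latent dimension 64, three gated-conv blocks, kernel 3, four
#' attention heads, feed-forward width 1024, dropout 0.1); `tiny = TRUE`
#' returns the scaled-down preset used for desk-scale experiments and
#' tests.
#'
#' @param d Model (embedding) dimension.
#' @param dz Latent dimension of the VAE.
#' @param m Gated-convolution blocks per VAE encoder/decoder.
#' @param k Convolution kernel size (odd, stride 1, length-preserving).
#' @param heads Attention heads.
#' @param dff Transformer feed-forward dimension.
#' @param n_layers Encoder and decoder layers in the transformer.
#' @param dropout Dropout rate applied in both components during training.
#' @param L_max Fixed maximum sequence length (tokens + start/end).
#' @param tiny Return the tiny preset (d=32, dz=8, m=2, heads=2, dff=64,
#'   L_max=32) instead.
#' @return A list of class `sd_config`.
#' @export
model_config <- function(d = 256, dz = 64, m = 3, k = 3, heads = 4,
                         dff = 1024, n_layers = 3, dropout = 0.1,
                         L_max = 128, tiny = FALSE) {
  if (tiny)
    return(model_config(d = 32, dz = 8, m = 2, k = 3, heads = 2, dff = 64,
                        n_layers = 3, dropout = 0.1, L_max = 32))
  cfg <- list(d = d, dz = dz, m = m, k = k, heads = heads, dff = dff,
              n_layers = n_layers, dropout = dropout, L_max = L_max)
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x >= 0, logical(1))),
            k %% 2 == 1, d %% heads == 0)
  class(cfg) <- "sd_config"
  cfg
}

# --- parameter trees ------------------------------------------------------

# apply f leaf-wise over parallel nested lists of arrays
tree_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- lapply(seq_along(xs[[1]]),
                  function(i) do.call(tree_map, c(list(f), lapply(xs, `[[`, i))))
    names(out) <- names(xs[[1]])
    out
  } else {
    do.call(f, xs)
  }
}

tree_zeros_like <- function(p) tree_map(function(x) array(0, dim(x) %||% length(x)), p)

# convolution kernels are stored as (d_in, d_out, k) with one slice per tap
gated_block_init <- function(k, d) {
  list(U1 = glorot(c(d, d, k)), c1 = zeros(d),
       U2 = glorot(c(d, d, k)), c2 = zeros(d))
}

attn_init <- function(d) {
  list(Wq = glorot(c(d, d)), bq = zeros(d), Wk = glorot(c(d, d)), bk = zeros(d),
       Wv = glorot(c(d, d)), bv = zeros(d), Wo = glorot(c(d, d)), bo = zeros(d))
}

ln_init <- function(d) list(g = rep(1, d), b = rep(0, d))

ffn_init <- function(d, dff) {
  list(W1 = glorot(c(d, dff)), b1 = zeros(dff),
       W2 = glorot(c(dff, d)), b2 = zeros(d))
}

# VAE parameters (embedding, encoder blocks, latent heads, decoder)
init_vae_params <- function(cfg, v) {
  d <- cfg$d; dz <- cfg$dz
  list(E1 = glorot(c(v, d)),
       enc = lapply(seq_len(cfg$m), function(i) gated_block_init(cfg$k, d)),
       W1 = glorot(c(d, dz)), b1 = zeros(dz),
       W2 = glorot(c(d, dz)), b2 = zeros(dz),
       W3 = glorot(c(dz, cfg$L_max * d)), b3 = zeros(cfg$L_max * d),
       dec = lapply(seq_len(cfg$m), function(i) gated_block_init(cfg$k, d)),
       W4 = glorot(c(d, v)), b4 = zeros(v))
}

enc_layer_init <- function(cfg) {
  list(attn = attn_init(cfg$d), ln1 = ln_init(cfg$d),
       ff = ffn_init(cfg$d, cfg$dff), ln2 = ln_init(cfg$d))
}

dec_layer_init <- function(cfg) {
  list(self = attn_init(cfg$d), ln1 = ln_init(cfg$d),
       cross = attn_init(cfg$d), ln2 = ln_init(cfg$d),
       ff = ffn_init(cfg$d, cfg$dff), ln3 = ln_init(cfg$d))
}

# transformer parameters (shared source/target embedding E2)
init_tr_params <- function(cfg, v) {
  list(E2 = glorot(c(v, cfg$d)),
       enc = lapply(seq_len(cfg$n_layers), function(i) enc_layer_init(cfg)),
       dec = lapply(seq_len(cfg$n_layers), function(i) dec_layer_init(cfg)),
       Wout = glorot(c(cfg$d, v)), bout = zeros(v))
}

init_params <- function(cfg, v, seed = NULL) {
  with_seed(seed, list(vae = init_vae_params(cfg, v),
                       tr = init_tr_params(cfg, v)))
}

# --- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint holds the named parameter arrays of both components, the
#' configuration, the vocabulary and the training log. Reload is bit-exact.
#'
#' @param ckpt A checkpoint object (class `sd_checkpoint`), as returned by
#'   [fit_generator()].
#' @param path File path (created/overwritten).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "sd_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("no such checkpoint: %s", path)
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "sd_checkpoint")) stopf("not a checkpoint file: %s", path)
  ckpt
}

#' @export
print.sd_checkpoint <- function(x, ...) {
  cat(sprintf("<sd_checkpoint> d=%d dz=%d v=%d L_max=%d mode=%s steps=%d\n",
              x$config$d, x$config$dz, x$vocab$v, x$config$L_max,
              x$mode, x$steps))
  invisible(x)
}
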