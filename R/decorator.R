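# The decorating transformer: translates a generic-scaffold token sequence
# into a decorated molecule sequence. Post-norm layers (residual + layer
# normalization after each sublayer), padding-masked encoder attention,
# causal-masked decoder self-attention, shared source/target embedding.

# --- input switch ---------------------------------------------------------

#' Select the transformer's scaffold input
#'
#' During training the ground-truth scaffold one-hot matrix is used
#' (teacher forcing, keeping the path differentiable); at inference the
#' VAE's row-stochastic output is collapsed by per-row argmax (ties broken
#' by the lowest token index) into a one-hot matrix.
#'
#' @param mode `"training"` or `"inference"`.
#' @param X_truth Ground-truth one-hot matrix (training mode).
#' @param X_hat Row-stochastic matrix from the VAE decoder (inference mode).
#' @return A one-hot matrix.
#' @export
select_transformer_input <- function(mode = c("training", "inference"),
                                     X_truth = NULL, X_hat = NULL) {
  mode <- match.arg(mode)
  if (mode == "training") {
    if (is.null(X_truth)) stopf("missing input: X_truth is required in training mode")
    if (inherits(X_truth, "sd_encseq")) X_truth <- X_truth$X
    return(X_truth)
  }
  if (is.null(X_hat)) stopf("missing input: X_hat is required in inference mode")
  ids <- max.col(X_hat, ties.method = "first")
  out <- matrix(0, nrow(X_hat), ncol(X_hat))
  out[cbind(seq_len(nrow(X_hat)), ids)] <- 1
  out
}

# --- batched forward/backward --------------------------------------------

transformer_encoder_fwd <- function(src_ids, src_mask, p, cfg, training) {
  B <- nrow(src_ids); L <- ncol(src_ids); d <- ncol(p$E2)
  X <- p$E2[as.vector(src_ids), , drop = FALSE] + posenc_flat(L, d, B)
  drop_in <- dropout_fwd(X, cfg$dropout, training)
  X <- drop_in$out
  layers <- vector("list", length(p$enc))
  for (i in seq_along(p$enc)) {
    lp <- p$enc[[i]]
    at <- mha_fwd(X, X, lp$attn, cfg$heads, src_mask, B, L, causal = FALSE)
    dr1 <- dropout_fwd(at$out, cfg$dropout, training)
    ln1 <- layernorm_fwd(X + dr1$out, lp$ln1$g, lp$ln1$b)
    h1 <- linear_fwd(ln1$out, lp$ff$W1, lp$ff$b1)
    hr <- relu(h1)
    h2 <- linear_fwd(hr, lp$ff$W2, lp$ff$b2)
    dr2 <- dropout_fwd(h2, cfg$dropout, training)
    ln2 <- layernorm_fwd(ln1$out + dr2$out, lp$ln2$g, lp$ln2$b)
    layers[[i]] <- list(Xin = X, at = at, dr1 = dr1, ln1 = ln1,
                        h1 = h1, hr = hr, dr2 = dr2, ln2 = ln2)
    X <- ln2$out
  }
  list(out = X, layers = layers, drop_in = drop_in, B = B, L = L, d = d)
}

transformer_decoder_fwd <- function(tgt_ids, tgt_mask, memory, src_mask,
                                    p, cfg, training) {
  B <- nrow(tgt_ids); L <- ncol(tgt_ids); d <- ncol(p$E2)
  Y <- p$E2[as.vector(tgt_ids), , drop = FALSE] + posenc_flat(L, d, B)
  drop_in <- dropout_fwd(Y, cfg$dropout, training)
  Y <- drop_in$out
  layers <- vector("list", length(p$dec))
  for (i in seq_along(p$dec)) {
    lp <- p$dec[[i]]
    sa <- mha_fwd(Y, Y, lp$self, cfg$heads, tgt_mask, B, L, causal = TRUE)
    dr1 <- dropout_fwd(sa$out, cfg$dropout, training)
    ln1 <- layernorm_fwd(Y + dr1$out, lp$ln1$g, lp$ln1$b)
    ca <- mha_fwd(ln1$out, memory, lp$cross, cfg$heads, src_mask, B, L,
                  causal = FALSE)
    dr2 <- dropout_fwd(ca$out, cfg$dropout, training)
    ln2 <- layernorm_fwd(ln1$out + dr2$out, lp$ln2$g, lp$ln2$b)
    h1 <- linear_fwd(ln2$out, lp$ff$W1, lp$ff$b1)
    hr <- relu(h1)
    h2 <- linear_fwd(hr, lp$ff$W2, lp$ff$b2)
    dr3 <- dropout_fwd(h2, cfg$dropout, training)
    ln3 <- layernorm_fwd(ln2$out + dr3$out, lp$ln3$g, lp$ln3$b)
    layers[[i]] <- list(Yin = Y, sa = sa, dr1 = dr1, ln1 = ln1, ca = ca,
                        dr2 = dr2, ln2 = ln2, h1 = h1, hr = hr, dr3 = dr3,
                        ln3 = ln3)
    Y <- ln3$out
  }
  logits <- linear_fwd(Y, p$Wout, p$bout)
  list(probs = softmax_rows(logits), out = Y, layers = layers,
       drop_in = drop_in, B = B, L = L, d = d)
}

transformer_fwd <- function(src_ids, src_mask, dec_in_ids, tgt_mask, p, cfg,
                            training = FALSE) {
  enc <- transformer_encoder_fwd(src_ids, src_mask, p, cfg, training)
  dec <- transformer_decoder_fwd(dec_in_ids, tgt_mask, enc$out, src_mask,
                                 p, cfg, training)
  list(enc = enc, dec = dec, probs = dec$probs)
}

# full backward pass; dLogits ((B*L) x v). Returns the gradient tree.
transformer_bwd <- function(dLogits, fw, src_ids, dec_in_ids, p, cfg) {
  enc <- fw$enc; dec <- fw$dec
  B <- dec$B; L <- dec$L
  g <- list(E2 = array(0, dim(p$E2)), enc = vector("list", length(p$enc)),
            dec = vector("list", length(p$dec)), Wout = NULL, bout = NULL)
  lo <- linear_bwd(dLogits, dec$out, p$Wout)
  g$Wout <- lo$dW; g$bout <- lo$db
  dY <- lo$dX
  dMem <- matrix(0, enc$B * enc$L, enc$d)
  for (i in rev(seq_along(p$dec))) {
    lp <- p$dec[[i]]; cc <- dec$layers[[i]]
    l3 <- layernorm_bwd(dY, cc$ln3, lp$ln3$g)
    dres <- l3$dX
    dh2 <- dropout_bwd(dres, cc$dr3$mask)
    l2b <- linear_bwd(dh2, cc$hr, lp$ff$W2)
    dh1 <- l2b$dX * (cc$h1 > 0)
    l1b <- linear_bwd(dh1, cc$ln2$out, lp$ff$W1)
    dln2 <- dres + l1b$dX
    l2 <- layernorm_bwd(dln2, cc$ln2, lp$ln2$g)
    dres2 <- l2$dX
    dca <- dropout_bwd(dres2, cc$dr2$mask)
    cb <- mha_bwd(dca, cc$ca$cache, lp$cross, cfg$heads, B, L)
    dMem <- dMem + cb$dMkv
    dln1 <- dres2 + cb$dMq
    l1 <- layernorm_bwd(dln1, cc$ln1, lp$ln1$g)
    dres1 <- l1$dX
    dsa <- dropout_bwd(dres1, cc$dr1$mask)
    sb <- mha_bwd(dsa, cc$sa$cache, lp$self, cfg$heads, B, L)
    dY <- dres1 + sb$dMq + sb$dMkv
    g$dec[[i]] <- list(self = sb$grads, ln1 = list(g = l1$dg, b = l1$db),
                       cross = cb$grads, ln2 = list(g = l2$dg, b = l2$db),
                       ff = list(W1 = l1b$dW, b1 = l1b$db,
                                 W2 = l2b$dW, b2 = l2b$db),
                       ln3 = list(g = l3$dg, b = l3$db))
  }
  dY <- dropout_bwd(dY, dec$drop_in$mask)
  aggY <- rowsum(dY, as.vector(dec_in_ids))
  g$E2[as.integer(rownames(aggY)), ] <- g$E2[as.integer(rownames(aggY)), ] + aggY
  dX <- dMem
  for (i in rev(seq_along(p$enc))) {
    lp <- p$enc[[i]]; cc <- enc$layers[[i]]
    l2 <- layernorm_bwd(dX, cc$ln2, lp$ln2$g)
    dres <- l2$dX
    dh2 <- dropout_bwd(dres, cc$dr2$mask)
    l2b <- linear_bwd(dh2, cc$hr, lp$ff$W2)
    dh1 <- l2b$dX * (cc$h1 > 0)
    l1b <- linear_bwd(dh1, cc$ln1$out, lp$ff$W1)
    dln1 <- dres + l1b$dX
    l1 <- layernorm_bwd(dln1, cc$ln1, lp$ln1$g)
    dres1 <- l1$dX
    dat <- dropout_bwd(dres1, cc$dr1$mask)
    ab <- mha_bwd(dat, cc$at$cache, lp$attn, cfg$heads, B, L)
    dX <- dres1 + ab$dMq + ab$dMkv
    g$enc[[i]] <- list(attn = ab$grads, ln1 = list(g = l1$dg, b = l1$db),
                       ff = list(W1 = l1b$dW, b1 = l1b$db,
                                 W2 = l2b$dW, b2 = l2b$db),
                       ln2 = list(g = l2$dg, b = l2$db))
  }
  dX <- dropout_bwd(dX, enc$drop_in$mask)
  aggX <- rowsum(dX, as.vector(src_ids))
  g$E2[as.integer(rownames(aggX)), ] <- g$E2[as.integer(rownames(aggX)), ] + aggX
  g
}

# --- exported operations --------------------------------------------------

#' Teacher-forced decoration
#'
#' The encoder consumes the embedded scaffold; the decoder consumes the
#' target under a causal mask. The encoded target already carries the
#' start-token prefix, so output position `t` depends only on the scaffold
#' and on target tokens before `t`, and the prediction at position `t`
#' scores target position `t + 1`. Rows of the output are probability
#' distributions over the vocabulary.
#'
#' @param X_scaffold,Y_target `sd_encseq` objects (shared vocabulary).
#' @param params Transformer parameter list (checkpoint element
#'   `params$tr`).
#' @param heads Number of attention heads.
#' @return Row-stochastic matrix `L_max x v`.
#' @export
decorate_teacher_forced <- function(X_scaffold, Y_target, params, heads = 4) {
  stopifnot(inherits(X_scaffold, "sd_encseq"), inherits(Y_target, "sd_encseq"))
  L <- length(X_scaffold$ids)
  if (length(Y_target$ids) != L) stopf("shape mismatch between scaffold and target")
  src <- matrix(X_scaffold$ids, 1)
  dec_in <- matrix(Y_target$ids, 1)
  cfg <- list(heads = heads, dropout = 0)
  fw <- transformer_fwd(src, matrix(seq_len(L) <= X_scaffold$length, 1),
                        dec_in, dec_in != 1L, params, cfg, training = FALSE)
  fw$probs
}

#' Greedy autoregressive decoration of a scaffold
#'
#' Starts from the start token and repeatedly appends the argmax next
#' token until the end token or `max_len`; deterministic for fixed
#' parameters. With `temperature > 0` tokens are instead sampled from the
#' tempered distribution (used by the retry loop of
#' [decorate_scaffold()]).
#'
#' @param X_scaffold An `sd_encseq` of the (generic) scaffold.
#' @param params Transformer parameter list.
#' @param vocab The shared vocabulary.
#' @param heads Attention heads.
#' @param max_len Maximum number of generated tokens.
#' @param temperature 0 for greedy argmax decoding; otherwise a softmax
#'   temperature for stochastic decoding.
#' @return The decoded SMILES string (validity is judged by the caller).
#' @export
decorate_autoregressive <- function(X_scaffold, params, vocab, heads = 4,
                                    max_len = NULL, temperature = 0) {
  stopifnot(inherits(X_scaffold, "sd_encseq"))
  L <- length(X_scaffold$ids)
  max_len <- max_len %||% L
  ids <- decode_autoregressive_batch(matrix(X_scaffold$ids, 1),
                                     matrix(seq_len(L) <= X_scaffold$length, 1),
                                     params, list(heads = heads, dropout = 0),
                                     vocab, max_len, temperature)
  decode_ids(ids[1, ], vocab)
}

# Batched greedy/temperature decoding. src_ids: B x L. Returns B x L id
# matrix of generated sequences (start, tokens..., end, pads).
decode_autoregressive_batch <- function(src_ids, src_mask, p, cfg, vocab,
                                        max_len, temperature = 0) {
  B <- nrow(src_ids); L <- ncol(src_ids)
  enc <- transformer_encoder_fwd(src_ids, src_mask, p, cfg, training = FALSE)
  out <- matrix(vocab$pad_id, B, L)
  out[, 1] <- vocab$start_id
  done <- rep(FALSE, B)
  for (t in seq_len(min(max_len, L - 1L))) {
    dec <- transformer_decoder_fwd(out, out != vocab$pad_id, enc$out,
                                   src_mask, p, cfg, training = FALSE)
    pr <- dec$probs[(t - 1L) * B + seq_len(B), , drop = FALSE]
    if (temperature > 0) {
      lg <- log(pmax(pr, 1e-12)) / temperature
      nxt <- apply(lg, 1, function(r) {
        w <- exp(r - max(r)); sample.int(length(r), 1L, prob = w)
      })
    } else {
      nxt <- max.col(pr, ties.method = "first")
    }
    nxt[done] <- vocab$pad_id
    out[, t + 1L] <- nxt
    done <- done | nxt == vocab$end_id
    if (all(done)) break
  }
  out
}
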