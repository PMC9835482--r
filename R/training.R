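# Joint end-to-end training: the three-part loss, the KL-annealing
# schedule, the warm-up learning-rate schedule, and the Adam loop.

#' KL-annealing weight schedule
#'
#' `gamma = min(0.01, 0.001 + floor(max(0, step_num - 40000) / 5000) / 10000)`:
#' a plateau at 0.001 for the first 40k steps, then a staircase rising by
#' 0.0001 every 5000 steps, capped at 0.01. Annealing the KL weight keeps
#' the posterior from collapsing early in training.
#'
#' @param step_num Training step (vectorized, `>= 0`).
#' @return The KL weight gamma, in `[0.001, 0.01]`.
#' @export
gamma_schedule <- function(step_num) {
  if (any(step_num < 0)) stopf("negative step number")
  pmin(0.01, 0.001 + floor(pmax(0, step_num - 40000) / 5000) / 10000)
}

#' Warm-up learning-rate schedule
#'
#' `lr = d^(-1/2) * min(step_num^(-1/2), step_num * 10000^(-3/2))`: linear
#' warm-up to step 10000, then inverse-square-root decay; the two branches
#' meet at the unique maximum, step 10000.
#'
#' @param step_num Training step (vectorized, `>= 1`).
#' @param d Model dimension.
#' @return Learning rate.
#' @export
lr_schedule <- function(step_num, d) {
  if (any(step_num < 1)) stopf("step number must be >= 1")
  d^(-0.5) * pmin(step_num^(-0.5), step_num * 10000^(-1.5))
}

# --- masked cross-entropy -------------------------------------------------

# probs: flat (B*L) x v (rows batch-fastest); target_ids, loss_mask:
# (B, L). The average is 1/l per sequence over its non-pad positions,
# then averaged over the batch. Returns the scalar loss and dLogits (the
# exact softmax+CE gradient).
ce_masked <- function(probs, target_ids, loss_mask, B, L, want_grad = TRUE) {
  lens <- rowSums(loss_mask)
  bi <- rep(seq_len(B), L)
  pt <- probs[cbind(seq_len(B * L), as.vector(target_ids))]
  nll <- -log(pmax(pt, 1e-12)) * as.vector(loss_mask)
  loss <- mean(rowsum(nll, bi)[, 1] / pmax(lens, 1))
  if (!want_grad) return(list(loss = loss))
  # (probs - onehot) weighted by 1/(B*l_b), zero at masked positions
  w <- as.vector(loss_mask) / (B * pmax(lens[bi], 1))
  dLogits <- probs * w
  at <- cbind(seq_len(B * L), as.vector(target_ids))
  dLogits[at] <- dLogits[at] - w
  list(loss = loss, dLogits = dLogits)
}

#' Joint training loss breakdown
#'
#' `L = gamma * L_KL + L_vr + L_tr` with the two cross-entropies averaged
#' (natural log) over the non-pad positions of their reference sequences
#' and the KL term from [kl_divergence()].
#'
#' @param X,Y Reference one-hot matrices (`l x v`; rows after the end
#'   token must be pad one-hots) or `sd_encseq` objects.
#' @param X_hat,Y_hat Row-stochastic prediction matrices aligned row-wise
#'   with `X` and `Y`.
#' @param mu,log_var Posterior parameters of the latent state.
#' @param step_num Training step (sets gamma).
#' @return List of class `sd_loss`: `l_kl`, `l_vr`, `l_tr`, `gamma`,
#'   `total`.
#' @export
joint_loss <- function(X, X_hat, Y, Y_hat, mu, log_var, step_num) {
  xe <- onehot_ce(X, X_hat)
  ye <- onehot_ce(Y, Y_hat)
  l_kl <- kl_divergence(mu, log_var)
  gamma <- gamma_schedule(step_num)
  out <- list(l_kl = l_kl, l_vr = xe, l_tr = ye, gamma = gamma,
              total = gamma * l_kl + xe + ye)
  class(out) <- "sd_loss"
  out
}

#' @export
print.sd_loss <- function(x, ...) {
  cat(sprintf("loss: total=%.4f (gamma=%.4g, kl=%.4f, vae_ce=%.4f, tr_ce=%.4f)\n",
              x$total, x$gamma, x$l_kl, x$l_vr, x$l_tr))
  invisible(x)
}

# elementwise CE between a one-hot reference and a row-stochastic
# prediction, averaged over the reference's non-pad rows (pad = column 1)
onehot_ce <- function(ref, pred) {
  if (inherits(ref, "sd_encseq")) ref <- ref$X
  if (!all(abs(rowSums(pred) - 1) < 1e-3))
    stopf("prediction matrix is not row-stochastic")
  if (!identical(dim(ref), dim(pred))) stopf("shape mismatch in cross-entropy")
  keep <- which(apply(ref, 1, which.max) != 1L)
  if (!length(keep)) stopf("reference has no non-pad positions")
  -sum(ref[keep, , drop = FALSE] * log(pmax(pred[keep, , drop = FALSE], 1e-12))) /
    length(keep)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L, m = tree_zeros_like(params), v = tree_zeros_like(params))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.98, eps = 1e-9) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 / (1 - beta1^t); c2 <- 1 / (1 - beta2^t)
  params <- tree_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# --- the training loop ----------------------------------------------------

#' Train the two-step generator end-to-end
#'
#' Builds the shared vocabulary from the corpus (molecules plus their
#' generic scaffolds), forms (source, target) pairs — `mode = "s2m"` pairs
#' each molecule with its generic scaffold as the source, `mode = "m2m"`
#' uses the molecule on both sides — and optimizes
#' `gamma * L_KL + L_vr + L_tr` with Adam under the warm-up learning-rate
#' schedule. The VAE autoencodes the source sequence; the transformer is
#' teacher-forced on the ground-truth source, which severs the VAE-to-
#' transformer gradient path exactly as the training scheme prescribes.
#'
#' Deterministic for a fixed seed: parameter initialization, epoch
#' shuffling, reparameterization noise and dropout all draw from one RNG
#' stream seeded at entry.
#'
#' @param corpus Character vector of training SMILES.
#' @param config An `sd_config` from [model_config()].
#' @param epochs Number of passes over the corpus.
#' @param batch_size Molecules per optimization step.
#' @param seed Integer seed controlling all randomness of the run.
#' @param mode `"s2m"` (scaffold-to-molecule) or `"m2m"` ablation.
#' @param log_every Record the loss breakdown every this many steps.
#' @param verbose Print the loss at each logged step.
#' @return An `sd_checkpoint`: parameters, config, vocabulary, mode and a
#'   `loss_log` data.frame with columns step, epoch, gamma, lr, l_kl,
#'   l_vr, l_tr, total.
#' @export
fit_generator <- function(corpus, config = model_config(tiny = TRUE),
                          epochs = 10, batch_size = 64, seed = 1,
                          mode = c("s2m", "m2m"), log_every = 10,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  if (!length(corpus)) stopf("empty training corpus")
  vocab <- build_vocabulary(corpus)
  n <- length(corpus)
  src_smiles <- if (mode == "s2m") {
    vapply(corpus, to_generic_scaffold, character(1), USE.NAMES = FALSE)
  } else corpus
  enc_or_fail <- function(s, i) {
    tryCatch(encode_ids(s, vocab, config$L_max),
             error = function(e) stopf("molecule %d ('%s'): %s", i, s,
                                       conditionMessage(e)))
  }
  src_ids <- t(vapply(seq_len(n), function(i) enc_or_fail(src_smiles[i], i),
                      integer(config$L_max)))
  tgt_ids <- t(vapply(seq_len(n), function(i) enc_or_fail(corpus[i], i),
                      integer(config$L_max)))
  with_seed(seed, {
    params <- list(vae = init_vae_params(config, vocab$v),
                   tr = init_tr_params(config, vocab$v))
    opt <- adam_init(params)
    step <- 0L
    log <- list()
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + batch_size - 1L, n)]
        step <- step + 1L
        gamma <- gamma_schedule(step)
        lr <- lr_schedule(step, config$d)
        res <- train_step(params, src_ids[idx, , drop = FALSE],
                          tgt_ids[idx, , drop = FALSE], config, gamma)
        upd <- adam_step(params, res$grads, opt, lr)
        params <- upd$params; opt <- upd$state
        if (step %% log_every == 0L || (epoch == 1L && s0 == 1L)) {
          row <- data.frame(step = step, epoch = epoch, gamma = gamma,
                            lr = lr, l_kl = res$l_kl, l_vr = res$l_vr,
                            l_tr = res$l_tr, total = res$total)
          log[[length(log) + 1L]] <- row
          if (verbose)
            message(sprintf(
              "step %d (epoch %d): total=%.4f kl=%.3f vae=%.3f tr=%.3f lr=%.2e",
              step, epoch, res$total, res$l_kl, res$l_vr, res$l_tr, lr))
        }
      }
    }
    ckpt <- list(params = params, config = config, vocab = vocab,
                 mode = mode, seed = seed, steps = step,
                 loss_log = do.call(rbind, log))
    class(ckpt) <- "sd_checkpoint"
    ckpt
  })
}

# one optimization step on a batch; returns loss parts and gradient tree
train_step <- function(params, src, tgt, cfg, gamma) {
  B <- nrow(src); L <- ncol(src)
  pad <- 1L
  src_mask <- src != pad
  # --- VAE on the source sequence ---
  enc <- vae_encode_fwd(src, src_mask, params$vae, cfg, training = TRUE)
  eps <- matrix(rnorm(B * cfg$dz), B, cfg$dz)
  z <- enc$mu + exp(0.5 * enc$log_var) * eps
  dec <- vae_decode_fwd(z, params$vae, cfg, training = TRUE)
  vr <- ce_masked(dec$probs, src, src_mask, B, L)
  l_kl <- mean(-0.5 * rowSums(1 + enc$log_var - enc$mu^2 - exp(enc$log_var)))
  dKL_dmu <- gamma * enc$mu / B
  dKL_dlv <- gamma * 0.5 * (exp(enc$log_var) - 1) / B
  g_vae <- vae_bwd(vr$dLogits, enc, dec, eps, dKL_dmu, dKL_dlv, src,
                   params$vae, cfg)
  # --- transformer, teacher-forced on the ground-truth source ---
  tgt_out <- cbind(tgt[, -1, drop = FALSE], matrix(pad, B, 1))
  loss_mask <- tgt_out != pad
  fw <- transformer_fwd(src, src_mask, tgt, tgt != pad, params$tr, cfg,
                        training = TRUE)
  tr <- ce_masked(fw$probs, tgt_out, loss_mask, B, L)
  g_tr <- transformer_bwd(tr$dLogits, fw, src, tgt, params$tr, cfg)
  list(grads = list(vae = g_vae, tr = g_tr),
       l_kl = l_kl, l_vr = vr$loss, l_tr = tr$loss,
       total = gamma * l_kl + vr$loss + tr$loss)
}

#' Teacher-forced token accuracy of a trained model
#'
#' Fraction of next-token predictions (argmax under teacher forcing) that
#' match the reference molecule tokens, over all non-pad target positions
#' of the given corpus. Used to monitor memorization on small corpora.
#'
#' @param ckpt An `sd_checkpoint`.
#' @param corpus Character vector of molecules (defaults pairs are rebuilt
#'   with the checkpoint's mode).
#' @return Accuracy in `[0, 1]`.
#' @export
teacher_forced_accuracy <- function(ckpt, corpus) {
  stopifnot(inherits(ckpt, "sd_checkpoint"))
  cfg <- ckpt$config; vocab <- ckpt$vocab
  src_smiles <- if (ckpt$mode == "s2m") {
    vapply(corpus, to_generic_scaffold, character(1), USE.NAMES = FALSE)
  } else corpus
  src <- t(vapply(src_smiles, function(s) encode_ids(s, vocab, cfg$L_max),
                  integer(cfg$L_max)))
  tgt <- t(vapply(corpus, function(s) encode_ids(s, vocab, cfg$L_max),
                  integer(cfg$L_max)))
  fw <- transformer_fwd(src, src != 1L, tgt, tgt != 1L, ckpt$params$tr, cfg,
                        training = FALSE)
  B <- nrow(src); L <- ncol(src)
  tgt_out <- cbind(tgt[, -1, drop = FALSE], matrix(1L, B, 1))
  mask <- tgt_out != 1L
  pred <- matrix(max.col(fw$probs, ties.method = "first"), B, L)
  sum((pred == tgt_out) & mask) / sum(mask)
}
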