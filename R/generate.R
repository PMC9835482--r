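# The two inference modes: random generation from the latent prior, and
# decoration of a given scaffold — both wrapped by the validity-check
# component (discard invalid strings and regenerate).

#' Random molecule generation from the latent prior
#'
#' For each requested molecule a latent vector is drawn from N(0, I),
#' decoded by the VAE into a generic-scaffold string, collapsed to one-hot
#' by per-row argmax, fed to the transformer encoder, and greedily decoded
#' into a molecule string. With the validity check enabled, any chemically
#' invalid output is discarded and regenerated with a fresh latent draw,
#' up to `max_attempts` per slot (a slot that exhausts its attempts is
#' returned with `valid = FALSE`), so every *valid-flagged* batch has
#' validity exactly 100%.
#'
#' Exactly one normal vector is consumed per attempt, in slot order within
#' each retry round, so results are bit-identical for a fixed seed.
#'
#' @param n Number of molecules to generate.
#' @param ckpt An `sd_checkpoint` from [fit_generator()].
#' @param seed Integer seed for the latent draws.
#' @param validity_check Discard-and-retry invalid strings?
#' @param max_attempts Attempt budget per slot.
#' @param batch Internal decode batch size.
#' @return A data.frame with columns `scaffold_smiles`, `molecule_smiles`,
#'   `attempts`, `valid`.
#' @export
sample_random <- function(n, ckpt, seed = 1, validity_check = TRUE,
                          max_attempts = 100, batch = 64) {
  stopifnot(inherits(ckpt, "sd_checkpoint"))
  if (n == 0)
    return(data.frame(scaffold_smiles = character(0),
                      molecule_smiles = character(0),
                      attempts = integer(0), valid = logical(0)))
  cfg <- ckpt$config; vocab <- ckpt$vocab
  out <- data.frame(scaffold_smiles = rep(NA_character_, n),
                    molecule_smiles = rep(NA_character_, n),
                    attempts = rep(0L, n), valid = rep(FALSE, n))
  with_seed(seed, {
    pending <- seq_len(n)
    repeat {
      for (s0 in seq(1L, length(pending), by = batch)) {
        slots <- pending[s0:min(s0 + batch - 1L, length(pending))]
        eps <- t(vapply(slots, function(i) rnorm(cfg$dz), numeric(cfg$dz)))
        res <- generate_from_z(eps, ckpt)
        out$scaffold_smiles[slots] <- res$scaffold
        out$molecule_smiles[slots] <- res$molecule
        out$attempts[slots] <- out$attempts[slots] + 1L
        out$valid[slots] <- is_valid_smiles(res$molecule)
      }
      if (!validity_check) break
      pending <- which(!out$valid & out$attempts < max_attempts)
      if (!length(pending)) break
    }
  })
  out
}

# decode a batch of latent vectors into scaffold and molecule strings
generate_from_z <- function(z, ckpt) {
  cfg <- ckpt$config; vocab <- ckpt$vocab
  B <- nrow(z); L <- cfg$L_max
  probs <- vae_decode_fwd(z, ckpt$params$vae, cfg)$probs  # flat (B*L) x v
  # per-row argmax -> one-hot scaffold (inference branch of the input switch)
  ids <- max.col(probs, ties.method = "first")
  src_ids <- matrix(ids, B, L)
  scaffold <- vapply(seq_len(B), function(b) decode_ids(src_ids[b, ], vocab),
                     character(1))
  src_mask <- seq_mask_from_ids(src_ids, vocab)
  mol_ids <- decode_autoregressive_batch(src_ids, src_mask, ckpt$params$tr,
                                         list(heads = cfg$heads, dropout = 0),
                                         vocab, L - 1L)
  molecule <- vapply(seq_len(B), function(b) decode_ids(mol_ids[b, ], vocab),
                     character(1))
  list(scaffold = scaffold, molecule = molecule)
}

# attention mask for decoded id sequences: positions up to the first end
# token (inclusive); everything if no end token was emitted
seq_mask_from_ids <- function(ids, vocab) {
  B <- nrow(ids); L <- ncol(ids)
  mask <- matrix(TRUE, B, L)
  for (b in seq_len(B)) {
    e <- which(ids[b, ] == vocab$end_id)
    if (length(e)) mask[b, ] <- seq_len(L) <= e[1]
  }
  mask
}

#' Decorate a given scaffold into a molecule
#'
#' The input is reduced to its generic carbon scaffold first (unless
#' `reduce = FALSE`), so an arbitrary seed molecule can be used as input.
#' Decoding is greedy and deterministic; when the validity check is on and
#' the greedy decode is invalid, retries switch to temperature-1.0
#' sampling (greedy retries would be pointless).
#'
#' @param scaffold_smiles A valid SMILES string (scaffold or full
#'   molecule).
#' @param ckpt An `sd_checkpoint`.
#' @param validity_check Retry invalid decodes?
#' @param max_attempts Attempt budget.
#' @param reduce Reduce the input to its generic scaffold first.
#' @param seed Seed for the sampling retries.
#' @return A one-row data.frame like [sample_random()]'s.
#' @export
decorate_scaffold <- function(scaffold_smiles, ckpt, validity_check = TRUE,
                              max_attempts = 100, reduce = TRUE, seed = 1) {
  stopifnot(inherits(ckpt, "sd_checkpoint"))
  if (!is_valid_smiles(scaffold_smiles))
    stopf("invalid scaffold: '%s'", scaffold_smiles)
  scaf <- if (reduce) to_generic_scaffold(scaffold_smiles)
          else canonicalize(scaffold_smiles)
  enc <- encode_onehot(scaf, ckpt$vocab, ckpt$config$L_max)
  with_seed(seed, {
    attempts <- 0L
    mol <- NA_character_
    valid <- FALSE
    repeat {
      attempts <- attempts + 1L
      temp <- if (attempts == 1L) 0 else 1
      mol <- decorate_autoregressive(enc, ckpt$params$tr, ckpt$vocab,
                                     heads = ckpt$config$heads,
                                     temperature = temp)
      valid <- is_valid_smiles(mol)
      if (valid || !validity_check || attempts >= max_attempts) break
    }
    data.frame(scaffold_smiles = scaf, molecule_smiles = mol,
               attempts = attempts, valid = valid)
  })
}

#' Generic validity-check retry loop
#'
#' Invokes `producer` (a zero-argument function returning a SMILES string)
#' up to `max_attempts` times and returns the first output whose
#' canonicalization succeeds, together with the attempt count.
#'
#' @param producer Zero-argument function returning a candidate string.
#' @param max_attempts Attempt budget (`>= 1`).
#' @return List with `smiles` (the first valid output) and `attempts`.
#' @export
validity_check_loop <- function(producer, max_attempts = 100) {
  if (max_attempts < 1) stopf("max_attempts must be >= 1")
  for (attempt in seq_len(max_attempts)) {
    cand <- producer()
    if (is_valid_smiles(cand))
      return(list(smiles = cand, attempts = attempt))
  }
  stopf("validity check exhausted after %d attempts", max_attempts)
}
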