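# SMILES tokenization, the shared source/target vocabulary, and one-hot
# sequence encoding/decoding.

# Multi-character tokens first: bracket atoms, Cl/Br, %nn ring closures.
.smiles_token_re <- "\\[[^\\]]+\\]|Br|Cl|%[0-9]{2}|."

#' Tokenize a SMILES string
#'
#' By default a regex tokenizer that keeps `Cl`, `Br`, bracket atoms
#' `[...]` and `%nn` ring closures as single tokens, so the decoder can
#' never emit a chemically meaningless fragment of a two-character symbol.
#' `char_level = TRUE` splits into single characters instead.
#'
#' @param smiles A SMILES string.
#' @param char_level Split into single characters?
#' @return Character vector of tokens.
#' @export
tokenize_smiles <- function(smiles, char_level = FALSE) {
  if (!is_string(smiles)) stopf("smiles must be a single string")
  if (char_level) return(strsplit(smiles, "", fixed = TRUE)[[1]])
  m <- gregexpr(.smiles_token_re, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles)
    stopf("untokenizable string: '%s'", smiles)
  toks
}

#' Build the shared token vocabulary of a corpus
#'
#' Collects every token appearing in the corpus *and* in the generic
#' scaffolds of the corpus (the source and target sides share one
#' vocabulary), plus the three specials pad/start/end. Ordering is
#' deterministic: specials first, then sorted tokens.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param include_scaffolds Also include tokens of each molecule's generic
#'   scaffold (recommended; scaffold tokens are a subset of
#'   `{C, ring digits, parentheses}` anyway).
#' @param char_level Use character-level tokenization.
#' @return An object of class `sd_vocab`: list with `tokens`, `v`,
#'   `pad_id`, `start_id`, `end_id` (1-based indices) and the tokenizer
#'   mode.
#' @export
build_vocabulary <- function(corpus, include_scaffolds = TRUE,
                             char_level = FALSE) {
  if (length(corpus) == 0) stopf("empty corpus")
  toks <- unlist(lapply(corpus, tokenize_smiles, char_level = char_level))
  if (include_scaffolds) {
    scaf <- vapply(corpus, to_generic_scaffold, character(1))
    toks <- c(toks, unlist(lapply(scaf, tokenize_smiles,
                                  char_level = char_level)))
  }
  tokens <- c("<pad>", "<start>", "<end>",
              sort(unique(toks), method = "radix"))
  vocab <- list(tokens = tokens, v = length(tokens),
                pad_id = 1L, start_id = 2L, end_id = 3L,
                char_level = char_level)
  class(vocab) <- "sd_vocab"
  vocab
}

#' @export
print.sd_vocab <- function(x, ...) {
  cat(sprintf("<sd_vocab> %d tokens (%s): %s\n", x$v,
              if (x$char_level) "char-level" else "regex",
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

token_ids <- function(smiles, vocab) {
  toks <- tokenize_smiles(smiles, char_level = vocab$char_level)
  ids <- match(toks, vocab$tokens)
  if (anyNA(ids))
    stopf("unknown token '%s' in '%s'", toks[which(is.na(ids))[1]], smiles)
  ids
}

# Token-id row of length L_max: start, tokens, end, pads.
encode_ids <- function(smiles, vocab, L_max) {
  ids <- token_ids(smiles, vocab)
  l <- length(ids) + 2L
  if (l > L_max)
    stopf("sequence too long: %d tokens + specials > L_max = %d",
          length(ids), L_max)
  c(vocab$start_id, ids, vocab$end_id, rep(vocab$pad_id, L_max - l))
}

#' One-hot encode a SMILES string
#'
#' Produces the binary sequence matrix consumed by the models: row `t` is
#' the one-hot vector of token `t`, with layout start, tokens, end, then
#' pad rows up to `L_max`.
#'
#' @param smiles SMILES string whose tokens are all in `vocab`.
#' @param vocab An `sd_vocab`.
#' @param L_max Fixed matrix length (tokenized length + 2 must fit).
#' @return List of class `sd_encseq`: `X` (binary `L_max` x `v` matrix) and
#'   `length` (true token count including start/end).
#' @export
encode_onehot <- function(smiles, vocab, L_max) {
  ids <- encode_ids(smiles, vocab, L_max)
  X <- matrix(0, L_max, vocab$v)
  X[cbind(seq_len(L_max), ids)] <- 1
  l <- length(token_ids(smiles, vocab)) + 2L
  structure(list(X = X, length = l, ids = ids), class = "sd_encseq")
}

#' Decode a probability or one-hot matrix to a SMILES string
#'
#' Takes the per-row argmax (ties broken by the lowest token index), maps
#' to tokens, truncates at the first end token and strips the specials.
#' Never errors: whatever string results is judged by downstream validity
#' checking.
#'
#' @param M Matrix with `v` columns (row-stochastic or one-hot).
#' @param vocab An `sd_vocab`.
#' @return The decoded SMILES string (possibly empty).
#' @export
decode_string <- function(M, vocab) {
  if (ncol(M) != vocab$v) stopf("matrix has %d columns, vocabulary size is %d",
                                ncol(M), vocab$v)
  ids <- apply(M, 1, which.max)
  decode_ids(ids, vocab)
}

decode_ids <- function(ids, vocab) {
  stop_at <- which(ids == vocab$end_id)
  if (length(stop_at)) ids <- ids[seq_len(stop_at[1] - 1L)]
  ids <- ids[!(ids %in% c(vocab$pad_id, vocab$start_id, vocab$end_id))]
  paste(vocab$tokens[ids], collapse = "")
}

#' Serialize / reload a vocabulary as a plain-text token list
#'
#' One token per line; the line number is the token index, so reload is
#' bit-exact.
#'
#' @param vocab An `sd_vocab`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c(sprintf("#char_level=%d", as.integer(vocab$char_level)),
               vocab$tokens), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  char_level <- identical(lines[1], "#char_level=1")
  tokens <- lines[-1]
  vocab <- list(tokens = tokens, v = length(tokens),
                pad_id = 1L, start_id = 2L, end_id = 3L,
                char_level = char_level)
  class(vocab) <- "sd_vocab"
  vocab
}
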