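# Shared fixtures, built in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a small fixed molecule list covering rings, branches, heteroatoms, halogens
fixture_smiles <- function() {
  c("CCO", "CCC", "CCN", "CC(C)O", "CCCl", "CCBr", "c1ccccc1", "Cc1ccccc1",
    "c1ccncc1", "C1CCCCC1", "C1CCOCC1", "CC(=O)C", "CCOC", "CC(C)C",
    "CCS", "C1CCNCC1", "Cc1ccco1", "CC(F)C", "c1ccsc1", "CCCO")
}

# a seeded tiny synthetic corpus (cheap, reused across tests)
fixture_corpus <- function(n = 60) {
  memo(paste0("corpus", n), function()
    generate_synthetic_corpus(n, seed = 11, filter = corpus_filter(preset = "tiny")))
}

# a reduced configuration that trains in seconds
fixture_config <- function() {
  model_config(d = 16, dz = 4, m = 2, k = 3, heads = 2, dff = 32,
               n_layers = 2, dropout = 0.1, L_max = 24)
}

# a briefly trained checkpoint on the fixed molecule list (memorization is
# NOT required for the tests that use this; determinism and shapes are)
fixture_checkpoint <- function() {
  memo("ckpt", function()
    fit_generator(fixture_smiles(), fixture_config(), epochs = 30,
                  batch_size = 20, seed = 4, log_every = 10))
}

# random token-id sequences for model-level tests: start, tokens, end, pads
random_ids <- function(B, L, v, len_range = c(4L, L - 2L)) {
  t(vapply(seq_len(B), function(b) {
    l <- sample(len_range[1]:len_range[2], 1)
    c(2L, sample(4:v, l - 2L, replace = TRUE), 3L, rep(1L, L - l))
  }, integer(L)))
}
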