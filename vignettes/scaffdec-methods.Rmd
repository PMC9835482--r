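---
title: "scaffdec: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scaffdec: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`scaffdec`: what the model assumes, which parameters matter, what the
synthetic data generator does and does not emulate, and where the design
was genuinely open.

## The two-step generative model

A molecule is a SMILES token sequence. Its *generic carbon scaffold* is
the molecule obtained by replacing every heavy atom with carbon and
every bond with a single bond — a valid, saturated, uncharged molecule
that preserves heavy-atom count and connectivity and discards
everything else. Generation is split along this abstraction:

1. **Scaffold distribution** (`R/vae.R`). A variational autoencoder over
   scaffold sequences: embedding plus fixed sinusoidal positional
   encoding, `m` residual gated-convolution blocks
   (`A + (A⋆U1+c1) ⊙ σ(A⋆U2+c2)`, kernel `k`, stride 1, symmetric zero
   padding so length is preserved), max-pooling over positions, two
   affine heads for `μ` and `log σ²`, the reparameterization trick, and
   a *non-autoregressive* decoder: an affine map `dz → L_max·d`,
   reshaped row-major to a sequence, `m` more gated-conv blocks, and a
   position-wise softmax. The sequence length is implicit: decoding
   truncates at the first emitted end token.
2. **Decoration** (`R/decorator.R`). A 3-layer encoder/decoder
   transformer with multi-head attention, post-norm residual layer
   normalization, and feed-forward sublayers, sharing one token
   vocabulary (and one embedding matrix) across source and target.
   During training the transformer is *teacher-forced* on the
   ground-truth scaffold, which keeps the loss differentiable and
   severs the gradient path from the transformer into the VAE; at
   inference the VAE output is collapsed by per-row argmax.

The joint objective is `γ·L_KL + L_vr + L_tr`: the closed-form KL of the
diagonal Gaussian posterior from the standard normal prior, and two
natural-log cross-entropies, each averaged over the non-pad positions
of its reference sequence (per sequence, then over the batch).
Optimization is Adam (β₁ = 0.9, β₂ = 0.98, ε = 1e-9, the values
customary for the warm-up schedule used) with
`lr = d^(-1/2)·min(step^(-1/2), step·10000^(-3/2))` and the staircase KL
annealing `γ = min(0.01, 0.001 + ⌊max(0, step−40000)/5000⌋/10000)`:
γ holds at 0.001 through step 44999, then rises by 0.0001 every 5000
steps to the 0.01 cap. Annealing the KL weight is what keeps the
posterior from collapsing while the reconstruction terms are still
large.

## Tunable parameters

| Parameter | Meaning | Full default | Tiny preset |
|---|---|---|---|
| `d` | model/embedding width | 256 | 32 |
| `dz` | latent dimension | 64 | 8 |
| `m` | gated-conv blocks per coder | 3 | 2 |
| `k` | conv kernel (odd) | 3 | 3 |
| `heads` | attention heads | 4 | 2 |
| `dff` | feed-forward width | 1024 | 64 |
| `n_layers` | transformer layers | 3 | 3 |
| `dropout` | dropout rate (both components) | 0.1 | 0.1 |
| `L_max` | fixed sequence length | 128 | 32 |
| batch size | molecules per step | 64 | 64 |

The *tiny preset* (`model_config(tiny = TRUE)`) is the package's
desk-scale configuration: it keeps every mechanism (annealing, warm-up,
teacher forcing, masking) intact while making a full
corpus-train-generate-evaluate cycle run in minutes on one CPU. The
problem sizes used by the shipped end-to-end checks are: a
2000-molecule synthetic corpus, 50 training epochs (1600 steps), 1000
validity-checked samples; a 50-pair corpus at 600 epochs for the
memorization benchmark; 1000–5000 molecules for the structural
property checks.

Two choices specific to the memorization benchmark: its 50
(scaffold, molecule) pairs are drawn with *distinct* generic scaffolds,
because small-molecule corpora share scaffolds heavily and a
one-to-many scaffold-to-molecule map places a structural ceiling on
teacher-forced accuracy that no amount of training removes; and dropout
is set to 0 there, since the benchmark's goal is deliberate
overfitting and dropout exists to prevent exactly that.

## Numerical and architectural decisions

Where the mathematical description leaves room, the package decides as
follows (each of these is pinned by a test):

- **Tokenization.** Regex tokens with `Cl`, `Br`, bracket atoms and
  `%nn` ring closures as single units, so the decoder can never emit
  half of a two-character element symbol. A character-level mode
  (`char_level = TRUE`) is available for comparison. The vocabulary is
  the sorted set of corpus *and* scaffold tokens after the three
  specials (pad, start, end), so both model sides share one index map.
- **Fixed-length sequences.** All sequences are padded to `L_max`.
  Cross-entropies ignore pad positions; the VAE encoder zeroes pad
  embeddings *before* the convolution stack (a k-wide kernel would
  otherwise let pad content bleed into real positions) and masks pads
  to −∞ before max-pooling; the transformer masks pad keys in
  attention. Consequence: the posterior is invariant to anything
  written beyond the end token.
- **Reshape orientation.** The decoder's `z'` is unpacked row-major
  (position-major) to `L_max × d` — the only orientation that types the
  subsequent convolution stack at fixed `L_max`.
- **Argmax ties** break to the lowest token index, for determinism.
- **Layer normalization** is post-norm (applied to the residual sum),
  matching the original transformer this architecture builds on;
  ε = 1e-5.
- **log σ², not σ,** is the latent head output, for numerical
  stability; probabilities are floored at 1e-12 inside logs.
- **Dropout** applies to embeddings, attention outputs and feed-forward
  outputs in the transformer and to the VAE coder inputs/outputs, all
  from one configured rate.
- **Decoding** is greedy argmax. Randomness in *de novo* generation
  comes entirely from the latent draw, so decoding determinism makes
  runs reproducible; a temperature-sampling mode exists and is what the
  scaffold-decoration retry path uses (greedy retries would repeat the
  same string).
- **Validity-check loop.** Up to `max_attempts = 100` regenerations per
  slot (fresh `z` each attempt for random generation; temperature-1
  sampling from the second attempt for decoration). One normal vector
  is consumed per attempt in slot order, making batches bit-identical
  under a fixed seed regardless of internal batching.
- **One RNG stream per run.** Initialization, shuffling,
  reparameterization noise and dropout all draw from a single stream
  seeded at entry; this is simpler than separate streams and equally
  deterministic, and reruns with the same seed produce identical loss
  logs.
- **Training step count** starts at 1 for both schedules (the warm-up
  formula requires step ≥ 1; the γ plateau makes the choice immaterial
  below step 40000).

## Chemistry layer

SMILES parsing, validity, canonicalization, molecular weight, logP,
TPSA and SMARTS matching are delegated to Open Babel via `ChemmineOB`;
molecule identity throughout the package is canonical-SMILES string
equality under Open Babel's canonicalization (any single consistent
canonical form would do; none of the metrics depend on which).
Scaffold extraction neutralizes formal charges and drops isotopes and
stereochemistry before carbon substitution — generic skeletons carry
none of these, and neutralization is what guarantees the scaffold is
itself valid.

Two descriptor components are implemented in the package because no
installed R package provides them:

- **Circular fingerprints** (`ecfp4_fingerprint`): radius-2,
  1024-bit, ECFP4-style. Atom invariants are (atomic number, heavy
  degree, formal charge, implicit-H estimate, aromatic flag);
  environments grow over bonds with the bond order as part of the hash;
  identifiers fold modulo 1024. Duplicate-environment pruning is not
  performed, so absolute bit densities differ slightly from other
  toolkits — Tanimoto *comparisons* within the package are unaffected,
  which is all the metrics require.
- **QED** (`qed_score`): the published desirability-function model
  (weighted geometric mean of eight ADS-transformed properties) on
  Open Babel-computed properties, with the published acceptor and
  structural-alert SMARTS sets (`inst/extdata/`). Two multi-component
  alert patterns are unsupported by Open Babel's SMARTS engine and are
  skipped; together with logP/HBA calculator differences this shifts
  QED by a few hundredths relative to other implementations — the
  same order of disagreement that exists between established QED
  implementations themselves.

## The synthetic corpus generator

`generate_synthetic_corpus()` emulates the structural envelope of
drug-like benchmark sets: heavy atoms from {C, N, O, S, F, Cl, Br},
no formal charges, no ring larger than 8 atoms (the pool only contains
5/6-membered rings), and a molecular-weight window — 250–350 Da by
default, 20–120 Da in the tiny preset. Molecules are grown by seeded
random attachment of fragments (chain atoms, halogen terminals,
aliphatic and aromatic rings, N/O/S heterocycles) under an exact
incremental mass budget; heteroatom–heteroatom and halogen–heteroatom
bonds are excluded, as they are rare in such corpora. Validity is
guaranteed by construction and re-verified by canonicalization;
duplicates are rejected, so a corpus is a set of distinct canonical
SMILES.

What it does **not** emulate: the property *marginals* of real
screening libraries (logP/QED shapes are narrower), PAINS or
medicinal-chemistry alert filtering, stereochemistry, charged species,
tautomer diversity, and rings assembled from multiple fused templates.
Tests passing on this corpus therefore demonstrate that the mechanisms
work (encoding, training dynamics, scaffold fidelity, metric
arithmetic), not that the model reaches any particular quality on real
chemical libraries — full-scale claims would require training on a real
corpus at the full configuration.

## Known limitations

- Training is CPU-bound R + Armadillo; the full 256-dimensional
  configuration on about a million molecules is out of desk-scale reach. The
  implementation is exact, just small.
- The non-autoregressive VAE decoder can emit token sequences that are
  not well-formed SMILES; the validity-check loop absorbs this at
  generation time (and its retry count is reported).
- Scaffolds with atoms of degree > 4 (from hypervalent or charged
  centers) canonicalize but are chemically exotic; the synthetic filter
  never produces them.
- `add_carbon` operates at character level, so it can split a
  two-character token and produce an invalid string — deliberately
  retained, as this is the baseline's characteristic behavior.
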