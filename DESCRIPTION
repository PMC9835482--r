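Package: scaffdec
Title: Two-Step Scaffold-Based Molecule Generation with a VAE and a Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates drug-like molecules in two steps: a variational
    autoencoder with gated convolutions models the distribution of generic
    carbon scaffolds (every heavy atom carbon, every bond single), and a
    sequence-to-sequence transformer decorates a scaffold with atom types and
    bond orders to yield a full molecule, both trained jointly end-to-end on
    SMILES strings. Includes SMILES chemistry utilities backed by Open Babel
    (validity, canonicalization, descriptors, circular fingerprints), the
    generation metrics validity, uniqueness, novelty, recovery, similarity and
    scaffold similarity, an add-a-carbon string baseline, a seeded synthetic
    drug-like corpus generator with MOSES-style structural filters, and
    scaffold-disjoint data splitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
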