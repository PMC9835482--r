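# Chemistry-level operations: canonicalization, generic scaffolds,
# descriptors, fingerprints, file I/O.

test_that("canonicalization maps equivalent SMILES to one form and is idempotent", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize("C(C)O"), canonicalize("CCO"))
  can <- canonicalize("c1ccccc1O")
  expect_identical(canonicalize(can), can)
  for (s in fixture_smiles()) {
    can <- canonicalize(s)
    expect_identical(canonicalize(can), can)
  }
})

test_that("invalid SMILES raise an invalid-molecule error", {
  expect_error(canonicalize("C1CC"), "invalid molecule")
  expect_error(canonicalize(""), "invalid molecule")
  expect_error(canonicalize("xyz[*"), "invalid molecule")
  expect_identical(is_valid_smiles(c("CCO", "C1CC", "")),
                   c(TRUE, FALSE, FALSE))
})

test_that("generic scaffold replaces atoms by carbon and bonds by single bonds", {
  expect_identical(to_generic_scaffold("CCO"), "CCC")
  expect_identical(to_generic_scaffold("c1ccccc1"), "C1CCCCC1")
  expect_identical(to_generic_scaffold("CCC"), "CCC")
  # double bonds become single: acetone -> isobutane skeleton
  expect_identical(to_generic_scaffold("CC(=O)C"),
                   to_generic_scaffold("CC(C)C"))
  # charged input is neutralized before substitution
  expect_identical(to_generic_scaffold("[NH4+]"), "C")
})

test_that("scaffold extraction is idempotent, carbon-only and heavy-atom preserving", {
  corpus <- fixture_corpus()$smiles
  for (s in corpus) {
    scaf <- to_generic_scaffold(s)
    expect_identical(to_generic_scaffold(scaf), scaf)
    g_in <- scaffdec:::mol_graph(s)
    g_out <- scaffdec:::mol_graph(scaf)
    expect_equal(g_out$n_atoms, g_in$n_atoms)
    expect_true(all(g_out$element == "C"))
    expect_true(all(g_out$bonds$order == 1L))
    # scaffold SMILES use only the carbon-skeleton alphabet
    expect_true(all(grepl("^[C0-9()%]+$", scaf)))
  }
})

test_that("descriptors match hand-computed molecular weights", {
  expect_equal(compute_descriptors("C", qed = FALSE)$mw, 16.04, tolerance = 1e-3)
  expect_equal(compute_descriptors("CCO", qed = FALSE)$mw, 46.07, tolerance = 1e-3)
  d <- compute_descriptors("CC(=O)Nc1ccc(O)cc1")
  expect_gt(d$qed, 0); expect_lt(d$qed, 1)
  for (s in c("CCO", "c1ccccc1", "CCN")) {
    q <- qed_score(s)
    expect_gt(q, 0); expect_lt(q, 1)
  }
})

test_that("descriptors agree with an independent toolkit on a tiny fixture", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  smiles <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1")
  script <- paste(
    "from rdkit import Chem",
    "from rdkit.Chem import Descriptors",
    sprintf("for s in %s:", paste0("['", paste(smiles, collapse = "','"), "']")),
    "    m = Chem.MolFromSmiles(s)",
    "    print(Descriptors.MolWt(m))",
    sep = "\n")
  out <- tryCatch(system2("python", "-", input = script, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  skip_if(is.null(out) || length(out) != length(smiles), "rdkit unavailable")
  ref_mw <- as.numeric(out)
  mw <- vapply(smiles, function(s) compute_descriptors(s, qed = FALSE)$mw,
               numeric(1), USE.NAMES = FALSE)
  expect_equal(mw, ref_mw, tolerance = 0.01)
})

test_that("fingerprint Tanimoto is a bounded symmetric similarity with identity 1", {
  expect_equal(ecfp4_tanimoto("CCO", "CCO"), 1)
  expect_equal(ecfp4_tanimoto("CCO", "OCC"), 1)  # canonicalization first
  ab <- ecfp4_tanimoto("CCO", "CCC")
  expect_identical(ab, ecfp4_tanimoto("CCC", "CCO"))
  expect_gt(ab, 0); expect_lt(ab, 1)
  for (pair in list(c("c1ccccc1", "c1ccncc1"), c("CC(C)O", "CCS"))) {
    t12 <- ecfp4_tanimoto(pair[1], pair[2])
    expect_gte(t12, 0); expect_lte(t12, 1)
    expect_identical(t12, ecfp4_tanimoto(pair[2], pair[1]))
  }
})

test_that("Tanimoto equals the set computation on the raw bit vectors", {
  fa <- ecfp4_fingerprint("CCO")
  fb <- ecfp4_fingerprint("CCC")
  expect_length(fa, 1024)
  expect_length(fb, 1024)
  # independent set arithmetic on the bit positions
  a <- which(fa); b <- which(fb)
  expected <- length(intersect(a, b)) / length(union(a, b))
  expect_equal(ecfp4_tanimoto("CCO", "CCC"), expected)
})

test_that(".smi round-trips, skipping blanks and name columns", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "", "  ", "c1ccccc1\tbenzene", "CCC"), path)
  expect_identical(read_smi(path), c("CCO", "c1ccccc1", "CCC"))
  write_smi(c("CCO", "CCN"), path)
  expect_identical(read_smi(path), c("CCO", "CCN"))
  expect_error(read_smi(file.path(tempdir(), "nope.smi")), "no such file")
})

test_that("molecule_records flags invalid rows and caches descriptors for valid ones", {
  rec <- molecule_records(c("CCO", "C1CC"), descriptors = TRUE)
  expect_identical(rec$valid, c(TRUE, FALSE))
  expect_equal(rec$mw[1], 46.07, tolerance = 1e-3)
  expect_true(is.na(rec$mw[2]))
})
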