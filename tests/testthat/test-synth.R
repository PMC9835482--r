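# Synthetic corpus generation, the add-a-carbon baseline, and
# scaffold-disjoint splitting.

test_that("add_carbon inserts exactly one C at a seeded random position", {
  expect_identical(add_carbon("CC", seed = 1), "CCC")
  src <- c("CCO", "c1ccccc1", "CC(=O)N")
  out <- add_carbon(src, seed = 9)
  expect_identical(nchar(out), nchar(src) + 1L)
  # seeded runs are reproducible
  expect_identical(add_carbon(src, seed = 9), out)
  # insertion position is uniform over all nchar+1 slots (character level)
  ins <- add_carbon(rep("OO", 200), seed = 3)
  expect_setequal(unique(ins), c("COO", "OCO", "OOC"))
})

test_that("the corpus generator emits valid, distinct, filter-passing molecules", {
  filt <- corpus_filter(preset = "tiny")
  corpus <- fixture_corpus()
  expect_true(all(corpus$valid))
  expect_identical(anyDuplicated(corpus$smiles), 0L)
  expect_true(all(corpus$mw >= filt$mw_min & corpus$mw <= filt$mw_max))
  for (s in corpus$smiles[1:20]) expect_true(passes_filter(s, filt))
  # determinism
  again <- generate_synthetic_corpus(10, seed = 11, filter = filt)
  expect_identical(again$smiles, generate_synthetic_corpus(10, seed = 11,
                                                           filter = filt)$smiles)
})

test_that("scaffolds of generated molecules keep the ring-size constraint", {
  filt <- corpus_filter(preset = "tiny")
  for (s in fixture_corpus()$smiles[1:15]) {
    scaf <- to_generic_scaffold(s)
    rs <- scaffdec:::ring_sizes(scaf)
    if (length(rs)) expect_lte(max(rs), filt$max_ring_size)
  }
})

test_that("the default filter window bounds molecular weight at 250-350 Da", {
  filt <- corpus_filter()
  expect_equal(filt$mw_min, 250)
  expect_equal(filt$mw_max, 350)
  corpus <- generate_synthetic_corpus(25, seed = 7, filter = filt)
  expect_lte(max(corpus$mw), 350)
  expect_gte(min(corpus$mw), 250)
  expect_true(all(vapply(corpus$smiles[1:5], passes_filter, logical(1),
                         filter = filt)))
})

test_that("scaffold-disjoint splitting keeps novel scaffolds out of train/test", {
  corpus <- fixture_corpus()$smiles
  sp <- split_by_scaffold(corpus, c(0.6, 0.2, 0.2), seed = 5)
  expect_setequal(c(sp$train, sp$test, sp$novel_scaffold), corpus)
  scaf <- function(x) unique(vapply(x, to_generic_scaffold, character(1)))
  expect_length(intersect(scaf(sp$novel_scaffold),
                          scaf(c(sp$train, sp$test))), 0)
  sp2 <- split_by_scaffold(corpus, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(sp2$train, sp$train)
})

test_that("a three-scaffold corpus forces one group per partition", {
  tiny <- c("CCO", "c1ccccc1", "CCCCCC")
  sp <- split_by_scaffold(tiny, c(1, 1, 1) / 3, seed = 1)
  expect_gte(length(sp$novel_scaffold), 1)
  expect_gte(length(sp$train), 1)
  expect_gte(length(sp$test), 1)
  expect_error(split_by_scaffold(c("CCO", "OCC", "CCC"), c(1, 1, 1) / 3),
               "insufficient scaffold diversity")
})

test_that("AddCarbon never recovers references that are not one-carbon extensions", {
  refs <- fixture_smiles()[1:6]
  scafs <- vapply(refs, to_generic_scaffold, character(1), USE.NAMES = FALSE)
  gen <- add_carbon(scafs, seed = 13)
  m <- reference_metrics(gen, refs)
  expect_equal(m$recovery, 0)
  expect_lte(m$similarity, 100)
})
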