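# The add-a-carbon baseline, the seeded synthetic drug-like corpus
# generator, and scaffold-disjoint train/test/novel-scaffold splitting.

#' Structural filter for synthetic corpora
#'
#' The MOSES-style constraints: a molecular-weight window, an allowed
#' element set, no formal charges, and no rings larger than
#' `max_ring_size` atoms. `preset = "tiny"` is the scaled-down window
#' (20-120 Da, 30 tokens) used for fast desk-scale runs.
#'
#' @param mw_min,mw_max Molecular-weight window in Da.
#' @param allowed_elements Heavy-atom element set (hydrogens implicit).
#' @param max_ring_size Largest allowed ring.
#' @param forbid_charges Reject formally charged atoms.
#' @param max_tokens Longest allowed SMILES in tokens (so sequences fit
#'   the model's `L_max` with start/end).
#' @param preset `"moses"` (the default window, 250-350 Da) or `"tiny"`.
#' @return A list of class `sd_filter`.
#' @export
corpus_filter <- function(mw_min = 250, mw_max = 350,
                          allowed_elements = c("C", "N", "O", "F", "S",
                                               "Cl", "Br"),
                          max_ring_size = 8, forbid_charges = TRUE,
                          max_tokens = 126,
                          preset = c("moses", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    mw_min <- 20; mw_max <- 120; max_tokens <- 30
  }
  stopifnot(mw_min < mw_max, max_ring_size >= 3)
  out <- list(mw_min = mw_min, mw_max = mw_max,
              allowed_elements = allowed_elements,
              max_ring_size = max_ring_size,
              forbid_charges = forbid_charges, max_tokens = max_tokens)
  class(out) <- "sd_filter"
  out
}

#' Does a molecule pass a structural filter?
#'
#' @param smiles A SMILES string.
#' @param filter An `sd_filter`.
#' @return TRUE/FALSE (invalid molecules fail).
#' @export
passes_filter <- function(smiles, filter = corpus_filter()) {
  can <- tryCatch(canonicalize(smiles), error = function(e) NULL)
  if (is.null(can)) return(FALSE)
  g <- mol_graph(can)
  if (!all(g$element %in% filter$allowed_elements)) return(FALSE)
  if (filter$forbid_charges && any(g$charge != 0)) return(FALSE)
  rs <- vapply(graph_rings(g), length, integer(1))
  if (length(rs) && max(rs) > filter$max_ring_size) return(FALSE)
  if (length(tokenize_smiles(can)) > filter$max_tokens) return(FALSE)
  mw <- as.numeric(ChemmineOB::prop_OB(ob_mol(can))$MW)
  mw >= filter$mw_min && mw <= filter$mw_max
}

# --- fragment pool --------------------------------------------------------

.h_mass <- 1.008
.atom_frags <- list(
  list(tok = "C",  cap = 4L, mass = 12.011 + 4 * .h_mass, w = 0.50),
  list(tok = "N",  cap = 3L, mass = 14.007 + 3 * .h_mass, w = 0.10),
  list(tok = "O",  cap = 2L, mass = 15.999 + 2 * .h_mass, w = 0.14),
  list(tok = "S",  cap = 2L, mass = 32.06 + 2 * .h_mass,  w = 0.05),
  list(tok = "F",  cap = 1L, mass = 18.998 + .h_mass,     w = 0.09),
  list(tok = "Cl", cap = 1L, mass = 35.45 + .h_mass,      w = 0.08),
  list(tok = "Br", cap = 1L, mass = 79.904 + .h_mass,     w = 0.04)
)
.ring_frags <- list(
  list(tokens = rep("c", 6), sites = 1:5,
       mass = 6 * 12.011 + 6 * .h_mass, w = 0.22),                # benzene
  list(tokens = rep("C", 6), sites = 1:5,
       mass = 6 * 12.011 + 12 * .h_mass, w = 0.10),               # cyclohexane
  list(tokens = rep("C", 5), sites = 1:4,
       mass = 5 * 12.011 + 10 * .h_mass, w = 0.07),               # cyclopentane
  list(tokens = rep("C", 4), sites = 1:3,
       mass = 4 * 12.011 + 8 * .h_mass, w = 0.04),                # cyclobutane
  list(tokens = rep("C", 3), sites = 1:2,
       mass = 3 * 12.011 + 6 * .h_mass, w = 0.04),                # cyclopropane
  list(tokens = c("c", "c", "c", "n", "c", "c"), sites = c(1:3, 5),
       mass = 5 * 12.011 + 14.007 + 5 * .h_mass, w = 0.10),       # pyridine
  list(tokens = c("c", "c", "c", "n", "c", "n"), sites = 1:3,
       mass = 4 * 12.011 + 2 * 14.007 + 4 * .h_mass, w = 0.05),   # pyrimidine
  list(tokens = c("C", "C", "C", "N", "C", "C"), sites = c(1:3, 5),
       mass = 5 * 12.011 + 14.007 + 11 * .h_mass, w = 0.08),      # piperidine
  list(tokens = c("C", "C", "C", "O", "C", "C"), sites = c(1:3, 5),
       mass = 5 * 12.011 + 15.999 + 10 * .h_mass, w = 0.07),      # oxane
  list(tokens = c("C", "C", "C", "N", "C"), sites = c(1:3, 5),
       mass = 4 * 12.011 + 14.007 + 9 * .h_mass, w = 0.05),       # pyrrolidine
  list(tokens = c("C", "C", "C", "O", "C"), sites = c(1:3, 5),
       mass = 4 * 12.011 + 15.999 + 8 * .h_mass, w = 0.05),       # oxolane
  list(tokens = c("c", "c", "c", "s", "c"), sites = 1:3,
       mass = 4 * 12.011 + 32.06 + 4 * .h_mass, w = 0.04),        # thiophene
  list(tokens = c("c", "c", "c", "o", "c"), sites = 1:3,
       mass = 4 * 12.011 + 15.999 + 4 * .h_mass, w = 0.04),       # furan
  list(tokens = c("c", "c", "c", "[nH]", "c"), sites = 1:3,
       mass = 4 * 12.011 + 14.007 + 5 * .h_mass, w = 0.03),       # pyrrole
  list(tokens = c("c", "c", "[nH]", "c", "n"), sites = c(1, 2, 4),
       mass = 3 * 12.011 + 2 * 14.007 + 4 * .h_mass, w = 0.02)    # imidazole
)
.min_child_mass <- 16.043 - 2 * .h_mass  # a methyl branch
# double/triple-bond chain decorations (from a carbon parent with >= 2
# free valences): carbonyl, alkene, imine, thione, nitrile
.multi_frags <- list(
  list(tok = "O", cap = 2L, order = 2L, pre = "=",
       mass = 15.999 + 2 * .h_mass, w = 0.45),
  list(tok = "C", cap = 4L, order = 2L, pre = "=",
       mass = 12.011 + 4 * .h_mass, w = 0.25),
  list(tok = "N", cap = 3L, order = 2L, pre = "=",
       mass = 14.007 + 3 * .h_mass, w = 0.10),
  list(tok = "S", cap = 2L, order = 2L, pre = "=",
       mass = 32.06 + 2 * .h_mass, w = 0.05),
  list(tok = "N", cap = 3L, order = 3L, pre = "#",
       mass = 14.007 + 3 * .h_mass, w = 0.15)
)

# Recursively grow one fragment within a heavy-mass budget. Every bond of
# order b replaces b hydrogens on each side, so the exact molecular weight
# is the sum of standalone fragment masses minus 2 * 1.008 * b per bond.
# Heteroatom-heteroatom and halogen-heteroatom bonds are avoided (as in
# drug-like corpora): a non-carbon parent only accepts carbon or ring
# children (ring attachment sites are always carbons). Double/triple-bond
# decorations (carbonyl, alkene, imine, thione, nitrile) hang off chain
# carbons with enough free valence.
grow_fragment <- function(budget, is_root, env, parent_carbon = TRUE,
                          order_in = 1L) {
  bond_cost <- if (is_root) 0 else 2 * .h_mass * order_in
  use_ring <- order_in == 1L && env$digit < 9L &&
    runif(1) < (if (is_root) 0.75 else 0.30)
  pool <- if (use_ring) .ring_frags else .atom_frags
  if (!use_ring && !parent_carbon)
    pool <- Filter(function(f) f$tok == "C", pool)
  feas <- Filter(function(f) f$mass - bond_cost <= budget + 1, pool)
  if (!length(feas) && use_ring)
    feas <- Filter(function(f) f$mass - bond_cost <= budget + 1,
                   if (parent_carbon) .atom_frags else
                     Filter(function(f) f$tok == "C", .atom_frags))
  if (!length(feas)) return(NULL)
  w <- vapply(feas, `[[`, numeric(1), "w")
  f <- feas[[sample.int(length(feas), 1, prob = w)]]
  mass <- f$mass - bond_cost
  remaining <- budget - mass
  if (!is.null(f$tokens)) {
    env$digit <- env$digit + 1L
    digit <- as.character(env$digit)
    k <- length(f$tokens)
    branch <- rep("", k)
    # atom 1 carries the bond to the parent; it is only substitutable at
    # the root (aromatic carbons have exactly one free valence)
    sites <- if (is_root) f$sites else setdiff(f$sites, 1L)
    for (site in sites[sample.int(length(sites))]) {
      if (remaining < .min_child_mass || runif(1) > 0.5) next
      child <- grow_fragment(remaining * runif(1, 0.4, 1), FALSE, env,
                             parent_carbon = TRUE)
      if (is.null(child)) next
      branch[site] <- paste0(branch[site], "(", child$smi, ")")
      mass <- mass + child$mass
      remaining <- remaining - child$mass
    }
    parts <- vapply(seq_len(k), function(i) {
      if (i == 1L) paste0(f$tokens[i], digit, branch[i])
      else if (i == k) paste0(f$tokens[i], digit)
      else paste0(f$tokens[i], branch[i])
    }, character(1))
    return(list(smi = paste(parts, collapse = ""), mass = mass))
  }
  # chain atom: spend the remaining valence units on children
  units <- f$cap - (if (is_root) 0L else order_in)
  smi <- f$tok
  first <- TRUE
  while (units >= 1L && remaining >= .min_child_mass) {
    p_go <- if (first) 0.9 else 0.4
    if (runif(1) > p_go) break
    child <- NULL
    pre <- ""
    used <- 1L
    if (f$tok == "C" && units >= 2L && runif(1) < 0.3) {
      mf <- Filter(function(m) m$order <= units &&
                     m$mass - 2 * .h_mass * m$order <= remaining + 1,
                   .multi_frags)
      if (length(mf)) {
        mw_ <- vapply(mf, `[[`, numeric(1), "w")
        mfr <- mf[[sample.int(length(mf), 1, prob = mw_)]]
        child <- grow_chain_atom(mfr, remaining * runif(1, 0.4, 1), env)
        if (!is.null(child)) { pre <- mfr$pre; used <- mfr$order }
      }
    }
    if (is.null(child)) {
      child <- grow_fragment(remaining * runif(1, 0.4, 1), FALSE, env,
                             parent_carbon = f$tok == "C")
      pre <- ""
      used <- 1L
    }
    if (is.null(child)) break
    smi <- paste0(smi, "(", pre, child$smi, ")")
    mass <- mass + child$mass
    remaining <- remaining - child$mass
    units <- units - used
    first <- FALSE
  }
  list(smi = smi, mass = mass)
}

# grow a specific multi-bond child fragment (head element and bond order
# fixed by `spec`), then extend its leftover valence with single bonds
grow_chain_atom <- function(spec, budget, env) {
  mass <- spec$mass - 2 * .h_mass * spec$order
  if (mass > budget + 1) return(NULL)
  remaining <- budget - mass
  units <- spec$cap - spec$order
  smi <- spec$tok
  while (units >= 1L && remaining >= .min_child_mass) {
    if (runif(1) > 0.5) break
    child <- grow_fragment(remaining * runif(1, 0.4, 1), FALSE, env,
                           parent_carbon = spec$tok == "C")
    if (is.null(child)) break
    smi <- paste0(smi, "(", child$smi, ")")
    mass <- mass + child$mass
    remaining <- remaining - child$mass
    units <- units - 1L
  }
  list(smi = smi, mass = mass)
}

#' Generate a seeded synthetic drug-like corpus
#'
#' Molecules are grown by random attachment of fragments from a fixed pool
#' (C/N/O/S chain atoms, halogen terminals, five- and six-membered
#' aliphatic and aromatic rings) under an exact incremental
#' molecular-weight budget, then canonicalized. Every emitted molecule is
#' valid and passes the filter by construction: the element set and
#' uncharged atoms come from the pool, rings only come from <=6-membered
#' templates, and proposals outside the weight window or token limit are
#' rejected. Deterministic for a fixed seed.
#'
#' @param n Number of distinct molecules.
#' @param seed Integer seed.
#' @param filter An [corpus_filter()]; its window steers growth.
#' @param max_proposals Proposal budget before giving up.
#' @return A data.frame of molecule records: `smiles` (canonical),
#'   `valid`, `mw`, `logp`, `qed` (NA; compute on demand).
#' @export
generate_synthetic_corpus <- function(n, seed = 1, filter = corpus_filter(),
                                      max_proposals = 400 * n) {
  stopifnot(n >= 1)
  seen <- new.env(parent = emptyenv())
  smiles <- character(n); mw <- numeric(n); logp <- numeric(n)
  count <- 0L
  with_seed(seed, {
    for (prop in seq_len(max_proposals)) {
      if (count >= n) break
      env <- new.env(parent = emptyenv()); env$digit <- 0L
      # upward-biased target: growth tends to undershoot, and the upper
      # part of the window carries most of the structural diversity
      target <- filter$mw_min +
        (filter$mw_max - filter$mw_min) * sqrt(runif(1))
      node <- grow_fragment(target, TRUE, env)
      if (is.null(node)) next
      if (node$mass < filter$mw_min || node$mass > filter$mw_max) next
      if (length(tokenize_smiles(node$smi)) > filter$max_tokens) next
      if (!is.null(seen[[node$smi]])) next  # cheap raw-string pre-dedup
      seen[[node$smi]] <- TRUE
      can <- tryCatch(canonicalize(node$smi), error = function(e) NULL)
      if (is.null(can) || !is.null(seen[[can]])) next
      props <- ChemmineOB::prop_OB(ob_mol(can))
      m <- as.numeric(props$MW)
      if (m < filter$mw_min || m > filter$mw_max) next
      seen[[can]] <- TRUE
      count <- count + 1L
      smiles[count] <- can; mw[count] <- m; logp[count] <- as.numeric(props$logP)
    }
  })
  if (count < n)
    stopf("unable to satisfy the filter: %d of %d molecules after %d proposals",
          count, n, max_proposals)
  data.frame(smiles = smiles, valid = TRUE, mw = mw, logp = logp,
             qed = NA_real_)
}

# --- AddCarbon baseline ---------------------------------------------------

#' The add-a-carbon string baseline
#'
#' Inserts one `"C"` character at a uniformly random position of each
#' input string (character-level, so an insertion may split a
#' two-character token and produce an invalid string — the baseline's
#' sub-100% validity is part of its behavior). Output length is always
#' input length + 1.
#'
#' @param smiles Character vector of source strings (validity not
#'   required).
#' @param seed Optional seed; NULL uses the current RNG stream.
#' @return Character vector of the same length.
#' @export
add_carbon <- function(smiles, seed = NULL) {
  with_seed(seed, vapply(smiles, function(s) {
    pos <- sample.int(nchar(s) + 1L, 1L) - 1L
    paste0(substr(s, 1, pos), "C", substr(s, pos + 1, nchar(s)))
  }, character(1), USE.NAMES = FALSE))
}

# --- scaffold-disjoint splitting -----------------------------------------

#' Scaffold-disjoint train/test/novel-scaffold split
#'
#' Molecules are grouped by canonical generic scaffold; whole scaffold
#' groups are assigned to the novel-scaffold partition until its fraction
#' is met, so no scaffold of the novel set ever appears in train or test;
#' the remaining molecules are split molecule-wise into train and test.
#'
#' @param corpus Character vector of SMILES (or a data.frame with a
#'   `smiles` column).
#' @param fractions Length-3 numeric (train, test, novel), summing to 1.
#' @param seed Integer seed.
#' @return List of class `sd_split` with character vectors `train`,
#'   `test`, `novel_scaffold`, and the `scaffolds` lookup used.
#' @export
split_by_scaffold <- function(corpus, fractions = c(0.8, 0.1, 0.1),
                              seed = 1) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  scaf <- vapply(corpus, to_generic_scaffold, character(1), USE.NAMES = FALSE)
  groups <- split(seq_along(corpus), scaf)
  if (length(groups) < 3) stopf("insufficient scaffold diversity: %d distinct scaffolds",
                                length(groups))
  n <- length(corpus)
  with_seed(seed, {
    ord <- sample(names(groups))
    novel_idx <- integer(0)
    target_novel <- fractions[3] * n
    for (gname in ord) {
      if (length(novel_idx) >= target_novel) break
      novel_idx <- c(novel_idx, groups[[gname]])
    }
    rest <- setdiff(seq_len(n), novel_idx)
    rest <- sample(rest)
    n_train <- round(length(rest) * fractions[1] / (fractions[1] + fractions[2]))
    train_idx <- rest[seq_len(n_train)]
    test_idx <- setdiff(rest, train_idx)
    out <- list(train = corpus[train_idx], test = corpus[test_idx],
                novel_scaffold = corpus[novel_idx],
                scaffolds = stats::setNames(scaf, corpus))
    class(out) <- "sd_split"
    out
  })
}
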