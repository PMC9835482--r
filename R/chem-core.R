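# Chemistry-level operations backed by Open Babel (via ChemmineOB):
# SMILES validity and canonicalization, molecular graphs, generic-scaffold
# extraction, and descriptor calculation.

ob_convert <- function(from, to, text) {
  # Open Babel prints parse warnings to stderr; the empty-output convention
  # is what signals an invalid molecule.
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  out
}

ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

#' Canonicalize a SMILES string
#'
#' Maps any SMILES of a molecule to a unique canonical form (Open Babel's
#' canonical SMILES algorithm), so that string equality on the result is
#' molecule identity. Idempotent: `canonicalize(canonicalize(s)) ==
#' canonicalize(s)`.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @examples
#' canonicalize("OCC")   # "CCO"
#' @export
canonicalize <- function(smiles) {
  if (!is_string(smiles) || !nzchar(smiles))
    stopf("invalid molecule: input must be a non-empty SMILES string")
  out <- ob_convert("SMI", "CAN", smiles)
  out <- sub("[ \t].*$", "", trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1] %||% ""))
  if (is.na(out) || !nzchar(out))
    stopf("invalid molecule: cannot parse SMILES '%s'", smiles)
  out
}

#' Test SMILES strings for chemical validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector: can each string be parsed as a molecule?
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is_string(s) || !nzchar(s)) return(FALSE)
    !inherits(tryCatch(canonicalize(s), error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
}

# --- molecular graph ------------------------------------------------------

# Parse a molecule into a simple graph: atoms (element, charge, aromatic)
# and bonds (i, j, order). Atom order follows the SMILES atom order, which
# Open Babel preserves when writing the molblock; aromaticity is read off
# the SMILES tokens (lowercase atoms) since the molblock is kekulized.
mol_graph <- function(smiles) {
  block <- ob_convert("SMI", "SDF", smiles)
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stopf("invalid molecule: cannot parse SMILES '%s'", smiles)
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stopf("invalid molecule: empty structure for '%s'", smiles)
  atom_lines <- lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1, 3)),
      j = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[ ]+")[[1]])
    n <- flds[1]
    for (q in seq_len(n)) charge[flds[2 * q]] <- flds[2 * q + 1]
  }
  aromatic <- smiles_atom_aromatic(smiles, na)
  list(n_atoms = na, element = elem, charge = charge, aromatic = aromatic,
       bonds = bonds, molblock = lines)
}

# Aromatic flags per atom, in SMILES atom order (lowercase organic-subset
# atoms and lowercase-headed bracket atoms are aromatic).
smiles_atom_aromatic <- function(smiles, n_atoms) {
  toks <- tokenize_smiles(smiles)
  atom <- vapply(toks, is_atom_token, logical(1))
  at <- toks[atom]
  flag <- vapply(at, function(tk) {
    body <- if (startsWith(tk, "[")) sub("^\\[[0-9]*", "", tk) else tk
    grepl("^(b|c|n|o|p|s|se|as)", body)
  }, logical(1))
  if (length(flag) >= n_atoms) flag[seq_len(n_atoms)] else c(flag, rep(FALSE, n_atoms - length(flag)))
}

is_atom_token <- function(tk) {
  grepl("^\\[", tk) || tk %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                                 "Cl", "Br", "b", "c", "n", "o", "p", "s")
}

# --- generic scaffold -----------------------------------------------------

#' Extract the generic carbon scaffold of a molecule
#'
#' The generic scaffold is the molecule obtained by replacing every heavy
#' atom with carbon and every bond with a single bond; it preserves the
#' heavy-atom count and connectivity and nothing else. Formal charges,
#' isotopes, aromaticity and stereochemistry are all erased, so the scaffold
#' is itself a valid (saturated, uncharged) molecule. The operation is
#' idempotent.
#'
#' @param smiles A valid SMILES string.
#' @return Canonical SMILES of the generic scaffold.
#' @examples
#' to_generic_scaffold("CCO")       # "CCC"
#' to_generic_scaffold("c1ccccc1")  # "C1CCCCC1"
#' @export
to_generic_scaffold <- function(smiles) {
  g <- mol_graph(smiles)
  lines <- g$molblock
  na <- g$n_atoms
  nb <- nrow(g$bonds)
  # text surgery on the kekulized molblock: every atom becomes "C ", every
  # bond order 1; charge/isotope property lines are dropped.
  for (idx in seq_len(na)) {
    ln <- lines[4 + idx]
    substr(ln, 32, 34) <- "C  "
    # clear the charge field (columns 37-39) of the atom line
    if (nchar(ln) >= 39) substr(ln, 37, 39) <- "  0"
    lines[4 + idx] <- ln
  }
  for (idx in seq_len(nb)) {
    ln <- lines[4 + na + idx]
    substr(ln, 7, 9) <- "  1"
    lines[4 + na + idx] <- ln
  }
  keep <- !grepl("^M  (CHG|ISO|RAD)", lines)
  block <- paste(lines[keep], collapse = "\n")
  out <- ob_convert("SDF", "CAN", block)
  out <- sub("[ \t].*$", "", trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1] %||% ""))
  if (!nzchar(out)) stopf("scaffold extraction failed for '%s'", smiles)
  out
}

# --- descriptors ----------------------------------------------------------

ob_properties <- function(smiles) {
  mol <- ob_mol(smiles)
  p <- ChemmineOB::prop_OB(mol)
  list(mol = mol, props = p)
}

#' Compute molecular descriptors
#'
#' Molecular weight (standard atomic weights, implicit hydrogens included),
#' the octanol-water partition coefficient logP by Open Babel's
#' atomic-contribution method, and the quantitative estimate of
#' drug-likeness (QED, see [qed_score()]).
#'
#' @param smiles A valid SMILES string.
#' @param qed Compute the QED score too? (It is the expensive part: a SMARTS
#'   scan for structural alerts.)
#' @return A list with `mw` (Da), `logp`, and `qed` (in (0,1), or `NA` when
#'   `qed = FALSE`).
#' @examples
#' compute_descriptors("CCO", qed = FALSE)$mw  # about 46.07
#' @export
compute_descriptors <- function(smiles, qed = TRUE) {
  smiles <- canonicalize(smiles)
  ob <- ob_properties(smiles)
  list(mw = as.numeric(ob$props$MW),
       logp = as.numeric(ob$props$logP),
       qed = if (qed) qed_score(smiles, ob = ob) else NA_real_)
}

#' Build molecule records for a set of SMILES
#'
#' @param smiles Character vector of SMILES strings (not necessarily valid).
#' @param descriptors Attach mw/logP (and optionally QED) for valid records?
#' @param qed Include the QED score (slower)?
#' @return A data.frame with columns `smiles` (canonical where valid),
#'   `valid`, `mw`, `logp`, `qed`. Descriptor columns are `NA` for invalid
#'   rows.
#' @export
molecule_records <- function(smiles, descriptors = TRUE, qed = FALSE) {
  n <- length(smiles)
  out <- data.frame(smiles = as.character(smiles), valid = FALSE,
                    mw = NA_real_, logp = NA_real_, qed = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    can <- tryCatch(canonicalize(smiles[i]), error = function(e) NULL)
    if (is.null(can)) next
    out$smiles[i] <- can
    out$valid[i] <- TRUE
    if (descriptors) {
      d <- compute_descriptors(can, qed = qed)
      out$mw[i] <- d$mw; out$logp[i] <- d$logp; out$qed[i] <- d$qed
    }
  }
  out
}

# --- .smi I/O -------------------------------------------------------------

#' Read a .smi file
#'
#' One SMILES per line; an optional whitespace-separated name is ignored;
#' blank lines are skipped.
#'
#' @param path File path.
#' @return Character vector of SMILES strings.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}

#' Write a .smi file (one SMILES per line)
#'
#' @param smiles Character vector.
#' @param path File path.
#' @export
write_smi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
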