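# Circular (Morgan/ECFP-style) fingerprints and Tanimoto similarity.

# default heavy-atom valences used to estimate implicit hydrogen counts
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1)

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                    Cl = 17, Br = 35, I = 53)

# deterministic 31-bit integer hash of an integer vector
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' 1024-bit circular fingerprint of radius 2
#'
#' An ECFP4-style fingerprint: each atom starts from an invariant hash of
#' (atomic number, heavy degree, formal charge, implicit hydrogen count,
#' aromaticity), environments are grown for two iterations over the bonds
#' (bond order distinguishes single/double/triple/aromatic), and every
#' environment identifier is folded into 1024 bits.
#'
#' @param smiles A valid SMILES string.
#' @return Logical vector of length 1024 (the on-bits of the fingerprint).
#' @export
ecfp4_fingerprint <- function(smiles) {
  smiles <- canonicalize(smiles)
  g <- mol_graph(smiles)
  n <- g$n_atoms
  elem <- g$element
  zn <- .atomic_number[elem]
  zn[is.na(zn)] <- 0
  # adjacency with bond codes (aromatic bond when both atoms aromatic)
  nbrs <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[r]; j <- g$bonds$j[r]; o <- g$bonds$order[r]
      code <- if (g$aromatic[i] && g$aromatic[j]) 4L else o
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, code))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, code))
    }
  }
  degree <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  # implicit H estimate from default valence (kekulized orders)
  bondsum_kek <- vapply(seq_len(n), function(i) {
    b <- g$bonds
    sum(b$order[b$i == i | b$j == i])
  }, integer(1))
  defv <- .default_valence[elem]
  defv[is.na(defv)] <- 4
  nh <- pmax(0L, as.integer(defv) + abs(g$charge) - bondsum_kek)
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(zn[i], degree[i], g$charge[i] + 8L, nh[i], as.integer(g$aromatic[i])))
  }, numeric(1))
  all_ids <- ids
  for (r in 1:2) {
    new_ids <- ids
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (is.null(nb)) { new_ids[i] <- hash_ints(c(r, ids[i])); next }
      pairs <- cbind(nb[, 2], ids[nb[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      new_ids[i] <- hash_ints(c(r, ids[i], as.numeric(t(pairs[ord, , drop = FALSE]))))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- logical(1024)
  bits[unique(all_ids %% 1024) + 1] <- TRUE
  bits
}

#' Tanimoto similarity between two molecules' circular fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|} over the 1024-bit fingerprints of
#' [ecfp4_fingerprint()]. Symmetric; equals 1 for identical canonical
#' SMILES. The degenerate 0/0 case (two atom-free fingerprints) is defined
#' as 1.
#'
#' @param a,b Valid SMILES strings.
#' @return Similarity in \[0, 1\].
#' @export
ecfp4_tanimoto <- function(a, b) {
  fa <- ecfp4_fingerprint(a)
  fb <- ecfp4_fingerprint(b)
  tanimoto_bits(fa, fb)
}

# Tanimoto on two logical bit vectors; 0/0 convention = 1.
tanimoto_bits <- function(fa, fb) {
  un <- sum(fa | fb)
  if (un == 0) return(1)
  sum(fa & fb) / un
}
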