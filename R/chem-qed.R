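# Quantitative estimate of drug-likeness (QED), after Bickerton et al.'s
# desirability-function model: eight physicochemical properties are each
# mapped through an asymmetric double-sigmoid desirability function (ADS)
# and combined as a weighted geometric mean.
#
# Properties here are computed with Open Babel (logP, TPSA, HBD), published
# SMARTS definitions (acceptors, structural alerts, rotatable bonds) and the
# package's own ring perception, so absolute values can differ by a few
# hundredths from other toolkits' QED implementations (a known property of
# QED across property calculators).

.qed_ads <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 1e-09,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939, d = 1e-09,
             e = 1.317690384, f = 0.375760881, dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883, d = 1e-09,
             e = 0.185904477, f = 0.875193782, dmax = 417.725314)
)

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# hydrogen-bond-acceptor SMARTS of the QED model
.qed_acceptors <- c(
  "[oH0;X2]", "[OH1;X2;v2]", "[OH0;X2;v2]", "[OH0;X1;v2]", "[O-;X1]",
  "[SH0;X2;v2]", "[SH0;X1;v2]", "[S-;X1]", "[nH0;X2]", "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]"
)

.qed_rotatable <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.qed_env <- new.env(parent = emptyenv())

qed_alert_smarts <- function() {
  if (is.null(.qed_env$alerts)) {
    path <- system.file("extdata", "qed_structural_alerts.smarts",
                        package = "scaffdec")
    pats <- readLines(path, warn = FALSE)
    # multi-component ("." disconnected) patterns are not supported by the
    # Open Babel SMARTS matcher; drop them up front
    .qed_env$alerts <- pats[!grepl(".", pats, fixed = TRUE)]
  }
  .qed_env$alerts
}

ads <- function(x, p) {
  num <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  num / p[["dmax"]]
}

ob_smarts_count <- function(mol, pattern) {
  res <- tryCatch(suppressWarnings(ChemmineOB::smartsSearch_OB(mol, pattern)),
                  error = function(e) NA_real_)
  as.numeric(res)
}

# --- ring perception ------------------------------------------------------

# Rings of the molecular graph: for every chord of a spanning forest, the
# shortest cycle through that chord (BFS in the graph minus the chord).
# Returns a list of atom-index vectors; covers the cyclomatic ring count.
graph_rings <- function(g) {
  n <- g$n_atoms
  b <- g$bonds
  if (nrow(b) == 0) return(list())
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  # spanning forest by BFS
  in_tree <- rep(FALSE, nrow(b))
  visited <- rep(FALSE, n)
  edge_key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  tree_edges <- character(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          tree_edges <- c(tree_edges, paste(min(u, v), max(u, v)))
          queue <- c(queue, v)
        }
      }
    }
  }
  in_tree <- edge_key %in% tree_edges
  rings <- list()
  for (r in which(!in_tree)) {
    u <- b$i[r]; v <- b$j[r]
    # BFS shortest path u -> v avoiding the chord itself
    prev <- rep(NA_integer_, n)
    seen <- rep(FALSE, n); seen[u] <- TRUE
    queue <- u
    while (length(queue) && !seen[v]) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[x]]) {
        if (x == u && y == v) next
        if (!seen[y]) { seen[y] <- TRUE; prev[y] <- x; queue <- c(queue, y) }
      }
    }
    if (!seen[v]) next
    path <- v
    while (path[1] != u) path <- c(prev[path[1]], path)
    rings[[length(rings) + 1]] <- path
  }
  unique(lapply(rings, function(x) sort(x)))
}

ring_sizes <- function(smiles) {
  g <- mol_graph(smiles)
  vapply(graph_rings(g), length, integer(1))
}

count_aromatic_rings <- function(g) {
  rings <- graph_rings(g)
  if (!length(rings)) return(0L)
  sum(vapply(rings, function(r) all(g$aromatic[r]), logical(1)))
}

# --- QED ------------------------------------------------------------------

#' Quantitative estimate of drug-likeness
#'
#' The weighted-geometric-mean QED score over eight properties: molecular
#' weight, logP, H-bond acceptors and donors, polar surface area, rotatable
#' bonds, aromatic rings and structural-alert count, each passed through its
#' published desirability function. Scores lie strictly inside (0, 1);
#' higher is more drug-like.
#'
#' Two of the published alert patterns use multi-component SMARTS that Open
#' Babel's matcher rejects; they are skipped, which can shift the alert
#' count (and QED by a small amount) relative to other toolkits.
#'
#' @param smiles A valid SMILES string.
#' @param ob Internal: reuse an existing Open Babel molecule/property pair.
#' @return QED score in (0, 1).
#' @export
qed_score <- function(smiles, ob = NULL) {
  smiles <- canonicalize(smiles)
  if (is.null(ob)) ob <- ob_properties(smiles)
  mol <- ob$mol
  props <- ob$props
  g <- mol_graph(smiles)
  hba <- sum(vapply(.qed_acceptors, function(p) {
    x <- ob_smarts_count(mol, p); if (is.na(x)) 0 else x
  }, numeric(1)))
  rotb <- ob_smarts_count(mol, .qed_rotatable) / 2
  alerts <- sum(vapply(qed_alert_smarts(), function(p) {
    x <- ob_smarts_count(mol, p)
    !is.na(x) && x > 0
  }, logical(1)))
  vals <- c(MW = as.numeric(props$MW),
            ALOGP = as.numeric(props$logP),
            HBA = hba,
            HBD = as.numeric(props$HBD),
            PSA = as.numeric(props$TPSA),
            ROTB = rotb,
            AROM = as.numeric(count_aromatic_rings(g)),
            ALERTS = as.numeric(alerts))
  d <- vapply(names(vals), function(k) ads(vals[[k]], .qed_ads[[k]]), numeric(1))
  d <- pmax(d, 1e-10)
  unname(exp(sum(.qed_weights * log(d)) / sum(.qed_weights)))
}
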