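# Batch-level evaluation metrics for SMILES generators. Molecule identity
# throughout is canonical-SMILES string equality.

#' Validity, uniqueness and novelty of a generated batch
#'
#' Validity is the fraction of chemically parseable strings among all
#' generated strings; uniqueness the fraction of distinct canonical SMILES
#' among the valid ones; novelty the fraction of valid molecules whose
#' canonical SMILES is not in the (canonicalized) training set. All three
#' are reported as percentages.
#'
#' @param generated Character vector of generated strings (non-empty).
#' @param training_set Character vector of training SMILES (only needed
#'   for novelty).
#' @return List with `validity`, `uniqueness`, `novelty` (percent),
#'   `n_generated`, `n_valid`.
#' @export
distribution_metrics <- function(generated, training_set = NULL) {
  if (!length(generated)) stopf("empty input: no generated molecules")
  ok <- is_valid_smiles(generated)
  n_valid <- sum(ok)
  validity <- 100 * n_valid / length(generated)
  if (n_valid == 0)
    stopf("no valid molecules: uniqueness/novelty are undefined")
  can <- vapply(generated[ok], canonicalize, character(1), USE.NAMES = FALSE)
  uniqueness <- 100 * length(unique(can)) / n_valid
  novelty <- NA_real_
  if (!is.null(training_set)) {
    train_can <- vapply(training_set, canonicalize, character(1),
                        USE.NAMES = FALSE)
    novelty <- 100 * sum(!(can %in% train_can)) / n_valid
  }
  list(validity = validity, uniqueness = uniqueness, novelty = novelty,
       n_generated = length(generated), n_valid = n_valid)
}

#' Recovery, similarity and scaffold similarity against paired references
#'
#' `generated[i]` must have been produced from the generic scaffold of
#' `references[i]`. Recovery is the fraction of valid generated molecules
#' identical (canonical SMILES) to their reference; similarity the mean
#' fingerprint Tanimoto between valid generated molecules and their
#' references; scaffold similarity the same between the generic scaffolds
#' of the two. All averaged over the valid generated molecules and
#' reported as percentages.
#'
#' @param generated,references Equal-length character vectors.
#' @return List with `recovery`, `similarity`, `scaffold_similarity`
#'   (percent), `n_generated`, `n_valid`.
#' @export
reference_metrics <- function(generated, references) {
  if (length(generated) != length(references))
    stopf("length mismatch: %d generated vs %d references",
          length(generated), length(references))
  ok <- is_valid_smiles(generated)
  n_valid <- sum(ok)
  if (n_valid == 0) stopf("no valid molecules among the generated set")
  gen <- vapply(generated[ok], canonicalize, character(1), USE.NAMES = FALSE)
  ref <- vapply(references[ok], canonicalize, character(1), USE.NAMES = FALSE)
  recovery <- 100 * mean(gen == ref)
  sim <- mean(vapply(seq_along(gen),
                     function(i) ecfp4_tanimoto(gen[i], ref[i]), numeric(1)))
  ss <- mean(vapply(seq_along(gen), function(i) {
    ecfp4_tanimoto(to_generic_scaffold(gen[i]), to_generic_scaffold(ref[i]))
  }, numeric(1)))
  list(recovery = recovery, similarity = 100 * sim,
       scaffold_similarity = 100 * ss,
       n_generated = length(generated), n_valid = n_valid)
}

#' Property-distribution report (MW, logP, QED)
#'
#' Computes the per-molecule molecular weight, logP and QED arrays, a
#' summary table (mean, sd, quartiles) written as CSV, and fixed-policy
#' histograms (50 equal-width bins spanning each property's range) as PNG,
#' into `out_dir`. Invalid molecules are skipped with a warning count.
#'
#' @param molecules Character vector of SMILES.
#' @param out_dir Output directory (created if missing); NULL to skip
#'   writing files.
#' @param qed Include QED (the slow one)?
#' @return Invisibly, a list with the per-molecule `properties`
#'   data.frame, the `summary` data.frame and `n_skipped`.
#' @export
property_distribution_report <- function(molecules, out_dir = NULL,
                                         qed = TRUE) {
  if (!length(molecules)) stopf("empty input: no molecules")
  ok <- is_valid_smiles(molecules)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("%d invalid molecules skipped", n_skipped))
  mols <- molecules[ok]
  if (!length(mols)) stopf("empty input: no valid molecules")
  desc <- lapply(mols, compute_descriptors, qed = qed)
  props <- data.frame(smiles = vapply(mols, canonicalize, character(1),
                                      USE.NAMES = FALSE),
                      mw = vapply(desc, `[[`, numeric(1), "mw"),
                      logp = vapply(desc, `[[`, numeric(1), "logp"),
                      qed = vapply(desc, `[[`, numeric(1), "qed"))
  summ <- do.call(rbind, lapply(c("mw", "logp", "qed"), function(k) {
    x <- props[[k]]
    if (all(is.na(x))) return(NULL)
    data.frame(property = k, mean = mean(x), sd = sd(x),
               q0 = min(x), q25 = quantile(x, 0.25), q50 = quantile(x, 0.5),
               q75 = quantile(x, 0.75), q100 = max(x), row.names = NULL)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(props, file.path(out_dir, "properties.csv"), row.names = FALSE)
    write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (k in c("mw", "logp", "qed")) {
      if (all(is.na(props[[k]]))) next
      dfk <- data.frame(value = props[[k]])
      p <- ggplot2::ggplot(dfk, ggplot2::aes(x = value)) +
        ggplot2::geom_histogram(bins = 50) +
        ggplot2::labs(x = k, y = "count") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, paste0("hist_", k, ".png")), p,
                      width = 5, height = 3.5, dpi = 120)
    }
  }
  invisible(list(properties = props, summary = summ, n_skipped = n_skipped))
}
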