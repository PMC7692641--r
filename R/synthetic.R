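# Synthetic labeled peptide generator with controllable class separation.
#
# Residues are drawn iid from per-class frequency profiles; optional short
# motifs can be implanted at random admissible offsets. This is enough to
# exercise the full pipeline (profile differences create informative
# unigrams and bigrams, motifs create informative trigrams) while staying
# fully auditable. It does not emulate evolutionary correlations,
# amphipathic periodicity, or realistic length/composition coupling.

#' Default per-class residue frequency profiles
#'
#' Three 20-residue simplex profiles plus a shared background. The ACP-like
#' profile is enriched in lysine, leucine, alanine and phenylalanine; the
#' AMP-like profile in glycine, cysteine and (mildly) lysine; the negative
#' profile equals the background. The numbers are repository constants
#' chosen to mirror the qualitative composition differences between the
#' three classes, obtained by multiplying a uniform background by the boost
#' factors below and renormalizing.
#'
#' @return A list with simplex numeric vectors `ACP`, `AMP`, `NEG`,
#'   `background`, each named by residue.
#' @export
default_profiles <- function() {
  bg <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  boost <- function(base, factors) {
    w <- base
    w[names(factors)] <- w[names(factors)] * factors
    w / sum(w)
  }
  list(
    ACP = boost(bg, c(K = 4, L = 3, A = 3, F = 2)),
    AMP = boost(bg, c(G = 3.5, C = 3, K = 2)),
    NEG = bg,
    background = bg
  )
}

#' Configuration for the synthetic peptide generator
#'
#' @param n_per_class Number of peptides per class (single count or a
#'   named vector over ACP/AMP/NEG).
#' @param length_range Inclusive integer range of peptide lengths, within
#'   \[5, 200\] (default \[5, 50\], the length span the classifier is
#'   intended for); lengths are drawn uniformly.
#' @param profiles Per-class residue profiles as from [default_profiles()].
#' @param separation Scalar in \[0, 1\] interpolating each class profile
#'   toward the shared background; 0 makes all classes identically
#'   background-distributed (a null data set by construction).
#' @param motifs Optional named list of class motifs (e.g.
#'   `list(ACP = "KLAK")`) implanted verbatim at a uniform random
#'   admissible offset.
#' @param motif_prob Per-peptide implant probability (default 0: profiles
#'   only).
#' @param seed RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 300L, length_range = c(5L, 50L),
                         profiles = default_profiles(), separation = 1,
                         motifs = NULL, motif_prob = 0, seed = 1L) {
  if (length(n_per_class) == 1) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 3),
                                   PEPTIDE_CLASSES)
  }
  stopifnot(all(PEPTIDE_CLASSES %in% names(n_per_class)),
            all(n_per_class >= 1))
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 5 || length_range[2] > 200) {
    stop("`length_range` must be an increasing integer pair within [5, 200]",
         call. = FALSE)
  }
  for (nm in c(PEPTIDE_CLASSES, "background")) {
    p <- profiles[[nm]]
    if (is.null(p) || length(p) != 20 || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      stop("profile '", nm, "' must be a 20-residue simplex vector",
           call. = FALSE)
    }
  }
  stopifnot(separation >= 0, separation <= 1,
            motif_prob >= 0, motif_prob <= 1)
  structure(
    list(n_per_class = n_per_class[PEPTIDE_CLASSES],
         length_range = length_range, profiles = profiles,
         separation = separation, motifs = motifs,
         motif_prob = motif_prob, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a labeled synthetic peptide set
#'
#' Draws peptide lengths uniformly from the configured range and residues
#' iid from the (separation-interpolated) class profile, then implants the
#' class motif with the configured probability at a uniformly random
#' admissible offset. Deterministic under the configured seed.
#'
#' @param config A [synth_config()].
#' @return A list with `peptides` (labeled peptide table, ids like
#'   `ACP_0001`) and `provenance` (the resolved generation parameters).
#' @export
generate_peptides <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  bg <- config$profiles$background
  out <- lapply(PEPTIDE_CLASSES, function(cl) {
    n <- config$n_per_class[[cl]]
    prof <- config$separation * config$profiles[[cl]] +
      (1 - config$separation) * bg
    # sample.int keeps a degenerate range (min == max) deterministic
    lens <- config$length_range[1] - 1L +
      sample.int(config$length_range[2] - config$length_range[1] + 1L, n,
                 replace = TRUE)
    motif <- config$motifs[[cl]]
    seqs <- vapply(lens, function(len) {
      s <- sample(AA_ALPHABET, len, replace = TRUE, prob = prof)
      if (!is.null(motif) && nchar(motif) <= len &&
          stats::runif(1) < config$motif_prob) {
        at <- sample.int(len - nchar(motif) + 1L, 1L)
        s[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    peptide_set(sprintf("%s_%04d", cl, seq_len(n)), seqs, cl)
  })
  peps <- do.call(rbind, out)
  provenance <- list(
    generator = "pepstack::generate_peptides",
    n_per_class = as.list(config$n_per_class),
    length_range = config$length_range,
    separation = config$separation,
    motifs = config$motifs,
    motif_prob = config$motif_prob,
    seed = config$seed,
    profiles = lapply(config$profiles, as.list)
  )
  list(peptides = peps, provenance = provenance)
}

#' Write a synthetic data set to disk
#'
#' Emits a FASTA file, a two-column labels TSV (`id`, `label`), and a JSON
#' provenance file recording every generation parameter.
#'
#' @param sim Output of [generate_peptides()].
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>_labels.tsv` and `<prefix>_provenance.json`.
#' @return Invisibly the three paths.
#' @export
write_synthetic <- function(sim, prefix) {
  fasta <- paste0(prefix, ".fasta")
  labels <- paste0(prefix, "_labels.tsv")
  prov <- paste0(prefix, "_provenance.json")
  write_fasta(sim$peptides, fasta)
  utils::write.table(sim$peptides[, c("id", "label")], labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$provenance, prov, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fasta, labels = labels, provenance = prov))
}
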