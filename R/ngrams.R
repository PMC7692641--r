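# 5-mer decomposition and binarized gapped n-gram encoding.

#' Admissible gap patterns for the n-gram vocabulary
#'
#' Returns the ordered list of (size, gaps) patterns defining the vocabulary
#' over windows of length `k`:
#' unigrams; bigrams with a single gap of 0 up to `k - 2` residues; trigrams
#' with a gap of 0 or 1 between the first/second and second/third residue.
#' A pattern's span (`n + sum(gaps)`) never exceeds `k`. For the default
#' `k = 5` this gives 1 + 4 + 4 = 9 patterns.
#'
#' @param k Window (mer) length, >= 3.
#' @return A list of lists with elements `n` (size) and `gaps` (integer
#'   vector of gap lengths, length `n - 1`).
#' @export
ngram_gap_patterns <- function(k = 5L) {
  stopifnot(k >= 3)
  pats <- list(list(n = 1L, gaps = integer(0)))
  for (g in 0:(k - 2L)) {
    pats <- c(pats, list(list(n = 2L, gaps = as.integer(g))))
  }
  for (g1 in 0:1) {
    for (g2 in 0:1) {
      if (3L + g1 + g2 <= k) {
        pats <- c(pats, list(list(n = 3L, gaps = as.integer(c(g1, g2)))))
      }
    }
  }
  for (p in pats) {
    if (p$n + sum(p$gaps) > k) {
      stop("gap pattern spans more than the window length", call. = FALSE)
    }
  }
  pats
}

# Residue positions touched by a pattern anchored at its first residue:
# 1, then cumulative (1 + gap).
pattern_positions <- function(pattern) {
  cumsum(c(1L, 1L + pattern$gaps))
}

# Canonical text of a descriptor: residues joined with one "_" per skipped
# position, e.g. "KL" (gap 0), "K__A" (gap 2), "K_A_L" (gaps 1,1).
descriptor_text <- function(residue_matrix, gaps) {
  n <- ncol(residue_matrix)
  out <- residue_matrix[, 1]
  if (n > 1) {
    for (j in 2:n) {
      out <- paste0(out, strrep("_", gaps[j - 1L]), residue_matrix[, j])
    }
  }
  out
}

# All residue n-tuples in lexicographic order (first letter major).
residue_tuples <- function(n) {
  grid <- expand.grid(rep(list(AA_ALPHABET), n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  as.matrix(grid[do.call(order, as.list(grid)), rev(seq_len(n)), drop = FALSE])
}

#' Enumerate the canonical n-gram vocabulary
#'
#' The complete, duplicate-free, canonically ordered list of n-gram
#' descriptors for a window of length `k`. Descriptors are ordered first by
#' gap pattern (unigram; bigram gaps 0,1,2,3; trigram gaps (0,0), (0,1),
#' (1,0), (1,1)), then lexicographically by residues. Under the default
#' `k = 5` the vocabulary holds 20 + 4 * 20^2 + 4 * 20^3 = 33,620
#' descriptors. The order is deterministic across runs.
#'
#' @param k Window length.
#' @return Character vector of descriptor texts, canonically ordered.
#' @examples
#' length(ngram_vocabulary())  # 33620
#' @export
ngram_vocabulary <- function(k = 5L) {
  unlist(lapply(ngram_gap_patterns(k), function(p) {
    tuples <- residue_tuples(p$n)
    # tuples are built lexicographically ordered
    descriptor_text(tuples, p$gaps)
  }), use.names = FALSE)
}

#' Decompose peptides into overlapping 5-mers
#'
#' Slides a window of `k` residues with stride 1 over each peptide,
#' producing `length - k + 1` mers per peptide with ascending 0-based
#' offsets. Training labels are inherited by every mer of a peptide.
#'
#' @param peptides A peptide table; every sequence must have length >= `k`.
#' @param k Window length (default 5).
#' @return A data frame with columns `parent_id`, `offset` (0-based),
#'   `mer`, `label`.
#' @export
decompose_to_mers <- function(peptides, k = 5L) {
  stopifnot(is.data.frame(peptides), k >= 1)
  len <- nchar(peptides$seq)
  too_short <- len < k
  if (any(too_short)) {
    stop("peptide(s) shorter than ", k, " residues cannot be decomposed: ",
         paste(peptides$id[too_short], collapse = ", "), call. = FALSE)
  }
  n_mers <- len - k + 1L
  idx <- rep.int(seq_len(nrow(peptides)), n_mers)
  offset <- unlist(lapply(n_mers, function(n) seq_len(n) - 1L),
                   use.names = FALSE)
  label <- if ("label" %in% names(peptides)) {
    peptides$label[idx]
  } else {
    NA_character_
  }
  data.frame(
    parent_id = peptides$id[idx],
    offset = offset,
    mer = substring(peptides$seq[idx], offset + 1L, offset + k),
    label = label,
    stringsAsFactors = FALSE
  )
}

# Tokenize mers into (row, descriptor) occurrence pairs by sliding every
# gap pattern over every admissible anchor. Returns a list with integer
# vector `i` and character vector `token`; pairs are not deduplicated.
mer_ngram_tokens <- function(mers, k = 5L) {
  stopifnot(all(nchar(mers) == k))
  m <- matrix(unlist(strsplit(mers, "", fixed = TRUE), use.names = FALSE),
              nrow = length(mers), ncol = k, byrow = TRUE)
  ii <- list()
  tok <- list()
  piece <- 1L
  for (p in ngram_gap_patterns(k)) {
    pos <- pattern_positions(p)
    span <- max(pos)
    for (anchor in 0:(k - span)) {
      cols <- anchor + pos
      ii[[piece]] <- seq_len(length(mers))
      tok[[piece]] <- descriptor_text(m[, cols, drop = FALSE], p$gaps)
      piece <- piece + 1L
    }
  }
  list(i = unlist(ii, use.names = FALSE), token = unlist(tok, use.names = FALSE))
}

#' Extract the n-grams present in a single mer
#'
#' The exact set of vocabulary descriptors occurring at one or more
#' positions of the mer. A gap position matches any residue; multiplicity is
#' discarded (presence/absence only) and n-grams are position-independent
#' within the window.
#'
#' @param mer A string of exactly `k` residues.
#' @param k Window length.
#' @return Character vector of distinct descriptors, in canonical
#'   vocabulary order of first occurrence classes (sorted canonically).
#' @examples
#' extract_ngrams("AAAAA")  # 9 descriptors
#' @export
extract_ngrams <- function(mer, k = 5L) {
  mer <- toupper(mer)
  if (length(mer) != 1 || nchar(mer) != k) {
    stop("`mer` must be a single string of exactly ", k, " residues",
         call. = FALSE)
  }
  validate_sequences(mer)
  unique(mer_ngram_tokens(mer, k)$token)
}

#' Build the binary mers-by-n-grams occurrence matrix
#'
#' Entry (i, j) is 1 iff descriptor j occurs at least once in mer i
#' (binarized occurrence). Columns follow the supplied vocabulary order;
#' occurrences of descriptors outside the vocabulary are dropped, which is
#' how prediction-time featurization restricts to a model's selected
#' descriptors.
#'
#' @param mers Output of [decompose_to_mers()] (or a character vector of
#'   mers).
#' @param vocabulary Character vector of descriptors defining the columns;
#'   defaults to the full canonical vocabulary.
#' @param k Window length.
#' @return A sparse binary [Matrix::dgCMatrix-class] with one row per mer
#'   (named `parent_id:offset` when available) and one column per
#'   descriptor.
#' @export
build_feature_matrix <- function(mers, vocabulary = ngram_vocabulary(k),
                                 k = 5L) {
  if (is.data.frame(mers)) {
    mer_seq <- mers$mer
    row_names <- paste(mers$parent_id, mers$offset, sep = ":")
  } else {
    mer_seq <- as.character(mers)
    row_names <- NULL
  }
  if (anyDuplicated(vocabulary)) {
    stop("vocabulary contains duplicate descriptors", call. = FALSE)
  }
  toks <- mer_ngram_tokens(mer_seq, k)
  j <- match(toks$token, vocabulary)
  keep <- !is.na(j)
  pair_key <- paste(toks$i[keep], j[keep])
  first <- !duplicated(pair_key)
  fm <- Matrix::sparseMatrix(
    i = toks$i[keep][first],
    j = j[keep][first],
    x = 1,
    dims = c(length(mer_seq), length(vocabulary)),
    dimnames = list(row_names, vocabulary)
  )
  methods::as(fm, "CsparseMatrix")
}

#' Export a feature matrix as sparse triplets
#'
#' Writes a three-column TSV (`mer`, `descriptor`, `value`) holding the
#' nonzero entries of a binary feature matrix.
#'
#' @param fm A sparse feature matrix from [build_feature_matrix()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_feature_triplets <- function(fm, path) {
  tr <- Matrix::summary(fm)
  out <- data.frame(
    mer = if (is.null(rownames(fm))) tr$i else rownames(fm)[tr$i],
    descriptor = colnames(fm)[tr$j],
    value = as.integer(tr$x)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
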