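# Independent oracles used by the tests. These deliberately take different
# algorithmic routes than the package implementation.

# Subset-enumeration oracle for n-gram extraction: enumerate every subset of
# 1-3 residue positions of the mer, derive its gap pattern from the position
# differences, and keep the admissible ones (bigram gap <= k - 2, trigram
# gaps each <= 1). Position scanning never happens here.
oracle_extract_ngrams <- function(mer, k = 5L) {
  chars <- strsplit(mer, "", fixed = TRUE)[[1]]
  stopifnot(length(chars) == k)
  out <- character(0)
  for (n in 1:3) {
    for (pos in utils::combn(k, n, simplify = FALSE)) {
      gaps <- diff(pos) - 1L
      if (n == 2 && gaps > k - 2L) next
      if (n == 3 && any(gaps > 1L)) next
      txt <- chars[pos[1]]
      if (n > 1) {
        for (j in 2:n) txt <- paste0(txt, strrep("_", gaps[j - 1]), chars[pos[j]])
      }
      out <- c(out, txt)
    }
  }
  unique(out)
}

# Brute-force permutation oracle for QuiPT: enumerate every assignment of
# the target's positive labels to positions and count assignments whose
# information gain reaches the observed one.
oracle_quipt_exact <- function(feature, target) {
  N <- length(feature)
  n_t <- sum(target)
  assignments <- utils::combn(N, n_t, simplify = FALSE)
  obs <- information_gain(sum(feature & target), n_t, sum(feature), N)
  hits <- vapply(assignments, function(pos) {
    y <- integer(N); y[pos] <- 1L
    ig <- information_gain(sum(feature & y), n_t, sum(feature), N)
    ig >= obs - 1e-12 * max(1, obs)
  }, logical(1))
  mean(hits)
}

# Monte-Carlo permutation oracle: permute the target uniformly at random.
oracle_quipt_mc <- function(feature, target, n_perm = 1e5) {
  N <- length(feature)
  n_t <- sum(target)
  obs <- information_gain(sum(feature & target), n_t, sum(feature), N)
  ones <- which(feature == 1)
  hits <- vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(N, n_t)
    ig <- information_gain(sum(pos %in% ones), n_t, sum(feature), N)
    ig >= obs - 1e-12 * max(1, obs)
  }, logical(1))
  mean(hits)
}

# Pairwise-ordering oracle for the Hand-Till AU1U: enumerate every couple
# of samples within each class pair and count correct orderings, 1/2 for
# ties.
oracle_au1u <- function(truth, probs, classes = PEPTIDE_CLASSES) {
  colnames(probs) <- classes
  pair_auc <- function(scores, is_pos) {
    pos <- which(is_pos); neg <- which(!is_pos)
    total <- 0
    for (p in pos) {
      for (q in neg) {
        total <- total + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
      }
    }
    total / (length(pos) * length(neg))
  }
  vals <- c()
  for (pair in utils::combn(classes, 2, simplify = FALSE)) {
    rows <- which(truth %in% pair)
    if (!all(pair %in% truth[rows])) next
    a <- pair_auc(probs[rows, pair[1]], truth[rows] == pair[1])
    b <- pair_auc(probs[rows, pair[2]], truth[rows] == pair[2])
    vals <- c(vals, (a + b) / 2)
  }
  mean(vals)
}

random_mer <- function(k = 5L) {
  paste(sample(AA_ALPHABET, k, replace = TRUE), collapse = "")
}

# Small, quickly separable synthetic sets for model-level unit tests.
tiny_training_set <- function(n = 50, seed = 42) {
  generate_peptides(synth_config(n_per_class = n, length_range = c(5, 20),
                                 seed = seed))$peptides
}

tiny_config <- function(seed = 1) {
  model_config(trees_layer1 = 150L, trees_layer2 = 150L, seed = seed)
}

mito_fixture_path <- function() {
  system.file("extdata", "mito_acps.fasta", package = "pepstack")
}
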