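# Sequence I/O, validation and physicochemical profiling.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino-acid one-letter codes, alphabetically ordered.
#' Every sequence handled by the package is validated against this alphabet;
#' nonstandard codes (B, J, O, U, X, Z) and gap characters are rejected
#' because the n-gram vocabulary is defined over exactly these 20 letters and
#' silently skipping residues would corrupt 5-mer offsets.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy values
#'
#' Per-residue hydropathy indices (Kyte & Doolittle 1982), given to one
#' decimal. Positive values are hydrophobic.
#'
#' @format A named numeric vector of length 20.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Peptide class labels
#'
#' Fixed class order used throughout: anticancer (ACP), antimicrobial (AMP)
#' and background non-ACP/non-AMP (NEG).
#'
#' @format A character vector of length 3.
#' @export
PEPTIDE_CLASSES <- c("ACP", "AMP", "NEG")

#' Assemble a validated peptide table
#'
#' The central data structure is a plain data frame with columns `id`, `seq`
#' and `label`. Sequences are uppercased and checked against
#' [AA_ALPHABET]; ids must be unique.
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of amino-acid sequences (case-insensitive).
#' @param label Optional class labels, each in `c("ACP", "AMP", "NEG")` or
#'   `NA` for unlabeled peptides.
#' @return A data frame with columns `id`, `seq`, `label`.
#' @examples
#' peptide_set("KLA", "KLAKLAKKLAKLAK")
#' @export
peptide_set <- function(id, seq, label = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length", call. = FALSE)
  }
  label <- rep_len(as.character(label), length(id))
  validate_sequences(seq, id)
  dup <- duplicated(id)
  if (any(dup)) {
    stop("duplicate peptide id(s): ", paste(unique(id[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad_label <- !is.na(label) & !label %in% PEPTIDE_CLASSES
  if (any(bad_label)) {
    stop("invalid class label(s): ", paste(unique(label[bad_label]), collapse = ", "),
         "; expected ACP, AMP or NEG", call. = FALSE)
  }
  data.frame(id = id, seq = seq, label = label, stringsAsFactors = FALSE)
}

#' Validate amino-acid sequences
#'
#' Checks that every sequence is non-empty and uses only the 20 canonical
#' amino-acid letters. The error names the offending character and record.
#'
#' @param seq Character vector of (already uppercased) sequences.
#' @param id Optional identifiers used in error messages.
#' @return Invisibly `TRUE`.
#' @keywords internal
validate_sequences <- function(seq, id = seq_along(seq)) {
  if (any(is.na(seq) | !nzchar(seq))) {
    bad <- id[is.na(seq) | !nzchar(seq)]
    stop("empty sequence for record(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    off <- setdiff(unique(chars[[i]]), AA_ALPHABET)
    if (length(off) > 0) {
      stop("invalid residue(s) '", paste(off, collapse = "', '"),
           "' in record '", id[i],
           "'; only the 20 canonical amino-acid letters are allowed",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read peptides from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a peptide
#' table. The record id is the first whitespace-delimited token of the
#' header. Sequences are uppercased and validated against the canonical
#' alphabet; duplicate ids are rejected. An empty file yields an empty table.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional labels: either a named character vector
#'   (names = peptide ids) or the path to a two-column TSV (`id`, `label`).
#' @return A peptide table (see [peptide_set()]).
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(peptide_set(character(0), character(0)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  peps <- peptide_set(ids, seqs)
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      lab_tab <- utils::read.delim(labels, header = TRUE,
                                   stringsAsFactors = FALSE)
      labels <- stats::setNames(lab_tab$label, lab_tab$id)
    }
    peps$label <- unname(labels[peps$id])
    bad <- !is.na(peps$label) & !peps$label %in% PEPTIDE_CLASSES
    if (any(bad)) {
      stop("invalid class label(s) in label table: ",
           paste(unique(peps$label[bad]), collapse = ", "), call. = FALSE)
    }
  }
  peps
}

#' Write peptides to a FASTA file
#'
#' @param peptides A peptide table.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(peptides, path, width = 60L) {
  stopifnot(is.data.frame(peptides), all(c("id", "seq") %in% names(peptides)))
  set <- Biostrings::BStringSet(stats::setNames(peptides$seq, peptides$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Partition peptides by sequence length
#'
#' Splits a peptide table into the records whose length lies in
#' `[min_len, max_len]` and those outside it. The model never sees peptides
#' shorter than the 5-mer window, so training data are filtered at
#' `min_len = 5`. The partition is exhaustive and order-preserving.
#'
#' @param peptides A peptide table.
#' @param min_len Minimum length kept (inclusive), >= 1.
#' @param max_len Optional maximum length kept (inclusive); unbounded if `NULL`.
#' @return A list with elements `kept` and `removed`, both peptide tables.
#' @export
filter_by_length <- function(peptides, min_len = 5L, max_len = NULL) {
  stopifnot(is.data.frame(peptides), min_len >= 1)
  len <- nchar(peptides$seq)
  keep <- len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  list(
    kept = peptides[keep, , drop = FALSE],
    removed = peptides[!keep, , drop = FALSE]
  )
}

# pKa values for the optional pH-dependent charge mode (EMBOSS-like set).
DEFAULT_PKA <- c(
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
  nterm = 8.6, cterm = 3.6
)

#' Net charge of a peptide
#'
#' Default (`method = "counting"`): the simple residue count
#' `#K + #R - #D - #E`, in elementary charge units. Histidine is excluded
#' from the positive count because it is mostly neutral at pH 7. The
#' `"ph"` method instead sums Henderson-Hasselbalch partial charges at the
#' given pH over the ionizable side chains (K, R, H positive; D, E, C, Y
#' negative) and, optionally, the free termini, with a configurable pKa
#' table.
#'
#' @param seq Character vector of validated sequences.
#' @param method `"counting"` (default) or `"ph"`.
#' @param pH pH for the `"ph"` method.
#' @param pka Named pKa table for the `"ph"` method; must contain entries
#'   `K, R, H, D, E, C, Y` and, if `termini = TRUE`, `nterm` and `cterm`.
#' @param termini Include free N/C termini in the `"ph"` method?
#' @return Numeric vector of net charges.
#' @examples
#' net_charge("KLAKLAKKLAKLAK")  # +7
#' @export
net_charge <- function(seq, method = c("counting", "ph"), pH = 7,
                       pka = DEFAULT_PKA, termini = TRUE) {
  method <- match.arg(method)
  seq <- toupper(seq)
  validate_sequences(seq)
  count_res <- function(s, letters) {
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) sum(ch %in% letters), numeric(1))
  }
  if (method == "counting") {
    return(count_res(seq, c("K", "R")) - count_res(seq, c("D", "E")))
  }
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  neg_frac <- function(pk) -1 / (1 + 10^(pk - pH))
  vapply(strsplit(seq, "", fixed = TRUE), function(ch) {
    z <- sum(vapply(ch, function(a) {
      switch(a,
             K = pos_frac(pka[["K"]]), R = pos_frac(pka[["R"]]),
             H = pos_frac(pka[["H"]]),
             D = neg_frac(pka[["D"]]), E = neg_frac(pka[["E"]]),
             C = neg_frac(pka[["C"]]), Y = neg_frac(pka[["Y"]]),
             0)
    }, numeric(1)))
    if (termini) z <- z + pos_frac(pka[["nterm"]]) + neg_frac(pka[["cterm"]])
    z
  }, numeric(1))
}

#' Mean Kyte-Doolittle hydropathy of a peptide
#'
#' Arithmetic mean of the per-residue hydropathy values in [KD_HYDROPATHY].
#'
#' @param seq Character vector of validated sequences.
#' @return Numeric vector of mean hydropathy indices.
#' @examples
#' hydropathy_index("AAAAAAAAAK")  # 1.23
#' @export
hydropathy_index <- function(seq) {
  seq <- toupper(seq)
  validate_sequences(seq)
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) mean(KD_HYDROPATHY[ch]), numeric(1))
}

#' Amino-acid composition
#'
#' Residue frequencies over the 20-letter alphabet. Grouping modes:
#' `"pool"` treats all peptides as one group (pooled residue counts divided
#' by total residues), `"label"` pools within each class label, and
#' `"peptide"` gives one row per peptide. Every row sums to 1.
#'
#' @param peptides A non-empty peptide table.
#' @param by Grouping mode.
#' @return A matrix with one row per group and 20 alphabetical residue
#'   columns.
#' @export
aa_composition <- function(peptides, by = c("pool", "label", "peptide")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(peptides))
  if (nrow(peptides) == 0) {
    stop("cannot compute composition of an empty peptide set", call. = FALSE)
  }
  validate_sequences(peptides$seq, peptides$id)
  count_row <- function(seqs) {
    ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    tab <- table(factor(ch, levels = AA_ALPHABET))
    as.numeric(tab) / length(ch)
  }
  groups <- switch(by,
    pool = list(all = peptides$seq),
    label = split(peptides$seq, peptides$label),
    peptide = stats::setNames(as.list(peptides$seq), peptides$id)
  )
  out <- t(vapply(groups, count_row, numeric(length(AA_ALPHABET))))
  colnames(out) <- AA_ALPHABET
  out
}

#' Per-peptide property table
#'
#' Computes, for each peptide, its length, net charge (counting rule), mean
#' Kyte-Doolittle hydropathy, and 20-residue composition.
#'
#' @param peptides A non-empty peptide table.
#' @return A data frame with columns `id`, `length`, `net_charge`,
#'   `hydropathy`, then the 20 composition columns in alphabetical order.
#' @export
peptide_properties <- function(peptides) {
  stopifnot(is.data.frame(peptides))
  if (nrow(peptides) == 0) {
    stop("empty peptide set", call. = FALSE)
  }
  comp <- aa_composition(peptides, by = "peptide")
  data.frame(
    id = peptides$id,
    length = nchar(peptides$seq),
    net_charge = net_charge(peptides$seq),
    hydropathy = hydropathy_index(peptides$seq),
    comp,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

#' Write a property table as TSV
#'
#' @param props Output of [peptide_properties()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_properties <- function(props, path) {
  utils::write.table(props, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
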