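# Evaluation metrics: confusion matrices, accuracy, Cohen's kappa,
# rank-based AUC, Hand-Till AU1U, and the binarized ACP-vs-rest mode.

#' Confusion matrix over the fixed class order
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels, aligned to `truth`.
#' @param classes Class order for rows (truth) and columns (predicted).
#' @return An integer matrix of counts, truth in rows.
#' @export
confusion_matrix <- function(truth, predicted, classes = PEPTIDE_CLASSES) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Classification accuracy
#'
#' Fraction of correctly classified samples: trace over total.
#'
#' @param cm A square confusion matrix.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy and `p_e` the agreement expected from the marginal
#' distributions. When `p_e = 1` (both marginals degenerate) kappa is
#' defined as 1 if the agreement is also perfect and 0 otherwise.
#'
#' @param cm A square confusion matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Rank-based binary AUC
#'
#' Probability that a uniformly random positive sample scores above a
#' uniformly random negative one, with ties credited 1/2 (Mann-Whitney
#' convention; equals the trapezoidal ROC area).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (logical, or 0/1) aligned to `scores`; both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
binary_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hand-Till AU1U: mean pairwise one-vs-one AUC
#'
#' Multi-class AUC approximation: for each unordered pair of classes
#' \{i, j\}, restrict to samples of those classes and average the AUC of the
#' class-i probability at discriminating i from j with the AUC of the
#' class-j probability at discriminating j from i; AU1U is the mean over
#' all pairs. Pairs missing a class are excluded with a warning.
#'
#' @param truth True class labels.
#' @param probs Numeric matrix of class probabilities with one column per
#'   class (column names = class labels, in the order of `classes`), rows
#'   on the simplex.
#' @param classes Class set.
#' @return AU1U in \[0, 1\].
#' @export
au1u <- function(truth, probs, classes = PEPTIDE_CLASSES) {
  truth <- as.character(truth)
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(truth), ncol(probs) == length(classes))
  colnames(probs) <- classes  # columns are taken in `classes` order
  present <- intersect(classes, unique(truth))
  if (length(present) < 2) {
    stop("need at least two classes present to compute AU1U", call. = FALSE)
  }
  pair_idx <- utils::combn(classes, 2, simplify = FALSE)
  vals <- vapply(pair_idx, function(pair) {
    rows <- truth %in% pair
    if (!all(pair %in% truth)) return(NA_real_)
    a_ij <- binary_auc(probs[rows, pair[1]], truth[rows] == pair[1])
    a_ji <- binary_auc(probs[rows, pair[2]], truth[rows] == pair[2])
    (a_ij + a_ji) / 2
  }, numeric(1))
  if (anyNA(vals)) {
    warning("excluding class pair(s) with a missing class from AU1U")
  }
  mean(vals, na.rm = TRUE)
}

#' Binarize three-class predictions to ACP versus rest
#'
#' Collapses AMP and NEG into a single "rest" class: the ACP score is the
#' ACP probability and the rest score is the AMP + NEG probability sum. The
#' decision is ACP iff the ACP probability strictly exceeds the threshold
#' (default 0.5), making the boundary case deterministic (rest).
#'
#' @param probs Matrix of three-class probabilities (columns ACP, AMP, NEG),
#'   rows on the simplex.
#' @param threshold Decision threshold on the ACP probability.
#' @return Data frame with columns `score_ACP`, `score_rest`, `decision`
#'   (factor ACP/rest).
#' @export
binarize_predictions <- function(probs, threshold = 0.5) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3)
  if (any(abs(rowSums(probs) - 1) > 1e-9) || any(probs < 0)) {
    stop("probability rows must lie on the simplex", call. = FALSE)
  }
  score_acp <- probs[, 1]
  data.frame(
    score_ACP = score_acp,
    score_rest = probs[, 2] + probs[, 3],
    decision = factor(ifelse(score_acp > threshold, "ACP", "rest"),
                      levels = c("ACP", "rest"))
  )
}

#' Binary classification metrics
#'
#' Sensitivity, specificity, precision, accuracy, and the Matthews
#' correlation coefficient for a 2x2 confusion matrix (positive class
#' first, truth in rows). Degenerate denominators are handled as
#' documented: MCC with a zero factor is reported as 0; precision with no
#' predicted positives is reported as `NA`.
#'
#' @param cm A 2x2 confusion matrix with truth in rows, positives first.
#' @return A list with `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `mcc`.
#' @export
binary_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(2, 2)))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- cm[1, 1]; fn <- cm[1, 2]
  fp <- cm[2, 1]; tn <- cm[2, 2]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    accuracy = (tp + tn) / sum(cm),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  )
}

#' Multi-class metrics from labels and probabilities
#'
#' Convenience wrapper computing the three headline measures (accuracy,
#' AU1U, Cohen's kappa) from true labels, a probability matrix, and the
#' corresponding decisions.
#'
#' @param truth True class labels.
#' @param probs Probability matrix (columns in class order).
#' @param decisions Predicted class labels; derived by [decide_class()]
#'   from `probs` when omitted.
#' @param classes Class order.
#' @return A named list with `accuracy`, `au1u`, `kappa`.
#' @export
multiclass_metrics <- function(truth, probs, decisions = NULL,
                               classes = PEPTIDE_CLASSES) {
  if (is.null(decisions)) decisions <- decide_class(probs, classes)
  cm <- confusion_matrix(truth, decisions, classes)
  list(
    accuracy = accuracy(cm),
    au1u = au1u(truth, probs, classes),
    kappa = cohen_kappa(cm)
  )
}
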