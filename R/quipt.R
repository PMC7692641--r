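# Quick Permutation Test (QuiPT): exact feature/class association testing.
#
# For a binary feature x and binary target y, permuting the target labels
# leaves the margins (number of target positives n_t, feature positives n_f)
# fixed, so the co-occurrence count n11 follows a hypergeometric law. The
# exact permutation p-value of any statistic that is a function of the
# contingency table is therefore the hypergeometric tail mass of counts
# whose statistic is at least the observed one — no sampling needed.

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Information gain of a 2x2 contingency table
#'
#' Mutual information (in nats) between a binary feature and a binary
#' target, i.e. `H(target) - H(target | feature)`, with the convention
#' `0 * log 0 = 0`. This is the selection criterion ranked by the
#' permutation test. Vectorized over `n11`.
#'
#' @param n11 Count of rows with feature = 1 and target = 1.
#' @param n1. Count of target positives.
#' @param n.1 Count of feature positives.
#' @param N Total number of rows.
#' @return Information gain in nats (>= 0 up to rounding).
#' @examples
#' information_gain(5, 5, 5, 10)  # log(2)
#' @export
information_gain <- function(n11, n1., n.1, N) {
  stopifnot(N > 0, n1. >= 0, n1. <= N, n.1 >= 0, n.1 <= N)
  lo <- pmax(0, n1. + n.1 - N)
  hi <- pmin(n1., n.1)
  if (any(n11 < lo | n11 > hi)) {
    stop("inconsistent contingency counts: n11 outside [",
         "max(0, n1. + n.1 - N), min(n1., n.1)]", call. = FALSE)
  }
  n10 <- n.1 - n11   # feature 1, target 0
  n01 <- n1. - n11   # feature 0, target 1
  n00 <- N - n.1 - n01
  ig <- (xlogx(n11) + xlogx(n10) + xlogx(n01) + xlogx(n00) -
           xlogx(n.1) - xlogx(N - n.1) - xlogx(n1.) - xlogx(N - n1.) +
           xlogx(N)) / N
  pmax(ig, 0)
}

# Exact tail p-values for every achievable co-occurrence count given the
# margins. Returns a list with the support, per-count statistic, and
# per-count p-value P(IG >= IG(c) - tol) under Hypergeom(N, n_t, n_f).
# Ties in IG are pooled with relative tolerance `tol` so that symmetric
# tables (c and its mirror) both land in the tail.
quipt_tail_table <- function(n_t, n_f, N, tol = 1e-12) {
  support <- max(0L, n_t + n_f - N):min(n_t, n_f)
  ig <- information_gain(support, n_t, n_f, N)
  mass <- stats::dhyper(support, n_t, N - n_t, n_f)
  ord <- order(ig, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  ig_sorted <- ig[ord]
  # p(c) = mass of all support points with IG >= IG(c) - tol * max(1, IG(c));
  # the count of such points is n - #(points < threshold).
  thresh <- ig - tol * pmax(1, abs(ig))
  n_tail <- length(ig_sorted) - findInterval(thresh, rev(ig_sorted))
  pval <- pmin(cum[pmax(n_tail, 1L)], 1)
  list(support = support, statistic = ig, p_value = pval)
}

#' Exact permutation p-value for a binary feature/target pair
#'
#' Computes the information-gain statistic of the observed 2x2 table and
#' its exact permutation p-value by conditioning on the margins: under
#' random relabeling the co-occurrence count is hypergeometric, and the
#' p-value is the total mass of counts whose statistic reaches the observed
#' one (ties pooled with a small relative tolerance). A constant feature or
#' target yields statistic 0 and p-value 1.
#'
#' @param feature Binary (0/1 or logical) vector.
#' @param target Binary vector of the same length.
#' @param criterion Statistic to rank; defaults to [information_gain()].
#'   Must accept `(n11, n1., n.1, N)` vectorized over `n11`.
#' @return A list with `statistic` (nats), `p_value`, and the margins
#'   `n11`, `n_target`, `n_feature`, `n`.
#' @examples
#' quipt_pvalue(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5))  # p = 2/252
#' @export
quipt_pvalue <- function(feature, target, criterion = information_gain) {
  feature <- as.integer(as.logical(feature))
  target <- as.integer(as.logical(target))
  if (length(feature) != length(target)) {
    stop("`feature` and `target` must have the same length", call. = FALSE)
  }
  N <- length(feature)
  if (N < 2) stop("need at least two observations", call. = FALSE)
  n_t <- sum(target)
  n_f <- sum(feature)
  n11 <- sum(feature & target)
  if (n_t %in% c(0L, N) || n_f %in% c(0L, N)) {
    return(list(statistic = 0, p_value = 1,
                n11 = n11, n_target = n_t, n_feature = n_f, n = N))
  }
  tab <- quipt_tail_table_for(criterion, n_t, n_f, N)
  at <- match(n11, tab$support)
  list(statistic = tab$statistic[at], p_value = tab$p_value[at],
       n11 = n11, n_target = n_t, n_feature = n_f, n = N)
}

# Tail table for an arbitrary criterion (information_gain uses the fast
# closed-form path above; other criteria share the same machinery).
quipt_tail_table_for <- function(criterion, n_t, n_f, N, tol = 1e-12) {
  if (identical(criterion, information_gain)) {
    return(quipt_tail_table(n_t, n_f, N, tol))
  }
  support <- max(0L, n_t + n_f - N):min(n_t, n_f)
  stat <- criterion(support, n_t, n_f, N)
  mass <- stats::dhyper(support, n_t, N - n_t, n_f)
  pval <- vapply(stat, function(s) {
    sum(mass[stat >= s - tol * max(1, abs(s))])
  }, numeric(1))
  list(support = support, statistic = stat, p_value = pmin(pval, 1))
}

#' Select informative n-grams across all pairwise class contrasts
#'
#' Runs the exact permutation test on every feature for each of the three
#' pairwise contrasts (ACP/AMP, ACP/NEG, AMP/NEG), restricting rows to the
#' two classes of the contrast. A descriptor is selected when its p-value
#' falls below `alpha` in at least one contrast (union rule; switch to
#' `combine = "intersection"` to require all three). All per-contrast
#' results are retained for audit. No multiple-testing correction is
#' applied beyond the fixed threshold.
#'
#' @param fm Binary feature matrix (mers x descriptors), e.g. from
#'   [build_feature_matrix()].
#' @param labels Class labels aligned to the rows of `fm`; all three
#'   classes must be present.
#' @param alpha Selection threshold on the exact p-value (default 1e-4).
#' @param combine `"union"` (default) or `"intersection"` across contrasts.
#' @param criterion Ranking statistic; defaults to [information_gain()].
#' @return A list with `selected` (descriptors in canonical column order)
#'   and `report` (data frame: descriptor, contrast, statistic, p_value,
#'   selected).
#' @export
select_informative <- function(fm, labels, alpha = 1e-4,
                               combine = c("union", "intersection"),
                               criterion = information_gain) {
  combine <- match.arg(combine)
  stopifnot(nrow(fm) == length(labels), alpha > 0, alpha < 1)
  labels <- as.character(labels)
  missing_cl <- setdiff(PEPTIDE_CLASSES, unique(labels))
  if (length(missing_cl) > 0) {
    stop("class(es) absent from labels: ", paste(missing_cl, collapse = ", "),
         call. = FALSE)
  }
  pairs <- list(c("ACP", "AMP"), c("ACP", "NEG"), c("AMP", "NEG"))
  p_desc <- colnames(fm)
  reports <- lapply(pairs, function(pair) {
    rows <- labels %in% pair
    sub <- fm[rows, , drop = FALSE]
    y <- labels[rows] == pair[1]
    N <- sum(rows)
    n_t <- sum(y)
    n_f <- Matrix::colSums(sub)
    n11 <- Matrix::colSums(sub[y, , drop = FALSE])
    stat <- numeric(length(n_f))
    pval <- rep(1, length(n_f))
    informative <- n_f > 0 & n_f < N
    for (nf in unique(n_f[informative])) {
      tab <- quipt_tail_table_for(criterion, n_t, nf, N)
      cols <- which(n_f == nf)
      at <- match(n11[cols], tab$support)
      stat[cols] <- tab$statistic[at]
      pval[cols] <- tab$p_value[at]
    }
    data.frame(
      descriptor = p_desc,
      contrast = paste(pair, collapse = "/"),
      statistic = stat,
      p_value = pval,
      selected = pval < alpha,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, reports)
  hit <- tapply(report$selected, report$descriptor,
                if (combine == "union") any else all)
  selected <- p_desc[hit[p_desc]]
  list(selected = selected, report = report)
}

#' Write a selection report as TSV
#'
#' @param selection Output of [select_informative()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_selection_report <- function(selection, path) {
  utils::write.table(selection$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
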