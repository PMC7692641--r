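# Stacked two-layer random forest: layer 1 classifies 5-mers from binarized
# n-gram occurrences; layer 2 classifies peptides from summary statistics of
# their mers' class probabilities. Layer-2 training features come from
# layer-1 out-of-bag probabilities so that stacking is leakage-free.

MODEL_SCHEMA_VERSION <- "1"

#' Model configuration
#'
#' @param trees_layer1 Trees in the mer-level forest (default 2000).
#' @param trees_layer2 Trees in the peptide-level forest (default 500).
#' @param mtry Features sampled per split; `NULL` (default) uses
#'   `floor(sqrt(p))` at each layer, the standard classification default.
#' @param alpha Feature-selection p-value threshold (default 1e-4).
#' @param k Mer window length (default 5).
#' @param seed Master RNG seed; expanded into independent per-stage seeds
#'   (feature selection order is deterministic; the forests and fold
#'   shuffles get their own streams).
#' @return A list of class `model_config`.
#' @export
model_config <- function(trees_layer1 = 2000L, trees_layer2 = 500L,
                         mtry = NULL, alpha = 1e-4, k = 5L, seed = 1L) {
  stopifnot(trees_layer1 >= 1, trees_layer2 >= 1,
            alpha > 0, alpha < 1, k >= 3)
  structure(
    list(trees_layer1 = as.integer(trees_layer1),
         trees_layer2 = as.integer(trees_layer2),
         mtry = mtry, alpha = alpha, k = as.integer(k),
         seed = as.integer(seed), classes = PEPTIDE_CLASSES),
    class = "model_config"
  )
}

# Expand the master seed into independent per-stage integer seeds.
stage_seeds <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Class decision from a probability matrix
#'
#' Argmax over class probabilities with exact ties broken toward NEG, then
#' AMP, then ACP — the conservative ordering that minimizes false ACP
#' calls.
#'
#' @param probs Numeric matrix with one column per class in `classes`
#'   order.
#' @param classes Class order.
#' @return Character vector of decisions.
#' @export
decide_class <- function(probs, classes = PEPTIDE_CLASSES) {
  probs <- as.matrix(probs)
  # ties.method = "last" prefers the rightmost (most conservative) class
  classes[max.col(probs, ties.method = "last")]
}

# Names of the peptide-level statistic schema: 7 statistics per class plus
# the mer count, 22 in total.
statistic_schema <- function(classes = PEPTIDE_CLASSES) {
  c(as.vector(t(outer(classes,
                      c("mean", "median", "min", "max", "var",
                        "frac_high", "run_high"),
                      paste, sep = "_"))),
    "n_mers")
}

#' Peptide-level statistics of mer class probabilities
#'
#' Aggregates the ordered sequence of a peptide's mer probabilities into
#' the fixed 22-statistic schema: for each class, the mean, median, min,
#' max and variance of the mer probabilities, the fraction of mers with
#' probability > 0.5, and the longest consecutive run of mers with
#' probability > 0.5 divided by the mer count; plus the mer count itself.
#' The variance of a single mer is 0.
#'
#' @param probs Numeric matrix of mer probabilities (rows = mers in offset
#'   order, columns = classes) for one peptide.
#' @param classes Class order.
#' @return Named numeric vector of length 22.
#' @export
compute_peptide_statistics <- function(probs, classes = PEPTIDE_CLASSES) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1) {
    stop("at least one mer prediction is required", call. = FALSE)
  }
  stopifnot(ncol(probs) == length(classes))
  longest_run <- function(flag) {
    if (!any(flag)) return(0L)
    r <- rle(flag)
    max(r$lengths[r$values])
  }
  n <- nrow(probs)
  out <- unlist(lapply(seq_along(classes), function(ci) {
    p <- probs[, ci]
    v <- if (n == 1) 0 else stats::var(p)
    c(mean(p), stats::median(p), min(p), max(p), v,
      sum(p > 0.5) / n, longest_run(p > 0.5) / n)
  }))
  stats::setNames(c(out, n), statistic_schema(classes))
}

# Statistics for many peptides at once; parent_ids must be grouped with
# mers in offset order (as produced by decompose_to_mers).
peptide_feature_matrix <- function(parent_ids, probs,
                                   classes = PEPTIDE_CLASSES) {
  groups <- split(seq_along(parent_ids),
                  factor(parent_ids, levels = unique(parent_ids)))
  out <- t(vapply(groups, function(idx) {
    compute_peptide_statistics(probs[idx, , drop = FALSE], classes)
  }, numeric(length(statistic_schema(classes)))))
  out
}

# Replace never-out-of-bag rows (possible with few trees) by the mean OOB
# probability profile so downstream statistics stay simplex-valued.
fill_oob_gaps <- function(oob) {
  bad <- !stats::complete.cases(oob) | is.nan(rowSums(oob))
  if (any(bad)) {
    fill <- colMeans(oob[!bad, , drop = FALSE])
    oob[bad, ] <- matrix(fill, sum(bad), ncol(oob), byrow = TRUE)
  }
  oob
}

#' Train the stacked mer/peptide classifier
#'
#' Pipeline: decompose every training peptide into 5-mers (labels
#' inherited), binarize gapped n-gram occurrences, select informative
#' descriptors with the exact permutation test on all three pairwise class
#' contrasts, fit the mer-level probability forest, derive leakage-free
#' mer probabilities for the training set from the forest's out-of-bag
#' predictions, aggregate them into per-peptide statistics, and fit the
#' peptide-level probability forest on those. Deterministic given
#' `config$seed`.
#'
#' @param peptides Labeled peptide table; all three classes must be
#'   present and every sequence must have length >= `config$k`.
#' @param config A [model_config()].
#' @return A `pepstack_model` object (selected descriptors, both forests,
#'   statistic schema, manifest with class counts and seeds).
#' @export
train_model <- function(peptides, config = model_config()) {
  stopifnot(is.data.frame(peptides), inherits(config, "model_config"))
  if (anyNA(peptides$label)) {
    stop("all training peptides must be labeled", call. = FALSE)
  }
  missing_cl <- setdiff(PEPTIDE_CLASSES, unique(peptides$label))
  if (length(missing_cl) > 0) {
    stop("training data must contain all three classes; missing: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  too_short <- nchar(peptides$seq) < config$k
  if (any(too_short)) {
    stop("training peptide(s) shorter than ", config$k, " residues: ",
         paste(peptides$id[too_short], collapse = ", "), call. = FALSE)
  }
  seeds <- stage_seeds(config$seed, 3L)

  mers <- decompose_to_mers(peptides, config$k)
  vocab <- ngram_vocabulary(config$k)
  fm <- build_feature_matrix(mers, vocab, config$k)
  selection <- select_informative(fm, mers$label, alpha = config$alpha)
  if (length(selection$selected) == 0) {
    stop("no n-gram passed the selection threshold (alpha = ", config$alpha,
         "); use more training data or a larger alpha", call. = FALSE)
  }
  x1 <- fm[, selection$selected, drop = FALSE]
  y1 <- factor(mers$label, levels = PEPTIDE_CLASSES)
  mtry1 <- if (is.null(config$mtry)) floor(sqrt(ncol(x1))) else config$mtry
  rf1 <- ranger::ranger(
    x = x1, y = y1, probability = TRUE,
    num.trees = config$trees_layer1, mtry = max(1L, mtry1),
    seed = seeds[1], num.threads = 1L, verbose = FALSE
  )
  oob <- fill_oob_gaps(rf1$predictions[, PEPTIDE_CLASSES, drop = FALSE])

  stats_x <- peptide_feature_matrix(mers$parent_id, oob)
  y2 <- factor(peptides$label[match(rownames(stats_x), peptides$id)],
               levels = PEPTIDE_CLASSES)
  mtry2 <- if (is.null(config$mtry)) floor(sqrt(ncol(stats_x))) else config$mtry
  rf2 <- ranger::ranger(
    x = stats_x, y = y2, probability = TRUE,
    num.trees = config$trees_layer2, mtry = max(1L, mtry2),
    seed = seeds[2], num.threads = 1L, verbose = FALSE
  )

  structure(
    list(
      config = config,
      selected = selection$selected,
      selection_report = selection$report,
      layer1 = rf1,
      statistic_schema = statistic_schema(),
      layer2 = rf2,
      manifest = list(
        schema_version = MODEL_SCHEMA_VERSION,
        classes = PEPTIDE_CLASSES,
        class_counts = as.list(table(peptides$label)),
        n_mers = nrow(mers),
        n_selected = length(selection$selected),
        seed = config$seed,
        stage_seeds = seeds,
        k = config$k,
        alpha = config$alpha,
        trees_layer1 = config$trees_layer1,
        trees_layer2 = config$trees_layer2
      )
    ),
    class = "pepstack_model"
  )
}

#' @export
print.pepstack_model <- function(x, ...) {
  cat("Stacked mer/peptide random-forest classifier\n")
  cat("  classes:        ", paste(x$manifest$classes, collapse = ", "), "\n")
  cat("  selected n-grams:", x$manifest$n_selected, "\n")
  cat("  layer-1 trees:  ", x$manifest$trees_layer1,
      " layer-2 trees: ", x$manifest$trees_layer2, "\n")
  cat("  training mers:  ", x$manifest$n_mers, "\n")
  invisible(x)
}

# Layer-1 probabilities for a mer table under a trained model.
predict_mer_probs <- function(model, mers) {
  fm <- build_feature_matrix(mers, model$selected, model$config$k)
  pred <- stats::predict(model$layer1, data = fm, num.threads = 1L)
  pred$predictions[, PEPTIDE_CLASSES, drop = FALSE]
}

#' Predict peptide classes with a trained model
#'
#' Each valid peptide is decomposed into 5-mers, scored by the mer-level
#' forest, aggregated into the peptide statistics, and classified by the
#' peptide-level forest. Records shorter than the mer window or containing
#' non-canonical residues yield per-record error entries (NA probabilities)
#' rather than aborting the run; peptides longer than 50 residues are
#' predicted but flagged, since the intended use is peptides of at most 50
#' residues.
#'
#' @param model A trained `pepstack_model`.
#' @param peptides Peptide table (labels ignored).
#' @param per_mer If `TRUE`, attach the per-mer probability table as
#'   attribute `"mer_predictions"`.
#' @return Data frame with columns `id`, `prob_ACP`, `prob_AMP`,
#'   `prob_NEG`, `decision`, `warnings` (empty string when clean; an error
#'   note for rejected records).
#' @export
predict_peptides <- function(model, peptides, per_mer = FALSE) {
  stopifnot(inherits(model, "pepstack_model"), is.data.frame(peptides))
  k <- model$config$k
  n <- nrow(peptides)
  seq_up <- toupper(peptides$seq)
  note <- character(n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    chars <- strsplit(seq_up[i], "", fixed = TRUE)[[1]]
    off <- setdiff(unique(chars), AA_ALPHABET)
    if (length(chars) == 0 || length(off) > 0) {
      ok[i] <- FALSE
      note[i] <- paste0("invalid residue(s): ",
                        paste(off, collapse = ","))
    } else if (length(chars) < k) {
      ok[i] <- FALSE
      note[i] <- paste0("sequence shorter than ", k, " residues")
    } else if (length(chars) > 50) {
      note[i] <- "length > 50; model intended for peptides of 5-50 residues"
    }
  }
  if (any(nchar(seq_up) > 50 & ok)) {
    warning("input contains peptide(s) longer than 50 residues; ",
            "predictions are flagged in the `warnings` column")
  }
  probs <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, paste0("prob_", PEPTIDE_CLASSES)))
  decision <- rep(NA_character_, n)
  mer_report <- NULL
  if (any(ok)) {
    valid <- peptide_set(peptides$id[ok], seq_up[ok])
    mers <- decompose_to_mers(valid, k)
    mer_probs <- predict_mer_probs(model, mers)
    stats_x <- peptide_feature_matrix(mers$parent_id, mer_probs)
    stats_x <- stats_x[match(valid$id, rownames(stats_x)), , drop = FALSE]
    pred <- stats::predict(model$layer2, data = stats_x, num.threads = 1L)
    p2 <- pred$predictions[, PEPTIDE_CLASSES, drop = FALSE]
    probs[ok, ] <- p2
    decision[ok] <- decide_class(p2)
    if (per_mer) {
      mer_report <- data.frame(mers[, c("parent_id", "offset", "mer")],
                               mer_probs, stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(
    id = peptides$id,
    probs,
    decision = decision,
    warnings = note,
    stringsAsFactors = FALSE
  )
  if (per_mer) attr(out, "mer_predictions") <- mer_report
  out
}

#' @export
predict.pepstack_model <- function(object, newdata, ...) {
  predict_peptides(object, newdata, ...)
}

#' Length-stratified cross-validation folds
#'
#' Within each class, peptides are sorted by sequence length (ties shuffled
#' under the seed) and dealt to the folds in serpentine order, so every
#' fold sees approximately the same length distribution and per-class fold
#' sizes differ by at most one.
#'
#' @param peptides Labeled peptide table.
#' @param folds Number of folds (>= 2).
#' @param seed RNG seed for tie shuffling.
#' @return Integer vector of fold assignments (1..folds) aligned to
#'   `peptides`.
#' @export
assign_cv_folds <- function(peptides, folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(peptides), folds >= 2)
  cls_sizes <- table(peptides$label)
  if (any(cls_sizes < folds)) {
    stop("every class needs at least `folds` members; too small: ",
         paste(names(cls_sizes)[cls_sizes < folds], collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(peptides))
  for (cl in unique(peptides$label)) {
    idx <- which(peptides$label == cl)
    ord <- idx[order(nchar(peptides$seq[idx]),
                     stats::runif(length(idx)))]
    # serpentine deal (1..folds, folds..1, ...) so no fold systematically
    # receives the shorter member of each length block
    pattern <- rep_len(c(seq_len(folds), rev(seq_len(folds))),
                       length(ord))
    fold[ord] <- pattern
  }
  fold
}

#' Cross-validate both layers of the stacked model
#'
#' For each fold, trains the full pipeline on the remaining folds and
#' evaluates accuracy, AU1U and Cohen's kappa on the held-out mers
#' (mer layer) and held-out peptides (peptide layer).
#'
#' @param peptides Labeled peptide table.
#' @param config A [model_config()]; per-fold training seeds are derived
#'   from `config$seed`.
#' @param folds Number of folds (default 5).
#' @return A list with `per_fold` (long data frame: fold, layer, measure,
#'   value), `summary` (layer x measure with mean, sd and se across
#'   folds), and `fold_assignment`.
#' @export
cross_validate <- function(peptides, config = model_config(), folds = 5L) {
  fold <- assign_cv_folds(peptides, folds, seed = stage_seeds(config$seed, 3L)[3])
  fold_seeds <- stage_seeds(config$seed + 1L, folds)
  rows <- list()
  for (f in seq_len(folds)) {
    train_set <- peptides[fold != f, , drop = FALSE]
    test_set <- peptides[fold == f, , drop = FALSE]
    cfg <- config
    cfg$seed <- fold_seeds[f]
    fit <- train_model(train_set, cfg)

    test_mers <- decompose_to_mers(test_set, config$k)
    mer_probs <- predict_mer_probs(fit, test_mers)
    mer_m <- multiclass_metrics(test_mers$label, mer_probs)

    pep_pred <- predict_peptides(fit, test_set)
    pep_probs <- as.matrix(pep_pred[, paste0("prob_", PEPTIDE_CLASSES)])
    pep_m <- multiclass_metrics(test_set$label, pep_probs,
                                decisions = pep_pred$decision)

    rows[[f]] <- data.frame(
      fold = f,
      layer = rep(c("mer", "peptide"), each = 3),
      measure = rep(c("accuracy", "au1u", "kappa"), 2),
      value = c(mer_m$accuracy, mer_m$au1u, mer_m$kappa,
                pep_m$accuracy, pep_m$au1u, pep_m$kappa),
      stringsAsFactors = FALSE
    )
  }
  per_fold <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ layer + measure, per_fold, function(v) {
    c(mean = mean(v), sd = stats::sd(v), se = stats::sd(v) / sqrt(length(v)))
  })
  summary <- data.frame(agg[, c("layer", "measure")],
                        agg$value, stringsAsFactors = FALSE)
  list(per_fold = per_fold, summary = summary, fold_assignment = fold)
}

#' Save a trained model archive
#'
#' Writes the model as a single compressed archive containing a manifest
#' (schema version, configuration, seeds, selected descriptors, class
#' order) together with both forests.
#'
#' @param model A `pepstack_model`.
#' @param path Output path (conventionally `.rds`).
#' @return Invisibly `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pepstack_model"))
  saveRDS(model, path, compress = "gzip")
  invisible(path)
}

#' Load a trained model archive
#'
#' Validates the archive and its schema version; a truncated or foreign
#' file yields an explicit load error, and an incompatible schema version
#' an explicit incompatibility error.
#'
#' @param path Path to an archive written by [save_model()].
#' @return A `pepstack_model`.
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model archive '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(model, "pepstack_model") || is.null(model$manifest)) {
    stop("'", path, "' is not a pepstack model archive", call. = FALSE)
  }
  if (!identical(model$manifest$schema_version, MODEL_SCHEMA_VERSION)) {
    stop("incompatible model schema version '",
         model$manifest$schema_version, "' (expected '",
         MODEL_SCHEMA_VERSION, "')", call. = FALSE)
  }
  model
}
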