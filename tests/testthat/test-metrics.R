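test_that("confusion matrix counts with fixed class order", {
  cm <- confusion_matrix(c("ACP", "ACP", "AMP", "NEG"),
                         c("ACP", "AMP", "AMP", "NEG"))
  expect_equal(dim(cm), c(3, 3))
  expect_equal(sum(cm), 4)
  expect_equal(cm["ACP", "AMP"], 1L)
  perfect <- confusion_matrix(rep(PEPTIDE_CLASSES, 5), rep(PEPTIDE_CLASSES, 5))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  all_neg <- confusion_matrix(rep(PEPTIDE_CLASSES, 3), rep("NEG", 9))
  expect_true(all(all_neg[, c("ACP", "AMP")] == 0))
  # false-ACP rate bookkeeping on a 194-negative set with 3 ACP calls
  neg <- confusion_matrix(rep("NEG", 194),
                          c(rep("ACP", 3), rep("NEG", 191)))
  expect_equal(neg["NEG", "ACP"] / sum(neg["NEG", ]), 3 / 194)
  expect_error(confusion_matrix("ACP", "FOO"), "unknown")
})

test_that("accuracy and kappa match hand-computed worked examples", {
  cm <- matrix(c(30, 10, 10, 50), 2, 2, byrow = TRUE)
  expect_equal(accuracy(cm), 0.8)
  expect_equal(cohen_kappa(cm), 0.28 / 0.48)
  diag3 <- diag(c(5, 6, 7))
  expect_equal(accuracy(diag3), 1)
  expect_equal(cohen_kappa(diag3), 1)
  zero_diag <- matrix(1, 3, 3) - diag(3)
  expect_equal(accuracy(zero_diag), 0)
  # predicting a single class always gives kappa 0
  one_col <- matrix(c(3, 0, 0, 7, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(cohen_kappa(one_col), 0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("kappa is invariant under simultaneous class permutation", {
  set.seed(3)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 5), 3, 3)
    perm <- sample(3)
    expect_equal(cohen_kappa(cm), cohen_kappa(cm[perm, perm]))
  }
})

test_that("binary AUC is the tie-aware pairwise ordering probability", {
  expect_equal(binary_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(binary_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(binary_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(binary_auc(1:3, c(1, 1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:10) {
    scores <- round(runif(30), 1)
    labels <- rbinom(30, 1, 0.5)
    if (sum(labels) %in% c(0, 30)) next
    ref <- as.numeric(pROC::auc(labels, scores, direction = "<",
                                quiet = TRUE))
    expect_equal(binary_auc(scores, labels), ref)
  }
})

test_that("AU1U equals the pairwise-enumeration oracle on random instances", {
  one_hot <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  expect_equal(au1u(rep(PEPTIDE_CLASSES, 2), one_hot), 1)
  flat <- matrix(1 / 3, 6, 3)
  expect_equal(au1u(rep(PEPTIDE_CLASSES, 2), flat), 0.5)
  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    truth <- sample(PEPTIDE_CLASSES, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    probs <- matrix(rgamma(n * 3, 1), n, 3)
    probs <- probs / rowSums(probs)
    if (length(unique(truth)) < 3) {
      expect_warning(got <- au1u(truth, probs), "missing")
    } else {
      got <- au1u(truth, probs)
    }
    expect_equal(got, oracle_au1u(truth, probs))
  }
  expect_error(au1u(rep("ACP", 4), matrix(1 / 3, 4, 3)), "two classes")
})

test_that("two-class AU1U reduces to the binary AUC", {
  set.seed(21)
  truth <- sample(c("ACP", "AMP"), 30, replace = TRUE)
  truth[1:2] <- c("ACP", "AMP")
  p_acp <- runif(30)
  p_amp <- (1 - p_acp) * 0.8
  probs <- cbind(p_acp, p_amp, 1 - p_acp - p_amp)
  expect_warning(got <- au1u(truth, probs), "missing")
  expect_equal(got, binary_auc(p_acp, truth == "ACP"))
})

test_that("binarization sums AMP and NEG into the rest class", {
  probs <- rbind(c(0.2, 0.5, 0.3), c(0.6, 0.3, 0.1), c(0.5, 0.25, 0.25))
  bin <- binarize_predictions(probs)
  expect_equal(bin$score_rest, c(0.8, 0.4, 0.5))
  expect_equal(bin$score_ACP + bin$score_rest, rep(1, 3))
  # strict threshold: exactly 0.5 falls to rest
  expect_equal(as.character(bin$decision), c("rest", "ACP", "rest"))
  expect_error(binarize_predictions(rbind(c(0.9, 0.3, 0.1))), "simplex")
})

test_that("binary metrics match the hand-computed table and handle degenerates", {
  cm <- matrix(c(30, 10, 10, 50), 2, 2, byrow = TRUE)
  m <- binary_metrics(cm)
  expect_equal(m$mcc, 1400 / 2400)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 50 / 60)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 0.8)
  perfect <- binary_metrics(matrix(c(4, 0, 0, 6), 2, 2, byrow = TRUE))
  expect_true(all(unlist(perfect) == 1))
  none_pred <- binary_metrics(matrix(c(0, 5, 0, 5), 2, 2, byrow = TRUE))
  expect_true(is.na(none_pred$precision))
  expect_equal(none_pred$mcc, 0)
})

test_that("metrics stay in their documented ranges on random inputs", {
  set.seed(29)
  for (i in 1:200) {
    cm <- matrix(rpois(9, sample(1:10, 1)), 3, 3)
    if (sum(cm) == 0) next
    expect_gte(accuracy(cm), 0); expect_lte(accuracy(cm), 1)
    k <- cohen_kappa(cm)
    expect_gte(k, -1); expect_lte(k, 1)
  }
  for (i in 1:200) {
    scores <- runif(20)
    labels <- rbinom(20, 1, 0.5)
    if (sum(labels) %in% c(0, 20)) next
    a <- binary_auc(scores, labels)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})
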