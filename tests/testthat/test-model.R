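test_that("peptide statistics match hand computation", {
  # three mers, all certainly ACP
  const <- matrix(rep(c(1, 0, 0), each = 3), 3, 3)
  s <- compute_peptide_statistics(const)
  expect_equal(unname(s[c("ACP_mean", "ACP_median", "ACP_min", "ACP_max")]),
               rep(1, 4))
  expect_equal(unname(s["ACP_var"]), 0)
  expect_equal(unname(s[c("ACP_frac_high", "ACP_run_high")]), c(1, 1))
  expect_equal(unname(s["n_mers"]), 3)

  # p_ACP = (0.9, 0.2, 0.8): two above 0.5 but never adjacent
  p_acp <- c(0.9, 0.2, 0.8)
  probs <- cbind(p_acp, (1 - p_acp) / 2, (1 - p_acp) / 2)
  s2 <- compute_peptide_statistics(probs)
  expect_equal(unname(s2["ACP_mean"]), mean(p_acp))
  expect_equal(unname(s2["ACP_frac_high"]), 2 / 3)
  expect_equal(unname(s2["ACP_run_high"]), 1 / 3)
  expect_equal(unname(s2["ACP_median"]), 0.8)
  expect_equal(unname(s2["ACP_var"]), var(p_acp))

  # single mer: run and fraction statistics coincide
  one <- compute_peptide_statistics(matrix(c(0.7, 0.2, 0.1), 1, 3))
  expect_equal(unname(one["ACP_frac_high"]), unname(one["ACP_run_high"]))
  expect_equal(unname(one["AMP_frac_high"]), unname(one["AMP_run_high"]))
  expect_equal(unname(one["ACP_var"]), 0)
  expect_length(s, 22)
  expect_error(compute_peptide_statistics(matrix(numeric(0), 0, 3)),
               "at least one")
})

test_that("training demands all three classes and long-enough peptides", {
  peps <- tiny_training_set(30)
  expect_error(train_model(peps[peps$label != "NEG", ], tiny_config()),
               "NEG")
  bad <- rbind(peps, peptide_set("shorty", "KLAK", label = "ACP"))
  expect_error(train_model(bad, tiny_config()), "shorty")
  unlabeled <- peps
  unlabeled$label[3] <- NA
  expect_error(train_model(unlabeled, tiny_config()), "labeled")
})

test_that("training is deterministic: same seed, same serialized model", {
  peps <- tiny_training_set(40)
  a <- train_model(peps, tiny_config(seed = 7))
  b <- train_model(peps, tiny_config(seed = 7))
  a$layer1$call <- b$layer1$call <- NULL
  a$layer2$call <- b$layer2$call <- NULL
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- train_model(peps, tiny_config(seed = 8))
  probe <- tiny_training_set(10, seed = 77)
  expect_identical(predict_peptides(a, probe), predict_peptides(b, probe))
  expect_false(identical(predict_peptides(a, probe)$prob_ACP,
                         predict_peptides(c_, probe)$prob_ACP))
})

test_that("predictions are simplex-valued and repeatable", {
  fit <- train_model(tiny_training_set(40), tiny_config())
  probe <- tiny_training_set(15, seed = 123)
  p1 <- predict_peptides(fit, probe)
  p2 <- predict_peptides(fit, probe)
  expect_identical(p1, p2)
  probs <- as.matrix(p1[, paste0("prob_", PEPTIDE_CLASSES)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_true(all(probs >= 0))
  expect_true(all(p1$decision %in% PEPTIDE_CLASSES))
})

test_that("invalid records yield per-record errors, not a crash", {
  fit <- train_model(tiny_training_set(40), tiny_config())
  mixed <- data.frame(
    id = c("good", "short", "alien"),
    seq = c("KLAKLAKKLAKLAK", "KLAK", "KLXKLAKLA"),
    label = NA_character_, stringsAsFactors = FALSE
  )
  pred <- predict_peptides(fit, mixed)
  expect_equal(nrow(pred), 3)
  expect_false(is.na(pred$prob_ACP[1]))
  expect_true(is.na(pred$prob_ACP[2]))
  expect_match(pred$warnings[2], "shorter than 5")
  expect_true(is.na(pred$prob_ACP[3]))
  expect_match(pred$warnings[3], "invalid residue")
})

test_that("over-length peptides are predicted but flagged", {
  fit <- train_model(tiny_training_set(40), tiny_config())
  long <- peptide_set("long1", paste(rep("KLAKW", 12), collapse = ""))
  expect_warning(pred <- predict_peptides(fit, long), "longer than 50")
  expect_false(is.na(pred$prob_ACP))
  expect_match(pred$warnings, "length > 50")
})

test_that("per-mer report aligns with the peptide decomposition", {
  fit <- train_model(tiny_training_set(40), tiny_config())
  probe <- peptide_set("p", "KLAKLAKKLA")
  pred <- predict_peptides(fit, probe, per_mer = TRUE)
  mer_rep <- attr(pred, "mer_predictions")
  expect_equal(nrow(mer_rep), nchar(probe$seq) - 4)
  expect_equal(mer_rep$offset, 0:(nchar(probe$seq) - 5))
  expect_equal(unname(rowSums(as.matrix(mer_rep[, PEPTIDE_CLASSES]))),
               rep(1, nrow(mer_rep)), tolerance = 1e-9)
})

test_that("fold assignment is balanced, length-stratified and deterministic", {
  peps <- peptide_set(sprintf("p%02d", 1:10),
                      vapply(5:14, function(l) {
                        paste(rep("A", l), collapse = "")
                      }, character(1)))
  peps$label <- "ACP"
  fold <- assign_cv_folds(peps, folds = 5, seed = 1)
  expect_equal(as.vector(table(fold)), rep(2, 5))
  expect_identical(fold, assign_cv_folds(peps, folds = 5, seed = 1))

  set.seed(2)
  lens <- sample(5:54, 60, replace = TRUE)
  big <- peptide_set(sprintf("q%02d", 1:60),
                     vapply(lens, function(l) {
                       paste(sample(AA_ALPHABET, l, replace = TRUE),
                             collapse = "")
                     }, character(1)))
  big$label <- rep(PEPTIDE_CLASSES, each = 20)
  f <- assign_cv_folds(big, folds = 5, seed = 3)
  sizes <- table(big$label, f)
  expect_true(all(abs(sizes - 4) <= 1))
  fold_means <- tapply(nchar(big$seq), f, mean)
  expect_true(all(abs(fold_means - mean(lens)) <= 5))
  expect_error(assign_cv_folds(big[1:4, ], folds = 5), "at least")
})

test_that("cross-validation reports both layers for every fold", {
  peps <- tiny_training_set(25, seed = 5)
  cv <- cross_validate(peps, tiny_config(), folds = 3)
  expect_equal(nrow(cv$per_fold), 3 * 2 * 3)
  expect_setequal(unique(cv$per_fold$layer), c("mer", "peptide"))
  expect_setequal(unique(cv$per_fold$measure), c("accuracy", "au1u", "kappa"))
  expect_true(all(is.finite(cv$per_fold$value)))
  expect_equal(nrow(cv$summary), 6)
  expect_true(all(c("mean", "sd", "se") %in% names(cv$summary)))
  expect_error(cross_validate(peps[peps$label == "ACP", ], tiny_config(),
                              folds = 3))
})

test_that("model archives round-trip and reject foreign or truncated files", {
  fit <- train_model(tiny_training_set(40), tiny_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  probe <- tiny_training_set(20, seed = 31)
  expect_identical(predict_peptides(fit, probe),
                   predict_peptides(back, probe))
  expect_equal(back$manifest$n_selected, length(back$selected))
  expect_identical(back$selected, fit$selected)

  trunc <- withr::local_tempfile(fileext = ".rds")
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:50], trunc)
  expect_error(load_model(trunc), "cannot read")

  foreign <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), foreign)
  expect_error(load_model(foreign), "not a pepstack model")

  stale <- fit
  stale$manifest$schema_version <- "0"
  stale_path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(stale, stale_path)
  expect_error(load_model(stale_path), "incompatible")
})

test_that("decision ties break conservatively toward NEG, then AMP", {
  probs <- rbind(
    c(1 / 3, 1 / 3, 1 / 3),
    c(0.4, 0.4, 0.2),
    c(0.25, 0.25, 0.5),
    c(0.7, 0.2, 0.1)
  )
  expect_equal(decide_class(probs), c("NEG", "AMP", "NEG", "ACP"))
})
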