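test_that("partition_by_residue_type conserves rows and excludes non-standard", {
  tab <- data.frame(res_name = c(rep("ALA", 5), rep("GLY", 3), "MSE"),
                    label = "FR", stringsAsFactors = FALSE)
  pt <- partition_by_residue_type(tab)
  expect_equal(vapply(pt$subsets, nrow, integer(1)),
               c(ALA = 5L, GLY = 3L))
  expect_equal(pt$excluded$res_name, "MSE")
  expect_equal(sum(vapply(pt$subsets, nrow, integer(1))) +
                 sum(pt$excluded$n), nrow(tab))
})

test_that("class_weight is n_neg/n_pos and rejects empty positives", {
  expect_equal(class_weight(10, 210), 21)
  expect_equal(class_weight(7, 7), 1)
  expect_error(class_weight(0, 100), "no AFR rows")
})

test_that("log_loss matches closed-form values", {
  expect_equal(log_loss(1, 1), 0, tolerance = 1e-10)
  expect_equal(log_loss(1, 0.5), log(2))
  expect_equal(log_loss(c(1, 0), c(0.9, 0.2)), -(log(0.9) + log(0.8)) / 2)
  expect_error(log_loss(numeric(0), numeric(0)), "empty")
  # monotone toward the label
  ll <- vapply(seq(0.1, 0.9, 0.1), function(p) log_loss(1, p), numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("training recovers a separable synthetic subset", {
  tb <- synth_feature_table(200, 200, n_features = 6, n_informative = 2,
                            shift = 3, seed = 21, residue_mix = c(ALA = 1))
  ens <- train_ensemble(tb, model_config())
  pr <- predict_residues(ens, tb)
  expect_gte(roc_auc(tb$label, pr$probability), 0.99)
})

test_that("label shuffling yields chance-level held-out performance", {
  aucs <- numeric(5)
  for (s in 1:5) {
    tb <- synth_feature_table(150, 150, n_features = 5, n_informative = 0,
                              shift = 0, seed = 30 + s, residue_mix = c(ALA = 1))
    half <- seq_len(150)
    tr <- tb[c(half, 150 + half), ][c(TRUE, FALSE), ]
    te <- tb[c(half, 150 + half), ][c(FALSE, TRUE), ]
    ens <- train_ensemble(as.data.frame(tr), model_config(
      feature_manifest = descriptor_columns(tb)))
    aucs[s] <- roc_auc(te$label, predict_residues(ens, te)$probability)
  }
  expect_gt(mean(aucs), 0.35); expect_lt(mean(aucs), 0.65)
})

test_that("training and prediction are deterministic", {
  tb <- synth_feature_table(60, 240, n_features = 5, n_informative = 2,
                            shift = 1, seed = 41, residue_mix = c(LEU = 1))
  e1 <- train_ensemble(tb, model_config(seed = 7))
  e2 <- train_ensemble(tb, model_config(seed = 7))
  expect_identical(predict_residues(e1, tb)$probability,
                   predict_residues(e2, tb)$probability)
})

test_that("predict_residues routes rows and applies the threshold", {
  tb <- synth_feature_table(60, 240, n_features = 4, n_informative = 2,
                            shift = 2, seed = 51,
                            residue_mix = c(ALA = 0.5, GLY = 0.5))
  ens <- train_ensemble(tb, model_config())
  pr <- predict_residues(ens, tb, threshold = 0.5)
  expect_equal(pr$predicted_label, ifelse(pr$probability >= 0.5, "AFR", "FR"))
  # routing oracle: ALA rows scored by the ALA model alone
  ala_rows <- tb$res_name == "ALA"
  X <- as.matrix(as.data.frame(tb)[ala_rows, ens$features])
  direct <- stats::plogis(alloscan:::.gbt_margin_cpp(ens$models$ALA, X))
  expect_equal(pr$probability[ala_rows], direct)
  # empty table
  expect_equal(nrow(predict_residues(ens, tb[0, ])), 0)
  # types without a model predict FR with NA probability
  tb2 <- tb; tb2$res_name[1] <- "TRP"
  pr2 <- predict_residues(ens, tb2)
  expect_true(is.na(pr2$probability[1]))
  expect_equal(pr2$predicted_label[1], "FR")
  expect_error(predict_residues(ens, tb[, -6]), "missing feature")
})

test_that("feature importance finds planted signal, zeroes constants", {
  tb <- synth_feature_table(150, 450, n_features = 5, n_informative = 1,
                            shift = 2.5, seed = 61, residue_mix = c(ALA = 1))
  tb$f05 <- 1 # constant column
  ens <- train_ensemble(tb, model_config())
  att <- feature_importance(ens, tb, "attribution")
  expect_equal(names(which.max(att$ensemble_mean)), "f01")
  expect_true(all(att$ensemble_mean >= 0))
  per <- feature_importance(ens, tb, "permutation", seed = 3, k = 5)
  expect_equal(names(which.max(per$ensemble_mean)), "f01")
  expect_equal(unname(per$ensemble_mean["f05"]), 0)
})

test_that("ensembles survive a save/load round trip bit-exactly", {
  tb <- synth_feature_table(60, 240, n_features = 5, n_informative = 2,
                            shift = 1.5, seed = 71,
                            residue_mix = c(ALA = 0.4, GLY = 0.3, SER = 0.3))
  ens <- train_ensemble(tb, model_config())
  d <- tempfile()
  save_ensemble(ens, d)
  ens2 <- load_ensemble(d)
  expect_identical(predict_residues(ens, tb)$probability,
                   predict_residues(ens2, tb)$probability)
  expect_equal(ens2$features, ens$features)
  expect_true(file.exists(file.path(d, "manifest.json")))
})

test_that("model_config enforces the documented bounds", {
  expect_error(model_config(depth = 12), "depth")
  expect_error(model_config(learning_rate = 0.8), "learning_rate")
  expect_silent(model_config(depth = 10, learning_rate = 0.001))
})
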