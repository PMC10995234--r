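test_that("confusion counts classify cough as the positive class", {
  truth <- c("cough", "cough", "non_cough", "non_cough")
  cc <- confusion(truth, truth)
  expect_identical(unlist(cc), c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  flipped <- ifelse(truth == "cough", "non_cough", "cough")
  cc2 <- confusion(flipped, truth)
  expect_identical(unlist(cc2), c(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
  expect_equal(sum(unlist(cc2)), 4)
  expect_error(confusion("cough", truth), "equal length")
})

test_that("metrics follow their defining ratios", {
  m <- classification_metrics(confusion_counts(TP = 9, TN = 8, FP = 2,
                                               FN = 1))
  expect_equal(unname(m["SN"]), 0.9)
  expect_equal(unname(m["SP"]), 0.8)
  expect_equal(unname(m["ACC"]), 0.85)
  expect_equal(unname(m["PPV"]), 9 / 11)
  expect_equal(unname(m["F1"]), 18 / 21)

  perfect <- classification_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(unname(perfect[c("ACC", "SN", "SP", "PPV", "NPV", "F1")]),
               rep(1, 6))
  expect_equal(unname(perfect[c("FPR", "FNR", "FDR")]), rep(0, 3))
  expect_false(attr(perfect, "degenerate"))

  degen <- classification_metrics(confusion_counts(0, 5, 0, 0))
  expect_equal(unname(degen["SN"]), 0)
  expect_true(attr(degen, "degenerate"))
})

test_that("complementary metric identities hold on random counts", {
  set.seed(31)
  for (i in 1:25) {
    cc <- confusion_counts(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
    m <- classification_metrics(cc)
    expect_equal(unname(m["SN"] + m["FNR"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["SP"] + m["FPR"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["PPV"] + m["FDR"]), 1, tolerance = 1e-12)
    expect_equal(unname(m["F1"]),
                 unname(2 * m["PPV"] * m["SN"] / (m["PPV"] + m["SN"])),
                 tolerance = 1e-12)
  }
})

test_that("the classifier separates separable data and not null data", {
  fn <- feature_names()
  tb <- simulate_feature_table(200, 2, seed = 32, effect_size = 8)
  feats <- attr(tb, "informative_features")
  model <- fit_classifier(tb, feats)
  expect_equal(mean(predict(model, tb) == tb$label), 1.0)
  p <- predict(model, tb, type = "prob")
  expect_true(all(p >= 0 & p <= 1))

  null_tb <- simulate_feature_table(2000, 0, seed = 33)
  half <- seq(1, 2000, by = 2)  # interleaved so both halves carry both classes
  null_model <- fit_classifier(null_tb[half, ], fn)
  acc <- mean(predict(null_model, null_tb[-half, ]) ==
                null_tb$label[-half])
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)

  again <- fit_classifier(tb, feats)
  expect_identical(predict(again, tb), predict(model, tb))
  expect_error(fit_classifier(tb[tb$label == "cough", ], feats),
               "both classes")
})

test_that("training is insulated from the test windows", {
  tb <- simulate_feature_table(400, 3, seed = 34)
  train <- tb[tb$subject_id != "S5", ]
  test <- tb[tb$subject_id == "S5", ]
  model <- fit_classifier(train)
  mutated <- test
  mutated[, feature_names()] <- mutated[, feature_names()] * 100 + 7
  model2 <- fit_classifier(train)
  expect_identical(coughmotion:::ridge_coefs(model$fit),
                   coughmotion:::ridge_coefs(model2$fit))
  expect_identical(model$standardize, model2$standardize)
  # predictions on the untouched test set are unaffected by whatever
  # happened to other copies of it
  expect_identical(predict(model, test), predict(model2, test))
})

test_that("record-split evaluation covers the 34-model grid", {
  tb <- simulate_feature_table(600, 4, seed = 35)
  set.seed(36)
  idx <- sample(600, 400)
  train <- tb[idx, ]
  test <- tb[-idx, ]
  rks <- rank_all(train, ranker_config(seed = 8))
  res <- evaluate_record_split(train, test, rks, eval_config())
  expect_equal(nrow(res), 34)
  expect_equal(sum(res$method == "Baseline"), 1)
  expect_equal(sort(unique(res$n_features)), c(10, 20, 30, 43))
  expect_equal(res$TP + res$TN + res$FP + res$FN, rep(200L, 34))
  # metric identities on every emitted row
  for (i in seq_len(nrow(res))) {
    m <- classification_metrics(confusion_counts(res$TP[i], res$TN[i],
                                                 res$FP[i], res$FN[i]))
    expect_equal(as.numeric(m), as.numeric(unlist(res[i, names(m)])),
                 tolerance = 1e-12)
  }
})

test_that("LOSO folds hold one subject out and average per-fold metrics", {
  tb <- simulate_feature_table(500, 4, seed = 37, n_subjects = 4)
  cfg <- eval_config(k_values = c(10L), include_baseline = TRUE)
  lo <- evaluate_loso(tb, cfg, ranker_config(seed = 9))
  expect_equal(sort(unique(lo$per_fold$fold)), paste0("S", 1:4))
  expect_equal(nrow(lo$summary), 12)  # 11 methods x 1 k + baseline
  expect_equal(nrow(lo$per_fold), 12 * 4)
  # every subject tested exactly once per model
  expect_equal(as.integer(table(lo$per_fold$fold)), rep(12L, 4))
  # summed counts cover all windows once per model
  base <- lo$summary[lo$summary$method == "Baseline", ]
  expect_equal(base$TP + base$TN + base$FP + base$FN, nrow(tb))
  # mean-of-folds identity
  for (i in seq_len(nrow(lo$summary))) {
    sel <- lo$per_fold$method == lo$summary$method[i] &
      lo$per_fold$n_features == lo$summary$n_features[i]
    expect_equal(lo$summary$ACC[i], mean(lo$per_fold$ACC[sel]),
                 tolerance = 1e-12)
    expect_equal(lo$summary$F1[i], mean(lo$per_fold$F1[sel]),
                 tolerance = 1e-12)
  }
  # pooled metrics satisfy the identities on the summed counts
  for (i in seq_len(nrow(lo$summary))) {
    m <- classification_metrics(confusion_counts(
      lo$summary$TP[i], lo$summary$TN[i], lo$summary$FP[i],
      lo$summary$FN[i]))
    expect_equal(unname(m["ACC"]), lo$summary$pooled_ACC[i],
                 tolerance = 1e-12)
  }
  expect_error(evaluate_loso(tb[tb$subject_id == "S1", ]), "2 subjects")
})

test_that("report_results names the best cell per protocol and metric", {
  tb <- simulate_feature_table(400, 4, seed = 38)
  set.seed(39)
  idx <- sample(400, 280)
  rks <- rank_all(tb[idx, ], ranker_config(seed = 10))
  res <- evaluate_record_split(tb[idx, ], tb[-idx, ], rks, eval_config())
  rep <- report_results(res)
  accbest <- rep$best[rep$best$metric == "ACC", ]
  expect_equal(accbest$value, max(res$ACC))
  fprbest <- rep$best[rep$best$metric == "FPR", ]
  expect_equal(fprbest$value, min(res$FPR))

  path <- withr::local_tempfile(fileext = ".csv")
  report_results(res, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 34)
  expect_equal(back$ACC, res$ACC, tolerance = 1e-12)
})
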