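# One strongly informative feature among 42 noise features.
single_informative <- function(n = 2000, seed = 21) {
  tb <- simulate_feature_table(n, 1, seed = seed, effect_size = 2)
  list(tb = tb, inf = attr(tb, "informative_features"))
}

test_that("tree-model importances find the informative feature", {
  fx <- single_informative()
  rk <- rank_model_based(fx$tb, "forest_gini", seed = 1)
  expect_equal(unname(rk$ranks[fx$inf]), 1L)
  expect_setequal(rk$ranks, 1:43)

  rk_xgb <- rank_model_based(fx$tb, "xgboost_gain", seed = 1)
  expect_equal(unname(rk_xgb$ranks[fx$inf]), 1L)
})

test_that("tree importance ranking is invariant to row duplication", {
  fx <- single_informative(600, seed = 22)
  doubled <- feature_table(rbind(as.data.frame(fx$tb),
                                 as.data.frame(fx$tb)))
  a <- rank_model_based(fx$tb, "tree_gini", seed = 5)
  b <- rank_model_based(doubled, "tree_gini", seed = 5)
  expect_identical(a$ranks, b$ranks)
})

test_that("all-noise tables still yield valid permutations", {
  tb <- simulate_feature_table(300, 0, seed = 23)
  for (rk in list(rank_model_based(tb, "xgboost_gain", seed = 2),
                  rank_pc1(tb), rank_correlation(tb))) {
    expect_setequal(rk$ranks, 1:43)
  }
  one_class <- tb[tb$label == "cough", ]
  expect_error(rank_model_based(one_class, "forest_gini"), "both classes")
})

test_that("PC1 loadings rank dominant correlated features first", {
  # two duplicated high-variance columns among unit noise: PC1 of the
  # covariance (unstandardized) must be spanned by them
  tb <- simulate_feature_table(500, 0, seed = 24)
  fn <- feature_names()
  set.seed(25)
  shared <- rnorm(500, sd = 6)
  tb[[fn[5]]] <- shared + rnorm(500, sd = 0.2)
  tb[[fn[17]]] <- shared + rnorm(500, sd = 0.2)
  rk <- rank_pc1(tb, standardize = FALSE)
  expect_setequal(top_features(rk, 2), fn[c(5, 17)])

  evr <- attr(rk, "explained_variance_ratio")
  expect_equal(sum(evr), 1, tolerance = 1e-12)
  expect_gt(evr[1], 0.5)

  # |loading| makes the ranking invariant to the PC1 sign convention
  X <- feature_matrix(tb)
  ev <- eigen(stats::cov(X))$vectors[, 1]
  expect_setequal(fn[order(-abs(ev))][1:2], top_features(rk, 2))
})

test_that("leave-one-feature-out scores redundancy near zero", {
  fx <- single_informative(1200, seed = 26)
  tb <- fx$tb
  fn <- feature_names()
  # plant an exact duplicate of the informative feature
  dup <- setdiff(fn, fx$inf)[1]
  tb[[dup]] <- tb[[fx$inf]]
  cfg <- ranker_config(seed = 3)
  rk <- rank_leave_one_out(tb, cfg)
  expect_setequal(rk$ranks, 1:43)
  # removing either copy changes nothing: importance ~ 0
  expect_lt(abs(rk$scores[fx$inf]), 0.02)
  expect_lt(abs(rk$scores[dup]), 0.02)

  rk_single <- rank_leave_one_out(fx$tb, cfg)
  expect_equal(unname(rk_single$ranks[fx$inf]), 1L)
  expect_gt(attr(rk_single, "base_accuracy"), 0.7)
})

test_that("permutation importance ranks the informative feature first", {
  fx <- single_informative()
  tb <- fx$tb
  fn <- feature_names()
  const <- setdiff(fn, fx$inf)[1]
  tb[[const]] <- 1  # constant column: shuffling it cannot matter
  cfg <- ranker_config(seed = 4)
  rk <- rank_permutation(tb, cfg)
  expect_equal(unname(rk$ranks[fx$inf]), 1L)
  expect_equal(unname(rk$scores[const]), 0)

  top1 <- function(repeats) {
    top_features(rank_permutation(fx$tb,
                                  ranker_config(permutation_repeats =
                                                  repeats, seed = 4)), 1)
  }
  expect_identical(top1(1L), top1(10L))
})

test_that("RFE eliminates noise before signal and nests its top sets", {
  fx <- single_informative()
  cfg <- ranker_config(seed = 5)
  rks <- lapply(c(10L, 20L, 30L, 43L), rank_rfe, table = fx$tb,
                cfg = cfg)
  names(rks) <- c("10", "20", "30", "43")
  for (rk in rks) expect_setequal(rk$ranks, 1:43)
  expect_equal(unname(rks[["10"]]$ranks[fx$inf]), 1L)
  t10 <- top_features(rks[["10"]], 10)
  t20 <- top_features(rks[["20"]], 20)
  t30 <- top_features(rks[["30"]], 30)
  expect_true(all(t10 %in% t20))
  expect_true(all(t20 %in% t30))
  expect_error(rank_rfe(fx$tb, 15L, cfg), "rfe_n")
})

test_that("Spearman ranking honors monotone invariance", {
  tb <- simulate_feature_table(2000, 0, seed = 27)
  fn <- feature_names()
  y <- as.integer(tb$label == "cough")
  tb[[fn[1]]] <- y + 0  # feature equal to the label
  rk <- rank_correlation(tb)
  expect_equal(unname(rk$ranks[fn[1]]), 1L)
  expect_equal(unname(abs(rk$scores[fn[1]])), 1)
  expect_lt(max(abs(rk$scores[fn[-1]])), 0.1)

  tb2 <- tb
  tb2[[fn[2]]] <- exp(tb[[fn[2]]])
  rk2 <- rank_correlation(tb2)
  expect_equal(rk2$scores[fn[2]], rk$scores[fn[2]], tolerance = 1e-12)
})

test_that("rank_all emits 11 deterministic permutations", {
  tb <- simulate_feature_table(400, 3, seed = 28)
  cfg <- ranker_config(seed = 6)
  rks <- rank_all(tb, cfg)
  expect_named(rks, c("XGBoost", "DT", "RF", "PC1", "LOO", "PERM",
                      "RFE_10", "RFE_20", "RFE_30", "RFE_43", "Corr"))
  for (rk in rks) expect_setequal(rk$ranks, 1:43)
  rks2 <- rank_all(tb, cfg)
  for (nm in names(rks)) expect_identical(rks[[nm]]$ranks,
                                          rks2[[nm]]$ranks)

  mat <- ranking_matrix(rks)
  expect_equal(dim(mat), c(43, 12))
  member <- topk_membership(rks)
  expect_identical(member$XGBoost[mat$XGBoost <= 10][1], "top10")
  expect_true(all(member$Corr[mat$Corr > 30] == ""))
  expect_equal(sum(member$RF == "top20"), 10)
})

test_that("every method puts k informative features in its top 2k", {
  tb <- simulate_feature_table(2000, 5, seed = 29, effect_size = 2)
  inf <- attr(tb, "informative_features")
  rks <- rank_all(tb, ranker_config(seed = 7))
  for (nm in names(rks)) {
    expect_true(all(inf %in% top_features(rks[[nm]], 10)),
                label = paste(nm, "places informative features in top 10"))
  }
})

test_that("rankings ignore input column order", {
  tb <- simulate_feature_table(300, 2, seed = 30)
  scrambled <- tb[, sample(ncol(tb))]
  rk1 <- rank_correlation(tb)
  rk2 <- rank_correlation(feature_table(scrambled))
  expect_identical(rk1$ranks, rk2$ranks)
})
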