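.RANK_METHODS <- c("XGBoost", "DT", "RF", "PC1", "LOO", "PERM",
                   "RFE_10", "RFE_20", "RFE_30", "RFE_43", "Corr")

#' Ranking configuration
#'
#' Parameters shared by the wrapper-style ranking methods. The estimator
#' inside leave-one-out, permutation and RFE is the same
#' ridge-regularized logistic classifier used for final evaluation,
#' fitted on per-feature standardized inputs.
#'
#' @param permutation_repeats Shuffles per feature for permutation
#'   importance.
#' @param cv_folds Stratified cross-validation folds for score-based
#'   methods (leave-one-out importance).
#' @param C Inverse regularization strength of the logistic estimator.
#' @param seed Integer seed.
#' @return An object of class `"ranker_config"`.
#' @export
ranker_config <- function(permutation_repeats = 10L, cv_folds = 5L,
                          C = 1.0, seed = 1L) {
  if (permutation_repeats < 1L) {
    stop("permutation_repeats must be >= 1", call. = FALSE)
  }
  structure(list(permutation_repeats = as.integer(permutation_repeats),
                 cv_folds = as.integer(cv_folds), C = C,
                 seed = as.integer(seed)),
            class = "ranker_config")
}

# ---- shared estimator utilities ------------------------------------------

label_to_y <- function(label) as.integer(label == .POSITIVE)

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, function(c) sqrt(mean((c - mean(c))^2)))
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

# Ridge logistic regression on an already-standardized matrix. glmnet's
# penalized deviance (1/n) * loglik + lambda/2 ||w||^2 matches an
# unscaled penalty 1/(2C) ||w||^2 at lambda = 1 / (n * C).
ridge_logit <- function(X, y, C = 1.0) {
  glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                 lambda = 1 / (nrow(X) * C), standardize = FALSE,
                 maxit = 1e6)
}

ridge_predict <- function(fit, X) {
  as.integer(predict(fit, X, type = "response")[, 1] >= 0.5)
}

ridge_coefs <- function(fit) {
  cf <- as.matrix(stats::coef(fit))[, 1]
  cf[-1]  # drop intercept
}

# Stratified k-fold assignment (a fold index per row).
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Mean accuracy over pre-assigned CV folds; standardization statistics
# are recomputed from each fold's training part.
cv_accuracy <- function(X, y, fold, C = 1.0) {
  accs <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    st <- standardize_fit(X[tr, , drop = FALSE])
    fit <- ridge_logit(standardize_apply(X[tr, , drop = FALSE], st),
                       y[tr], C)
    pred <- ridge_predict(fit, standardize_apply(X[!tr, , drop = FALSE],
                                                 st))
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

# Descending-score ranks with ties broken by registry order.
rank_from_scores <- function(scores, method) {
  fn <- feature_names()
  scores <- scores[fn]
  scores[is.na(scores)] <- 0
  ord <- order(-scores, seq_along(fn))
  ranks <- integer(length(fn))
  ranks[ord] <- seq_along(fn)
  names(ranks) <- fn
  ranking_result(method, ranks, scores = scores)
}

check_two_classes <- function(table) {
  if (length(unique(table$label)) < 2L) {
    stop("training table must contain both classes", call. = FALSE)
  }
}

# ---- ranking methods -----------------------------------------------------

#' Model-based feature importance ranking
#'
#' Fits a tree-based model on the full training table and ranks features
#' by its built-in importance: gradient-boosting gain (`xgboost_gain`),
#' single-decision-tree Gini importance (`tree_gini`), or random-forest
#' mean decrease in Gini impurity (`forest_gini`). Features the model
#' never uses receive importance 0 and fall to the bottom, ordered by
#' the registry.
#'
#' @param table A training [feature_table()].
#' @param flavor Which tree model to use.
#' @param seed Integer seed for the stochastic fits.
#' @return A [ranking_result()].
#' @export
rank_model_based <- function(table,
                             flavor = c("xgboost_gain", "tree_gini",
                                        "forest_gini"),
                             seed = 1L) {
  flavor <- match.arg(flavor)
  check_two_classes(table)
  X <- feature_matrix(table)
  y <- label_to_y(table$label)
  set.seed(seed)
  scores <- setNames(numeric(ncol(X)), colnames(X))
  if (flavor == "xgboost_gain") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 6,
                    eta = 0.3, nthread = 1, seed = seed),
      data = dtrain, nrounds = 100, verbose = 0)
    imp <- xgboost::xgb.importance(model = fit)
    scores[imp$Feature] <- imp$Gain
    method <- "XGBoost"
  } else if (flavor == "tree_gini") {
    df <- data.frame(.y = factor(y), X, check.names = FALSE)
    # scale-free stopping rules (cp is relative to the root deviance)
    # and primary-split credit only, so importance is the summed Gini
    # improvement of actual splits and duplicating rows cannot change
    # the ranking
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, xval = 0,
                          maxsurrogate = 0))
    imp <- fit$variable.importance
    scores[names(imp)] <- imp
    method <- "DT"
  } else {
    fit <- randomForest::randomForest(X, factor(y), ntree = 100)
    imp <- fit$importance[, "MeanDecreaseGini"]
    scores[names(imp)] <- imp
    method <- "RF"
  }
  rank_from_scores(scores, method)
}

#' First-principal-component loading ranking
#'
#' Computes the first principal component of the (by default
#' standardized) feature matrix and ranks features by the absolute value
#' of their PC1 loading — their correlation with the dominant axis of
#' variation. The explained-variance ratio of every component is
#' attached as attribute `"explained_variance_ratio"`.
#'
#' @param table A training [feature_table()].
#' @param standardize Scale features to unit variance before the PCA.
#' @return A [ranking_result()].
#' @export
rank_pc1 <- function(table, standardize = TRUE) {
  if (nrow(table) < 2L) stop("need at least 2 rows", call. = FALSE)
  X <- feature_matrix(table)
  keep_sd <- apply(X, 2, sd)
  pc <- prcomp(X, center = TRUE,
               scale. = standardize && all(keep_sd > 0))
  loadings <- pc$rotation[, 1]
  res <- rank_from_scores(abs(loadings), "PC1")
  attr(res, "explained_variance_ratio") <- pc$sdev^2 / sum(pc$sdev^2)
  res
}

#' Leave-one-feature-out ranking
#'
#' Measures each feature's importance as the drop in cross-validated
#' accuracy of the logistic estimator when that single feature is
#' removed from the full set: base accuracy minus the accuracy without
#' the feature. Redundant features (whose information is carried by
#' others) score near zero.
#'
#' @param table A training [feature_table()].
#' @param cfg A [ranker_config()].
#' @return A [ranking_result()] with attribute `"base_accuracy"`.
#' @export
rank_leave_one_out <- function(table, cfg = ranker_config()) {
  check_two_classes(table)
  X <- feature_matrix(table)
  y <- label_to_y(table$label)
  fold <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  base <- cv_accuracy(X, y, fold, cfg$C)
  drops <- vapply(seq_len(ncol(X)), function(j) {
    base - cv_accuracy(X[, -j, drop = FALSE], y, fold, cfg$C)
  }, numeric(1))
  names(drops) <- colnames(X)
  res <- rank_from_scores(drops, "LOO")
  attr(res, "base_accuracy") <- base
  res
}

#' Permutation importance ranking
#'
#' Fits the logistic estimator once on all features, then scores the
#' accuracy penalty of destroying each feature's information by randomly
#' shuffling its column while leaving the fitted model untouched. The
#' shuffle is repeated (default 10 times) and the mean accuracy drop
#' ranks the feature.
#'
#' @param table A training [feature_table()].
#' @param cfg A [ranker_config()].
#' @return A [ranking_result()] with attribute `"base_accuracy"`.
#' @export
rank_permutation <- function(table, cfg = ranker_config()) {
  check_two_classes(table)
  X <- feature_matrix(table)
  y <- label_to_y(table$label)
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  fit <- ridge_logit(Xs, y, cfg$C)
  base <- mean(ridge_predict(fit, Xs) == y)
  set.seed(cfg$seed)
  drops <- vapply(seq_len(ncol(Xs)), function(j) {
    accs <- vapply(seq_len(cfg$permutation_repeats), function(r) {
      Xp <- Xs
      Xp[, j] <- sample(Xp[, j])
      mean(ridge_predict(fit, Xp) == y)
    }, numeric(1))
    base - mean(accs)
  }, numeric(1))
  names(drops) <- colnames(Xs)
  res <- rank_from_scores(drops, "PERM")
  attr(res, "base_accuracy") <- base
  res
}

# Full backwards-elimination path of the ridge-logistic estimator on the
# standardized training matrix. Returns the elimination order (first
# eliminated first) and, for every remaining-set size, the |coefficient|
# snapshot of the fit on that set.
rfe_path <- function(X, y, C = 1.0) {
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  remaining <- colnames(Xs)
  eliminated <- character(0)
  snapshots <- list()
  while (length(remaining) >= 2L) {
    fit <- ridge_logit(Xs[, remaining, drop = FALSE], y, C)
    ac <- abs(ridge_coefs(fit))
    snapshots[[as.character(length(remaining))]] <- ac
    # weakest feature out; ties resolved against later registry order
    reg <- match(remaining, feature_names())
    worst <- remaining[order(ac, -reg)][1]
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(eliminated = eliminated, snapshots = snapshots)
}

#' Recursive feature elimination ranking
#'
#' Repeatedly fits the logistic estimator on standardized features and
#' discards the feature with the smallest absolute coefficient until
#' `rfe_n` remain. Eliminated features are ranked worst-first by
#' elimination order (the first feature discarded gets rank 43); the
#' surviving `rfe_n` features are ranked `1..rfe_n` by descending
#' absolute coefficient of the fit on exactly that surviving set. With
#' `rfe_n = 43` no elimination happens and the ranking is the descending
#' absolute-coefficient order of a single fit.
#'
#' @param table A training [feature_table()].
#' @param rfe_n Number of surviving features (10, 20, 30 or 43).
#' @param cfg A [ranker_config()].
#' @param path Optional precomputed elimination path (internal reuse).
#' @return A [ranking_result()].
#' @export
rank_rfe <- function(table, rfe_n = 10L, cfg = ranker_config(),
                     path = NULL) {
  fn <- feature_names()
  if (!rfe_n %in% c(10L, 20L, 30L, 43L)) {
    stop("rfe_n must be one of 10, 20, 30, 43", call. = FALSE)
  }
  check_two_classes(table)
  if (is.null(path)) {
    path <- rfe_path(feature_matrix(table), label_to_y(table$label),
                     cfg$C)
  }
  n_elim <- length(fn) - rfe_n
  out <- if (n_elim > 0) path$eliminated[seq_len(n_elim)] else character(0)
  survivors_coef <- path$snapshots[[as.character(rfe_n)]]
  reg <- match(names(survivors_coef), fn)
  survivors <- names(survivors_coef)[order(-survivors_coef, reg)]
  ranks <- integer(length(fn))
  names(ranks) <- fn
  ranks[survivors] <- seq_len(rfe_n)
  if (n_elim > 0) ranks[out] <- length(fn) - seq_len(n_elim) + 1L
  ranking_result(sprintf("RFE_%d", rfe_n), ranks)
}

#' Spearman correlation ranking
#'
#' Ranks each feature by the absolute Spearman rank correlation between
#' its values and the binary target (cough = 1). Zero-variance features
#' get correlation 0.
#'
#' @param table A training [feature_table()].
#' @return A [ranking_result()].
#' @export
rank_correlation <- function(table) {
  check_two_classes(table)
  X <- feature_matrix(table)
  y <- label_to_y(table$label)
  rho <- apply(X, 2, function(col) {
    if (feat_var(col) == 0) return(0)
    cor(col, y, method = "spearman")
  })
  rank_from_scores(abs(rho), "Corr")
}

#' Run all 11 ranking configurations
#'
#' Runs the six ranking families over the training table in their eleven
#' configurations: XGBoost, DT, RF, PC1, LOO, PERM, RFE at 10/20/30/43
#' surviving features, and Spearman correlation. The four RFE variants
#' share one deterministic elimination path.
#'
#' @param table A training [feature_table()].
#' @param cfg A [ranker_config()].
#' @return A named list of 11 [ranking_result()] objects in method
#'   order.
#' @export
rank_all <- function(table, cfg = ranker_config()) {
  path <- rfe_path(feature_matrix(table), label_to_y(table$label),
                   cfg$C)
  res <- list(
    XGBoost = rank_model_based(table, "xgboost_gain", seed = cfg$seed),
    DT = rank_model_based(table, "tree_gini", seed = cfg$seed + 1L),
    RF = rank_model_based(table, "forest_gini", seed = cfg$seed + 2L),
    PC1 = rank_pc1(table),
    LOO = rank_leave_one_out(table, cfg),
    PERM = rank_permutation(table, cfg),
    RFE_10 = rank_rfe(table, 10L, cfg, path = path),
    RFE_20 = rank_rfe(table, 20L, cfg, path = path),
    RFE_30 = rank_rfe(table, 30L, cfg, path = path),
    RFE_43 = rank_rfe(table, 43L, cfg, path = path),
    Corr = rank_correlation(table))
  stopifnot(identical(names(res), .RANK_METHODS))
  res
}

#' Combined rank matrix of all methods
#'
#' @param rankings Named list of [ranking_result()] objects (e.g. from
#'   [rank_all()]).
#' @return A data frame with a `feature` column and one integer rank
#'   column per method (43 rows).
#' @export
ranking_matrix <- function(rankings) {
  fn <- feature_names()
  out <- data.frame(feature = fn, stringsAsFactors = FALSE)
  for (nm in names(rankings)) out[[nm]] <- rankings[[nm]]$ranks[fn]
  out
}

#' Top-k membership table
#'
#' Summarizes a rank matrix into membership categories: `"top10"`
#' (rank 1-10), `"top20"` (11-20), `"top30"` (21-30), `""` (below 30).
#'
#' @param rankings Named list of [ranking_result()] objects.
#' @return A data frame shaped like [ranking_matrix()] with category
#'   strings.
#' @export
topk_membership <- function(rankings) {
  mat <- ranking_matrix(rankings)
  for (nm in setdiff(names(mat), "feature")) {
    r <- mat[[nm]]
    mat[[nm]] <- ifelse(r <= 10, "top10",
                        ifelse(r <= 20, "top20",
                               ifelse(r <= 30, "top30", "")))
  }
  mat
}
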