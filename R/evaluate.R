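.METRICS <- c("ACC", "SN", "SP", "PPV", "NPV", "F1", "FPR", "FNR", "FDR")

#' Evaluation configuration
#'
#' @param protocols Which evaluation protocols to run.
#' @param k_values Numbers of top-ranked features to evaluate per
#'   ranking method.
#' @param include_baseline Also evaluate the all-features (43) baseline.
#' @param C Inverse regularization strength of the ridge logistic
#'   classifier.
#' @param loso_rank Whether leave-one-subject-out folds recompute the
#'   rankings on each fold's training windows (`"per_fold"`, default,
#'   leakage-free) or reuse one set of rankings supplied by the caller
#'   (`"global"`).
#' @param seed Integer seed.
#' @return An object of class `"eval_config"`.
#' @export
eval_config <- function(protocols = c("record_split", "LOSO"),
                        k_values = c(10L, 20L, 30L),
                        include_baseline = TRUE, C = 1.0,
                        loso_rank = c("per_fold", "global"),
                        seed = 1L) {
  if (!all(k_values %in% 1:43)) {
    stop("k_values must lie in 1..43", call. = FALSE)
  }
  structure(list(protocols = protocols,
                 k_values = as.integer(k_values),
                 include_baseline = isTRUE(include_baseline), C = C,
                 loso_rank = match.arg(loso_rank),
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Fit the cough/non-cough logistic classifier
#'
#' Ridge-regularized (L2) binary logistic regression on the selected
#' features, standardized with statistics computed from the training
#' table only. Prediction applies the stored training statistics to new
#' rows and thresholds the predicted cough probability at 0.5.
#'
#' @param table A training [feature_table()] containing both classes.
#' @param features Character vector of feature columns to use.
#' @param C Inverse regularization strength.
#' @return An object of class `"cough_classifier"`.
#' @export
fit_classifier <- function(table, features = feature_names(), C = 1.0) {
  check_two_classes(table)
  X <- feature_matrix(table)[, features, drop = FALSE]
  y <- label_to_y(table$label)
  st <- standardize_fit(X)
  fit <- ridge_logit(standardize_apply(X, st), y, C)
  structure(list(fit = fit, features = features, standardize = st,
                 C = C),
            class = "cough_classifier")
}

#' Predict labels or cough probabilities
#'
#' @param object A fitted [fit_classifier()] model.
#' @param newdata A [feature_table()].
#' @param type `"label"` for class labels, `"prob"` for cough
#'   probabilities.
#' @param ... Unused.
#' @return Character labels or numeric probabilities, one per row.
#' @export
predict.cough_classifier <- function(object, newdata,
                                     type = c("label", "prob"), ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata)[, object$features, drop = FALSE]
  p <- predict(object$fit, standardize_apply(X, object$standardize),
               type = "response")[, 1]
  if (type == "prob") return(unname(p))
  ifelse(p >= 0.5, "cough", "non_cough")
}

#' Confusion counts of a prediction
#'
#' Cough is the positive class: TP counts correctly identified coughs,
#' TN correctly labelled non-coughs, FP non-coughs called coughs, FN
#' coughs called non-coughs.
#'
#' @param pred,truth Character label vectors of equal length.
#' @return A [confusion_counts()] object.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  confusion_counts(TP = sum(pred == .POSITIVE & truth == .POSITIVE),
                   TN = sum(pred != .POSITIVE & truth != .POSITIVE),
                   FP = sum(pred == .POSITIVE & truth != .POSITIVE),
                   FN = sum(pred != .POSITIVE & truth == .POSITIVE))
}

#' Classification metrics from confusion counts
#'
#' Computes the nine standard binary metrics: accuracy
#' ACC = (TP+TN)/(TP+FP+FN+TN), sensitivity SN = TP/(TP+FN),
#' specificity SP = TN/(TN+FP), positive and negative predictive values
#' PPV = TP/(TP+FP) and NPV = TN/(TN+FN), F1 = 2 TP/(2 TP+FP+FN), and
#' the complementary rates FPR = FP/(TN+FP), FNR = FN/(TP+FN),
#' FDR = FP/(TP+FP). A metric whose denominator is zero is reported as 0
#' and flagged via the `"degenerate"` attribute.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named numeric vector of the nine metrics (fractions in
#'   \[0, 1\]).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  safe <- function(num, den) if (den == 0) 0 else num / den
  out <- c(ACC = safe(TP + TN, TP + FP + FN + TN),
           SN = safe(TP, TP + FN),
           SP = safe(TN, TN + FP),
           PPV = safe(TP, TP + FP),
           NPV = safe(TN, TN + FN),
           F1 = safe(2 * TP, 2 * TP + FP + FN),
           FPR = safe(FP, TN + FP),
           FNR = safe(FN, TP + FN),
           FDR = safe(FP, TP + FP))
  attr(out, "degenerate") <- (TP + FN == 0) || (TN + FP == 0) ||
    (TP + FP == 0) || (TN + FN == 0)
  out
}

eval_one <- function(train_tbl, test_tbl, features, protocol, method,
                     n_features, C) {
  model <- fit_classifier(train_tbl, features, C)
  counts <- confusion(predict(model, test_tbl), test_tbl$label)
  m <- classification_metrics(counts)
  cbind(data.frame(protocol = protocol, method = method,
                   n_features = n_features, TP = counts$TP,
                   TN = counts$TN, FP = counts$FP, FN = counts$FN,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(m)))
}

method_grid <- function(cfg) {
  grid <- expand.grid(method = .RANK_METHODS, n_features = cfg$k_values,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$method, .RANK_METHODS),
                     grid$n_features), ]
  if (cfg$include_baseline) {
    grid <- rbind(data.frame(method = "Baseline", n_features = 43L),
                  grid)
  }
  rownames(grid) <- NULL
  grid
}

#' Evaluate the top-k grid under the subject-record split
#'
#' For every ranking method and every k in `k_values`, trains the
#' logistic classifier on the training table restricted to that
#' method's top-k features and scores it on the test table, plus one
#' baseline model on all 43 features. With the default three k values
#' and 11 methods this yields 34 models.
#'
#' @param train_tbl,test_tbl Training and testing [feature_table()]s
#'   from the record split.
#' @param rankings Named list of [ranking_result()]s computed on the
#'   training table only.
#' @param cfg An [eval_config()].
#' @return A data frame with one row per model: protocol, method,
#'   n_features, confusion counts and the nine metrics.
#' @export
evaluate_record_split <- function(train_tbl, test_tbl, rankings,
                                  cfg = eval_config()) {
  grid <- method_grid(cfg)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    method <- grid$method[i]
    k <- grid$n_features[i]
    feats <- if (method == "Baseline") feature_names() else
      top_features(rankings[[method]], k)
    eval_one(train_tbl, test_tbl, feats, "record_split", method, k,
             cfg$C)
  })
  do.call(rbind, rows)
}

#' Evaluate the top-k grid under leave-one-subject-out
#'
#' One fold per subject: the fold's test set is every window of that
#' subject and its training set is every window of the others. By
#' default each fold recomputes all rankings on its own training
#' windows, so no information from the held-out subject reaches feature
#' selection. The summary reports, per (method, k), the arithmetic mean
#' of each metric across folds together with the summed confusion
#' counts and, for reference, metrics pooled over those summed counts
#' (columns prefixed `pooled_`).
#'
#' @param table A [feature_table()] covering all windows of the cohort.
#' @param cfg An [eval_config()].
#' @param rank_cfg A [ranker_config()] for per-fold ranking.
#' @param rankings Pre-computed rankings, used only when
#'   `cfg$loso_rank == "global"`.
#' @return A list with `summary` (34 rows by default) and `per_fold`
#'   (one row per model and fold).
#' @export
evaluate_loso <- function(table, cfg = eval_config(),
                          rank_cfg = ranker_config(), rankings = NULL) {
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2L) {
    stop("LOSO needs at least 2 subjects", call. = FALSE)
  }
  if (cfg$loso_rank == "global" && is.null(rankings)) {
    stop("global LOSO ranking requires precomputed rankings",
         call. = FALSE)
  }
  fold_rows <- lapply(subjects, function(subj) {
    train_tbl <- table[table$subject_id != subj, ]
    test_tbl <- table[table$subject_id == subj, ]
    degenerate <- length(unique(test_tbl$label)) < 2L
    fold_rankings <- if (cfg$loso_rank == "per_fold") {
      rank_all(train_tbl, rank_cfg)
    } else {
      rankings
    }
    grid <- method_grid(cfg)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      method <- grid$method[i]
      k <- grid$n_features[i]
      feats <- if (method == "Baseline") feature_names() else
        top_features(fold_rankings[[method]], k)
      eval_one(train_tbl, test_tbl, feats, "LOSO", method, k, cfg$C)
    })
    out <- do.call(rbind, rows)
    out$fold <- subj
    out$degenerate_fold <- degenerate
    out
  })
  per_fold <- do.call(rbind, fold_rows)
  grid <- method_grid(cfg)
  summary_rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- per_fold$method == grid$method[i] &
      per_fold$n_features == grid$n_features[i]
    block <- per_fold[sel, ]
    counts <- confusion_counts(TP = sum(block$TP), TN = sum(block$TN),
                               FP = sum(block$FP), FN = sum(block$FN))
    pooled <- classification_metrics(counts)
    names(pooled) <- paste0("pooled_", names(pooled))
    cbind(data.frame(protocol = "LOSO", method = grid$method[i],
                     n_features = grid$n_features[i],
                     TP = counts$TP, TN = counts$TN, FP = counts$FP,
                     FN = counts$FN, stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(block[, .METRICS]))),
          as.data.frame(as.list(pooled)))
  })
  list(summary = do.call(rbind, summary_rows), per_fold = per_fold)
}

#' Export results and summarize the best models
#'
#' Writes the long-format results table (one row per model) and returns
#' a per-protocol summary naming, for each metric, the best-scoring
#' (method, k) cell. Error-type metrics (FPR, FNR, FDR) are best when
#' smallest.
#'
#' @param results Data frame of evaluation rows (both protocols may be
#'   mixed).
#' @param path Optional CSV output path.
#' @return A list with `results` and `best` (data frame of per-protocol,
#'   per-metric winners), invisibly if `path` is given.
#' @export
report_results <- function(results, path = NULL) {
  lower_better <- c("FPR", "FNR", "FDR")
  best <- do.call(rbind, lapply(split(results, results$protocol),
                                function(block) {
    do.call(rbind, lapply(.METRICS, function(m) {
      i <- if (m %in% lower_better) which.min(block[[m]]) else
        which.max(block[[m]])
      data.frame(protocol = block$protocol[1], metric = m,
                 method = block$method[i],
                 n_features = block$n_features[i],
                 value = block[[m]][i], stringsAsFactors = FALSE)
    }))
  }))
  rownames(best) <- NULL
  out <- list(results = results, best = best)
  if (!is.null(path)) {
    write.csv(results, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
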