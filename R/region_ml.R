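# Region classification with leave-one-province-out CV, mean-|SHAP| genus
# selection, and cross-validated diet prediction from the selected genera.

.xgb_defaults <- function(objective) {
  # shallow, heavily regularized trees: leave-one-province-out folds pool
  # probabilities from models fit on different samples, and weaker models
  # keep the pooled null AUC centred at 0.5
  list(objective = objective, max_depth = 3, eta = 0.1,
       subsample = 0.8, colsample_bytree = 0.8, min_child_weight = 25,
       nthread = 1)
}

#' Leave-one-province-out region classifier
#'
#' Gradient-boosted trees on genus abundances predict the probability that a
#' participant belongs to the Southern region. Each fold holds out one
#' entire province and trains on all others, so no participant is ever
#' scored by a model that saw their province. The whole cycle is repeated
#' `n_repeats` times with derived seeds (`seed + repeat - 1`) and
#' per-participant probabilities are averaged across repeats.
#'
#' @param abundance a [genus_table()].
#' @param cohort a cohort table supplying `province` and `region`.
#' @param n_repeats reseeded repeats (default 10).
#' @param seed base integer seed.
#' @param nrounds boosting rounds per model (default 60).
#' @return A list of class `"region_classifier"`: `probability`
#'   (per-participant mean P(South)), `prob_by_repeat`, `auc`, `folds`
#'   (held-out province per fold), `models` (per repeat x fold, retained for
#'   SHAP), `features`, `params`, `seed`, `y` (1 = South).
#' @export
logo_region_classify <- function(abundance, cohort, n_repeats = 10, seed = 1,
                                 nrounds = 60) {
  X <- unclass(abundance)[match(cohort$participant_id, rownames(abundance)), ,
                          drop = FALSE]
  if (anyNA(X)) stop("abundance table does not cover the cohort")
  y <- as.numeric(cohort$region == "South")
  prov <- cohort$province
  reg_by_prov <- tapply(cohort$region, prov, function(r) unique(r))
  if (any(table(unlist(reg_by_prov)) < 2))
    stop("each region needs >= 2 provinces for leave-one-province-out folds")
  provinces <- sort(unique(prov))
  params <- .xgb_defaults("binary:logistic")
  prob_mat <- matrix(NA_real_, nrow(X), n_repeats,
                     dimnames = list(rownames(X), NULL))
  models <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- seed + r - 1
    models[[r]] <- vector("list", length(provinces))
    names(models[[r]]) <- provinces
    for (p in provinces) {
      test <- prov == p
      dtrain <- xgboost::xgb.DMatrix(X[!test, , drop = FALSE],
                                     label = y[!test], nthread = 1)
      # balance the classes within each training fold: holding out a whole
      # province skews the training base rate towards the other region,
      # which would otherwise shift that fold's probabilities wholesale
      spw <- sum(y[!test] == 0) / sum(y[!test] == 1)
      set.seed(rep_seed)
      fit <- xgboost::xgb.train(params = c(params,
                                           list(seed = rep_seed,
                                                scale_pos_weight = spw)),
                                data = dtrain, nrounds = nrounds, verbose = 0)
      prob_mat[test, r] <- stats::predict(fit, X[test, , drop = FALSE])
      models[[r]][[p]] <- list(model = fit, test = which(test))
    }
  }
  probability <- rowMeans(prob_mat)
  roc <- pROC::roc(response = y, predictor = probability, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  out <- list(probability = probability, prob_by_repeat = prob_mat,
              auc = as.numeric(pROC::auc(roc)), roc = roc,
              folds = provinces, models = models, features = colnames(X),
              params = params, nrounds = nrounds, n_repeats = n_repeats,
              seed = seed, y = y)
  class(out) <- "region_classifier"
  out
}

#' @export
print.region_classifier <- function(x, ...) {
  cat(sprintf("region_classifier: %d participants, %d provinces, %d repeats; AUC %.3f\n",
              length(x$probability), length(x$folds), x$n_repeats, x$auc))
  invisible(x)
}

#' Select region-discriminating genera by mean |SHAP|
#'
#' Averages the absolute per-sample SHAP attribution of each genus over the
#' held-out predictions of every fold model and every repeat. A genus is
#' selected when its mean absolute attribution exceeds a small tolerance
#' (1e-12, to separate true zeros from floating-point dust).
#'
#' @param report a [logo_region_classify()] result (with retained models).
#' @param abundance the [genus_table()] the classifier was run on.
#' @return Data frame with `genus`, `mean_abs_attribution`, `selected`,
#'   sorted by attribution, descending.
#' @export
select_discriminating_genera <- function(report, abundance) {
  X <- unclass(abundance)[names(report$probability), , drop = FALSE]
  acc <- numeric(ncol(X))
  n_rows <- 0
  for (r in seq_along(report$models)) {
    for (p in names(report$models[[r]])) {
      fold <- report$models[[r]][[p]]
      contrib <- stats::predict(fold$model, X[fold$test, , drop = FALSE],
                                predcontrib = TRUE)
      acc <- acc + colSums(abs(contrib[, report$features, drop = FALSE]))
      n_rows <- n_rows + length(fold$test)
    }
  }
  m <- acc / n_rows
  out <- data.frame(genus = report$features, mean_abs_attribution = m,
                    selected = m > 1e-12, stringsAsFactors = FALSE)
  out[order(-out$mean_abs_attribution), ]
}

#' Cross-validated diet prediction from selected genera
#'
#' Predicts a dietary factor from genus abundances with gradient-boosted
#' trees under k-fold cross-validation (folds stratified by region so
#' regional signal cannot leak between train and test unevenly). Regression
#' performance is the Pearson correlation of out-of-fold predictions with
#' the observed values; classification performance is the ROC AUC with its
#' 95% CI.
#'
#' @param abundance abundance matrix restricted to the selected genera.
#' @param outcome numeric vector (regression) or 0/1 vector
#'   (classification), complete.
#' @param task `"regression"` or `"classification"`.
#' @param region region labels used for fold stratification (optional).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param nrounds boosting rounds (default 60).
#' @return List with `predicted` (out-of-fold, every participant once),
#'   `fold` assignments and `performance` (`pearson_r` or `auc` with
#'   `auc_ci`).
#' @export
predict_diet_from_genera <- function(abundance, outcome,
                                     task = c("regression", "classification"),
                                     region = NULL, folds = 10, seed = 1,
                                     nrounds = 60) {
  task <- match.arg(task)
  X <- unclass(abundance)
  stopifnot(folds >= 2, nrow(X) == length(outcome))
  if (anyNA(outcome)) stop("outcome must be complete (impute first)")
  if (stats::sd(outcome) == 0) stop("constant outcome")
  if (task == "classification" && !all(outcome %in% c(0, 1)))
    stop("classification outcome must be 0/1")
  set.seed(seed)
  fold_id <- integer(length(outcome))
  strata <- if (is.null(region)) rep(1, length(outcome)) else region
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  params <- .xgb_defaults(
    if (task == "regression") "reg:squarederror" else "binary:logistic")
  pred <- numeric(length(outcome))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    dtrain <- xgboost::xgb.DMatrix(X[!test, , drop = FALSE],
                                   label = outcome[!test], nthread = 1)
    set.seed(seed + f)
    fit <- xgboost::xgb.train(params = c(params, list(seed = seed + f)),
                              data = dtrain, nrounds = nrounds, verbose = 0)
    pred[test] <- stats::predict(fit, X[test, , drop = FALSE])
  }
  perf <- if (task == "regression") {
    list(pearson_r = stats::cor(pred, outcome))
  } else {
    roc <- pROC::roc(response = outcome, predictor = pred, quiet = TRUE,
                     direction = "<", levels = c(0, 1))
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc)))  # degenerate at AUC = 1
    list(auc = as.numeric(pROC::auc(roc)), auc_ci = ci[c(1, 3)])
  }
  list(predicted = pred, fold = fold_id, performance = perf)
}
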