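#' Default hyperparameter grid for the RBP classifier
#'
#' Tree depth and boosting rounds are the two tuned hyperparameters.
#' @return data.frame with columns `max_depth`, `n_estimators`.
#' @export
default_grid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L),
              n_estimators = c(100L, 300L, 500L))
}

fit_xgb <- function(X, y, max_depth, n_estimators) {
  dtrain <- xgboost::xgb.DMatrix(unclass(X)[, , drop = FALSE], label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 0.3, nthread = 1),
    data = dtrain, nrounds = n_estimators, verbose = 0)
}

predict_xgb <- function(model, X) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(unclass(X)[, , drop = FALSE])))
}

# deterministic stratified k-fold assignment
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

f1_at_threshold <- function(y_true, scores, threshold = 0.5) {
  classification_metrics(confusion(y_true, as.integer(scores >= threshold)),
                         quiet = TRUE)[["F1"]]
}

#' Nested cross-validated training of the RBP classifier
#'
#' Stratified nested cross-validation for an extreme gradient boosting
#' (XGBoost) binary classifier: the inner loop selects the hyperparameter
#' grid point (tree depth x boosting rounds) maximizing mean F1; the outer
#' loop measures F1 and PR-AUC on held-out folds never seen during
#' selection. A final model is then refit on all data with the grid point
#' that maximizes the pooled inner-selection F1.
#'
#' @param X Feature matrix (rownames = protein ids).
#' @param y Binary labels (1 = RBP, 0 = Other).
#' @param grid data.frame of `max_depth`, `n_estimators` candidates.
#' @param k_outer,k_inner Fold counts (default 4 and 4).
#' @param seed RNG seed controlling fold assignment.
#' @param threshold Decision threshold on the positive-class probability
#'   (label 1 iff score >= threshold).
#' @return Object of class `rbp_classifier`: the fitted final model,
#'   selected hyperparameters, feature `schema`, decision threshold, and
#'   `cv` (class `rbp_cv`) holding per-outer-fold F1 / PR-AUC, the selected
#'   grid point per fold and the outer fold assignment.
#' @export
nested_cv <- function(X, y, grid = default_grid(), k_outer = 4, k_inner = 4,
                      seed = 42, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% 0:1) || length(unique(y)) < 2) {
    stop("y must contain both classes, coded 0/1")
  }
  if (!nrow(grid)) stop("empty hyperparameter grid")

  outer <- stratified_folds(y, k_outer, seed)
  fold_metrics <- data.frame(fold = seq_len(k_outer), F1 = NA_real_,
                             PR_AUC = NA_real_, max_depth = NA_integer_,
                             n_estimators = NA_integer_)
  inner_f1_sum <- matrix(0, nrow = nrow(grid), ncol = k_outer)

  for (fo in seq_len(k_outer)) {
    tr <- which(outer != fo)
    te <- which(outer == fo)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop("outer fold ", fo, " is single-class; use fewer folds or more data")
    }
    inner <- stratified_folds(y[tr], k_inner, seed + fo)
    inner_f1 <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(k_inner), function(fi) {
        itr <- tr[inner != fi]
        ite <- tr[inner == fi]
        m <- fit_xgb(X[itr, , drop = FALSE], y[itr],
                     grid$max_depth[g], grid$n_estimators[g])
        f1_at_threshold(y[ite], predict_xgb(m, X[ite, , drop = FALSE]),
                        threshold)
      }, 0))
    }, 0)
    inner_f1_sum[, fo] <- inner_f1
    best <- which.max(inner_f1)
    m <- fit_xgb(X[tr, , drop = FALSE], y[tr],
                 grid$max_depth[best], grid$n_estimators[best])
    sc <- predict_xgb(m, X[te, , drop = FALSE])
    fold_metrics$F1[fo] <- f1_at_threshold(y[te], sc, threshold)
    fold_metrics$PR_AUC[fo] <- pr_auc(y[te], sc)
    fold_metrics$max_depth[fo] <- grid$max_depth[best]
    fold_metrics$n_estimators[fo] <- grid$n_estimators[best]
  }

  final_best <- which.max(rowMeans(inner_f1_sum))
  final <- fit_xgb(X, y, grid$max_depth[final_best],
                   grid$n_estimators[final_best])
  schema <- attr(X, "schema")
  if (is.null(schema)) schema <- list(embed_dim = ncol(X),
                                      hmm_names = character())
  cv <- structure(list(fold_metrics = fold_metrics,
                       mean_F1 = mean(fold_metrics$F1),
                       mean_PR_AUC = mean(fold_metrics$PR_AUC),
                       outer_folds = outer, seed = seed),
                  class = "rbp_cv")
  structure(list(model = final,
                 max_depth = grid$max_depth[final_best],
                 n_estimators = grid$n_estimators[final_best],
                 schema = schema,
                 embedder = attr(X, "embedder"),
                 n_features = ncol(X),
                 threshold = threshold,
                 cv = cv),
            class = "rbp_classifier")
}

#' @export
print.rbp_cv <- function(x, ...) {
  cat(sprintf("Nested CV (%d outer folds): mean F1 = %.3f, mean PR-AUC = %.3f\n",
              nrow(x$fold_metrics), x$mean_F1, x$mean_PR_AUC))
  print(x$fold_metrics, row.names = FALSE)
  invisible(x)
}

#' @export
print.rbp_classifier <- function(x, ...) {
  cat("RBP gradient-boosting classifier\n")
  cat(sprintf("  features: %d (%d embedding + %d HMM scores), embedder: %s\n",
              x$n_features, x$schema$embed_dim, length(x$schema$hmm_names),
              if (is.null(x$embedder)) "external" else x$embedder))
  cat(sprintf("  hyperparameters: max_depth = %d, n_estimators = %d\n",
              x$max_depth, x$n_estimators))
  print(x$cv)
  invisible(x)
}

#' Predict RBP labels and scores
#'
#' @param object An `rbp_classifier`.
#' @param newdata Feature matrix with the same layout the model was trained
#'   on.
#' @param threshold Decision threshold (defaults to the one stored in the
#'   model); label 1 (RBP) iff score >= threshold.
#' @param ... Unused.
#' @return data.frame with `id`, `score` (positive-class probability) and
#'   `label` (1 = RBP, 0 = Other).
#' @export
predict.rbp_classifier <- function(object, newdata, threshold = NULL, ...) {
  if (ncol(newdata) != object$n_features) {
    stop("feature dimension mismatch: model expects ", object$n_features,
         ", got ", ncol(newdata))
  }
  if (is.null(threshold)) threshold <- object$threshold
  sc <- predict_xgb(object$model, newdata)
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(newdata)))
  data.frame(id = ids, score = sc, label = as.integer(sc >= threshold),
             stringsAsFactors = FALSE)
}
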