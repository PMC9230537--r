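#' Confusion counts for binary predictions
#'
#' Label 1 denotes the positive (RBP) class.
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Named integer vector `TP, FP, TN, FN` (class `confusion_counts`).
#' @export
confusion <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty truth vector")
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(c(TP = sum(y_true == 1 & y_pred == 1),
              FP = sum(y_true == 0 & y_pred == 1),
              TN = sum(y_true == 0 & y_pred == 0),
              FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' F1 = 2TP / (2TP + FP + FN); sensitivity = TP / (TP + FN); specificity =
#' TN / (TN + FP); MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as 0 (with a warning
#' unless `quiet`).
#'
#' @param cc Counts from [confusion()] (or any named vector with
#'   `TP, FP, TN, FN`).
#' @param quiet Suppress degenerate-denominator warnings.
#' @return Named numeric vector `F1, MCC, sensitivity, specificity`.
#' @export
classification_metrics <- function(cc, quiet = FALSE) {
  tp <- as.numeric(cc[["TP"]]); fp <- as.numeric(cc[["FP"]])
  tn <- as.numeric(cc[["TN"]]); fn <- as.numeric(cc[["FN"]])
  safe <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) warning(what, " has zero denominator; reported as 0")
      return(0)
    }
    num / den
  }
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "F1")
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  c(F1 = f1, MCC = mcc, sensitivity = sens, specificity = spec)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration (average precision): thresholds descend through
#' the unique scores and each recall increment contributes the precision at
#' that threshold, with no interpolation. Ties in scores are handled as one
#' threshold.
#'
#' @param y_true Binary truth vector (1 = positive).
#' @param scores Continuous scores, higher = more positive.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  npos <- sum(y_true == 1)
  if (npos == 0 || npos == length(y_true)) {
    stop("PR-AUC requires both classes in y_true")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  n_pred <- seq_along(y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  precision <- tp[keep] / n_pred[keep]
  recall <- tp[keep] / npos
  sum(diff(c(0, recall)) * precision)
}

#' Concordance of correct positive predictions across methods
#'
#' Venn-style region counts: for each of the 2^m - 1 non-empty method
#' combinations, the number of positives correctly predicted by exactly
#' that combination, plus the count missed by every method.
#'
#' @param method_sets Named list; each element the ids of positives a
#'   method predicted correctly.
#' @param all_positive_ids Ids of all true positives under evaluation.
#' @return Object of class `concordance_table`: data.frame `regions`
#'   (`methods`, `count`), `missed_by_all`, `union_size`, `n_positives`.
#' @export
concordance <- function(method_sets, all_positive_ids) {
  stopifnot(length(method_sets) >= 1)
  if (is.null(names(method_sets)) || any(!nzchar(names(method_sets)))) {
    names(method_sets) <- paste0("method", seq_along(method_sets))
  }
  for (nm in names(method_sets)) {
    bad <- setdiff(method_sets[[nm]], all_positive_ids)
    if (length(bad)) {
      stop("method '", nm, "' claims ids outside the positive set: ",
           paste(head(bad, 3), collapse = ", "))
    }
  }
  m <- length(method_sets)
  member <- sapply(method_sets, function(s) all_positive_ids %in% s)
  member <- matrix(member, ncol = m,
                   dimnames = list(NULL, names(method_sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  regions <- data.frame(
    methods = apply(combos, 1, function(z) {
      paste(names(method_sets)[as.logical(z)], collapse = "&")
    }),
    count = apply(combos, 1, function(z) {
      sum(apply(member, 1, function(r) all(r == as.logical(z))))
    }),
    stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 missed_by_all = sum(rowSums(member) == 0),
                 union_size = sum(rowSums(member) > 0),
                 n_positives = length(all_positive_ids)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance of correct positive predictions\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("missed by all: %d / %d positives\n", x$missed_by_all,
              x$n_positives))
  invisible(x)
}

#' Evaluate several binary predictors against a common truth
#'
#' @param y_true Named binary vector (names = protein ids, 1 = RBP).
#' @param predictions Named list of prediction data.frames (`id`, `label`).
#' @return List with `metrics` (one row per method) and `concordance`.
#' @export
evaluate_methods <- function(y_true, predictions) {
  ids <- names(y_true)
  stopifnot(!is.null(ids))
  rows <- lapply(names(predictions), function(nm) {
    p <- predictions[[nm]]
    lab <- setNames(p$label, p$id)[ids]
    if (anyNA(lab)) stop("method '", nm, "' is missing predictions")
    data.frame(method = nm,
               t(classification_metrics(confusion(y_true, lab), quiet = TRUE)),
               stringsAsFactors = FALSE)
  })
  pos_ids <- ids[y_true == 1]
  sets <- lapply(predictions, function(p) {
    lab <- setNames(p$label, p$id)[pos_ids]
    pos_ids[lab == 1]
  })
  list(metrics = do.call(rbind, rows),
       concordance = concordance(sets, pos_ids))
}
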