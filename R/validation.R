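#' Stratified fold assignment
#'
#' Shuffles the cases within each outcome class (seeded) and deals them
#' round-robin into \code{kFolds} folds, so per-fold class counts never
#' differ from the stratified ideal by more than 1: with 36 aggressive and
#' 69 indolent cases and 10 folds, every fold holds 3-4 aggressive and 6-7
#' indolent cases. Excluded cases are never assigned. When \code{kFolds}
#' equals the number of non-excluded cases the assignment degenerates to
#' leave-one-out (one case per fold); otherwise every class must have at
#' least \code{kFolds} members.
#'
#' @param labels output of \code{\link{assignLabels}} or a factor of
#'   aggressive/indolent/excluded with case ids as names.
#' @param kFolds number of folds (default 10).
#' @param seed integer seed for the within-class shuffles.
#' @return \code{data.frame(case_id, label, fold)} with one row per
#'   non-excluded case; \code{kFolds} is attached as an attribute.
#' @section Errors: a class smaller than \code{kFolds} (short of the
#'   leave-one-out case) raises an infeasible-stratification error (class
#'   \code{"wd_infeasible_stratification"}).
#' @export
stratifiedFolds <- function(labels, kFolds = 10, seed = 1L) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$label), labels$case_id)
  } else lab <- stats::setNames(as.character(labels), names(labels))
  lab <- lab[lab %in% c("aggressive", "indolent")]
  n <- length(lab)
  if (n == 0L) .wdError("no non-excluded cases", "wd_validation_error")
  if (kFolds < 2L || kFolds > n)
    .wdError("'kFolds' must be between 2 and the number of cases",
             "wd_validation_error")
  if (kFolds == n) {          # leave-one-out: one case per fold
    out <- data.frame(case_id = names(lab), label = lab,
                      fold = seq_len(n), stringsAsFactors = FALSE,
                      row.names = NULL)
    attr(out, "kFolds") <- kFolds
    return(out)
  }
  counts <- table(lab)
  if (any(counts < kFolds))
    .wdError(sprintf(
      "class '%s' has %d cases, fewer than kFolds = %d: stratification infeasible",
      names(counts)[which.min(counts)], min(counts), kFolds),
      "wd_infeasible_stratification")
  fold <- integer(n)
  withSeed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(lab == cl))
      fold[idx] <- rep_len(seq_len(kFolds), length(idx))
    }
  })
  out <- data.frame(case_id = names(lab), label = lab, fold = fold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "kFolds") <- kFolds
  out
}

#' Accuracy, PPV and NPV of dichotomous predictions
#'
#' Treats \code{"aggressive"} (or 1) as the positive class. Accuracy is
#' (TP+TN)/n, PPV is TP/(TP+FP), NPV is TN/(TN+FN). A metric whose
#' denominator is empty (e.g. PPV with no positive prediction) is reported
#' as \code{NA} and named in the \code{"undefined"} attribute rather than
#' silently coerced to 0.
#'
#' @param predictions predicted classes (character aggressive/indolent or
#'   0/1).
#' @param labels true classes, same coding.
#' @return named numeric \code{c(accuracy, ppv, npv)} with a
#'   \code{"counts"} attribute (TP, FP, TN, FN) and an \code{"undefined"}
#'   attribute naming any undefined metric.
#' @examples
#' p <- rep(c(1, 0), c(10, 10)); y <- rep(c(1, 0, 1, 0), c(7, 3, 4, 6))
#' classificationMetrics(p, y)  # accuracy 0.65, PPV 0.7, NPV 0.6
#' @export
classificationMetrics <- function(predictions, labels) {
  toBin <- function(z) {
    if (is.character(z) || is.factor(z))
      as.integer(as.character(z) == "aggressive")
    else as.integer(z)
  }
  p <- toBin(predictions); y <- toBin(labels)
  if (length(p) != length(y) || length(p) == 0L)
    .wdError("predictions and labels must be aligned and non-empty",
             "wd_validation_error")
  tp <- sum(p == 1L & y == 1L); fp <- sum(p == 1L & y == 0L)
  tn <- sum(p == 0L & y == 0L); fn <- sum(p == 0L & y == 1L)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  out <- c(accuracy = (tp + tn) / length(p), ppv = ppv, npv = npv)
  attr(out, "counts") <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' ROC curve and AUC of a graded score
#'
#' Operating points are obtained by sweeping the rule "score at or above
#' threshold is called aggressive" over the distinct observed scores (plus a
#' point above the maximum), giving the full curve from (0,0) to (1,1); for
#' a k-marker composite score there are at most k+2 such points. The AUC is
#' computed in its rank (Mann-Whitney) form: the probability that a random
#' aggressive case scores above a random indolent case, ties counted one
#' half.
#'
#' @param scores numeric scores, higher meaning more aggressive.
#' @param labels true classes (aggressive/indolent or 1/0).
#' @return list with \code{roc} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @section Errors: labels with a single class raise an error.
#' @examples
#' rocAuc(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "aggressive") else as.integer(labels)
  s <- as.numeric(scores)
  if (length(s) != length(y) || anyNA(s) || anyNA(y))
    .wdError("scores and labels must be aligned and non-missing",
             "wd_validation_error")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    .wdError("both classes must be present to compute a ROC curve",
             "wd_validation_error")
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(s >= t & y == 0L) / nNeg, numeric(1)),
    tpr = vapply(thr, function(t) sum(s >= t & y == 1L) / nPos, numeric(1)))
  list(roc = roc, auc = auc)
}

#' Stratified k-fold cross-validation of the WD classifier
#'
#' For each fold, fits \code{\link{fitWD}} on the remaining folds and
#' predicts the held-out cases, so every non-excluded case receives exactly
#' one out-of-fold score and call. Metrics (accuracy, PPV, NPV, AUC) are
#' pooled over all out-of-fold predictions rather than averaged per fold,
#' which is well defined when fold sizes are unequal.
#'
#' @inheritParams fitWD
#' @param kFolds number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @return A \linkS4class{WDCrossValidation}.
#' @examples
#' se <- normalizeBatch(simulateCohort(cohortConfig(nAggressive = 12,
#'   nIndolent = 20, seed = 5)))
#' cv <- runCV(se, assignLabels(se), directions = "auto", kFolds = 4,
#'             seed = 5)
#' cv@metrics
#' @export
runCV <- function(x, labels, directions, kFolds = 10, seed = 1L,
                  threshold = 0.5) {
  stopifnot(is(x, "StainingExperiment"))
  lab <- alignLabels(x, labels)
  folds <- stratifiedFolds(
    data.frame(case_id = colnames(x), label = lab), kFolds = kFolds,
    seed = seed)
  preds <- vector("list", kFolds)
  clfs <- vector("list", kFolds)
  for (f in seq_len(kFolds)) {
    testIds <- folds$case_id[folds$fold == f]
    trainIds <- folds$case_id[folds$fold != f]
    clf <- tryCatch(
      fitWD(x[, trainIds], folds[folds$fold != f, c("case_id", "label")],
            directions = directions, threshold = threshold),
      error = function(e)
        stop(errorCondition(sprintf("fold %d: %s", f, conditionMessage(e)),
                            class = c("wd_cv_error", "wd_error"))))
    p <- predict(clf, x[, testIds])
    p$fold <- f
    preds[[f]] <- p
    clfs[[f]] <- clf
  }
  pred <- do.call(rbind, preds)
  pred$label <- folds$label[match(pred$case_id, folds$case_id)]
  pred <- pred[, c("case_id", "fold", "label", "score", "prediction")]
  cm <- classificationMetrics(pred$prediction, pred$label)
  auc <- rocAuc(pred$score, pred$label)$auc
  new("WDCrossValidation", predictions = pred,
      metrics = c(accuracy = unname(cm["accuracy"]), ppv = unname(cm["ppv"]),
                  npv = unname(cm["npv"]), auc = auc),
      folds = folds, classifiers = clfs)
}
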