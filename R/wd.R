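#' Dichotomize expression values with a marker rule
#'
#' Converts expression values into per-marker votes \eqn{S_i \in \{0, 1\}}
#' (1 = aggressive). An oncogene-like marker votes aggressive at or above
#' its cutoff; a suppressor-like marker at or below it. Equality at the
#' cutoff goes to the aggressive side in both directions, mirroring the
#' composite rule's "aggressive if \eqn{S \ge 0.5}" tie convention. Missing
#' values yield \code{NA} votes for downstream handling.
#'
#' @param values numeric expression values.
#' @param rule a \linkS4class{MarkerRule}.
#' @return integer vector of 0/1 votes (NA where \code{values} is NA).
#' @examples
#' r <- MarkerRule("M", "oncogene", cutoff = 0.2)
#' dichotomize(c(0.3, 0.1, 0.2), r)  # 1 0 1
#' @export
dichotomize <- function(values, rule) {
  stopifnot(is(rule, "MarkerRule"))
  v <- as.numeric(values)
  if (rule@direction == "oncogene") as.integer(v >= rule@cutoff)
  else as.integer(v <= rule@cutoff)
}

#' Optimal-cutoff search for one marker
#'
#' Sweeps every distinct observed expression value as a candidate cutoff and
#' returns the one whose dichotomization agrees with the training labels
#' most often, together with that maximal training accuracy \eqn{\alpha}.
#' The candidate set is exactly the sorted observed values — no midpoints or
#' out-of-range sentinels — and ties in accuracy are broken toward the
#' smallest candidate for determinism. Single-class label vectors are
#' permitted; the search then returns the candidate that best approximates
#' the constant prediction (an all-indolent prediction is not representable
#' in this candidate scheme, so the attainable \eqn{\alpha} can fall short
#' of 1 in that case).
#'
#' @param values numeric training expression values (non-missing).
#' @param labels 0/1 vector (1 = aggressive), same length.
#' @param direction \code{"oncogene"} or \code{"suppressor"}.
#' @return list with \code{cutoff} and \code{accuracy}.
#' @section Errors: all values identical raises a degenerate-marker error
#'   (class \code{"wd_degenerate_marker"}).
#' @examples
#' searchOptimalCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1), "oncogene")
#' # cutoff 3, accuracy 1
#' @export
searchOptimalCutoff <- function(values, labels, direction) {
  direction <- match.arg(direction, c("oncogene", "suppressor"))
  x <- as.numeric(values)
  y <- as.integer(labels)
  if (length(x) != length(y))
    .wdError("'values' and 'labels' must be the same length",
             "wd_validation_error")
  if (any(is.na(x)) || any(is.na(y)) || !all(y %in% c(0L, 1L)))
    .wdError("values must be non-missing and labels 0/1",
             "wd_validation_error")
  cand <- sort(unique(x))
  if (length(cand) < 2L)
    .wdError("all expression values are identical; no cutoff separates them",
             "wd_degenerate_marker")
  # counts of each label at each distinct value, in candidate order; match()
  # compares doubles exactly (factor() would collapse values that merely
  # print identically)
  idx <- match(x, cand)
  pos <- tabulate(idx[y == 1L], nbins = length(cand))
  neg <- tabulate(idx[y == 0L], nbins = length(cand))
  if (direction == "oncogene") {
    # predict 1 iff x >= cutoff: correct = #pos at/above + #neg below
    correct <- rev(cumsum(rev(pos))) + c(0, cumsum(neg)[-length(neg)])
  } else {
    # predict 1 iff x <= cutoff: correct = #pos at/below + #neg above
    correct <- cumsum(pos) + (sum(neg) - cumsum(neg))
  }
  best <- which.max(correct)  # first maximum = smallest candidate
  list(cutoff = cand[best], accuracy = correct[best] / length(x))
}

#' Accuracy-proportional marker weights
#'
#' Converts per-marker training accuracies \eqn{\alpha_i} into composite
#' weights \eqn{w_i = \alpha_i / \sum_j \alpha_j}, so markers that separated
#' the training classes better carry proportionally more of the composite
#' score. Weights are invariant to rescaling all accuracies by a common
#' positive factor and always sum to 1.
#'
#' @param accuracies positive numeric vector of training accuracies.
#' @return numeric weights, same length and names, summing to 1.
#' @examples
#' computeWeights(c(0.724, 0.676, 0.667))
#' @export
computeWeights <- function(accuracies) {
  a <- as.numeric(accuracies)
  if (length(a) < 1L || any(is.na(a)) || any(a <= 0))
    .wdError("all accuracies must be positive", "wd_validation_error")
  stats::setNames(a / sum(a), names(accuracies))
}

#' Composite weighted score
#'
#' Combines per-marker votes into \eqn{S = \sum_i S_i w_i \in [0, 1]}. When
#' a case has missing votes and \code{renormalizeMissing} is \code{TRUE},
#' the weights are renormalized over that case's observed markers so the
#' score stays in [0, 1]; this is an extension for incomplete panels, not
#' part of the original procedure, and is off by default.
#'
#' @param predictions 0/1 votes: a vector (one case) or a cases-by-markers
#'   matrix.
#' @param weights weights from \code{\link{computeWeights}}.
#' @param renormalizeMissing handle NA votes by renormalizing weights over
#'   observed markers instead of propagating NA.
#' @return numeric score(s) in [0, 1].
#' @examples
#' w <- computeWeights(c(0.724, 0.676, 0.667))
#' compositeScore(c(1, 1, 0), w)  # 0.6773
#' @export
compositeScore <- function(predictions, weights, renormalizeMissing = FALSE) {
  if (abs(sum(weights) - 1) > 1e-12)
    .wdError("weights must sum to 1", "wd_validation_error")
  m <- if (is.matrix(predictions)) predictions
       else matrix(predictions, nrow = 1)
  if (ncol(m) != length(weights))
    .wdError("one prediction per weight is required", "wd_validation_error")
  if (!all(m %in% c(0, 1) | is.na(m)))
    .wdError("predictions must be 0/1", "wd_validation_error")
  s <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ]
    if (!anyNA(p)) return(sum(p * weights))
    if (!renormalizeMissing || all(is.na(p))) return(NA_real_)
    ok <- !is.na(p)
    sum(p[ok] * weights[ok] / sum(weights[ok]))
  }, numeric(1))
  if (is.matrix(predictions)) s else s[1]
}

#' Threshold a composite score into a class call
#'
#' @param score composite score(s) in [0, 1].
#' @param threshold decision threshold; scores at or above it are called
#'   aggressive (default 0.5).
#' @return character vector of \code{"aggressive"} / \code{"indolent"}.
#' @examples
#' classifyScore(c(0.5, 0.49, 1))  # aggressive indolent aggressive
#' @export
classifyScore <- function(score, threshold = 0.5) {
  ifelse(is.na(score), NA_character_,
         ifelse(score >= threshold, "aggressive", "indolent"))
}

#' Fit the Weighted Dichotomizing composite classifier
#'
#' For every marker in the (normalized) expression table, searches the
#' optimal cutoff on the non-excluded training cases, then weights the
#' markers by their training accuracies. Marker directions come from prior
#' biological knowledge via \code{directions}; with
#' \code{directions = "auto"} each marker instead adopts whichever direction
#' achieves the higher training accuracy (a data-driven mode that is not the
#' default usage).
#'
#' @param x a normalized \linkS4class{StainingExperiment}.
#' @param labels output of \code{\link{assignLabels}} (or an aligned factor);
#'   excluded cases are ignored.
#' @param directions named character vector mapping every marker to
#'   \code{"oncogene"}/\code{"suppressor"}, or \code{"auto"}.
#' @param threshold composite decision threshold, default 0.5.
#' @return A \linkS4class{CompositeClassifier}.
#' @examples
#' se <- simulateCohort(cohortConfig(nAggressive = 10, nIndolent = 15,
#'                                   seed = 3))
#' nse <- normalizeBatch(se)
#' lab <- assignLabels(nse)
#' fitWD(nse, lab, directions = c(FGFR1 = "suppressor", MYPT1 = "oncogene",
#'                                LDHB = "oncogene"))
#' @export
fitWD <- function(x, labels, directions, threshold = 0.5) {
  stopifnot(is(x, "StainingExperiment"))
  if (!isNormalized(x))
    .wdError("fitWD requires a normalized table; run normalizeBatch first",
             "wd_validation_error")
  lab <- alignLabels(x, labels)
  keep <- lab %in% c("aggressive", "indolent")
  y <- as.integer(lab[keep] == "aggressive")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    .wdError("need at least 2 aggressive and 2 indolent cases to fit",
             "wd_validation_error")
  expr <- intensities(x)[, keep, drop = FALSE]
  markers <- rownames(expr)
  auto <- identical(directions, "auto")
  if (!auto) {
    if (!all(markers %in% names(directions)))
      .wdError(paste("missing direction for marker(s):",
                     paste(setdiff(markers, names(directions)),
                           collapse = ", ")), "wd_validation_error")
  }
  rules <- lapply(markers, function(mk) {
    v <- expr[mk, ]
    ok <- !is.na(v)
    tryCatch({
      if (auto) {
        f1 <- searchOptimalCutoff(v[ok], y[ok], "oncogene")
        f2 <- searchOptimalCutoff(v[ok], y[ok], "suppressor")
        if (f1$accuracy >= f2$accuracy)
          MarkerRule(mk, "oncogene", f1$cutoff, f1$accuracy)
        else MarkerRule(mk, "suppressor", f2$cutoff, f2$accuracy)
      } else {
        f <- searchOptimalCutoff(v[ok], y[ok], directions[[mk]])
        MarkerRule(mk, directions[[mk]], f$cutoff, f$accuracy)
      }
    }, wd_error = function(e)
      stop(errorCondition(sprintf("marker %s: %s", mk, conditionMessage(e)),
                          class = class(e)[class(e) != "simpleError"])))
  })
  CompositeClassifier(rules,
                      computeWeights(vapply(rules, function(r) r@accuracy,
                                            numeric(1))),
                      threshold = threshold)
}

#' Predict with a fitted composite classifier
#'
#' @param object a \linkS4class{CompositeClassifier}.
#' @param newdata a normalized \linkS4class{StainingExperiment} containing
#'   the classifier's markers, or a cases-by-markers numeric matrix.
#' @param type \code{"class"} (default), \code{"score"}, or \code{"votes"}.
#' @param renormalizeMissing see \code{\link{compositeScore}}.
#' @return A data.frame with \code{case_id}, \code{score} and
#'   \code{prediction} for \code{type = "class"}; a named numeric vector for
#'   \code{"score"}; the 0/1 vote matrix for \code{"votes"}.
#' @export
setMethod("predict", "CompositeClassifier",
  function(object, newdata, type = c("class", "score", "votes"),
           renormalizeMissing = FALSE) {
    type <- match.arg(type)
    if (is(newdata, "StainingExperiment")) {
      if (!isNormalized(newdata))
        .wdError("prediction requires a normalized table",
                 "wd_validation_error")
      mat <- t(intensities(newdata))
    } else mat <- as.matrix(newdata)
    markers <- vapply(object@rules, function(r) r@marker, character(1))
    if (!all(markers %in% colnames(mat)))
      .wdError("newdata is missing classifier marker(s)",
               "wd_validation_error")
    votes <- vapply(seq_along(object@rules), function(i)
      dichotomize(mat[, markers[i]], object@rules[[i]]),
      integer(nrow(mat)))
    votes <- matrix(votes, nrow = nrow(mat),
                    dimnames = list(rownames(mat), markers))
    if (type == "votes") return(votes)
    s <- compositeScore(votes, object@weights,
                        renormalizeMissing = renormalizeMissing)
    s <- stats::setNames(as.numeric(s), rownames(mat))
    if (type == "score") return(s)
    data.frame(case_id = rownames(mat), score = as.numeric(s),
               prediction = classifyScore(s, object@threshold),
               stringsAsFactors = FALSE, row.names = NULL)
  })

#' Training accuracy of a fitted classifier on labeled data
#'
#' @param object a \linkS4class{CompositeClassifier}.
#' @param x a normalized \linkS4class{StainingExperiment}.
#' @param labels labels as in \code{\link{fitWD}}; excluded cases ignored.
#' @return fraction of non-excluded cases whose composite call matches the
#'   label.
#' @export
trainingAccuracy <- function(object, x, labels) {
  lab <- alignLabels(x, labels)
  keep <- lab %in% c("aggressive", "indolent")
  pred <- predict(object, x[, keep])
  mean(pred$prediction == as.character(lab[keep]))
}

#' Serialize / restore a fitted classifier as structured text
#'
#' The model file is JSON with one record per marker (name, direction,
#' cutoff, training accuracy), the weights and the decision threshold.
#'
#' @param object a \linkS4class{CompositeClassifier}.
#' @param path file path.
#' @return \code{writeWDModel} returns \code{path} invisibly;
#'   \code{readWDModel} returns the restored classifier.
#' @export
writeWDModel <- function(object, path) {
  stopifnot(is(object, "CompositeClassifier"))
  rules <- lapply(object@rules, function(r)
    list(marker = r@marker, direction = r@direction, cutoff = r@cutoff,
         accuracy = r@accuracy))
  # 17 significant digits so cutoffs survive the round trip bit-exactly;
  # equality at the cutoff is part of the decision rule
  jsonlite::write_json(list(model = "weighted-dichotomizing", rules = rules,
                            weights = object@weights,
                            threshold = object@threshold),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeWDModel
#' @export
readWDModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r)
    MarkerRule(r$marker, r$direction, r$cutoff, r$accuracy))
  CompositeClassifier(rules, unlist(obj$weights), threshold = obj$threshold)
}
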