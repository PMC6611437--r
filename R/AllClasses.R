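#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<-
NULL

#' StainingExperiment: per-case IHC marker intensities with TMA batch labels
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay,
#' \code{"intensity"}, with markers in rows and patient cases in columns.
#' \code{colData} must carry a \code{batch} column identifying the TMA each
#' case was stained on, and may carry clinical columns (\code{time_months},
#' \code{event}, \code{psa}, \code{gleason}, \code{margin}, \code{stage}).
#' The \code{normalized} slot flags whether intensities are raw Aperio-style
#' average intensities (non-negative) or have been through the within-TMA
#' median/range transform of \code{\link{normalizeBatch}}; a table is one or
#' the other, never mixed.
#'
#' @slot normalized logical scalar; \code{FALSE} for raw intensities.
#'
#' @seealso \code{\link{StainingExperiment}} (constructor),
#'   \code{\link{normalizeBatch}}, \code{\link{simulateCohort}}
#' @export
setClass("StainingExperiment",
  contains = "SummarizedExperiment",
  representation(normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("StainingExperiment", function(object) {
  msg <- NULL
  if (!("intensity" %in% assayNames(object)))
    msg <- c(msg, "assay 'intensity' is required")
  if (!("batch" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain a 'batch' column")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "'normalized' must be TRUE or FALSE")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "marker (row) and case (column) names are required")
  if (isFALSE(object@normalized) && "intensity" %in% assayNames(object)) {
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msg <- c(msg, "raw intensities must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a StainingExperiment
#'
#' @param intensity numeric matrix, markers in rows, cases in columns; both
#'   dimnames required.
#' @param batch character or factor of length \code{ncol(intensity)}: the TMA
#'   batch each case belongs to.
#' @param clinical optional \code{data.frame} of per-case clinical columns
#'   (rows aligned with the columns of \code{intensity}).
#' @param normalized logical; \code{TRUE} if the intensities have already been
#'   normalized within TMA.
#' @return A \linkS4class{StainingExperiment}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("FGFR1", "MYPT1"), c("P1", "P2", "P3")))
#' se <- StainingExperiment(m, batch = c("TMA1", "TMA1", "TMA2"))
#' intensities(se)
#' @export
StainingExperiment <- function(intensity, batch, clinical = NULL,
                               normalized = FALSE) {
  intensity <- as.matrix(intensity)
  if (length(batch) != ncol(intensity))
    stop("'batch' must have one entry per case (column)")
  cd <- DataFrame(batch = as.character(batch), row.names = colnames(intensity))
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    if (nrow(clinical) != ncol(intensity))
      stop("'clinical' must have one row per case")
    for (nm in setdiff(colnames(clinical), c("case_id", "batch_id", "batch")))
      cd[[nm]] <- clinical[[nm]]
  }
  new("StainingExperiment",
      SummarizedExperiment(assays = list(intensity = intensity), colData = cd),
      normalized = isTRUE(normalized))
}

#' MarkerRule: one marker's dichotomizing rule
#'
#' The fitted decision rule for a single marker: its biological direction,
#' the optimal cutoff chosen among the observed training expression values,
#' and the training accuracy \eqn{\alpha_i} that cutoff achieved. For an
#' oncogene-like marker a case votes aggressive when its expression is at or
#' above the cutoff; for a suppressor-like marker when at or below it.
#'
#' @slot marker character, marker name.
#' @slot direction \code{"oncogene"} or \code{"suppressor"}.
#' @slot cutoff numeric, on the scale of the training expression values.
#' @slot accuracy numeric in [0, 1], the training accuracy of the cutoff.
#' @seealso \code{\link{searchOptimalCutoff}}, \code{\link{dichotomize}}
#' @export
setClass("MarkerRule",
  representation(marker = "character", direction = "character",
                 cutoff = "numeric", accuracy = "numeric")
)

setValidity("MarkerRule", function(object) {
  msg <- NULL
  if (length(object@direction) != 1L ||
      !object@direction %in% c("oncogene", "suppressor"))
    msg <- c(msg, "direction must be 'oncogene' or 'suppressor'")
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
    msg <- c(msg, "cutoff must be a single finite number")
  if (length(object@accuracy) != 1L ||
      (!is.na(object@accuracy) &&
         (object@accuracy < 0 || object@accuracy > 1)))
    msg <- c(msg, "accuracy must lie in [0, 1] (NA before fitting)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname MarkerRule-class
#' @param marker,direction,cutoff,accuracy see slots.
#' @export
MarkerRule <- function(marker, direction, cutoff, accuracy = NA_real_) {
  new("MarkerRule", marker = as.character(marker),
      direction = match.arg(direction, c("oncogene", "suppressor")),
      cutoff = as.numeric(cutoff), accuracy = as.numeric(accuracy))
}

#' CompositeClassifier: the weighted-dichotomizing composite model
#'
#' Holds \eqn{k} per-marker \linkS4class{MarkerRule}s together with their
#' accuracy-proportional weights \eqn{w_i = \alpha_i / \sum_j \alpha_j} and
#' the decision threshold. A case's composite score is
#' \eqn{S = \sum_i S_i w_i} where \eqn{S_i \in \{0,1\}} is the marker vote,
#' and the case is called aggressive when \eqn{S \ge} \code{threshold}.
#'
#' @slot rules list of \linkS4class{MarkerRule}.
#' @slot weights numeric, positive, summing to 1, aligned with \code{rules}.
#' @slot threshold numeric decision threshold on the composite score
#'   (default 0.5).
#' @seealso \code{\link{fitWD}}, \code{\link{compositeScore}}
#' @export
setClass("CompositeClassifier",
  representation(rules = "list", weights = "numeric", threshold = "numeric"),
  prototype(threshold = 0.5)
)

setValidity("CompositeClassifier", function(object) {
  msg <- NULL
  k <- length(object@rules)
  if (k < 1L) msg <- c(msg, "at least one marker rule is required")
  if (!all(vapply(object@rules, is, logical(1), "MarkerRule")))
    msg <- c(msg, "all rules must be MarkerRule objects")
  if (length(object@weights) != k)
    msg <- c(msg, "one weight per rule is required")
  else {
    if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
    if (abs(sum(object@weights) - 1) > 1e-12)
      msg <- c(msg, "weights must sum to 1 (tolerance 1e-12)")
  }
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @rdname CompositeClassifier-class
#' @param rules,weights,threshold see slots.
#' @export
CompositeClassifier <- function(rules, weights, threshold = 0.5) {
  new("CompositeClassifier", rules = rules, weights = as.numeric(weights),
      threshold = threshold)
}

setMethod("show", "StainingExperiment", function(object) {
  callNextMethod()
  cat("intensities:", if (object@normalized) "normalized (within-TMA median/range)"
      else "raw", "\n")
  cat("TMA batches:", paste(unique(colData(object)$batch), collapse = ", "),
      "\n")
})

setMethod("show", "MarkerRule", function(object) {
  cat(sprintf("MarkerRule %s [%s]: cutoff %.4g, training accuracy %.3f\n",
              object@marker, object@direction, object@cutoff,
              object@accuracy))
})

setMethod("show", "CompositeClassifier", function(object) {
  cat(sprintf("CompositeClassifier with %d markers (aggressive if S >= %g)\n",
              length(object@rules), object@threshold))
  for (i in seq_along(object@rules)) {
    r <- object@rules[[i]]
    cat(sprintf("  %-8s %-10s cutoff %8.4g  alpha %.3f  weight %.3f\n",
                r@marker, r@direction, r@cutoff, r@accuracy,
                object@weights[i]))
  }
})

#' WDCrossValidation: pooled out-of-fold results of a stratified k-fold CV
#'
#' @slot predictions data.frame with one row per case: \code{case_id},
#'   \code{fold}, \code{label}, \code{score}, \code{prediction}.
#' @slot metrics named numeric: pooled \code{accuracy}, \code{ppv},
#'   \code{npv}, \code{auc}.
#' @slot folds the fold assignment used.
#' @slot classifiers list of the k per-fold fitted classifiers.
#' @seealso \code{\link{runCV}}
#' @export
setClass("WDCrossValidation",
  representation(predictions = "data.frame", metrics = "numeric",
                 folds = "data.frame", classifiers = "list")
)

setMethod("show", "WDCrossValidation", function(object) {
  cat(sprintf("WDCrossValidation: %d cases, %d folds\n",
              nrow(object@predictions), length(object@classifiers)))
  m <- object@metrics
  cat(sprintf("  accuracy %.3f  PPV %.3f  NPV %.3f  AUC %.3f\n",
              m["accuracy"], m["ppv"], m["npv"], m["auc"]))
})
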