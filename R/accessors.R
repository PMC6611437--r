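#' Accessors for StainingExperiment
#'
#' \code{intensities} returns the marker-by-case intensity matrix;
#' \code{batchIds} the per-case TMA batch labels; \code{isNormalized} whether
#' the table holds within-TMA normalized values; \code{clinicalData} the
#' per-case clinical columns as a plain \code{data.frame} keyed by
#' \code{case_id}; \code{syntheticTruth} the planted ground truth when the
#' object came from \code{\link{simulateCohort}} (otherwise \code{NULL}).
#'
#' @param x a \linkS4class{StainingExperiment}.
#' @return See description; accessor values, not copies of the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
intensities <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  assay(x, "intensity")
}

#' @rdname accessors
#' @export
batchIds <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  stats::setNames(as.character(colData(x)$batch), colnames(x))
}

#' @rdname accessors
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  x@normalized
}

#' @rdname accessors
#' @export
clinicalData <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  cd <- as.data.frame(colData(x))
  keep <- setdiff(colnames(cd), "batch")
  out <- cbind(data.frame(case_id = colnames(x), stringsAsFactors = FALSE),
               cd[, keep, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname accessors
#' @export
syntheticTruth <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  metadata(x)$truth
}

# classed error helper so callers can condition on failure modes
.wdError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wd_error")))
}
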