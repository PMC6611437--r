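#' Per-(marker, TMA) median and range statistics
#'
#' The within-TMA normalization rescales each raw average intensity \eqn{I}
#' to \eqn{I' = (I - M) / R}, where \eqn{M} is the median and \eqn{R} the
#' range (max minus min) of the intensities of all samples for that marker
#' on that TMA. \code{batchStats} computes \eqn{M} and \eqn{R} for one
#' stratum; missing intensities are excluded.
#'
#' @param x a \linkS4class{StainingExperiment}.
#' @param marker marker name (row of \code{x}).
#' @param batch TMA batch identifier.
#' @return list with \code{batch}, \code{marker}, \code{median},
#'   \code{range}, \code{n} (non-missing cases used).
#' @section Errors: fewer than 2 non-missing values in the stratum raises an
#'   insufficient-batch error (class \code{"wd_insufficient_batch"}); a zero
#'   range raises a degenerate-batch error (\code{"wd_degenerate_batch"}).
#' @examples
#' m <- matrix(1:5, nrow = 1, dimnames = list("M1", paste0("P", 1:5)))
#' se <- StainingExperiment(m, batch = rep("TMA1", 5))
#' batchStats(se, "M1", "TMA1")  # median 3, range 4
#' @export
batchStats <- function(x, marker, batch) {
  stopifnot(is(x, "StainingExperiment"))
  if (!marker %in% rownames(x))
    .wdError(sprintf("unknown marker '%s'", marker), "wd_validation_error")
  vals <- intensities(x)[marker, batchIds(x) == batch]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    .wdError(sprintf(
      "stratum (marker %s, batch %s) has %d non-missing value(s); >= 2 required",
      marker, batch, length(vals)), "wd_insufficient_batch")
  R <- max(vals) - min(vals)
  if (R == 0)
    .wdError(sprintf(
      "stratum (marker %s, batch %s) is degenerate: all intensities equal (range 0)",
      marker, batch), "wd_degenerate_batch")
  list(batch = batch, marker = marker, median = stats::median(vals),
       range = R, n = length(vals))
}

#' Within-TMA median/range normalization of raw intensities
#'
#' Applies \eqn{I' = (I - M)/R} independently in every (marker, TMA batch)
#' stratum of a raw-flagged table: \eqn{M} and \eqn{R} come from
#' \code{\link{batchStats}} on that stratum. After the transform every
#' stratum has median 0 and range exactly 1, and any per-batch affine
#' distortion \eqn{I \to aI + b} (\eqn{a > 0}) of the raw values leaves the
#' normalized values unchanged, which is what makes intensities measured on
#' different TMA reactions comparable. Missing values are excluded from
#' \eqn{M} and \eqn{R} and propagated as missing.
#'
#' @param x a raw-flagged \linkS4class{StainingExperiment}.
#' @return A normalized-flagged \linkS4class{StainingExperiment} with the
#'   same dimensions, colData and metadata.
#' @section Errors: errors from \code{\link{batchStats}} are propagated with
#'   the offending (marker, batch) stratum named.
#' @examples
#' m <- matrix(1:5, nrow = 1, dimnames = list("M1", paste0("P", 1:5)))
#' se <- StainingExperiment(m, batch = rep("TMA1", 5))
#' intensities(normalizeBatch(se))  # -0.5 -0.25 0 0.25 0.5
#' @export
normalizeBatch <- function(x) {
  stopifnot(is(x, "StainingExperiment"))
  if (isNormalized(x))
    .wdError("table is already normalized", "wd_validation_error")
  raw <- intensities(x)
  bids <- batchIds(x)
  out <- raw
  for (marker in rownames(raw)) {
    for (batch in unique(bids)) {
      st <- batchStats(x, marker, batch)
      sel <- bids == batch
      out[marker, sel] <- (raw[marker, sel] - st$median) / st$range
    }
  }
  res <- x
  res@normalized <- TRUE
  assay(res, "intensity", withDimnames = FALSE) <- out
  validObject(res)
  res
}
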