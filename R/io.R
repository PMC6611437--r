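#' Delimited-text I/O for expression, clinical and label tables
#'
#' The expression CSV has columns \code{case_id}, \code{batch_id} and one
#' column per marker; the clinical CSV has \code{case_id},
#' \code{time_months}, \code{event} (0/1) and optionally \code{psa},
#' \code{gleason}, \code{margin}, \code{stage}; the labels CSV has
#' \code{case_id}, \code{label}. These are the interchange formats between
#' pipeline stages.
#'
#' @param x object to write (\linkS4class{StainingExperiment} or
#'   data.frame).
#' @param path CSV path.
#' @param normalized for \code{readExpressionCsv}: whether the file holds
#'   normalized intensities.
#' @param clinical for \code{readExpressionCsv}: optional clinical
#'   data.frame (as from \code{readClinicalCsv}) merged into colData by
#'   \code{case_id}.
#' @return readers return the parsed object; writers return \code{path}
#'   invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeExpressionCsv <- function(x, path) {
  stopifnot(is(x, "StainingExperiment"))
  df <- data.frame(case_id = colnames(x), batch_id = unname(batchIds(x)),
                   t(intensities(x)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readExpressionCsv <- function(path, normalized = FALSE, clinical = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("case_id", "batch_id")
  if (!all(need %in% colnames(df)))
    .wdError("expression CSV must have case_id and batch_id columns",
             "wd_validation_error")
  markers <- setdiff(colnames(df), need)
  m <- t(as.matrix(df[, markers, drop = FALSE]))
  colnames(m) <- df$case_id
  if (!is.null(clinical)) {
    idx <- match(df$case_id, clinical$case_id)
    if (any(is.na(idx)))
      .wdError("clinical table is missing some expression cases",
               "wd_validation_error")
    clinical <- clinical[idx, setdiff(colnames(clinical), "case_id"),
                         drop = FALSE]
  }
  StainingExperiment(m, batch = df$batch_id, clinical = clinical,
                     normalized = normalized)
}

#' @rdname tableIO
#' @export
writeClinicalCsv <- function(x, path) {
  df <- if (is(x, "StainingExperiment")) clinicalData(x) else as.data.frame(x)
  if ("event" %in% colnames(df)) df$event <- as.integer(as.logical(df$event))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readClinicalCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("case_id", "time_months", "event") %in% colnames(df)))
    .wdError("clinical CSV must have case_id, time_months, event columns",
             "wd_validation_error")
  df$event <- as.logical(df$event)
  df
}

#' @rdname tableIO
#' @export
writeLabelsCsv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readLabelsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "label") %in% colnames(df)))
    .wdError("labels CSV must have case_id and label columns",
             "wd_validation_error")
  df$label <- factor(df$label,
                     levels = c("aggressive", "indolent", "excluded"))
  df
}
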