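#' Censoring-aware aggressive/indolent case redefinition
#'
#' Labels each patient from their censored time to biochemical recurrence
#' (BCR): \emph{aggressive} if BCR was observed within
#' \code{aggressiveWindow} months of surgery (default 36, i.e. 3 years);
#' \emph{indolent} if the patient remained BCR-free for at least
#' \code{indolentMinFollowup} months (default 72, i.e. 6 years);
#' \emph{excluded} otherwise. The boundary reading is literal: an event at
#' exactly the window is aggressive, censoring at exactly the minimum
#' follow-up is indolent. A patient whose BCR event occurs at or beyond
#' \code{indolentMinFollowup} did show BCR and is therefore excluded, not
#' indolent: the indolent class is reserved for non-relapse cases with long
#' follow-up.
#'
#' @param records a \code{data.frame} with columns \code{case_id},
#'   \code{time_months} (positive), \code{event} (logical: BCR observed), or
#'   a \linkS4class{StainingExperiment} carrying those clinical columns.
#' @param aggressiveWindow months; events at or before this are aggressive.
#' @param indolentMinFollowup months; event-free follow-up at or beyond this
#'   is indolent. Must exceed \code{aggressiveWindow}.
#' @return \code{data.frame(case_id, label)} with \code{label} a factor with
#'   levels \code{aggressive}, \code{indolent}, \code{excluded}; exactly one
#'   row per record.
#' @examples
#' rec <- data.frame(case_id = c("a", "b", "c", "d"),
#'                   time_months = c(24, 84, 54, 54),
#'                   event = c(TRUE, FALSE, TRUE, FALSE))
#' assignLabels(rec)  # aggressive, indolent, excluded, excluded
#' @export
assignLabels <- function(records, aggressiveWindow = 36,
                         indolentMinFollowup = 72) {
  if (is(records, "StainingExperiment")) records <- clinicalData(records)
  records <- as.data.frame(records)
  need <- c("case_id", "time_months", "event")
  if (!all(need %in% colnames(records)))
    .wdError(paste("records must contain columns:",
                   paste(need, collapse = ", ")), "wd_validation_error")
  if (nrow(records) == 0L)
    .wdError("records must be non-empty", "wd_validation_error")
  if (!(aggressiveWindow < indolentMinFollowup))
    .wdError("'aggressiveWindow' must be smaller than 'indolentMinFollowup'",
             "wd_validation_error")
  t <- as.numeric(records$time_months)
  ev <- as.logical(records$event)
  if (any(is.na(t)) || any(t <= 0))
    .wdError("time_months must be positive and non-missing",
             "wd_validation_error")
  if (any(is.na(ev)))
    .wdError("event must be TRUE/FALSE and non-missing",
             "wd_validation_error")
  label <- ifelse(ev & t <= aggressiveWindow, "aggressive",
                  ifelse(!ev & t >= indolentMinFollowup, "indolent",
                         "excluded"))
  data.frame(case_id = as.character(records$case_id),
             label = factor(label,
                            levels = c("aggressive", "indolent", "excluded")),
             stringsAsFactors = FALSE)
}

# Align a labels data.frame to the cases of a StainingExperiment, returning
# the factor (including excluded) in column order.
alignLabels <- function(x, labels) {
  if (is.data.frame(labels)) {
    idx <- match(colnames(x), labels$case_id)
    if (any(is.na(idx)))
      .wdError("labels are missing for some cases", "wd_validation_error")
    lab <- labels$label[idx]
  } else {
    if (length(labels) != ncol(x))
      .wdError("labels must cover every case", "wd_validation_error")
    lab <- labels
  }
  factor(as.character(lab), levels = c("aggressive", "indolent", "excluded"))
}
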