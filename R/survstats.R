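#' Median split into high/low expression groups
#'
#' Cases above the median expression form group H, cases below it group L.
#' Cases exactly at the median join L (H is defined by strictly exceeding
#' the median), a convention stated explicitly for determinism. With all
#' values distinct the group sizes differ by at most one.
#'
#' @param values named numeric expression values (names = case ids).
#' @return list with \code{split_value} (the median) and \code{groups}, a
#'   \code{data.frame(case_id, group)} with group levels L and H.
#' @section Errors: fewer than 2 distinct values raises a degenerate error.
#' @examples
#' medianSplit(c(a = 1, b = 2, c = 3, d = 4))  # L L H H, median 2.5
#' @export
medianSplit <- function(values) {
  v <- as.numeric(values)
  ids <- if (!is.null(names(values))) names(values)
         else as.character(seq_along(values))
  ok <- !is.na(v)
  if (length(unique(v[ok])) < 2L)
    .wdError("fewer than 2 distinct expression values; cannot split",
             "wd_degenerate_split")
  med <- stats::median(v[ok])
  grp <- ifelse(v > med, "H", "L")
  list(split_value = med,
       groups = data.frame(case_id = ids,
                           group = factor(grp, levels = c("L", "H")),
                           stringsAsFactors = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps \code{survival::survfit} and returns the per-group product-limit
#' curves in tidy form. With no censoring the estimate coincides exactly
#' with the empirical survival function.
#'
#' @param times positive event/censoring times (months).
#' @param events logical or 0/1; \code{TRUE} when the event (BCR) was
#'   observed.
#' @param groups optional group assignment (e.g. H/L from
#'   \code{\link{medianSplit}}); a single curve is returned when omitted.
#' @return data.frame with \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))  # survival 2/3, 1/3, 0
#' @export
kmEstimate <- function(times, events, groups = NULL) {
  t <- as.numeric(times); ev <- as.integer(as.logical(events))
  if (any(is.na(t)) || any(t <= 0))
    .wdError("times must be positive and non-missing", "wd_validation_error")
  if (is.null(groups)) groups <- rep("all", length(t))
  g <- as.character(groups)
  if (any(table(factor(g)) == 0L) || length(g) != length(t))
    .wdError("every group must be non-empty and aligned with times",
             "wd_validation_error")
  fit <- survival::survfit(survival::Surv(t, ev) ~ g1, data =
                             data.frame(t = t, ev = ev, g1 = g))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(g), length(sm$time))
         else sub("^g1=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor,
             survival = sm$surv, stringsAsFactors = FALSE)
}

#' Cox partial log-likelihood with Efron tie handling
#'
#' The explicit partial log-likelihood maximized by a Cox proportional-
#' hazards fit, written out directly: for each distinct event time with
#' \eqn{d} tied events, the Efron correction subtracts the tied events'
#' average risk in \eqn{d} graded steps from the risk-set total. Exposed so
#' that fitted coefficients can be validated against direct numerical
#' maximization of the same objective on small instances.
#'
#' @param beta coefficient vector.
#' @param x covariate matrix (cases by covariates) or vector.
#' @param times,events as in \code{\link{kmEstimate}}.
#' @return the partial log-likelihood value at \code{beta}.
#' @export
coxPartialLogLik <- function(beta, x, times, events) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  t <- as.numeric(times); ev <- as.logical(events)
  ll <- 0
  for (td in sort(unique(t[ev]))) {
    D <- which(ev & t == td)
    R <- which(t >= td)
    d <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D]) -
      sum(log(sumR - (seq_len(d) - 1) / d * sumD))
  }
  ll
}

#' Cox proportional-hazards comparison of prognostic factors
#'
#' Fits Cox models for time to BCR via \code{survival::coxph} with the
#' Efron approximation for tied event times, and reports one row per factor
#' in the conventional comparison-table shape: coefficient, its standard
#' error, Z = coef/SE, and the two-sided normal p-value. With
#' \code{type = "univariate"} each factor is fit alone; with
#' \code{"multivariate"} all factors enter one joint model. Fits that fail
#' to converge or show a monotone likelihood (numerically infinite
#' coefficients, as under perfect separation) are flagged in the
#' \code{flagged} column and a warning is raised — never silently reported.
#'
#' @param design data.frame of per-case factor values (numeric or
#'   2-level factors).
#' @param times,events as in \code{\link{kmEstimate}}.
#' @param type \code{"univariate"} or \code{"multivariate"}.
#' @return data.frame: \code{factor}, \code{coef}, \code{se}, \code{z},
#'   \code{p}, \code{fit_type}, \code{flagged}.
#' @examples
#' d <- data.frame(grp = rep(0:1, each = 10))
#' tm <- c(rexp(10, 1), rexp(10, 3)); ev <- rep(1, 20)
#' coxFit(d, tm, ev)
#' @export
coxFit <- function(design, times, events,
                   type = c("univariate", "multivariate")) {
  type <- match.arg(type)
  design <- as.data.frame(design)
  t <- as.numeric(times); ev <- as.integer(as.logical(events))
  if (sum(ev) < 1L)
    .wdError("at least one event is required", "wd_validation_error")
  isConst <- vapply(design, function(v) length(unique(v[!is.na(v)])) < 2L,
                    logical(1))
  if (any(isConst))
    .wdError(paste("constant factor(s):",
                   paste(colnames(design)[isConst], collapse = ", ")),
             "wd_validation_error")
  oneFit <- function(df) {
    dat <- cbind(df, .t = t, .ev = ev)
    fml <- stats::as.formula(paste("survival::Surv(.t, .ev) ~",
                                   paste(colnames(df), collapse = " + ")))
    warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = "efron"),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    bad <- warned | !is.finite(cf[, "coef"]) | abs(cf[, "coef"]) > 15 |
      !is.finite(cf[, "se(coef)"])
    if (any(bad))
      warning(sprintf("flagged Cox fit (non-convergence or monotone likelihood): %s",
                      paste(rownames(cf)[bad], collapse = ", ")))
    data.frame(factor = rownames(cf), coef = cf[, "coef"],
               se = cf[, "se(coef)"], z = cf[, "z"],
               p = cf[, "Pr(>|z|)"], fit_type = type, flagged = bad,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (type == "multivariate") return(oneFit(design))
  do.call(rbind, lapply(colnames(design), function(nm)
    oneFit(design[, nm, drop = FALSE])))
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson correlations over pairwise-complete observations, as used to
#' screen markers against clinical variables before any dichotomization. A
#' pair with fewer than 3 complete observations, or involving a
#' zero-variance column, is reported as \code{NA} and flagged rather than
#' invented.
#'
#' @param variables data.frame or matrix of per-case numeric columns.
#' @return symmetric correlation matrix with unit diagonal; flagged
#'   undefined entries are listed (as "row:col") in the \code{"undefined"}
#'   attribute.
#' @examples
#' correlationMatrix(data.frame(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4)))
#' @export
correlationMatrix <- function(variables) {
  m <- as.matrix(as.data.frame(variables))
  storage.mode(m) <- "double"
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = "pearson"))
  nObs <- crossprod(!is.na(m))
  r[nObs < 3L] <- NA_real_
  diag(r) <- ifelse(diag(nObs) >= 1L, 1, NA_real_)
  und <- which(is.na(r), arr.ind = TRUE)
  attr(r, "undefined") <- if (nrow(und))
    paste(rownames(r)[und[, 1]], colnames(r)[und[, 2]], sep = ":")
    else character(0)
  r
}

#' Median-split survival comparison for every marker
#'
#' For each marker: splits the cases into H/L at the median expression,
#' fits a Cox model with the H-group indicator (the p-value reported for
#' group separation), computes the log-rank test as a secondary output, and
#' returns the per-group Kaplan-Meier curves.
#'
#' @param x a \linkS4class{StainingExperiment} with clinical columns
#'   \code{time_months} and \code{event}.
#' @param markers markers to analyze (default: all rows).
#' @return list with \code{summary} (data.frame: marker, split_value, n_H,
#'   n_L, coef, se, z, p_cox, p_logrank, flagged) and \code{curves} (named
#'   list of KM data.frames).
#' @export
markerSurvival <- function(x, markers = NULL) {
  stopifnot(is(x, "StainingExperiment"))
  cl <- clinicalData(x)
  if (!all(c("time_months", "event") %in% colnames(cl)))
    .wdError("clinical columns time_months and event are required",
             "wd_validation_error")
  if (is.null(markers)) markers <- rownames(x)
  curves <- list()
  rows <- lapply(markers, function(mk) {
    v <- stats::setNames(intensities(x)[mk, ], colnames(x))
    ok <- !is.na(v)
    sp <- medianSplit(v[ok])
    g <- sp$groups$group
    t <- cl$time_months[ok]; ev <- cl$event[ok]
    cx <- coxFit(data.frame(H = as.integer(g == "H")), t, ev)
    lr <- survival::survdiff(survival::Surv(t, as.integer(ev)) ~ g)
    curves[[mk]] <<- kmEstimate(t, ev, groups = as.character(g))
    data.frame(marker = mk, split_value = sp$split_value,
               n_H = sum(g == "H"), n_L = sum(g == "L"),
               coef = cx$coef, se = cx$se, z = cx$z, p_cox = cx$p,
               p_logrank = stats::pchisq(lr$chisq, df = 1,
                                         lower.tail = FALSE),
               flagged = cx$flagged, stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), curves = curves)
}
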