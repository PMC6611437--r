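#' Closed-form best dichotomization accuracy of a two-normal marker
#'
#' The synthetic generator draws a marker's expression from two equal-variance
#' normal class-conditional distributions whose means sit symmetrically about
#' the planted cutoff, \code{separation} noise-SD units apart. For that model
#' the best achievable accuracy of any single-threshold rule has a closed
#' form: the optimal threshold sits at
#' \eqn{t^* = \log(\pi_0/\pi_1)/d} (in standardized units, with \eqn{d} the
#' separation and \eqn{\pi_1} the aggressive-class prior), and the resulting
#' accuracy is compared against the best constant predictor, whichever is
#' larger.
#'
#' @param separation standardized distance between the class means (in units
#'   of the within-class SD); non-negative.
#' @param priorAggressive prior probability of the aggressive class.
#' @return Best achievable (Bayes) accuracy, in [0.5, 1].
#' @examples
#' bayesAccuracy(2 * qnorm(0.72))        # 0.72 at equal priors
#' bayesAccuracy(0, priorAggressive = 0.3) # no signal: majority rate 0.7
#' @export
bayesAccuracy <- function(separation, priorAggressive = 0.5) {
  stopifnot(separation >= 0, priorAggressive > 0, priorAggressive < 1)
  p1 <- priorAggressive
  p0 <- 1 - p1
  if (separation == 0) return(max(p0, p1))
  t <- log(p0 / p1) / separation   # standardized, means at +/- separation/2
  acc <- p1 * (1 - stats::pnorm(t - separation / 2)) +
    p0 * stats::pnorm(t + separation / 2)
  max(acc, p0, p1)
}

#' Solve for the class separation giving a target best accuracy
#'
#' Inverse of \code{\link{bayesAccuracy}}: finds the standardized separation
#' between the two class-conditional means at which the best achievable
#' single-threshold accuracy equals \code{accuracy}. Used to calibrate
#' synthetic markers so their planted signal strength matches a prescribed
#' training accuracy.
#'
#' @param accuracy target best accuracy; must exceed the majority-class rate
#'   \code{max(priorAggressive, 1 - priorAggressive)} and be below 1.
#' @inheritParams bayesAccuracy
#' @return Standardized separation (noise-SD units).
#' @export
separationForAccuracy <- function(accuracy, priorAggressive = 0.5) {
  floor0 <- max(priorAggressive, 1 - priorAggressive)
  if (accuracy <= floor0 || accuracy >= 1)
    .wdError(sprintf(
      "'accuracy' must lie in (%.4f, 1): the majority-class rate is a floor",
      floor0), "wd_config_error")
  stats::uniroot(function(d) bayesAccuracy(d, priorAggressive) - accuracy,
                 interval = c(1e-8, 30), tol = 1e-10)$root
}

#' Define a panel of synthetic markers
#'
#' @param name marker names.
#' @param direction per-marker \code{"oncogene"} (higher expression in the
#'   aggressive class) or \code{"suppressor"} (higher in the indolent class).
#' @param trueCutoff planted decision boundary, raw intensity units.
#' @param classSeparation standardized distance between class means
#'   (noise-SD units); when \code{noiseSd} is 0 it is read in absolute
#'   intensity units, so a noiseless marker still carries a strictly
#'   separated planted signal.
#' @param noiseSd within-class SD, raw intensity units; non-negative.
#' @return data.frame with one row per marker.
#' @seealso \code{\link{defaultMarkerPanel}}
#' @export
markerPanel <- function(name, direction, trueCutoff, classSeparation,
                        noiseSd) {
  panel <- data.frame(name = as.character(name),
                      direction = as.character(direction),
                      trueCutoff = as.numeric(trueCutoff),
                      classSeparation = as.numeric(classSeparation),
                      noiseSd = as.numeric(noiseSd),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$name))
    .wdError("markers$name: duplicate marker names", "wd_config_error")
  if (!all(panel$direction %in% c("oncogene", "suppressor")))
    .wdError("markers$direction: must be 'oncogene' or 'suppressor'",
             "wd_config_error")
  if (any(panel$noiseSd < 0))
    .wdError("markers$noiseSd: must be >= 0", "wd_config_error")
  if (any(panel$classSeparation < 0))
    .wdError("markers$classSeparation: must be >= 0", "wd_config_error")
  panel
}

#' The default three-marker stromal panel
#'
#' Three markers named after the stromal proteins the method was designed
#' around — FGFR1 (suppressor-like in tumor-adjacent stroma: higher
#' expression goes with indolent disease), MYPT1 and LDHB (oncogene-like).
#' Their class separations are solved so that each marker's best achievable
#' single-threshold accuracy under the cohort's class priors equals the
#' given target (defaults 0.724, 0.676, 0.667). Cutoffs and noise are on a
#' 0-255 Aperio-style average-intensity scale.
#'
#' @param accuracies named numeric, target best accuracy per marker.
#' @param priorAggressive aggressive-class prior used for calibration;
#'   defaults to 36/105.
#' @param noiseSd within-class SD, intensity units.
#' @return A marker panel data.frame (see \code{\link{markerPanel}}).
#' @export
defaultMarkerPanel <- function(accuracies = c(FGFR1 = 0.724, MYPT1 = 0.676,
                                              LDHB = 0.667),
                               priorAggressive = 36 / 105, noiseSd = 20) {
  sep <- vapply(accuracies, separationForAccuracy, numeric(1),
                priorAggressive = priorAggressive)
  markerPanel(name = names(accuracies),
              direction = rep_len(c("suppressor", "oncogene", "oncogene"),
                                  length(accuracies)),
              trueCutoff = rep_len(c(150, 120, 135), length(accuracies)),
              classSeparation = sep, noiseSd = noiseSd)
}

#' Cohort-generator configuration
#'
#' Bundles and validates all knobs of \code{\link{simulateCohort}}. Counts
#' are patients per outcome class; \code{nIntermediate} cases satisfy
#' neither the aggressive nor the indolent redefinition rule and exercise
#' the exclusion path. Times are months throughout.
#'
#' @param nAggressive,nIndolent,nIntermediate class sizes (default 36/69/0,
#'   the redefined cohort composition).
#' @param markers marker panel data.frame (\code{\link{markerPanel}}).
#' @param nBatches number of TMA batches the cases are spread over.
#' @param batchShiftSd SD of the per-(batch, marker) additive intensity
#'   shift.
#' @param batchScaleRange length-2 positive interval for the multiplicative
#'   per-(batch, marker) scale.
#' @param aggressiveMaxMonths aggressive BCR event times are uniform on
#'   (0, this]; default 36 (3 years).
#' @param indolentFollowupMonths length-2 interval for indolent censored
#'   follow-up; default c(72, 120) (6-10 years).
#' @param seed integer seed; identical seeds reproduce the cohort exactly.
#' @return A validated list of class \code{"wd_cohort_config"}.
#' @export
cohortConfig <- function(nAggressive = 36, nIndolent = 69, nIntermediate = 0,
                         markers = defaultMarkerPanel(), nBatches = 4,
                         batchShiftSd = 10, batchScaleRange = c(0.8, 1.25),
                         aggressiveMaxMonths = 36,
                         indolentFollowupMonths = c(72, 120), seed = 1L) {
  cfg <- list(nAggressive = nAggressive, nIndolent = nIndolent,
              nIntermediate = nIntermediate, markers = markers,
              nBatches = nBatches, batchShiftSd = batchShiftSd,
              batchScaleRange = batchScaleRange,
              aggressiveMaxMonths = aggressiveMaxMonths,
              indolentFollowupMonths = indolentFollowupMonths,
              seed = seed)
  class(cfg) <- "wd_cohort_config"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  chkCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      .wdError(sprintf("'%s' must be a single non-negative integer", nm),
               "wd_config_error")
  }
  chkCount(cfg$nAggressive, "nAggressive")
  chkCount(cfg$nIndolent, "nIndolent")
  chkCount(cfg$nIntermediate, "nIntermediate")
  if (!is.data.frame(cfg$markers) || nrow(cfg$markers) < 1L)
    .wdError("'markers' must be a non-empty marker panel", "wd_config_error")
  markerPanel(cfg$markers$name, cfg$markers$direction, cfg$markers$trueCutoff,
              cfg$markers$classSeparation, cfg$markers$noiseSd)
  if (length(cfg$nBatches) != 1L || cfg$nBatches < 1 ||
      cfg$nBatches != round(cfg$nBatches))
    .wdError("'nBatches' must be a positive integer", "wd_config_error")
  if (length(cfg$batchShiftSd) != 1L || cfg$batchShiftSd < 0)
    .wdError("'batchShiftSd' must be >= 0", "wd_config_error")
  if (length(cfg$batchScaleRange) != 2L || any(cfg$batchScaleRange <= 0) ||
      diff(cfg$batchScaleRange) < 0)
    .wdError("'batchScaleRange' must be a positive non-decreasing interval",
             "wd_config_error")
  if (length(cfg$aggressiveMaxMonths) != 1L || cfg$aggressiveMaxMonths <= 0)
    .wdError("'aggressiveMaxMonths' must be > 0", "wd_config_error")
  if (length(cfg$indolentFollowupMonths) != 2L ||
      diff(cfg$indolentFollowupMonths) < 0 ||
      cfg$indolentFollowupMonths[1] <= cfg$aggressiveMaxMonths)
    .wdError(paste0("'indolentFollowupMonths' must be a non-decreasing ",
                    "interval starting after 'aggressiveMaxMonths'"),
             "wd_config_error")
  if (length(cfg$seed) != 1L || is.na(cfg$seed) ||
      cfg$seed != round(cfg$seed))
    .wdError("'seed' must be a single integer", "wd_config_error")
  invisible(cfg)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a TMA cohort with planted marker signal and censored BCR times
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. For each marker, aggressive and indolent cases are drawn from
#' two equal-variance normals whose means sit symmetrically about the
#' planted cutoff (which side is the aggressive one depends on the marker's
#' direction); intermediate cases are drawn from an equal mixture of the
#' two. Each case is assigned to a TMA batch and every (batch, marker)
#' stratum is distorted by a multiplicative scale and additive shift —
#' exactly the transform family the within-TMA median/range normalization
#' removes — then clipped at zero. Time to biochemical recurrence follows
#' the case-redefinition rules: aggressive cases relapse within
#' \code{aggressiveMaxMonths}, indolent cases are censored event-free inside
#' \code{indolentFollowupMonths}, intermediate cases either relapse between
#' the two windows or are censored before the indolent minimum, with equal
#' probability. Clinical covariates (pre-op PSA, Gleason score, margin,
#' stage) are drawn with class-dependent distributions for use by the
#' survival-analysis stage.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A raw-flagged \linkS4class{StainingExperiment} whose
#'   \code{colData} holds batch, clinical columns and the generating
#'   \code{true_label}, and whose metadata carries the planted truth
#'   (retrieve with \code{\link{syntheticTruth}}): per-marker cutoffs,
#'   directions and best achievable accuracies, per-(batch, marker) shift
#'   and scale, and per-case labels.
#' @examples
#' se <- simulateCohort(cohortConfig(nAggressive = 5, nIndolent = 8,
#'                                   seed = 7))
#' table(colData(se)$true_label)
#' @export
simulateCohort <- function(config) {
  validateCohortConfig(config)
  withSeed(config$seed, {
    n <- config$nAggressive + config$nIndolent + config$nIntermediate
    if (n < 1L) .wdError("empty cohort: all counts are zero",
                         "wd_config_error")
    labels <- rep(c("aggressive", "indolent", "intermediate"),
                  c(config$nAggressive, config$nIndolent,
                    config$nIntermediate))
    caseIds <- sprintf("case_%04d", seq_len(n))
    batches <- sprintf("TMA%d", rep_len(seq_len(config$nBatches), n))

    pm <- config$markers
    k <- nrow(pm)
    raw <- matrix(NA_real_, nrow = k, ncol = n,
                  dimnames = list(pm$name, caseIds))
    effects <- expand.grid(batch = sprintf("TMA%d", seq_len(config$nBatches)),
                           marker = pm$name, stringsAsFactors = FALSE)
    effects$shift <- stats::rnorm(nrow(effects), 0, config$batchShiftSd)
    effects$scale <- stats::runif(nrow(effects), config$batchScaleRange[1],
                                  config$batchScaleRange[2])
    for (j in seq_len(k)) {
      # classSeparation is in noise-SD units; in the zero-noise limit it is
      # read in absolute intensity units so a noiseless marker still has a
      # strictly separated, planted signal
      half <- if (pm$noiseSd[j] > 0)
        pm$classSeparation[j] * pm$noiseSd[j] / 2
      else pm$classSeparation[j] / 2
      aggMean <- pm$trueCutoff[j] +
        if (pm$direction[j] == "oncogene") half else -half
      indMean <- pm$trueCutoff[j] +
        if (pm$direction[j] == "oncogene") -half else half
      mu <- ifelse(labels == "aggressive", aggMean,
                   ifelse(labels == "indolent", indMean,
                          ifelse(stats::runif(n) < 0.5, aggMean, indMean)))
      x <- stats::rnorm(n, mean = mu, sd = pm$noiseSd[j])
      eff <- effects[effects$marker == pm$name[j], ]
      sc <- eff$scale[match(batches, eff$batch)]
      sh <- eff$shift[match(batches, eff$batch)]
      raw[j, ] <- pmax(0, sc * x + sh)
    }

    time <- numeric(n)
    event <- logical(n)
    for (i in seq_len(n)) {
      if (labels[i] == "aggressive") {
        event[i] <- TRUE
        time[i] <- stats::runif(1, 0, config$aggressiveMaxMonths)
      } else if (labels[i] == "indolent") {
        event[i] <- FALSE
        time[i] <- stats::runif(1, config$indolentFollowupMonths[1],
                                config$indolentFollowupMonths[2])
      } else {
        # intermediate: equal odds of a late event between the two windows or
        # censoring short of the indolent minimum -- satisfies neither rule
        event[i] <- stats::runif(1) < 0.5
        time[i] <- if (event[i])
          stats::runif(1, config$aggressiveMaxMonths,
                       config$indolentFollowupMonths[1])
        else stats::runif(1, 0, config$indolentFollowupMonths[1])
      }
    }

    isAgg <- labels == "aggressive"
    isInd <- labels == "indolent"
    clinical <- data.frame(
      time_months = time, event = event,
      psa = stats::rlnorm(n, meanlog = log(ifelse(isAgg, 12, 7)),
                          sdlog = 0.6),
      gleason = vapply(seq_len(n), function(i) {
        p <- if (isAgg[i]) c(0.10, 0.30, 0.40, 0.20)
             else if (isInd[i]) c(0.35, 0.40, 0.20, 0.05)
             else c(0.25, 0.35, 0.30, 0.10)
        sample(6:9, 1, prob = p)
      }, integer(1)),
      margin = ifelse(stats::runif(n) <
                        ifelse(isAgg, 0.45, ifelse(isInd, 0.20, 0.30)),
                      "positive", "negative"),
      stage = ifelse(stats::runif(n) <
                       ifelse(isAgg, 0.50, ifelse(isInd, 0.20, 0.35)),
                     "T3", "T2"),
      true_label = labels,
      stringsAsFactors = FALSE)

    se <- StainingExperiment(raw, batch = batches, clinical = clinical,
                             normalized = FALSE)
    prior <- if (config$nAggressive + config$nIndolent > 0)
      config$nAggressive / (config$nAggressive + config$nIndolent) else 0.5
    truth <- list(
      markers = data.frame(
        name = pm$name, direction = pm$direction,
        true_cutoff = pm$trueCutoff, class_separation = pm$classSeparation,
        noise_sd = pm$noiseSd,
        bayes_accuracy = vapply(
          ifelse(pm$noiseSd > 0, pm$classSeparation,
                 ifelse(pm$classSeparation > 0, Inf, 0)),
          bayesAccuracy, numeric(1),
          priorAggressive = max(min(prior, 1 - 1e-9), 1e-9)),
        stringsAsFactors = FALSE),
      batch_effects = effects,
      labels = stats::setNames(labels, caseIds),
      config = config)
    class(truth) <- "SyntheticTruth"
    metadata(se)$truth <- truth
    se
  })
}
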