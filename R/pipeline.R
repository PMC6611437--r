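#' Default end-to-end pipeline configuration
#'
#' Builds the configuration for \code{\link{runPipeline}}: the synthetic
#' cohort to simulate (or existing expression/clinical CSVs to read), marker
#' directions, case-redefinition windows, the number of CV folds and the
#' top-level seed from which every stochastic stage derives its own stream.
#' Times are months throughout.
#'
#' @param outDir output directory (created if needed).
#' @param seed top-level integer seed; the simulate stage uses it directly
#'   and the CV stage uses \code{seed + 1}.
#' @param cohort a \code{\link{cohortConfig}}; its own seed is overridden by
#'   \code{seed}.
#' @param directions named per-marker direction vector, or \code{"auto"}.
#' @param aggressiveWindow,indolentMinFollowup label windows in months.
#' @param kFolds CV folds.
#' @param expressionCsv,clinicalCsv optional paths to existing input tables;
#'   when given, the simulate stage is skipped and these are read instead.
#' @return A list of class \code{"wd_pipeline_config"}.
#' @export
defaultPipelineConfig <- function(outDir, seed = 1L,
                                  cohort = cohortConfig(seed = seed),
                                  directions = c(FGFR1 = "suppressor",
                                                 MYPT1 = "oncogene",
                                                 LDHB = "oncogene"),
                                  aggressiveWindow = 36,
                                  indolentMinFollowup = 72,
                                  kFolds = 10,
                                  expressionCsv = NULL, clinicalCsv = NULL) {
  cohort$seed <- seed
  cfg <- list(out_dir = outDir, seed = as.integer(seed), cohort = cohort,
              directions = directions, aggressive_window = aggressiveWindow,
              indolent_min_followup = indolentMinFollowup,
              k_folds = kFolds, time_unit = "months",
              expression_csv = expressionCsv, clinical_csv = clinicalCsv)
  class(cfg) <- "wd_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a \code{"wd_pipeline_config"} list.
#' @return \code{readPipelineConfig} returns the config list.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  cfg$cohort$markers <- as.list(cfg$cohort$markers)
  if (!identical(cfg$directions, "auto"))
    cfg$directions <- as.list(cfg$directions)   # yaml drops vector names
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cohort$markers <- as.data.frame(cfg$cohort$markers,
                                      stringsAsFactors = FALSE)
  cfg$cohort <- do.call(cohortConfig, cfg$cohort[
    intersect(names(cfg$cohort), names(formals(cohortConfig)))])
  cfg$directions <- unlist(cfg$directions)
  class(cfg) <- "wd_pipeline_config"
  cfg
}

#' Run the whole analysis pipeline
#'
#' Executes simulate (or read) -> normalize -> label -> fit -> training
#' evaluation -> cross-validate -> survival analysis, writing each stage's
#' output as delimited text under \code{config$out_dir} and finishing with
#' a JSON run manifest recording the seed, a hash of the configuration,
#' package and R versions and an MD5 checksum of every output file.
#' Re-running with the same configuration reproduces identical outputs and
#' an identical manifest. Any stage failure aborts with the stage name and
#' cause, after writing a manifest marked incomplete.
#'
#' @param config a \code{"wd_pipeline_config"} (see
#'   \code{\link{defaultPipelineConfig}}) or the path to its YAML form.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "wd_pipeline_config"))
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (p in c(config$expression_csv, config$clinical_csv))
    if (!is.null(p) && !file.exists(p))
      .wdError(sprintf("input path does not exist: %s", p), "wd_path_error")

  outputs <- character(0)
  stagesDone <- character(0)
  manifestPath <- file.path(outDir, "manifest.json")
  failed <- function(stage, e) {
    manifest <- list(status = "incomplete", failed_stage = stage,
                     error = conditionMessage(e),
                     stages_completed = stagesDone)
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("wd_pipeline_error", "wd_error")))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) failed(name, e))
    stagesDone <<- c(stagesDone, name)
    res
  }
  emit <- function(name) outputs <<- c(outputs, file.path(outDir, name))

  se <- stage("simulate", {
    if (!is.null(config$expression_csv)) {
      clin <- readClinicalCsv(config$clinical_csv)
      readExpressionCsv(config$expression_csv, normalized = FALSE,
                        clinical = clin)
    } else simulateCohort(config$cohort)
  })
  writeExpressionCsv(se, file.path(outDir, "expression_raw.csv"))
  emit("expression_raw.csv")
  writeClinicalCsv(se, file.path(outDir, "clinical.csv"))
  emit("clinical.csv")

  nse <- stage("normalize", normalizeBatch(se))
  writeExpressionCsv(nse, file.path(outDir, "expression_normalized.csv"))
  emit("expression_normalized.csv")

  labels <- stage("label", assignLabels(
    clinicalData(se), aggressiveWindow = config$aggressive_window,
    indolentMinFollowup = config$indolent_min_followup))
  writeLabelsCsv(labels, file.path(outDir, "labels.csv"))
  emit("labels.csv")

  clf <- stage("fit", fitWD(nse, labels, directions = config$directions))
  writeWDModel(clf, file.path(outDir, "model.json"))
  emit("model.json")

  trainMetrics <- stage("train_eval", {
    keep <- labels$label != "excluded"
    pr <- predict(clf, nse[, labels$case_id[keep]])
    utils::write.csv(pr, file.path(outDir, "training_predictions.csv"),
                     row.names = FALSE)
    cm <- classificationMetrics(pr$prediction, labels$label[keep])
    auc <- rocAuc(predict(clf, nse[, labels$case_id[keep]], type = "score"),
                  labels$label[keep])$auc
    c(accuracy = unname(cm["accuracy"]), ppv = unname(cm["ppv"]),
      npv = unname(cm["npv"]), auc = auc)
  })
  emit("training_predictions.csv")

  cv <- stage("cv", runCV(nse, labels, directions = config$directions,
                          kFolds = config$k_folds, seed = config$seed + 1L))
  utils::write.csv(cv@predictions, file.path(outDir, "cv_predictions.csv"),
                   row.names = FALSE)
  emit("cv_predictions.csv")
  roc <- rocAuc(cv@predictions$score, cv@predictions$label)
  utils::write.csv(roc$roc, file.path(outDir, "roc_points.csv"),
                   row.names = FALSE)
  emit("roc_points.csv")
  jsonlite::write_json(
    list(training = as.list(trainMetrics), cross_validation =
           as.list(cv@metrics), k_folds = config$k_folds),
    file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  emit("metrics.json")

  surv <- stage("survival", {
    ms <- markerSurvival(nse)
    km <- do.call(rbind, lapply(names(ms$curves), function(mk)
      cbind(marker = mk, ms$curves[[mk]])))
    utils::write.csv(km, file.path(outDir, "km_tables.csv"),
                     row.names = FALSE)
    utils::write.csv(ms$summary, file.path(outDir, "marker_survival.csv"),
                     row.names = FALSE)
    cl <- clinicalData(se)
    design <- data.frame(psa = cl$psa, gleason = cl$gleason,
                         margin = as.integer(cl$margin == "positive"),
                         stage = as.integer(cl$stage == "T3"))
    expr <- t(intensities(nse))
    design <- cbind(as.data.frame(expr), design)
    cox <- rbind(coxFit(design, cl$time_months, cl$event, "univariate"),
                 coxFit(design, cl$time_months, cl$event, "multivariate"))
    utils::write.csv(cox, file.path(outDir, "cox_table.csv"),
                     row.names = FALSE)
    corr <- correlationMatrix(cbind(as.data.frame(expr),
                                    psa = cl$psa, gleason = cl$gleason,
                                    time_months = cl$time_months))
    utils::write.csv(as.data.frame(corr),
                     file.path(outDir, "correlation_matrix.csv"))
    ms$summary
  })
  emit("km_tables.csv"); emit("marker_survival.csv")
  emit("cox_table.csv"); emit("correlation_matrix.csv")

  # hash the configuration without the output location, so runs of the same
  # analysis into different directories share a config identity
  cfgForHash <- config
  cfgForHash$out_dir <- NULL
  cfgFile <- tempfile(fileext = ".yaml")
  writePipelineConfig(cfgForHash, cfgFile)
  manifest <- list(
    status = "complete",
    seed = config$seed,
    stage_seeds = list(simulate = config$seed, cv = config$seed + 1L),
    config_md5 = unname(tools::md5sum(cfgFile)),
    package_version = as.character(utils::packageVersion("stromaWD")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stagesDone,
    checksums = as.list(tools::md5sum(outputs)))
  names(manifest$checksums) <- basename(outputs)
  unlink(cfgFile)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  invisible(manifest)
}
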