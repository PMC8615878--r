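#' @importFrom utils write.csv read.csv packageVersion
NULL

#' Write a FeatureSet as a delimited table with a JSON layout sidecar
#'
#' One row per trial: subject_id, y, then the feature columns named
#' ch<channel>_b<bin>.
#'
#' @param features a [FeatureSet-class]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeFeatureSet <- function(features, path) {
  lay <- featureLayout(features)
  df <- data.frame(subject_id = subjectId(features),
                   y = as.character(featureLabels(features)))
  X <- featureMatrix(features)
  colnames(X) <- sprintf("ch%s_b%02d", lay$channel, lay$bin)
  write.csv(cbind(df, X), path, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(subject_id = subjectId(features), channels = features@channels,
         bin_times = features@binTimes),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FeatureSet written by [writeFeatureSet()]
#'
#' @param path CSV path (JSON sidecar expected alongside)
#' @return a [FeatureSet-class]
#' @export
readFeatureSet <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(X) <- NULL
  new("FeatureSet", subjectId = df$subject_id[1], X = X,
      y = factor(df$y, levels = c("correct", "incorrect")),
      channels = side$channels, binTimes = side$bin_times)
}

#' Write an EpochSet as a delimited array plus JSON sidecar
#'
#' The numeric array is flattened to a (trials*channels) x samples table;
#' the sidecar records ids, sampling rate, channel names, times and the
#' per-trial labels needed to reconstruct the object.
#'
#' @param epochs an [EpochSet-class]
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeEpochSet <- function(epochs, path) {
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(3, 2, 1)), d[3], d[1] * d[2])
  utils::write.table(t(flat), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(subject_id = epochs@subjectId, fs = epochs@fs,
         channel_names = epochs@channelNames, times = epochs@times,
         task_label = epochs@taskLabel, feedback_label = epochs@feedbackLabel,
         correctness = epochs@correctness),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EpochSet written by [writeEpochSet()]
#'
#' @param path TSV path (JSON sidecar expected alongside)
#' @return an [EpochSet-class]
#' @export
readEpochSet <- function(path) {
  side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  flat <- as.matrix(read.csv(path, sep = "\t", header = FALSE))
  nT <- length(side$correctness); nC <- length(side$channel_names)
  nS <- length(side$times)
  data <- aperm(array(t(flat), c(nS, nC, nT)), c(3, 2, 1))
  new("EpochSet", subjectId = side$subject_id, fs = side$fs,
      channelNames = side$channel_names, times = side$times, data = data,
      taskLabel = side$task_label, feedbackLabel = side$feedback_label,
      correctness = side$correctness)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized top-level sections (all optional; missing fields take the
#' package defaults): \code{cohort} (fields of [cohortConfig()] plus
#' \code{shiftSeed} and the ranges of [makeCohortShifts()]), \code{template}
#' (fields of [erpTemplate()] minus the topography), \code{ot} (fields of
#' [otConfig()]), \code{decoding} (\code{classifiers}, \code{labelModes},
#' \code{seed}), and \code{stats} (\code{channel}, \code{alpha}).
#'
#' @param path YAML file path
#' @return nested configuration list
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

cfgGet <- function(cfg, section, field, default) {
  v <- cfg[[section]][[field]]
  if (is.null(v)) default else v
}

#' Run the full simulate -> preprocess -> evaluate -> report pipeline
#'
#' Generates a shifted synthetic cohort, builds features, runs the
#' leave-one-subject-out ablation (OT on/off, requested label modes and
#' classifiers), computes the ERP contrast, and writes all artifacts plus
#' a manifest (configuration echo, package version, seed, and MD5 checksums
#' of every output) into \code{outDir}. Idempotent for a fixed seed.
#'
#' @param config nested list as returned by [readRunConfig()] (possibly
#'   empty for all defaults)
#' @param outDir output directory, created if needed
#' @param seed master seed overriding the configured one (optional)
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  masterSeed <- if (!is.null(seed)) seed else cfgGet(config, "cohort", "seed", 1)

  cc <- cohortConfig(
    nSubjects = cfgGet(config, "cohort", "nSubjects", 8),
    nTrials = cfgGet(config, "cohort", "nTrials", 96),
    errorRate = cfgGet(config, "cohort", "errorRate", 0.2568),
    noiseSd = cfgGet(config, "cohort", "noiseSd", 2.5),
    alphaAmp = cfgGet(config, "cohort", "alphaAmp", 2),
    seed = masterSeed)
  tpl <- erpTemplate(
    negLatency = cfgGet(config, "template", "negLatency", 0.25),
    negAmp = cfgGet(config, "template", "negAmp", -6),
    posLatency = cfgGet(config, "template", "posLatency", 0.40),
    posAmp = cfgGet(config, "template", "posAmp", 4),
    peakWidth = cfgGet(config, "template", "peakWidth", 0.04))
  shifts <- makeCohortShifts(
    cc@nSubjects,
    gainRange = unlist(cfgGet(config, "cohort", "gainRange", c(0.5, 2.5))),
    jitterRange = unlist(cfgGet(config, "cohort", "jitterRange",
                                c(-0.03, 0.03))),
    seed = masterSeed + 101)
  otCfg <- otConfig(
    lambdaEntropy = cfgGet(config, "ot", "lambdaEntropy", 0.05),
    etaGroup = cfgGet(config, "ot", "etaGroup", 10))
  classifiers <- cfgGet(config, "decoding", "classifiers", "random_forest")
  labelModes <- cfgGet(config, "decoding", "labelModes",
                       c("semisupervised_target", "unsupervised_target"))
  statsChannel <- cfgGet(config, "stats", "channel", "Cz")

  message("[simulate] generating ", cc@nSubjects, "-subject cohort")
  cohort <- generateCohort(cc, shifts, tpl)

  message("[preprocess] building feature matrices")
  spec <- designLowpassFir(fs = cc@fs)
  features <- lapply(cohort, buildFeatures, spec = spec)
  paths <- character(0)
  for (id in names(features)) {
    p <- file.path(outDir, sprintf("features_%s.csv", id))
    writeFeatureSet(features[[id]], p)
    paths <- c(paths, p, sub("\\.csv$", ".json", p))
  }

  message("[evaluate] LOSO ablation: ",
          paste(classifiers, collapse = ", "))
  ab <- runAblation(features, classifiers = classifiers,
                    labelModes = labelModes, otCfg = otCfg,
                    seed = masterSeed)
  for (tag in names(ab$reports)) {
    p <- file.path(outDir, sprintf("metrics_%s.csv", tag))
    writeMetricsReport(ab$reports[[tag]], p)
    paths <- c(paths, p, sub("\\.csv$", ".json", p))
  }
  p <- file.path(outDir, "comparisons.csv")
  write.csv(ab$comparisons, p, row.names = FALSE)
  paths <- c(paths, p)

  message("[stats] ERP contrast at ", statsChannel)
  procCohort <- lapply(cohort, function(ep)
    baselineCorrect(surfaceLaplacian(applyLowpass(ep, spec))))
  st <- erpStats(procCohort, statsChannel)
  p <- file.path(outDir, sprintf("erp_stats_%s.csv", statsChannel))
  writeErpStats(st, p)
  paths <- c(paths, p)

  manifest <- list(
    package = "ErrPOT",
    version = as.character(packageVersion("ErrPOT")),
    seed = masterSeed,
    config = list(
      cohort = list(nSubjects = cc@nSubjects, nTrials = cc@nTrials,
                    errorRate = cc@errorRate, feedbackDelay = cc@feedbackDelay,
                    fs = cc@fs, epochSpan = cc@epochSpan,
                    noiseSd = cc@noiseSd, alphaAmp = cc@alphaAmp),
      template = list(negLatency = tpl@negLatency, negAmp = tpl@negAmp,
                      posLatency = tpl@posLatency, posAmp = tpl@posAmp,
                      peakWidth = tpl@peakWidth),
      ot = list(lambdaEntropy = otCfg@lambdaEntropy,
                etaGroup = otCfg@etaGroup,
                maxOuter = otCfg@maxOuter, maxSinkhorn = otCfg@maxSinkhorn,
                marginalTol = otCfg@marginalTol,
                costNormalize = otCfg@costNormalize),
      decoding = list(classifiers = classifiers, labelModes = labelModes),
      stats = list(channel = statsChannel)),
    checksums = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
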