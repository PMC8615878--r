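#' @importFrom stats sd
NULL

setMethod("show", "ErpTemplate", function(object) {
  cat("ErpTemplate: negative lobe", object@negAmp, "uV at",
      object@negLatency, "s; positive lobe", object@posAmp, "uV at",
      object@posLatency, "s (after feedback display); width",
      object@peakWidth, "s;", length(object@topography), "channels\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet '%s': %d trials x %d channels x %d samples @ %g Hz\n",
    object@subjectId, d[1], d[2], d[3], object@fs))
  cat(sprintf("  time span [%.4f, %.4f] s; incorrect trials: %d/%d\n",
              min(object@times), max(object@times),
              sum(object@correctness == "incorrect"), d[1]))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d trials x %d features (%d channels x %d bins)\n",
              object@subjectId, nrow(object@X), ncol(object@X),
              length(object@channels), length(object@binTimes)))
  cat(sprintf("  class balance: %d correct / %d incorrect\n",
              sum(object@y == "correct"), sum(object@y == "incorrect")))
})

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: %d-tap equiripple low-pass, pass %g Hz / stop %g Hz @ %g Hz\n",
    length(object@taps), object@passbandHz, object@stopbandHz, object@fs))
  cat(sprintf("  DC gain %.5f; stopband attenuation %.1f dB\n",
              object@dcGain, object@stopbandAttenuationDb))
})

setMethod("show", "TransportPlan", function(object) {
  cat(sprintf("TransportPlan: %d x %d coupling; marginal error %.2e; %s\n",
              nrow(object@coupling), ncol(object@coupling),
              object@marginalError,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s / %s / %s]\n", object@pipeline,
              object@classifier, object@labelMode))
  df <- object@perSubject
  print(df[, c("subject", "precision", "recall", "f1")], row.names = FALSE)
  cat(sprintf("  Mean %6.2f %6.2f %6.2f\n  SD   %6.2f %6.2f %6.2f\n",
              mean(df$precision), mean(df$recall), mean(df$f1),
              sd(df$precision), sd(df$recall), sd(df$f1)))
})

setMethod("show", "ErpStatsResult", function(object) {
  cat(sprintf(
    "ErpStatsResult @ %s: %d timepoints; %d correct vs %d incorrect trials\n",
    object@channel, length(object@times), object@nCorrect,
    object@nIncorrect))
  cat(sprintf("  %d/%d timepoints with p < %g\n",
              sum(object@pSeries < object@alpha), length(object@pSeries),
              object@alpha))
})

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("correctness", function(x) standardGeneric("correctness"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("featureLayout", function(x) standardGeneric("featureLayout"))
#' @rdname accessors
#' @export
setGeneric("coupling", function(x) standardGeneric("coupling"))
#' @rdname accessors
#' @export
setGeneric("transportedPoints", function(x) standardGeneric("transportedPoints"))
#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
#' @rdname accessors
#' @export
setGeneric("filterTaps", function(x) standardGeneric("filterTaps"))

#' Accessors for ErrPOT objects
#'
#' Small read-only accessors so downstream code never touches slots
#' directly: \code{epochData} (trials x channels x samples array),
#' \code{epochTimes}, \code{channelNames}, \code{correctness},
#' \code{subjectId}, \code{featureMatrix}, \code{featureLabels},
#' \code{featureLayout} (a data.frame mapping each feature column to its
#' channel and time bin), \code{coupling}, \code{transportedPoints},
#' \code{metricsTable} (per-subject metrics with Mean/SD footer rows), and
#' \code{filterTaps}.
#'
#' @param x the object
#' @name accessors
NULL

#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
setMethod("correctness", "EpochSet", function(x) x@correctness)
#' @rdname accessors
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "FeatureSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("featureMatrix", "FeatureSet", function(x) x@X)
#' @rdname accessors
setMethod("featureLabels", "FeatureSet", function(x) x@y)

#' @rdname accessors
setMethod("featureLayout", "FeatureSet", function(x) {
  nb <- length(x@binTimes)
  data.frame(
    column = seq_len(ncol(x@X)),
    channel = rep(x@channels, each = nb),
    bin = rep(seq_len(nb), times = length(x@channels)),
    time = rep(x@binTimes, times = length(x@channels)))
})

#' @rdname accessors
setMethod("coupling", "TransportPlan", function(x) x@coupling)
#' @rdname accessors
setMethod("transportedPoints", "TransportedFeatures", function(x) x@points)
#' @rdname accessors
setMethod("filterTaps", "FilterSpec", function(x) x@taps)

#' @rdname accessors
setMethod("metricsTable", "MetricsReport", function(x) {
  df <- x@perSubject
  num <- vapply(df, is.numeric, logical(1))
  mrow <- df[1, ]; srow <- df[1, ]
  mrow[num] <- lapply(df[num], mean)
  srow[num] <- lapply(df[num], sd)
  mrow$subject <- "Mean"; srow$subject <- "SD"
  rbind(df, mrow, srow)
})
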