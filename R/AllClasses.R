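#' @import methods
NULL

#' The 17-channel 10-20 montage used throughout
#'
#' Ordered electrode labels of the fronto-central/central/centro-parietal/
#' parietal subset assumed by the cohort generator and the surface Laplacian.
#'
#' @format Character vector of length 17.
#' @export
ERRPOT_CHANNELS <- c("Fz", "FC3", "FCz", "FC4", "C5", "C3", "C1", "Cz",
                     "C2", "C4", "C6", "CP3", "CPz", "CP4", "P3", "Pz", "P4")

#' ErpTemplate: biphasic error-related-potential waveform template
#'
#' A sum of two Gaussian lobes: a negative deflection followed by a positive
#' one, both timed relative to the moment the feedback is displayed (or
#' stimulation is felt), and scaled per channel by a scalp topography.
#'
#' @slot negLatency seconds after feedback display onset of the negative lobe
#' @slot negAmp microvolts, \eqn{\le 0}
#' @slot posLatency seconds after feedback display onset of the positive lobe
#' @slot posAmp microvolts, \eqn{\ge 0}
#' @slot peakWidth seconds; standard deviation of each Gaussian lobe
#' @slot topography named numeric vector of per-channel gains
#' @export
setClass("ErpTemplate",
  representation(negLatency = "numeric", negAmp = "numeric",
                 posLatency = "numeric", posAmp = "numeric",
                 peakWidth = "numeric", topography = "numeric"))

setValidity("ErpTemplate", function(object) {
  msg <- character()
  if (object@peakWidth <= 0) msg <- c(msg, "peakWidth must be > 0")
  if (!(object@negLatency > 0 && object@posLatency > object@negLatency))
    msg <- c(msg, "latencies must satisfy 0 < negLatency < posLatency")
  if (object@negAmp > 0) msg <- c(msg, "negAmp must be <= 0")
  if (object@posAmp < 0) msg <- c(msg, "posAmp must be >= 0")
  if (is.null(names(object@topography)))
    msg <- c(msg, "topography must be a named per-channel vector")
  if (length(msg)) msg else TRUE
})

#' SubjectShift: per-subject covariate-shift parameters
#'
#' Parameterizes the distortion separating one subject's recordings from the
#' cohort template: a multiplicative gain, a DC offset, a latency jitter
#' added to the ERP template lobes, and a cross-channel leakage strength.
#' The identity shift is \code{subjectShift(1, 0, 0, 0)}.
#'
#' @slot gain unitless multiplicative factor, > 0
#' @slot dcOffset microvolts added to every sample
#' @slot latencyJitter seconds added to both template latencies
#' @slot mixingStrength in [0, 1]; weight of uniform cross-channel leakage
#' @export
setClass("SubjectShift",
  representation(gain = "numeric", dcOffset = "numeric",
                 latencyJitter = "numeric", mixingStrength = "numeric"))

setValidity("SubjectShift", function(object) {
  msg <- character()
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@mixingStrength < 0 || object@mixingStrength > 1)
    msg <- c(msg, "mixingStrength must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: synthetic cohort generation parameters
#'
#' @slot nSubjects number of subjects
#' @slot nTrials trials per subject
#' @slot errorRate probability that a trial's feedback is incorrect
#' @slot feedbackDelay seconds between feedback-period onset and the actual
#'   display/stimulation of the feedback (the online decoder latency)
#' @slot fs sampling rate, Hz
#' @slot epochSpan seconds relative to feedback-period onset; must cover the
#'   baseline window and [0, 1.5] s
#' @slot noiseSd microvolts; standard deviation of the 1/f background noise
#' @slot alphaAmp microvolts; amplitude of the 8-12 Hz motor-imagery
#'   contaminant
#' @slot footMerge logical; whether left/right foot imagery count as one class
#'   when judging feedback correctness
#' @slot seed master integer seed
#' @export
setClass("CohortConfig",
  representation(nSubjects = "numeric", nTrials = "numeric",
                 errorRate = "numeric", feedbackDelay = "numeric",
                 fs = "numeric", epochSpan = "numeric", noiseSd = "numeric",
                 alphaAmp = "numeric", footMerge = "logical",
                 seed = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must be in [0, 1]")
  if (length(object@epochSpan) != 2 || diff(object@epochSpan) <= 0)
    msg <- c(msg, "epochSpan must be an increasing length-2 interval")
  if (object@epochSpan[1] > -2.3 + 1e-9 || object@epochSpan[2] < 1.5 - 1e-9)
    msg <- c(msg, "epochSpan must cover the baseline window and [0, 1.5] s")
  if (object@fs <= 2 * 12)
    msg <- c(msg, "fs must exceed twice the highest synthesized frequency")
  if (object@nSubjects < 1 || object@nTrials < 1)
    msg <- c(msg, "nSubjects and nTrials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EpochSet: feedback-locked multi-channel EEG trials for one subject
#'
#' @slot subjectId subject identifier
#' @slot fs sampling rate, Hz
#' @slot channelNames ordered electrode labels
#' @slot times seconds relative to feedback-period onset; uniform step 1/fs
#' @slot data numeric array, trials x channels x samples, microvolts
#' @slot taskLabel per-trial imagined movement: left_hand, right_hand, foot
#' @slot feedbackLabel per-trial limb the feedback targeted
#' @slot correctness per-trial "correct" or "incorrect"
#' @export
setClass("EpochSet",
  representation(subjectId = "character", fs = "numeric",
                 channelNames = "character", times = "numeric",
                 data = "array", taskLabel = "character",
                 feedbackLabel = "character", correctness = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    return("data must be a trials x channels x samples array")
  if (d[2] != length(object@channelNames))
    msg <- c(msg, "channel dimension must match channelNames")
  if (d[3] != length(object@times))
    msg <- c(msg, "sample dimension must match times")
  if (length(object@times) > 1) {
    steps <- diff(object@times)
    if (any(steps <= 0) || max(abs(steps - 1 / object@fs)) > 1e-9)
      msg <- c(msg, "times must increase with step exactly 1/fs")
  }
  for (v in c("taskLabel", "feedbackLabel", "correctness"))
    if (length(slot(object, v)) != d[1])
      msg <- c(msg, sprintf("%s must have one entry per trial", v))
  if (!all(object@correctness %in% c("correct", "incorrect")))
    msg <- c(msg, "correctness entries must be 'correct' or 'incorrect'")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: trials x features matrix with correctness labels
#'
#' Rows are trials; columns are (channel, time-bin) pairs laid out
#' channel-major, i.e. column \code{(c-1) * nBins + b} holds channel
#' \code{c}, bin \code{b}. Under the defaults (3 Laplacian channels, 24
#' bins) a 96-trial subject yields a 96 x 72 matrix.
#'
#' @slot subjectId subject identifier
#' @slot X numeric matrix, trials x d
#' @slot y factor with levels correct, incorrect
#' @slot channels ordered channel names contributing features
#' @slot binTimes seconds of each retained time bin (shared by all channels)
#' @export
setClass("FeatureSet",
  representation(subjectId = "character", X = "matrix", y = "factor",
                 channels = "character", binTimes = "numeric"))

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "rows of X must match length of y")
  if (ncol(object@X) != length(object@channels) * length(object@binTimes))
    msg <- c(msg, "ncol(X) must equal channels x bins")
  if (anyNA(object@X)) msg <- c(msg, "X must not contain missing values")
  if (!identical(levels(object@y), c("correct", "incorrect")))
    msg <- c(msg, "y levels must be c('correct', 'incorrect')")
  if (length(msg)) msg else TRUE
})

#' FilterSpec: designed equiripple FIR low-pass filter
#'
#' @slot taps symmetric (linear-phase) coefficient vector
#' @slot passbandHz upper passband edge, Hz
#' @slot stopbandHz lower stopband edge, Hz
#' @slot fs design sampling rate, Hz
#' @slot dcGain numerically evaluated response magnitude at 0 Hz
#' @slot stopbandAttenuationDb achieved minimum attenuation (positive dB)
#'   over frequencies at or above \code{stopbandHz}
#' @export
setClass("FilterSpec",
  representation(taps = "numeric", passbandHz = "numeric",
                 stopbandHz = "numeric", fs = "numeric", dcGain = "numeric",
                 stopbandAttenuationDb = "numeric"))

setValidity("FilterSpec", function(object) {
  msg <- character()
  n <- length(object@taps)
  if (n %% 2 != 1) msg <- c(msg, "tap count must be odd")
  if (max(abs(object@taps - rev(object@taps))) > 1e-12)
    msg <- c(msg, "taps must be symmetric (linear phase)")
  if (length(msg)) msg else TRUE
})

#' EmpiricalMeasure: discrete probability measure on feature points
#'
#' @slot support numeric matrix, N x d point coordinates
#' @slot mass numeric vector of N nonnegative weights summing to one
#' @export
setClass("EmpiricalMeasure",
  representation(support = "matrix", mass = "numeric"))

setValidity("EmpiricalMeasure", function(object) {
  msg <- character()
  if (nrow(object@support) < 1) msg <- c(msg, "need at least one point")
  if (length(object@mass) != nrow(object@support))
    msg <- c(msg, "mass must have one weight per support point")
  if (any(object@mass < 0)) msg <- c(msg, "mass must be nonnegative")
  if (abs(sum(object@mass) - 1) > 1e-12)
    msg <- c(msg, "mass must sum to 1 within 1e-12")
  if (length(msg)) msg else TRUE
})

#' CostMatrix: pairwise squared-Euclidean ground cost
#'
#' @slot values Ns x Nt nonnegative cost entries
#' @slot metric metric tag; "squared_euclidean"
#' @export
setClass("CostMatrix",
  representation(values = "matrix", metric = "character"))

setValidity("CostMatrix", function(object) {
  if (any(object@values < -1e-12)) "cost entries must be nonnegative" else TRUE
})

#' OTConfig: regularized optimal-transport solver settings
#'
#' @slot lambdaEntropy entropic regularization weight (> 0 for Sinkhorn)
#' @slot etaGroup group-sparsity (class) regularization weight, >= 0
#' @slot labelMode "unsupervised_target" or "semisupervised_target"; in the
#'   semisupervised mode the held-out subject's labels shape the coupling
#'   (never the classifier), mirroring the offline analysis setting
#' @slot maxOuter outer majorization-minimization iterations
#' @slot maxSinkhorn Sinkhorn scaling iterations per inner solve
#' @slot marginalTol maximum tolerated relative marginal violation
#' @slot costNormalize divide the cost by its median before solving so that
#'   lambdaEntropy and etaGroup are unitless relative to the cost scale
#' @slot standardize z-score features before computing the cost
#' @export
setClass("OTConfig",
  representation(lambdaEntropy = "numeric", etaGroup = "numeric",
                 labelMode = "character", maxOuter = "numeric",
                 maxSinkhorn = "numeric", marginalTol = "numeric",
                 costNormalize = "logical", standardize = "logical"))

setValidity("OTConfig", function(object) {
  msg <- character()
  if (object@lambdaEntropy < 0) msg <- c(msg, "lambdaEntropy must be >= 0")
  if (object@etaGroup < 0) msg <- c(msg, "etaGroup must be >= 0")
  if (!object@labelMode %in% c("unsupervised_target", "semisupervised_target"))
    msg <- c(msg, "unknown labelMode")
  if (object@marginalTol <= 0) msg <- c(msg, "marginalTol must be positive")
  if (length(msg)) msg else TRUE
})

#' TransportPlan: nonnegative coupling with prescribed marginals
#'
#' @slot coupling Ns x Nt nonnegative matrix
#' @slot sourceMass prescribed row sums
#' @slot targetMass prescribed column sums
#' @slot objective trace of the entropic dual objective per recorded
#'   iteration; Sinkhorn is block-coordinate ascent on the dual, so the
#'   trace is nondecreasing (empty for exact LP solutions)
#' @slot classIndex named list of source row index sets per class (possibly
#'   empty)
#' @slot converged logical
#' @slot marginalError achieved maximum relative marginal violation
#' @export
setClass("TransportPlan",
  representation(coupling = "matrix", sourceMass = "numeric",
                 targetMass = "numeric", objective = "numeric",
                 classIndex = "list", converged = "logical",
                 marginalError = "numeric"))

setValidity("TransportPlan", function(object) {
  msg <- character()
  if (nrow(object@coupling) != length(object@sourceMass))
    msg <- c(msg, "rows must match sourceMass")
  if (ncol(object@coupling) != length(object@targetMass))
    msg <- c(msg, "columns must match targetMass")
  if (any(object@coupling < 0)) msg <- c(msg, "coupling must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' TransportedFeatures: barycentric image of the source points
#'
#' @slot points Ns x d matrix; each source point relocated to the
#'   coupling-weighted average of the target support
#' @slot plan the TransportPlan used
#' @export
setClass("TransportedFeatures",
  representation(points = "matrix", plan = "TransportPlan"))

#' ClassifierSpec: classifier kind, hyperparameters and seed
#'
#' @slot kind one of random_forest, lda, logistic, linear_svm, bagging_lda,
#'   adaboost
#' @slot params named list of hyperparameters for the chosen kind
#' @slot seed integer seed fixed before fitting
#' @export
setClass("ClassifierSpec",
  representation(kind = "character", params = "list", seed = "numeric"))

setValidity("ClassifierSpec", function(object) {
  kinds <- c("random_forest", "lda", "logistic", "linear_svm",
             "bagging_lda", "adaboost")
  if (!object@kind %in% kinds)
    sprintf("kind must be one of: %s", paste(kinds, collapse = ", "))
  else TRUE
})

#' MetricsReport: per-subject and aggregate decoding metrics
#'
#' Precision/recall/F1 are reported in percent with "incorrect" as the
#' positive class; a weighted two-class average is carried alongside.
#'
#' @slot pipeline tag such as "with_ot" or "without_ot"
#' @slot classifier classifier kind
#' @slot labelMode OT label mode used ("none" when OT is off)
#' @slot perSubject data.frame: subject, precision, recall, f1,
#'   precisionW, recallW, f1W, tp, fp, fn, tn
#' @export
setClass("MetricsReport",
  representation(pipeline = "character", classifier = "character",
                 labelMode = "character", perSubject = "data.frame"))

setValidity("MetricsReport", function(object) {
  need <- c("subject", "precision", "recall", "f1")
  if (!all(need %in% names(object@perSubject)))
    "perSubject must contain subject, precision, recall, f1"
  else if (nrow(object@perSubject) &&
           (min(object@perSubject$f1) < 0 || max(object@perSubject$f1) > 100))
    "metrics must lie in [0, 100] percent"
  else TRUE
})

#' ErpStatsResult: condition-wise grand averages and per-timepoint tests
#'
#' @slot channel electrode the series refer to
#' @slot times seconds relative to feedback-period onset
#' @slot avgCorrect grand-average waveform over correct trials, microvolts
#' @slot avgIncorrect grand-average waveform over incorrect trials
#' @slot difference incorrect minus correct
#' @slot pSeries per-timepoint Kruskal-Wallis p-values
#' @slot alpha significance level (0.05)
#' @slot nCorrect,nIncorrect trial counts entering each average
#' @export
setClass("ErpStatsResult",
  representation(channel = "character", times = "numeric",
                 avgCorrect = "numeric", avgIncorrect = "numeric",
                 difference = "numeric", pSeries = "numeric",
                 alpha = "numeric", nCorrect = "numeric",
                 nIncorrect = "numeric"))

setValidity("ErpStatsResult", function(object) {
  n <- length(object@times)
  msg <- character()
  if (!all(vapply(list(object@avgCorrect, object@avgIncorrect,
                       object@difference, object@pSeries),
                  function(x) length(x) == n, logical(1))))
    msg <- c(msg, "all series must share the time axis")
  if (any(object@pSeries <= 0 | object@pSeries > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
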