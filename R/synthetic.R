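#' @importFrom stats rnorm runif fft mvfft
NULL

## Deterministic per-subject seed derived from (master seed, subject id).
## Simple polynomial string hash kept below 2^31 so it is a valid R seed.
subjectSeed <- function(seed, subjectId) {
  s <- as.integer(seed) %% 2147483647
  for (code in utf8ToInt(subjectId))
    s <- (s * 131 + code) %% 2147483647
  as.integer(s)
}

## Uniform time grid anchored so that t = 0 lies exactly on a sample.
## Half-open on the right: samples k/fs for k in [round(a*fs), round(b*fs)).
timeGrid <- function(epochSpan, fs) {
  k <- seq.int(round(epochSpan[1] * fs), round(epochSpan[2] * fs) - 1)
  k / fs
}

#' Default ErrP scalp topography
#'
#' Per-channel gains peaking over the fronto-central midline (FCz, Cz, CPz,
#' nearest the anterior cingulate generator) and decaying laterally, so the
#' deflection survives surface-Laplacian filtering at the midline centers.
#'
#' @return named numeric vector over [ERRPOT_CHANNELS]
#' @export
defaultTopography <- function() {
  c(Fz = 0.50, FC3 = 0.45, FCz = 0.90, FC4 = 0.45, C5 = 0.25, C3 = 0.40,
    C1 = 0.55, Cz = 1.00, C2 = 0.55, C4 = 0.40, C6 = 0.25, CP3 = 0.50,
    CPz = 0.85, CP4 = 0.50, P3 = 0.30, Pz = 0.45, P4 = 0.30)
}

#' Construct a biphasic ErrP waveform template
#'
#' The template is a sum of two Gaussian lobes, a negative deflection
#' followed by a positive rebound, centered at the given latencies after
#' the feedback display and scaled per channel by \code{topography}.
#'
#' @param negLatency seconds after feedback display of the negative lobe
#' @param negAmp microvolts (<= 0)
#' @param posLatency seconds after feedback display of the positive lobe
#' @param posAmp microvolts (>= 0)
#' @param peakWidth Gaussian lobe standard deviation, seconds
#' @param topography named per-channel gains
#' @return an [ErpTemplate-class]
#' @examples
#' tpl <- erpTemplate()
#' w <- evalTemplate(tpl, seq(0, 1, by = 1/256), "Cz")
#' @export
erpTemplate <- function(negLatency = 0.25, negAmp = -6, posLatency = 0.40,
                        posAmp = 4, peakWidth = 0.04,
                        topography = defaultTopography()) {
  if (peakWidth <= 0)
    stop("peakWidth must be positive")
  if (!(negLatency > 0 && posLatency > negLatency))
    stop("latencies must satisfy 0 < negLatency < posLatency")
  new("ErpTemplate", negLatency = negLatency, negAmp = negAmp,
      posLatency = posLatency, posAmp = posAmp, peakWidth = peakWidth,
      topography = topography)
}

#' Evaluate an ErpTemplate on a time grid
#'
#' @param template an [ErpTemplate-class]
#' @param times seconds relative to feedback display onset (i.e. already
#'   shifted by any feedback delay)
#' @param channels channel names to evaluate; must appear in the template
#'   topography
#' @param latencyShift seconds added to both lobe latencies (latency jitter)
#' @return matrix channels x length(times), microvolts
#' @export
evalTemplate <- function(template, times, channels = names(template@topography),
                         latencyShift = 0) {
  miss <- setdiff(channels, names(template@topography))
  if (length(miss))
    stop("channels missing from template topography: ",
         paste(miss, collapse = ", "))
  w <- template@peakWidth
  lobe <- function(lat, amp)
    amp * exp(-((times - lat - latencyShift)^2) / (2 * w^2))
  base <- lobe(template@negLatency, template@negAmp) +
    lobe(template@posLatency, template@posAmp)
  out <- outer(template@topography[channels], base)
  rownames(out) <- channels
  out
}

#' Construct a per-subject covariate shift
#'
#' @param gain multiplicative factor (> 0)
#' @param dcOffset microvolts added to every sample
#' @param latencyJitter seconds added to the ERP template latencies
#' @param mixingStrength in [0,1]; weight of uniform cross-channel leakage
#' @return a [SubjectShift-class]
#' @export
subjectShift <- function(gain = 1, dcOffset = 0, latencyJitter = 0,
                         mixingStrength = 0) {
  if (gain <= 0) stop("gain must be > 0")
  new("SubjectShift", gain = gain, dcOffset = dcOffset,
      latencyJitter = latencyJitter, mixingStrength = mixingStrength)
}

#' Construct a cohort generation configuration
#'
#' Defaults mirror the emulated study: 8 subjects, 96 trials each, 256 Hz,
#' 17-channel 10-20 montage, a 500 ms feedback relay delay, and an
#' incorrect-feedback rate of 25.68% (the complement of the 74.32% online
#' accuracy of the somato-sensory feedback group; use 0.34 for a
#' visual-feedback-like 66% cohort).
#'
#' @param nSubjects number of subjects
#' @param nTrials trials per subject
#' @param errorRate probability a trial's feedback is incorrect
#' @param feedbackDelay seconds from feedback-period onset to display
#' @param fs sampling rate, Hz
#' @param epochSpan seconds relative to feedback-period onset; must cover
#'   the baseline window [-2.3, -2.0] s and the analysis window [0, 1.5] s
#' @param noiseSd microvolts, 1/f background noise standard deviation
#' @param alphaAmp microvolts, amplitude of the 8-12 Hz contaminant
#' @param footMerge treat left/right foot as one imagery class
#' @param seed master integer seed
#' @return a [CohortConfig-class]
#' @export
cohortConfig <- function(nSubjects = 8, nTrials = 96, errorRate = 0.2568,
                         feedbackDelay = 0.5, fs = 256,
                         epochSpan = c(-2.3, 1.5), noiseSd = 2.5,
                         alphaAmp = 2, footMerge = TRUE, seed = 1) {
  new("CohortConfig", nSubjects = nSubjects, nTrials = nTrials,
      errorRate = errorRate, feedbackDelay = feedbackDelay, fs = fs,
      epochSpan = epochSpan, noiseSd = noiseSd, alphaAmp = alphaAmp,
      footMerge = footMerge, seed = seed)
}

## Bernoulli correctness stream: "incorrect" with probability errorRate.
## Factored out so the law-of-large-numbers behaviour of the labels can be
## exercised at large n without materializing epoch arrays.
drawCorrectness <- function(n, errorRate) {
  ifelse(runif(n) < errorRate, "incorrect", "correct")
}

## 1/f (pink) spectral shaping of unit white noise; returns n x m matrix of
## columns with approximately unit variance.
pinkNoiseMatrix <- function(n, m) {
  w <- matrix(rnorm(n * m), n, m)
  freqBins <- floor(n / 2)
  h <- numeric(n)
  idx <- seq_len(freqBins)
  h[1] <- 0                      # no DC power
  h[idx + 1] <- 1 / sqrt(idx)    # 1/f power: amplitude 1/sqrt(f)
  if (n > 1) h[n + 1 - idx] <- pmax(h[n + 1 - idx], h[idx + 1])
  y <- Re(mvfft(mvfft(w) * h, inverse = TRUE)) / n
  y / sqrt(mean(h^2))            # analytic renormalization to unit variance
}

## feedback labels consistent with a drawn correctness, under merged foot
feedbackFor <- function(task, correct) {
  if (correct) {
    switch(task,
           left_hand = "left_hand", right_hand = "right_hand",
           foot = sample(c("left_foot", "right_foot"), 1L))
  } else {
    wrong <- switch(task,
                    left_hand = c("right_hand", "left_foot", "right_foot"),
                    right_hand = c("left_hand", "left_foot", "right_foot"),
                    foot = c("left_hand", "right_hand"))
    sample(wrong, 1L)
  }
}

#' Generate one subject's feedback-locked epochs
#'
#' Each trial is 1/f background noise plus a coherent 8-12 Hz oscillation
#' (the motor-imagery contaminant, random frequency and phase per trial);
#' trials whose feedback is incorrect additionally carry the ErrP template,
#' delayed by the feedback relay and jittered by the subject's latency
#' shift. The whole recording is then passed through the subject's
#' gain/mixing/offset transform. Fully reproducible from
#' \code{(config@seed, subjectId)}.
#'
#' @param config a [CohortConfig-class]
#' @param shift a [SubjectShift-class]
#' @param template an [ErpTemplate-class]
#' @param subjectId subject identifier string
#' @return an [EpochSet-class]
#' @export
generateSubject <- function(config, shift, template, subjectId) {
  validObject(config); validObject(shift); validObject(template)
  channels <- ERRPOT_CHANNELS
  miss <- setdiff(channels, names(template@topography))
  if (length(miss))
    stop("template topography missing channels: ", paste(miss, collapse = ", "))
  set.seed(subjectSeed(config@seed, subjectId))
  n <- config@nTrials
  times <- timeGrid(config@epochSpan, config@fs)
  nS <- length(times); nC <- length(channels)

  correct <- drawCorrectness(n, config@errorRate)
  task <- sample(c("left_hand", "right_hand", "foot"), n, replace = TRUE)
  feedback <- vapply(seq_len(n),
                     function(i) feedbackFor(task[i], correct[i] == "correct"),
                     character(1))

  ## background: pink noise per trial x channel
  noise <- pinkNoiseMatrix(nS, n * nC) * config@noiseSd
  data <- aperm(array(noise, c(nS, nC, n)), c(3, 2, 1))

  ## coherent 8-12 Hz motor-imagery contaminant, one waveform per trial
  freqs <- runif(n, 8, 12)
  phases <- runif(n, 0, 2 * pi)
  alpha <- config@alphaAmp *
    sin(2 * pi * outer(freqs, times) + phases)   # n x nS
  data <- data + aperm(array(alpha, c(n, nS, nC)), c(1, 3, 2))

  ## ErrP deflection on incorrect trials only, locked to feedback display
  errIdx <- which(correct == "incorrect")
  if (length(errIdx)) {
    tpl <- evalTemplate(template, times - config@feedbackDelay, channels,
                        latencyShift = shift@latencyJitter)  # nC x nS
    for (i in errIdx)
      data[i, , ] <- data[i, , ] + tpl
  }

  epochs <- new("EpochSet", subjectId = subjectId, fs = config@fs,
                channelNames = channels, times = times, data = data,
                taskLabel = task, feedbackLabel = feedback,
                correctness = correct)
  applySubjectShift(epochs, shift)
}

#' Apply a covariate shift to an epoch set
#'
#' Computes \code{gain * (M(mixing) \%*\% data) + dcOffset} samplewise,
#' where the mixing operator \code{M(m) = (1-m) I + (m/C) 11'} leaks a
#' fraction \code{m} of the channel-mean into every channel. Labels are
#' untouched; the identity shift returns the input unchanged. (Latency
#' jitter acts at generation time, not here.)
#'
#' @param epochs an [EpochSet-class]
#' @param shift a [SubjectShift-class]
#' @return a shifted [EpochSet-class]
#' @export
applySubjectShift <- function(epochs, shift) {
  validObject(shift)
  m <- shift@mixingStrength
  data <- epochs@data
  if (m > 0) {
    nC <- dim(data)[2]
    chanMean <- apply(data, c(1, 3), mean)        # trials x samples
    data <- (1 - m) * data +
      m * aperm(array(chanMean, c(dim(data)[1], dim(data)[3], nC)),
                c(1, 3, 2))
  }
  if (shift@gain != 1 || shift@dcOffset != 0)
    data <- shift@gain * data + shift@dcOffset
  epochs@data <- data
  epochs
}

#' Deterministic moderate covariate shifts for a cohort
#'
#' Draws per-subject gains log-uniform in \code{gainRange}, DC offsets and
#' latency jitters uniform in their ranges, and mixing strengths uniform in
#' \code{mixingRange}, from a fixed seed. The default ranges emulate
#' plausible inter-subject variability in electrode gain/impedance
#' (amplitude factors 0.5-2.5x), ERP latency (+/- 30 ms) and volume
#' conduction differences.
#'
#' @param n number of subjects
#' @param gainRange multiplicative gain range (log-uniform)
#' @param dcRange DC offset range, microvolts
#' @param jitterRange latency jitter range, seconds
#' @param mixingRange cross-channel leakage range
#' @param seed integer seed
#' @return list of [SubjectShift-class] of length n
#' @export
makeCohortShifts <- function(n, gainRange = c(0.5, 2.5), dcRange = c(-5, 5),
                             jitterRange = c(-0.03, 0.03),
                             mixingRange = c(0, 0.3), seed = 1) {
  set.seed(as.integer(seed) %% 2147483647)
  lapply(seq_len(n), function(i)
    subjectShift(gain = exp(runif(1, log(gainRange[1]), log(gainRange[2]))),
                 dcOffset = runif(1, dcRange[1], dcRange[2]),
                 latencyJitter = runif(1, jitterRange[1], jitterRange[2]),
                 mixingStrength = runif(1, mixingRange[1], mixingRange[2])))
}

#' Identity shifts (no covariate shift) for a cohort
#'
#' @param n number of subjects
#' @return list of identity [SubjectShift-class]
#' @export
identityShifts <- function(n) {
  lapply(seq_len(n), function(i) subjectShift())
}

#' Generate a multi-subject cohort
#'
#' Subjects are generated independently from per-subject seeds derived from
#' the master seed, so the cohort is bit-reproducible and individual
#' subjects can be regenerated in isolation.
#'
#' @param config a [CohortConfig-class]
#' @param shifts list of [SubjectShift-class], one per subject
#' @param template an [ErpTemplate-class]
#' @param idPrefix prefix for subject identifiers (default "S")
#' @return named list of [EpochSet-class]
#' @export
generateCohort <- function(config, shifts = identityShifts(config@nSubjects),
                           template = erpTemplate(), idPrefix = "S") {
  validObject(config)
  if (length(shifts) != config@nSubjects)
    stop("need exactly one SubjectShift per subject")
  ids <- sprintf("%s%02d", idPrefix, seq_len(config@nSubjects))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  cohort <- lapply(seq_along(ids), function(i)
    generateSubject(config, shifts[[i]], template, ids[i]))
  names(cohort) <- ids
  cohort
}
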