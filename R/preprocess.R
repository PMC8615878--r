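#' @importFrom stats mvfft
NULL

#' Design the equiripple FIR low-pass filter
#'
#' Parks-McClellan (Remez exchange) linear-phase design with passband
#' [0, passHz] and stopband [stopHz, fs/2]. The returned spec records the
#' numerically evaluated DC gain and the achieved minimum stopband
#' attenuation; a design that fails to reach \code{minAttenDb} is reported
#' with a warning rather than silently accepted.
#'
#' @param fs sampling rate, Hz
#' @param passHz passband edge (default 6 Hz, below the 8-12 Hz
#'   motor-imagery band)
#' @param stopHz stopband edge (default 8 Hz)
#' @param nTaps odd tap count; the default 385 achieves ~56 dB over the
#'   2 Hz transition at 256 Hz
#' @param minAttenDb attenuation the design is expected to reach
#' @return a [FilterSpec-class]
#' @export
designLowpassFir <- function(fs = 256, passHz = 6, stopHz = 8, nTaps = 385,
                             minAttenDb = 40) {
  if (!(passHz > 0 && passHz < stopHz && stopHz < fs / 2))
    stop("need 0 < passHz < stopHz < fs/2")
  if (nTaps %% 2 != 1) stop("nTaps must be odd")
  nyq <- fs / 2
  taps <- signal::remez(nTaps - 1, c(0, passHz / nyq, stopHz / nyq, 1),
                        c(1, 1, 0, 0))
  resp <- firMagnitude(taps, fs, seq(0, nyq, length.out = 4097))
  dc <- resp[1]
  stopMask <- seq(0, nyq, length.out = 4097) >= stopHz
  atten <- -20 * log10(max(resp[stopMask]))
  if (atten < minAttenDb)
    warning(sprintf(
      "design reaches only %.1f dB stopband attenuation (target %g dB)",
      atten, minAttenDb))
  new("FilterSpec", taps = as.numeric(taps), passbandHz = passHz,
      stopbandHz = stopHz, fs = fs, dcGain = dc,
      stopbandAttenuationDb = atten)
}

#' Evaluate the magnitude response of an FIR filter
#'
#' Direct evaluation of the tap polynomial on the unit circle.
#'
#' @param taps FIR coefficients (or a [FilterSpec-class])
#' @param fs sampling rate, Hz
#' @param freqHz frequencies at which to evaluate, Hz
#' @return numeric vector of response magnitudes
#' @export
firMagnitude <- function(taps, fs, freqHz) {
  if (is(taps, "FilterSpec")) { fs <- taps@fs; taps <- taps@taps }
  k <- seq_along(taps) - 1
  vapply(freqHz, function(f) {
    om <- 2 * pi * f / fs
    Mod(sum(taps * exp(-1i * om * k)))
  }, numeric(1))
}

## Row-wise linear convolution with group-delay compensation.
## x: m x n matrix (rows are signals); returns m x n. Signals are padded by
## edge replication over the filter half-length to suppress edge transients.
convolveRows <- function(x, taps) {
  n <- ncol(x); L <- length(taps); gd <- (L - 1) / 2
  if (n < L)
    stop(sprintf("signal length %d shorter than filter length %d", n, L))
  padded <- cbind(x[, rep(1, gd), drop = FALSE], x,
                  x[, rep(n, gd), drop = FALSE])
  np <- ncol(padded)
  nfft <- 2^ceiling(log2(np + L - 1))
  H <- fft(c(taps, numeric(nfft - L)))
  X <- mvfft(t(cbind(padded, matrix(0, nrow(x), nfft - np))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft    # nfft x m
  ## full convolution index of the sample aligned with input sample i is
  ## i + gd (0-based); with gd leading pad samples, output i = 2*gd + i
  t(y[(2 * gd + 1):(2 * gd + n), , drop = FALSE])
}

#' Low-pass filter all epochs
#'
#' Single-pass FIR convolution with group-delay compensation (the symmetric
#' tap vector delays by (nTaps-1)/2 samples, which is removed) so that
#' event latencies are preserved; epoch edges are padded by edge
#' replication.
#'
#' @param epochs an [EpochSet-class]
#' @param spec a [FilterSpec-class] with matching sampling rate
#' @return filtered [EpochSet-class] of identical shape
#' @export
applyLowpass <- function(epochs, spec) {
  if (spec@fs != epochs@fs)
    stop("filter and epochs sampling rates differ")
  d <- dim(epochs@data)
  flat <- matrix(epochs@data, d[1] * d[2], d[3])  # (trial,channel) x sample
  epochs@data <- array(convolveRows(flat, spec@taps), d)
  epochs
}

#' Default surface-Laplacian montage
#'
#' Center electrodes FCz, Cz, CPz (over the anterior cingulate region) with
#' their nearest recorded 10-20 neighbors. Cz uses C1, FCz, C2, CPz.
#'
#' @return named list mapping each center to its neighbor labels
#' @export
defaultLaplacianMontage <- function() {
  list(FCz = c("Fz", "FC3", "FC4", "Cz"),
       Cz  = c("C1", "FCz", "C2", "CPz"),
       CPz = c("Cz", "CP3", "CP4", "Pz"))
}

#' Surface-Laplacian spatial filter
#'
#' For every montage center, subtracts the samplewise mean of its neighbor
#' electrodes; the output contains only the center channels, in montage
#' order.
#'
#' @param epochs an [EpochSet-class]
#' @param montage named list center -> neighbor labels
#' @return an [EpochSet-class] with one channel per montage center
#' @export
surfaceLaplacian <- function(epochs, montage = defaultLaplacianMontage()) {
  centers <- names(montage)
  have <- epochs@channelNames
  for (ctr in centers) {
    miss <- setdiff(c(ctr, montage[[ctr]]), have)
    if (length(miss))
      stop("montage channels absent from epochs: ", paste(miss, collapse = ", "))
  }
  d <- dim(epochs@data)
  out <- array(0, c(d[1], length(centers), d[3]))
  for (j in seq_along(centers)) {
    ctr <- centers[j]
    nb <- match(montage[[ctr]], have)
    neighborMean <- apply(epochs@data[, nb, , drop = FALSE], c(1, 3), mean)
    out[, j, ] <- epochs@data[, match(ctr, have), ] - neighborMean
  }
  epochs@data <- out
  epochs@channelNames <- centers
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from the whole epoch. The default window [-2.3, -2.0] s is the
#' 300 ms preceding the motor-imagery instruction, chosen to avoid both
#' imagery-related and feedback-related activity.
#'
#' @param epochs an [EpochSet-class]
#' @param baselineWindow length-2 seconds interval (closed)
#' @return baseline-corrected [EpochSet-class]
#' @export
baselineCorrect <- function(epochs, baselineWindow = c(-2.3, -2.0)) {
  sel <- which(epochs@times >= baselineWindow[1] - 1e-9 &
               epochs@times <= baselineWindow[2] + 1e-9)
  if (!length(sel))
    stop("baseline window contains no samples")
  base <- apply(epochs@data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs@data <- epochs@data - as.vector(base)   # recycles over samples
  epochs
}

#' Extract a time window from epochs
#'
#' Half-open window [from, to): at 256 Hz, [0, 1.5) keeps exactly 384
#' samples.
#'
#' @param epochs an [EpochSet-class]
#' @param window length-2 seconds interval, half-open on the right
#' @return windowed [EpochSet-class]
#' @export
windowEpochs <- function(epochs, window = c(0, 1.5)) {
  sel <- which(epochs@times >= window[1] - 1e-9 &
               epochs@times < window[2] - 1e-9)
  if (!length(sel)) stop("window contains no samples")
  epochs@data <- epochs@data[, , sel, drop = FALSE]
  epochs@times <- epochs@times[sel]
  epochs
}

#' Decimate epochs by an integer factor
#'
#' Keeps samples at indices 0, factor, 2*factor, ... (0-based); anti-alias
#' protection is assumed to come from the preceding 0-6 Hz low-pass. A
#' 384-sample window decimated by 16 yields 24 samples per channel.
#'
#' @param epochs an [EpochSet-class]
#' @param factor integer >= 1
#' @return decimated [EpochSet-class] with fs divided by factor
#' @export
decimateEpochs <- function(epochs, factor = 16) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  nS <- dim(epochs@data)[3]
  if (factor > nS) stop("factor exceeds the number of samples")
  keep <- seq(1, nS, by = factor)
  epochs@data <- epochs@data[, , keep, drop = FALSE]
  epochs@times <- epochs@times[keep]
  epochs@fs <- epochs@fs / factor
  epochs
}

#' Relabel trials to correct/incorrect feedback
#'
#' A trial is correct when the feedback targeted the imagined limb. Under
#' the merged-foot rule (the default), foot-imagery trials are correct when
#' the feedback went to either foot.
#'
#' @param taskLabel character vector in left_hand, right_hand, foot (or
#'   left_foot/right_foot when \code{footMerge = FALSE})
#' @param feedbackLabel character vector in left_hand, right_hand,
#'   left_foot, right_foot
#' @param footMerge logical; merge left/right foot imagery into one class
#' @return character vector in correct, incorrect
#' @export
relabelFeedback <- function(taskLabel, feedbackLabel, footMerge = TRUE) {
  taskVocab <- if (footMerge) c("left_hand", "right_hand", "foot")
               else c("left_hand", "right_hand", "left_foot", "right_foot")
  fbVocab <- c("left_hand", "right_hand", "left_foot", "right_foot")
  if (!all(taskLabel %in% taskVocab))
    stop("unknown task label: ", paste(setdiff(taskLabel, taskVocab), collapse = ", "))
  if (!all(feedbackLabel %in% fbVocab))
    stop("unknown feedback label: ",
         paste(setdiff(feedbackLabel, fbVocab), collapse = ", "))
  ok <- if (footMerge) {
    ifelse(taskLabel == "foot",
           feedbackLabel %in% c("left_foot", "right_foot"),
           feedbackLabel == taskLabel)
  } else feedbackLabel == taskLabel
  ifelse(ok, "correct", "incorrect")
}

#' Build the low-frequency feature matrix for one subject
#'
#' Runs the full chain: FIR low-pass, surface Laplacian (restricting to the
#' montage centers), baseline correction over the pre-imagery window,
#' extraction of the half-open [0, 1.5) s analysis window, decimation, and
#' channel-major flattening into one row per trial. Filtering precedes
#' window extraction so filter edge transients stay outside the analysis
#' window, and the baseline segment (which lies before the window) is still
#' available when its mean is taken.
#'
#' @param epochs an [EpochSet-class] covering the baseline and analysis
#'   windows
#' @param spec a [FilterSpec-class]
#' @param montage surface-Laplacian montage
#' @param window analysis window, half-open seconds
#' @param baselineWindow baseline window, closed seconds
#' @param factor decimation factor
#' @return a [FeatureSet-class] (96 trials x 72 features under defaults)
#' @export
buildFeatures <- function(epochs, spec = designLowpassFir(fs = epochs@fs),
                          montage = defaultLaplacianMontage(),
                          window = c(0, 1.5), baselineWindow = c(-2.3, -2.0),
                          factor = 16) {
  proc <- applyLowpass(epochs, spec)
  proc <- surfaceLaplacian(proc, montage)
  proc <- baselineCorrect(proc, baselineWindow)
  proc <- windowEpochs(proc, window)
  proc <- decimateEpochs(proc, factor)
  d <- dim(proc@data)
  ## channel-major layout: column (c-1)*nBins + b
  X <- matrix(aperm(proc@data, c(1, 3, 2)), d[1], d[2] * d[3])
  y <- factor(relabelFeedback(epochs@taskLabel, epochs@feedbackLabel),
              levels = c("correct", "incorrect"))
  new("FeatureSet", subjectId = epochs@subjectId, X = X, y = y,
      channels = proc@channelNames, binTimes = proc@times)
}

#' Reshape a FeatureSet back into per-channel time courses
#'
#' Inverse of the flattening in [buildFeatures()]: returns the trials x
#' channels x bins array.
#'
#' @param features a [FeatureSet-class]
#' @return numeric array trials x channels x bins
#' @export
unflattenFeatures <- function(features) {
  nb <- length(features@binTimes); nc <- length(features@channels)
  aperm(array(features@X, c(nrow(features@X), nb, nc)), c(1, 3, 2))
}
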