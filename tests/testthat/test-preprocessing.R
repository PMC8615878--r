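test_that("designed low-pass meets its DC and stopband contract", {
  spec <- fixFilter()
  expect_lt(abs(spec@dcGain - 1), 0.01)
  expect_gte(spec@stopbandAttenuationDb, 40)
  # linear phase: symmetric taps
  expect_equal(filterTaps(spec), rev(filterTaps(spec)))
  # numerically re-evaluate the response on a fresh grid
  f <- seq(8, 128, by = 0.5)
  expect_lt(max(firMagnitude(spec, freqHz = f)),
            10^(-spec@stopbandAttenuationDb / 20) + 1e-9)
  expect_error(designLowpassFir(passHz = 10, stopHz = 8), "passHz")
})

test_that("filtering preserves the passband and rejects the stopband", {
  spec <- fixFilter()
  t <- (0:972) / 256 - 2.3
  mk <- function(x) {
    data <- array(rep(x, each = 1), c(1, 1, length(x)))
    new("EpochSet", subjectId = "x", fs = 256, channelNames = "Cz",
        times = (seq_along(x) - 1) / 256, data = data,
        taskLabel = "foot", feedbackLabel = "left_foot",
        correctness = "correct")
  }
  # zero in, zero out
  expect_equal(max(abs(epochData(applyLowpass(mk(numeric(973)), spec)))), 0)
  # constant input passes at DC gain
  const <- epochData(applyLowpass(mk(rep(2, 973)), spec))
  expect_lt(max(abs(const - 2 * spec@dcGain)), 1e-6)
  # 2 Hz tone: amplitude preserved within ripple (interior samples)
  tone2 <- sin(2 * pi * 2 * t)
  y2 <- epochData(applyLowpass(mk(tone2), spec))[1, 1, ]
  interior <- 200:773
  gain2 <- firMagnitude(spec, freqHz = 2)
  expect_lt(max(abs(y2[interior] - gain2 * tone2[interior])), 0.02)
  # 10 Hz tone: attenuated by at least the achieved stopband attenuation
  tone10 <- sin(2 * pi * 10 * t)
  y10 <- epochData(applyLowpass(mk(tone10), spec))[1, 1, ]
  rmsIn <- sqrt(mean(tone10[interior]^2))
  rmsOut <- sqrt(mean(y10[interior]^2))
  expect_lt(rmsOut / rmsIn, 10^(-spec@stopbandAttenuationDb / 20) * 1.5)
  # epochs shorter than the filter are refused with the minimum length named
  expect_error(applyLowpass(mk(numeric(100)), spec), "filter length")
})

test_that("group delay is compensated: a slow pulse stays put", {
  spec <- fixFilter()
  t <- (0:972) / 256 - 2.3
  pulse <- exp(-((t - 0.4)^2) / (2 * 0.05^2))
  data <- array(pulse, c(1, 1, 973))
  ep <- new("EpochSet", subjectId = "x", fs = 256, channelNames = "Cz",
            times = t, data = data, taskLabel = "foot",
            feedbackLabel = "left_foot", correctness = "correct")
  y <- epochData(applyLowpass(ep, spec))[1, 1, ]
  expect_equal(which.max(y), which.max(pulse))
})

test_that("surface Laplacian subtracts the neighbor mean at each sample", {
  nC <- length(ERRPOT_CHANNELS)
  data <- array(0, c(1, nC, 2))
  idx <- function(ch) match(ch, ERRPOT_CHANNELS)
  data[1, idx("Cz"), ] <- 5
  data[1, idx("C1"), ] <- 1
  data[1, idx("FCz"), ] <- 3
  data[1, idx("C2"), ] <- 5
  data[1, idx("CPz"), ] <- 7
  ep <- new("EpochSet", subjectId = "x", fs = 256,
            channelNames = ERRPOT_CHANNELS, times = (0:1) / 256, data = data,
            taskLabel = "foot", feedbackLabel = "left_foot",
            correctness = "correct")
  lap <- surfaceLaplacian(ep)
  expect_identical(channelNames(lap), c("FCz", "Cz", "CPz"))
  expect_equal(epochData(lap)[1, 2, 1], 5 - mean(c(1, 3, 5, 7)))
  # common-mode rejection: identical signal everywhere -> all zero
  ep@data[] <- 3.3
  expect_equal(max(abs(epochData(surfaceLaplacian(ep)))), 0)
  # a missing neighbor is named
  ep2 <- ep; ep2@channelNames[idx("Pz")] <- "Oz"
  expect_error(surfaceLaplacian(ep2), "Pz")
})

test_that("baseline correction removes the baseline-window mean", {
  ep <- fixSmallCohort()[[1]]
  bc <- baselineCorrect(ep)
  sel <- epochTimes(bc) >= -2.3 & epochTimes(bc) <= -2.0
  resid <- apply(epochData(bc)[, , sel], c(1, 2), mean)
  expect_lt(max(abs(resid)), 1e-12)
  # constant trace maps to zero
  epc <- ep; epc@data[] <- 7
  expect_equal(max(abs(epochData(baselineCorrect(epc)))), 0)
  # already zero-mean in the window: unchanged
  expect_equal(epochData(baselineCorrect(bc)), epochData(bc))
  expect_error(baselineCorrect(ep, c(-9, -8.9)), "no samples")
})

test_that("windowing and decimation produce the printed lengths", {
  ep <- fixSmallCohort()[[1]]
  w <- windowEpochs(ep, c(0, 1.5))
  expect_equal(dim(epochData(w))[3], 384)
  d <- decimateEpochs(w, 16)
  expect_equal(dim(epochData(d))[3], 24)
  expect_equal(d@fs, 16)
  # ramp check: plain take-every-16th from index 0
  ramp <- w
  ramp@data <- array(rep(0:383, each = prod(dim(epochData(w))[1:2])),
                     dim(epochData(w)))
  expect_equal(epochData(decimateEpochs(ramp, 16))[1, 1, ],
               seq(0, 368, by = 16))
  expect_identical(epochData(decimateEpochs(w, 1)), epochData(w))
  expect_error(decimateEpochs(d, 100), "factor")
})

test_that("feedback relabeling follows the merged-foot correctness rule", {
  expect_equal(relabelFeedback("left_hand", "left_hand"), "correct")
  expect_equal(relabelFeedback("left_hand", "right_foot"), "incorrect")
  expect_equal(relabelFeedback("foot", "left_foot"), "correct")
  expect_equal(relabelFeedback("foot", "right_foot"), "correct")
  expect_equal(relabelFeedback("foot", "right_hand"), "incorrect")
  expect_equal(relabelFeedback(c("foot", "right_hand"),
                               c("left_hand", "right_hand")),
               c("incorrect", "correct"))
  # unmerged rule: foot sides must match exactly
  expect_equal(relabelFeedback("left_foot", "right_foot", footMerge = FALSE),
               "incorrect")
  expect_error(relabelFeedback("elbow", "left_hand"), "unknown task")
  expect_error(relabelFeedback("foot", "head"), "unknown feedback")
})

test_that("feature building yields trials x 72 with an invertible layout", {
  feats <- fixSmallFeatures()[[1]]
  expect_equal(dim(featureMatrix(feats)), c(24, 72))
  expect_identical(feats@channels, c("FCz", "Cz", "CPz"))
  lay <- featureLayout(feats)
  expect_equal(nrow(lay), 72)
  expect_equal(lay$channel[1:24], rep("FCz", 24))
  # un-flattening reproduces the decimated per-channel traces exactly
  arr <- unflattenFeatures(feats)
  expect_equal(arr[, 2, ], featureMatrix(feats)[, 24 + 1:24])
  # pipeline determinism
  again <- buildFeatures(fixSmallCohort()[[1]], fixFilter())
  expect_identical(featureMatrix(again), featureMatrix(feats))
  # single-trial input
  ep1 <- fixSmallCohort()[[1]]
  ep1@data <- ep1@data[1, , , drop = FALSE]
  for (s in c("taskLabel", "feedbackLabel", "correctness"))
    slot(ep1, s) <- slot(ep1, s)[1]
  expect_equal(dim(featureMatrix(buildFeatures(ep1, fixFilter()))), c(1, 72))
})

test_that("the 8-12 Hz contaminant is suppressed by the designed attenuation", {
  spec <- fixFilter()
  cc <- cohortConfig(nSubjects = 1, nTrials = 6, noiseSd = 1e-9,
                     alphaAmp = 2, errorRate = 0, seed = 8)
  ep <- generateSubject(cc, subjectShift(), erpTemplate(), "A")
  filt <- applyLowpass(ep, spec)
  interior <- 200:773
  pin <- mean(epochData(ep)[, , interior]^2)
  pout <- mean(epochData(filt)[, , interior]^2)
  # power drop at least the design attenuation (in power terms)
  expect_lt(pout / pin, 10^(-spec@stopbandAttenuationDb / 10) * 10)
  expect_gt(10 * log10(pin / pout), 40)
})
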