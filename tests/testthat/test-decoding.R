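test_that("metric arithmetic matches confusion counts and the F1 formula", {
  # perfect predictions
  m <- suppressWarnings(
    computeMetrics(rep(c("correct", "incorrect"), 5),
                   rep(c("correct", "incorrect"), 5)))
  expect_equal(c(m$precision, m$recall, m$f1), c(100, 100, 100))
  # TP=3, FP=1, FN=1 -> 75/75/75
  yt <- c(rep("incorrect", 4), "correct")
  yp <- c("incorrect", "incorrect", "incorrect", "correct", "incorrect")
  m2 <- suppressWarnings(computeMetrics(yt, yp))
  expect_equal(c(m2$precision, m2$recall, m2$f1), c(75, 75, 75))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(3, 1, 1))
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(m2$f1, 2 * m2$precision * m2$recall / (m2$precision + m2$recall))
  # degenerate denominator reports 0 with a warning
  w <- capture_warnings(z <- computeMetrics(c("correct", "correct"),
                                            c("correct", "correct")))
  expect_true(any(grepl("denominator", w)))
  expect_equal(z$precision, 0)
  expect_error(computeMetrics("correct", c("correct", "correct")), "length")
})

test_that("classifiers are deterministic under a fixed seed and separate a toy", {
  set.seed(99)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- factor(ifelse(X[, 2] > 0, "incorrect", "correct"),
              levels = c("correct", "incorrect"))
  probe <- matrix(rnorm(40 * 3), 40, 3)
  for (kind in c("random_forest", "lda", "logistic", "linear_svm",
                 "bagging_lda", "adaboost")) {
    spec <- classifierSpec(kind, seed = 7)
    m1 <- trainClassifier(X, y, spec)
    # a separable toy is learned on its own training set
    expect_gt(mean(predictClassifier(m1, X) == y), 0.95, label = kind)
    # refitting with the same seed reproduces held-out predictions exactly
    m2 <- trainClassifier(X, y, spec)
    expect_identical(predictClassifier(m1, probe), predictClassifier(m2, probe),
                     label = kind)
  }
  expect_error(trainClassifier(X, factor(rep("correct", n),
                                         levels = c("correct", "incorrect"))),
               "single class")
})

test_that("LOSO evaluates one fold per subject without touching target labels", {
  feats <- fixSmallFeatures()
  rep2 <- suppressWarnings(losoEvaluate(feats[1:2], useOT = FALSE,
                                        spec = classifierSpec(seed = 1)))
  expect_equal(nrow(rep2@perSubject), 2)
  expect_identical(rep2@perSubject$subject, names(feats)[1:2])
  rep3 <- losoEvaluate(feats, useOT = TRUE,
                       otCfg = otConfig(labelMode = "unsupervised_target"))
  expect_equal(nrow(rep3@perSubject), 3)
  expect_identical(rep3@labelMode, "unsupervised_target")

  # no leakage in unsupervised mode: scrambling the held-out subject's labels
  # changes the scored confusion but not the predictions themselves
  featsAlt <- feats
  yAlt <- featureLabels(featsAlt[[1]])
  featsAlt[[1]]@y <- factor(rev(as.character(yAlt)),
                            levels = c("correct", "incorrect"))
  repAlt <- losoEvaluate(featsAlt, useOT = TRUE,
                         otCfg = otConfig(labelMode = "unsupervised_target"))
  predictedPositives <- function(r) r@perSubject$tp + r@perSubject$fp
  expect_identical(predictedPositives(repAlt)[1], predictedPositives(rep3)[1])

  # full-run determinism
  repB <- losoEvaluate(feats, useOT = TRUE,
                       otCfg = otConfig(labelMode = "unsupervised_target"))
  expect_identical(rep3@perSubject, repB@perSubject)
  expect_error(losoEvaluate(feats[1], useOT = FALSE), "at least 2")
})

test_that("both arms clear 90% F1 on an unshifted high-SNR cohort", {
  cohort <- fixture("floorCohort", {
    cc <- cohortConfig(nSubjects = 4, nTrials = 48, noiseSd = 0.5,
                       alphaAmp = 0.5, seed = 3)
    generateCohort(cc, identityShifts(4))
  })
  feats <- lapply(cohort, buildFeatures, spec = fixFilter())
  without <- losoEvaluate(feats, useOT = FALSE)
  withOt <- losoEvaluate(feats, useOT = TRUE, otCfg = otConfig())
  expect_gt(meanF1(without), 90)
  expect_gt(meanF1(withOt), 90)
})

test_that("the OT advantage grows with the cohort's gain spread", {
  gaps <- vapply(c(1.0, 1.5, 2.0, 3.0), function(g) {
    cc <- cohortConfig(nSubjects = 4, nTrials = 32, noiseSd = 1.5,
                       alphaAmp = 1, seed = 21)
    shifts <- lapply(seq_len(4), function(i)
      subjectShift(gain = g^((i - 2.5) / 1.5)))
    feats <- lapply(generateCohort(cc, shifts), buildFeatures,
                    spec = fixFilter())
    w <- losoEvaluate(feats, useOT = TRUE, otCfg = otConfig())
    wo <- suppressWarnings(losoEvaluate(feats, useOT = FALSE))
    meanF1(w) - meanF1(wo)
  }, numeric(1))
  expect_true(all(diff(gaps) >= -1e-9))
  expect_gt(gaps[4], gaps[1])
})

test_that("ablation pairs arms and degenerate comparisons give p = 1", {
  feats <- fixSmallFeatures()
  ab <- suppressWarnings(
    runAblation(feats, classifiers = "lda",
                labelModes = "semisupervised_target", seed = 2))
  expect_named(ab$reports, c("lda_without_ot", "lda_with_ot_semisupervised"))
  expect_equal(nrow(ab$comparisons), 1)
  expect_true(ab$comparisons$p >= 0 && ab$comparisons$p <= 1)
  # identical arms -> all differences zero -> degenerate p = 1
  expect_equal(wilcoxonSignedRank(feats[[1]]@X[1, 1:8], feats[[1]]@X[1, 1:8]),
               1)
})

test_that("metrics reports serialize with Mean/SD footer and confusion JSON", {
  feats <- fixSmallFeatures()
  rep0 <- suppressWarnings(
    losoEvaluate(feats, useOT = FALSE, spec = classifierSpec("lda")))
  tab <- metricsTable(rep0)
  expect_identical(tail(tab$subject, 2), c("Mean", "SD"))
  expect_equal(tab$f1[nrow(tab) - 1], mean(rep0@perSubject$f1))
  tmp <- file.path(tempdir(), "report.csv")
  writeMetricsReport(rep0, tmp)
  expect_true(file.exists(tmp))
  side <- jsonlite::read_json(sub("csv$", "json", tmp), simplifyVector = TRUE)
  expect_equal(nrow(side$confusion), 3)
  back <- utils::read.csv(tmp)
  expect_equal(nrow(back), 5)   # 3 subjects + Mean + SD
})
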