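#' @importFrom stats glm predict binomial sd
NULL

#' Construct a classifier specification
#'
#' Available kinds and their default hyperparameters:
#' \itemize{
#'   \item \code{random_forest}: 100 trees, Gini criterion, bootstrap
#'     resampling (the headline decoder);
#'   \item \code{lda}: linear discriminant analysis;
#'   \item \code{logistic}: maximum-likelihood logistic regression
#'     (maxit 100);
#'   \item \code{linear_svm}: linear-kernel SVM, cost C = 1;
#'   \item \code{bagging_lda}: 100 bootstrap LDA learners, majority vote;
#'   \item \code{adaboost}: AdaBoost (SAMME) with 100 depth-1 decision
#'     stumps, learning rate 1.
#' }
#'
#' @param kind classifier kind
#' @param params named list overriding the defaults above
#' @param seed integer seed fixed before fitting
#' @return a [ClassifierSpec-class]
#' @export
classifierSpec <- function(kind = "random_forest", params = list(), seed = 1) {
  defaults <- switch(kind,
    random_forest = list(ntree = 100),
    lda = list(),
    logistic = list(maxit = 100),
    linear_svm = list(cost = 1.0, tolerance = 1e-4),
    bagging_lda = list(nEstimators = 100),
    adaboost = list(nEstimators = 100, learningRate = 1.0),
    list())
  params <- utils::modifyList(defaults, params)
  new("ClassifierSpec", kind = kind, params = params, seed = seed)
}

majorityVote <- function(predMatrix, levels) {
  ## predMatrix: trials x learners of characters
  factor(apply(predMatrix, 1, function(r) {
    tab <- table(factor(r, levels = levels))
    levels[which.max(tab)]   # ties break to the first level, deterministic
  }), levels = levels)
}

#' Train a correct/incorrect classifier
#'
#' Deterministic for a fixed spec seed. Returns a fitted model handle to be
#' used with [predictClassifier()].
#'
#' @param X numeric feature matrix (trials x d) or a [FeatureSet-class]
#' @param y factor with levels correct/incorrect (ignored when X is a
#'   FeatureSet)
#' @param spec a [ClassifierSpec-class]
#' @return a fitted model handle (list with class "errpotModel")
#' @export
trainClassifier <- function(X, y = NULL, spec = classifierSpec()) {
  if (is(X, "FeatureSet")) { y <- featureLabels(X); X <- featureMatrix(X) }
  y <- factor(y, levels = c("correct", "incorrect"))
  if (nlevels(droplevels(y)) < 2)
    stop("training set contains a single class")
  set.seed(as.integer(spec@seed))
  p <- spec@params
  lv <- levels(y)
  model <- switch(spec@kind,
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = p$ntree),
    lda = MASS::lda(X, grouping = y),
    logistic = {
      df <- data.frame(X)
      df$.y <- as.integer(y == "incorrect")
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           control = list(maxit = p$maxit)))
    },
    linear_svm = e1071::svm(X, y, kernel = "linear", cost = p$cost,
                            tolerance = p$tolerance, scale = FALSE),
    bagging_lda = {
      n <- nrow(X)
      fits <- vector("list", p$nEstimators)
      for (b in seq_len(p$nEstimators)) {
        repeat {   # redraw bootstrap samples that lose a class
          ix <- sample.int(n, n, replace = TRUE)
          if (nlevels(droplevels(y[ix])) == 2) break
        }
        fits[[b]] <- suppressWarnings(MASS::lda(X[ix, , drop = FALSE], y[ix]))
      }
      fits
    },
    adaboost = {
      ## SAMME with depth-1 rpart stumps
      n <- nrow(X)
      w <- rep(1 / n, n)
      learners <- list(); alphas <- numeric(0)
      df <- data.frame(X, .y = y)
      for (m in seq_len(p$nEstimators)) {
        fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                            method = "class",
                            control = rpart::rpart.control(
                              maxdepth = 1, cp = -1, minsplit = 2,
                              minbucket = 1, xval = 0))
        pred <- predict(fit, df, type = "class")
        err <- sum(w * (pred != y)) / sum(w)
        if (err >= 0.5) break
        err <- max(err, 1e-10)
        alpha <- p$learningRate * log((1 - err) / err)
        learners[[length(learners) + 1]] <- fit
        alphas <- c(alphas, alpha)
        w <- w * exp(alpha * (pred != y))
        w <- w / sum(w)
        if (err < 1e-9) break
      }
      list(learners = learners, alphas = alphas)
    },
    stop("unknown classifier kind"))
  structure(list(kind = spec@kind, model = model, levels = lv,
                 featureNames = colnames(X)),
            class = "errpotModel")
}

#' Predict classes from a fitted model handle
#'
#' @param model handle returned by [trainClassifier()]
#' @param X numeric feature matrix or [FeatureSet-class]
#' @return factor of predicted classes with levels correct/incorrect
#' @export
predictClassifier <- function(model, X) {
  if (is(X, "FeatureSet")) X <- featureMatrix(X)
  lv <- model$levels
  switch(model$kind,
    random_forest = predict(model$model, X),
    lda = predict(model$model, X)$class,
    logistic = {
      df <- data.frame(X)
      pr <- predict(model$model, newdata = df, type = "response")
      factor(ifelse(pr > 0.5, "incorrect", "correct"), levels = lv)
    },
    linear_svm = predict(model$model, X),
    bagging_lda = {
      preds <- vapply(model$model, function(f)
        as.character(predict(f, X)$class), character(nrow(X)))
      majorityVote(matrix(preds, nrow = nrow(X)), lv)
    },
    adaboost = {
      df <- data.frame(X)
      score <- numeric(nrow(X))
      for (m in seq_along(model$model$learners)) {
        pr <- predict(model$model$learners[[m]], df, type = "class")
        score <- score + model$model$alphas[m] * ifelse(pr == "incorrect", 1, -1)
      }
      factor(ifelse(score > 0, "incorrect", "correct"), levels = lv)
    },
    stop("unknown model kind"))
}

#' Precision, recall and F1 for trial classification
#'
#' "incorrect" is the positive class: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R), all in percent. A support-weighted
#' two-class average of each metric is reported alongside. Zero
#' denominators yield 0 with a warning.
#'
#' @param yTrue,yPred factors/characters in correct/incorrect
#' @param positive the positive class label
#' @return named list: precision, recall, f1, precisionW, recallW, f1W,
#'   tp, fp, fn, tn (percentages for the first six)
#' @export
computeMetrics <- function(yTrue, yPred, positive = "incorrect") {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  vocab <- c("correct", "incorrect")
  if (!all(c(yTrue, yPred) %in% vocab)) stop("labels outside vocabulary")
  negative <- setdiff(vocab, positive)
  prf <- function(pos) {
    tp <- sum(yTrue == pos & yPred == pos)
    fp <- sum(yTrue != pos & yPred == pos)
    fn <- sum(yTrue == pos & yPred != pos)
    safe <- function(num, den, what) {
      if (den == 0) { warning(what, " denominator zero; reporting 0"); 0 }
      else num / den
    }
    p <- safe(tp, tp + fp, "precision")
    r <- safe(tp, tp + fn, "recall")
    f <- if (p + r == 0) { warning("F1 denominator zero; reporting 0"); 0 }
         else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  }
  pos <- prf(positive); neg <- prf(negative)
  wPos <- mean(yTrue == positive)
  weighted <- wPos * pos + (1 - wPos) * neg
  tp <- sum(yTrue == positive & yPred == positive)
  fp <- sum(yTrue != positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  tn <- sum(yTrue != positive & yPred != positive)
  list(precision = 100 * pos[["p"]], recall = 100 * pos[["r"]],
       f1 = 100 * pos[["f"]], precisionW = 100 * weighted[["p"]],
       recallW = 100 * weighted[["r"]], f1W = 100 * weighted[["f"]],
       tp = tp, fp = fp, fn = fn, tn = tn)
}

poolFeatureSets <- function(featureList) {
  X <- do.call(rbind, lapply(featureList, featureMatrix))
  y <- factor(unlist(lapply(featureList, function(f)
    as.character(featureLabels(f)))), levels = c("correct", "incorrect"))
  list(X = X, y = y)
}

#' Leave-one-subject-out evaluation
#'
#' For each fold, the held-out subject is the target and all remaining
#' subjects, pooled, are the source. With \code{useOT}, the pooled source
#' is transported onto the target support (class-regularized transport plus
#' barycentric mapping; target labels participate only in semisupervised
#' mode and never reach the classifier) and the classifier is trained on
#' the transported source. Without OT, the classifier is trained on the raw
#' pooled source. The target subject's features never enter training in
#' either arm.
#'
#' @param featureList named list of [FeatureSet-class], one per subject
#' @param useOT logical; transport the source before training
#' @param otCfg an [OTConfig-class]
#' @param spec a [ClassifierSpec-class]
#' @return a [MetricsReport-class]
#' @export
losoEvaluate <- function(featureList, useOT = TRUE, otCfg = otConfig(),
                         spec = classifierSpec()) {
  if (length(featureList) < 2) stop("need at least 2 subjects for LOSO")
  rows <- lapply(seq_along(featureList), function(k) {
    target <- featureList[[k]]
    source <- poolFeatureSets(featureList[-k])
    if (nlevels(droplevels(source$y)) < 2)
      stop("fold source contains a single class")
    if (useOT) {
      tl <- if (otCfg@labelMode == "semisupervised_target")
        as.character(featureLabels(target)) else NULL
      ad <- otAdapt(source$X, featureMatrix(target),
                    as.character(source$y), tl, otCfg)
      model <- trainClassifier(ad$mapped, source$y, spec)
    } else {
      model <- trainClassifier(source$X, source$y, spec)
    }
    pred <- predictClassifier(model, featureMatrix(target))
    m <- computeMetrics(featureLabels(target), pred)
    data.frame(subject = subjectId(target), as.data.frame(m))
  })
  new("MetricsReport",
      pipeline = if (useOT) "with_ot" else "without_ot",
      classifier = spec@kind,
      labelMode = if (useOT) otCfg@labelMode else "none",
      perSubject = do.call(rbind, rows))
}

#' Mean F1 (positive class, percent) of a report
#' @param report a [MetricsReport-class]
#' @return scalar mean F1 over subjects
#' @export
meanF1 <- function(report) mean(report@perSubject$f1)

#' Ablation harness: OT on/off, label modes, classifier sweep
#'
#' Runs leave-one-subject-out decoding for every requested combination and
#' pairs arms with two-tailed exact Wilcoxon signed-rank tests on the
#' per-subject F1 scores: each with-OT arm against the no-OT baseline of
#' the same classifier.
#'
#' @param featureList named list of [FeatureSet-class]
#' @param classifiers character vector of classifier kinds
#' @param labelModes label modes to run for the with-OT arms
#' @param otCfg base [OTConfig-class] (labelMode field overridden per run)
#' @param seed classifier seed
#' @return list with \code{reports} (named list of [MetricsReport-class])
#'   and \code{comparisons} (data.frame: classifier, labelMode, meanF1WithOT,
#'   meanF1WithoutOT, p)
#' @export
runAblation <- function(featureList, classifiers = "random_forest",
                        labelModes = c("semisupervised_target",
                                       "unsupervised_target"),
                        otCfg = otConfig(), seed = 1) {
  reports <- list()
  comps <- list()
  for (cl in classifiers) {
    spec <- classifierSpec(cl, seed = seed)
    base <- losoEvaluate(featureList, useOT = FALSE, spec = spec)
    reports[[paste0(cl, "_without_ot")]] <- base
    for (mode in labelModes) {
      cfg <- otCfg; cfg@labelMode <- mode
      withOt <- losoEvaluate(featureList, useOT = TRUE, otCfg = cfg,
                             spec = spec)
      tag <- paste0(cl, "_with_ot_",
                    sub("_target$", "", mode))
      reports[[tag]] <- withOt
      p <- wilcoxonSignedRank(withOt@perSubject$f1, base@perSubject$f1)
      comps[[tag]] <- data.frame(
        classifier = cl, labelMode = mode,
        meanF1WithOT = meanF1(withOt), meanF1WithoutOT = meanF1(base),
        p = p)
    }
  }
  list(reports = reports, comparisons = do.call(rbind, comps))
}

#' Write a metrics report as a delimited table
#'
#' One row per subject with Precision/Recall/F1 columns and Mean/SD footer
#' rows, plus a JSON sidecar holding confusion counts and the tags.
#'
#' @param report a [MetricsReport-class]
#' @param path output CSV path; the sidecar replaces the extension with
#'   .json
#' @return invisibly, the path
#' @export
writeMetricsReport <- function(report, path) {
  tab <- metricsTable(report)
  utils::write.csv(tab[, c("subject", "precision", "recall", "f1")],
                   path, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(pipeline = report@pipeline, classifier = report@classifier,
         labelMode = report@labelMode,
         confusion = report@perSubject[, c("subject", "tp", "fp", "fn", "tn")]),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
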