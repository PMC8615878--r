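#' @importFrom stats kruskal.test pchisq
#' @importFrom graphics abline legend lines par plot
NULL

## stack all trials of one channel across a cohort into a trials x samples
## matrix, with the matching correctness labels
stackChannel <- function(cohort, channel) {
  if (is(cohort, "EpochSet")) cohort <- list(cohort)
  mats <- lapply(cohort, function(ep) {
    ci <- match(channel, ep@channelNames)
    if (is.na(ci)) stop("channel absent: ", channel)
    ep@data[, ci, , drop = TRUE]
  })
  mats <- lapply(mats, function(m) if (is.null(dim(m))) matrix(m, 1) else m)
  labels <- unlist(lapply(cohort, correctness))
  times <- epochTimes(if (is(cohort, "EpochSet")) cohort else cohort[[1]])
  list(data = do.call(rbind, mats), labels = labels, times = times)
}

#' Grand-average ERP over a cohort
#'
#' Mean waveform over all matching trials of all subjects at one channel.
#'
#' @param cohort list of [EpochSet-class] (or a single one)
#' @param channel electrode name
#' @param condition "correct" or "incorrect"
#' @return numeric time series with attributes \code{times} and \code{n}
#'   (trial count)
#' @export
grandAverage <- function(cohort, channel, condition) {
  if (!condition %in% c("correct", "incorrect"))
    stop("condition must be 'correct' or 'incorrect'")
  st <- stackChannel(cohort, channel)
  sel <- st$labels == condition
  if (!any(sel)) stop("no trials in condition ", condition)
  out <- colMeans(st$data[sel, , drop = FALSE])
  attr(out, "times") <- st$times
  attr(out, "n") <- sum(sel)
  out
}

#' Per-timepoint Kruskal-Wallis p-value series
#'
#' At every timepoint, a two-group rank test (correct vs incorrect trials,
#' pooled across subjects) with tie correction and the chi-square
#' approximation on 1 degree of freedom. Timepoints where all values tie
#' give p = 1 with a warning.
#'
#' @param cohort list of [EpochSet-class]
#' @param channel electrode name
#' @return numeric vector of p-values, one per timepoint
#' @export
kruskalWallisSeries <- function(cohort, channel) {
  st <- stackChannel(cohort, channel)
  g <- factor(st$labels, levels = c("correct", "incorrect"))
  if (min(table(g)) < 2) stop("need at least 2 trials per condition")
  tied <- FALSE
  p <- apply(st$data, 2, function(x) {
    if (length(unique(x)) == 1L) { tied <<- TRUE; return(1) }
    kruskal.test(x, g)$p.value
  })
  if (tied) warning("all-tied data at some timepoints; p = 1 there")
  unname(p)
}

#' Exact two-tailed Wilcoxon signed-rank test
#'
#' Drops zero differences (standard convention), ranks the absolute
#' differences with midranks for ties, and computes the two-tailed p-value
#' from the exact permutation null (all 2^n sign assignments, evaluated by
#' dynamic programming over the doubled-rank sums) for n <= 25; larger n
#' uses the normal approximation with tie correction.
#'
#' @param a,b paired numeric vectors (or \code{b} omitted to test
#'   differences \code{a} against zero)
#' @return two-tailed p-value; 1 when all differences are zero
#' @export
wilcoxonSignedRank <- function(a, b = NULL) {
  d <- if (is.null(b)) a else {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    a - b
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  if (n <= 25) {
    ## exact null: distribution of sum of a random subset of the ranks.
    ## doubled midranks are integers, enabling the DP.
    r2 <- as.integer(round(2 * r))
    maxSum <- sum(r2)
    counts <- numeric(maxSum + 1)
    counts[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(maxSum + 1 - rk)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * wPlus))
    total <- 2^n
    pLe <- sum(counts[seq_len(w2 + 1)]) / total
    pGe <- sum(counts[(w2 + 1):(maxSum + 1)]) / total
    min(1, 2 * min(pLe, pGe))
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (wPlus - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Full ERP contrast at one channel
#'
#' Grand averages per condition, their difference wave (incorrect minus
#' correct) and the per-timepoint Kruskal-Wallis p-series.
#'
#' @param cohort list of [EpochSet-class]
#' @param channel electrode name
#' @param alpha significance level
#' @return an [ErpStatsResult-class]
#' @export
erpStats <- function(cohort, channel, alpha = 0.05) {
  gc_ <- grandAverage(cohort, channel, "correct")
  gi <- grandAverage(cohort, channel, "incorrect")
  p <- kruskalWallisSeries(cohort, channel)
  new("ErpStatsResult", channel = channel, times = attr(gc_, "times"),
      avgCorrect = as.numeric(gc_), avgIncorrect = as.numeric(gi),
      difference = as.numeric(gi) - as.numeric(gc_), pSeries = p,
      alpha = alpha, nCorrect = attr(gc_, "n"), nIncorrect = attr(gi, "n"))
}

#' Export an ErpStatsResult as a delimited table
#'
#' Columns: time, mean_correct, mean_incorrect, difference, p.
#'
#' @param result an [ErpStatsResult-class]
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeErpStats <- function(result, path) {
  utils::write.csv(data.frame(
    time = result@times, mean_correct = result@avgCorrect,
    mean_incorrect = result@avgIncorrect, difference = result@difference,
    p = result@pSeries), path, row.names = FALSE)
  invisible(path)
}

#' Plot an ERP contrast
#'
#' Two stacked panels: condition-wise grand averages with the difference
#' wave, and the per-timepoint p-value trace with the significance level
#' and the feedback-display onset marked.
#'
#' @param result an [ErpStatsResult-class]
#' @param feedbackDelay seconds of the display-onset marker
#' @return invisibly, NULL
#' @export
plotErpStats <- function(result, feedbackDelay = 0.5) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- result@times
  ylim <- range(result@avgCorrect, result@avgIncorrect, result@difference)
  plot(t, result@avgCorrect, type = "l", col = "blue", ylim = ylim,
       xlab = "time from feedback-period onset (s)",
       ylab = expression(paste("amplitude (", mu, "V)")),
       main = result@channel)
  lines(t, result@avgIncorrect, col = "red")
  lines(t, result@difference, col = "black")
  abline(v = feedbackDelay, lty = 3)
  legend("topleft", c("correct", "incorrect", "difference"),
         col = c("blue", "red", "black"), lty = 1, bty = "n", cex = 0.8)
  plot(t, result@pSeries, type = "l", col = "grey40", log = "y",
       xlab = "time from feedback-period onset (s)", ylab = "p (KW)")
  abline(h = result@alpha, lty = 2)
  abline(v = feedbackDelay, lty = 3)
  invisible(NULL)
}
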