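#' @importFrom stats median
NULL

#' Construct a discrete empirical measure
#'
#' Places probability mass on observed feature points. Omitted weights give
#' the uniform measure 1/N; supplied weights are renormalized to sum to one.
#'
#' @param points numeric matrix N x d (a vector is taken as N x 1)
#' @param weights optional nonnegative weights, length N
#' @return an [EmpiricalMeasure-class]
#' @export
empiricalMeasure <- function(points, weights = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 1) stop("need at least one support point")
  if (is.null(weights)) {
    mass <- rep(1 / n, n)
  } else {
    if (length(weights) != n) stop("weights must match the number of points")
    if (any(weights < 0)) stop("weights must be nonnegative")
    tot <- sum(weights)
    if (tot <= 0) stop("weights must not be all zero")
    mass <- weights / tot
  }
  new("EmpiricalMeasure", support = points, mass = mass)
}

#' Pairwise squared-Euclidean cost matrix
#'
#' @param source,target [EmpiricalMeasure-class] objects (or plain point
#'   matrices) of equal dimensionality
#' @return a [CostMatrix-class] with values[i, j] = ||f_i^s - f_j^t||^2
#' @export
costMatrix <- function(source, target) {
  A <- if (is(source, "EmpiricalMeasure")) source@support else
    if (is.matrix(source)) source else matrix(source, ncol = 1)
  B <- if (is(target, "EmpiricalMeasure")) target@support else
    if (is.matrix(target)) target else matrix(target, ncol = 1)
  if (ncol(A) != ncol(B)) stop("source and target dimensionality differ")
  v <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  v[v < 0] <- 0    # clip float negatives
  new("CostMatrix", values = v, metric = "squared_euclidean")
}

costValues <- function(cost) {
  if (is(cost, "CostMatrix")) cost@values else as.matrix(cost)
}

marginalViolation <- function(tau, ps, pt) {
  rv <- abs(rowSums(tau) - ps) / pmax(ps, .Machine$double.eps)
  cv <- abs(colSums(tau) - pt) / pmax(pt, .Machine$double.eps)
  max(rv, cv)
}

logSumExpRows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

entropicObjective <- function(tau, J, lambda) {
  pos <- tau > 0
  sum(tau * J) + lambda * sum(tau[pos] * log(tau[pos]))
}

## Dual objective of the entropic problem; Sinkhorn is exact block
## coordinate ascent on this, so it is monotonically nondecreasing.
dualObjective <- function(f, g, J, lambda, ps, pt) {
  sum(f * ps) + sum(g * pt) - lambda * sum(exp((outer(f, g, "+") - J) / lambda))
}

#' Entropy-regularized optimal transport via Sinkhorn scaling
#'
#' Solves \eqn{\min_{\tau} \langle \tau, J \rangle + \lambda \sum \tau \log
#' \tau} over couplings with row sums \code{ps} and column sums \code{pt},
#' by alternating Sinkhorn-Knopp scaling. When \code{lambda} is small
#' relative to the cost scale the iteration runs in the log domain to avoid
#' underflow.
#'
#' @param cost a [CostMatrix-class] or plain matrix
#' @param ps,pt source/target probability masses (default uniform)
#' @param lambda entropic weight, > 0
#' @param maxIter maximum scaling iterations
#' @param tol maximum relative marginal violation at convergence
#' @param logDomain "auto", TRUE or FALSE; small lambda relative to the
#'   cost scale selects the log domain with epsilon-scaling warm starts
#' @param round project the final iterate onto the marginal polytope (the
#'   standard rounding of near-feasible Sinkhorn output), so returned plans
#'   satisfy the marginals to machine precision
#' @param traceEvery record the primal objective every this many iterations
#' @param warmStart optional list(f, g) of dual potentials to start from
#'   (as attached to a previous plan via \code{attr(plan, "potentials")})
#' @return a [TransportPlan-class]
#' @export
sinkhornPlan <- function(cost, ps = NULL, pt = NULL, lambda = 1,
                         maxIter = 1000, tol = 1e-9, logDomain = "auto",
                         round = TRUE, traceEvery = 10, warmStart = NULL) {
  J <- costValues(cost)
  ns <- nrow(J); nt <- ncol(J)
  if (is.null(ps)) ps <- rep(1 / ns, ns)
  if (is.null(pt)) pt <- rep(1 / nt, nt)
  if (lambda <= 0) stop("lambda must be > 0 for Sinkhorn (use exactTransport)")
  if (abs(sum(ps) - sum(pt)) > 1e-9) stop("marginal masses must balance")
  med <- median(J[J > 0])
  if (!length(med) || !is.finite(med)) med <- 1
  ## the plain scaling iteration underflows once exp(-max(J)/lambda) hits
  ## the double floor; stay in the log domain whenever that is close
  useLog <- if (identical(logDomain, "auto"))
    lambda / med < 1e-2 || max(J) / lambda > 500
  else isTRUE(logDomain)

  obj <- numeric(0)
  tau <- NULL
  converged <- FALSE
  potentials <- NULL
  if (!useLog) {
    K <- exp(-J / lambda)
    v <- rep(1, nt)
    for (it in seq_len(maxIter)) {
      u <- ps / as.vector(K %*% v)
      v <- pt / as.vector(crossprod(K, u))
      tau <- (u * K) * rep(v, each = ns)
      if (!all(is.finite(tau))) { useLog <- TRUE; break }
      if (it %% traceEvery == 0 || it == 1)
        obj <- c(obj, dualObjective(lambda * log(u), lambda * log(v), J,
                                    lambda, ps, pt))
      if (marginalViolation(tau, ps, pt) < tol) { converged <- TRUE; break }
    }
    if (!useLog) potentials <- list(f = lambda * log(pmax(u, .Machine$double.xmin)),
                                    g = lambda * log(pmax(v, .Machine$double.xmin)))
  }
  if (useLog) {
    converged <- FALSE
    obj <- numeric(0)
    lps <- log(ps); lpt <- log(pt)
    if (!is.null(warmStart)) {
      f <- warmStart$f; g <- warmStart$g
      lambdas <- lambda
    } else {
      f <- numeric(ns); g <- numeric(nt)
      ## epsilon scaling: anneal the temperature down to lambda while
      ## warm-starting the dual potentials; makes small-lambda runs fast
      lambdas <- lambda
      if (lambda < med) {
        k <- ceiling(log2(med / lambda))
        lambdas <- c(med / 2^(seq_len(k) - 1), lambda)
      }
    }
    iterBudget <- c(rep(25, length(lambdas) - 1), maxIter)
    for (stage in seq_along(lambdas)) {
      lam <- lambdas[stage]
      Jl <- J / lam
      for (it in seq_len(iterBudget[stage])) {
        f <- lam * (lps - logSumExpRows(matrix(g / lam, ns, nt, byrow = TRUE) -
                                          Jl + f / lam)) + f
        g <- lam * (lpt - logSumExpRows(t(matrix(f / lam, ns, nt) - Jl) +
                                          g / lam)) + g
        if (stage == length(lambdas) &&
            (it %% 5 == 0 || it == 1 || it == iterBudget[stage])) {
          tau <- exp(outer(f / lam, g / lam, "+") - Jl)
          if (it %% traceEvery == 0 || it == 1)
            obj <- c(obj, dualObjective(f, g, J, lam, ps, pt))
          if (marginalViolation(tau, ps, pt) < tol) { converged <- TRUE; break }
        }
      }
    }
    if (is.null(tau)) tau <- exp(outer(f / lambda, g / lambda, "+") - J / lambda)
    potentials <- list(f = f, g = g)
  }
  if (!converged && !round)
    warning(sprintf(
      "Sinkhorn did not reach tol %.1e in %d iterations (marginal error %.2e)",
      tol, maxIter, marginalViolation(tau, ps, pt)))
  if (round) tau <- roundToPolytope(tau, ps, pt)
  err <- marginalViolation(tau, ps, pt)
  out <- new("TransportPlan", coupling = tau, sourceMass = ps,
             targetMass = pt, objective = obj, classIndex = list(),
             converged = converged || round, marginalError = err)
  attr(out, "potentials") <- potentials
  out
}

## Round a nonnegative near-coupling onto the transport polytope:
## scale rows then columns down where they overshoot, and repair the
## remaining deficit with a rank-one nonnegative correction. Leaves
## feasible plans essentially untouched.
roundToPolytope <- function(tau, ps, pt) {
  r <- rowSums(tau)
  tau <- tau * pmin(1, ps / pmax(r, .Machine$double.xmin))
  cs <- colSums(tau)
  tau <- tau * rep(pmin(1, pt / pmax(cs, .Machine$double.xmin)), each = nrow(tau))
  dr <- pmax(ps - rowSums(tau), 0)
  dc <- pmax(pt - colSums(tau), 0)
  s <- sum(dr)
  if (s > 0 && sum(dc) > 0) tau <- tau + outer(dr, dc) / s
  pmax(tau, 0)
}

#' Construct an OT solver configuration
#'
#' @param lambdaEntropy entropic weight, unitless relative to the median
#'   cost when \code{costNormalize}; the 0.05 default keeps unsupervised
#'   couplings diffuse enough to be robust while preserving a sharp
#'   barycentric map
#' @param etaGroup group-sparsity weight; 10 is the headline setting
#' @param labelMode "semisupervised_target" (target labels shape the
#'   coupling, never the classifier) or "unsupervised_target"
#' @param maxOuter outer majorization-minimization iterations
#' @param maxSinkhorn inner Sinkhorn iterations
#' @param marginalTol relative marginal tolerance
#' @param costNormalize divide the cost by its positive median before
#'   solving
#' @param standardize z-score features before cost computation (used by
#'   [otAdapt()])
#' @return an [OTConfig-class]
#' @export
otConfig <- function(lambdaEntropy = 0.05, etaGroup = 10,
                     labelMode = "semisupervised_target", maxOuter = 10,
                     maxSinkhorn = 1000, marginalTol = 1e-9,
                     costNormalize = TRUE, standardize = FALSE) {
  new("OTConfig", lambdaEntropy = lambdaEntropy, etaGroup = etaGroup,
      labelMode = labelMode, maxOuter = maxOuter, maxSinkhorn = maxSinkhorn,
      marginalTol = marginalTol, costNormalize = costNormalize,
      standardize = standardize)
}

classIndexSets <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("correct", "incorrect"))
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  lapply(split(seq_along(labels), labels), as.integer)
}

#' Class-regularized optimal transport
#'
#' Adds a group-sparse class penalty to entropic transport so that each
#' target point draws mass from source points of a single class. Solved by
#' majorization-minimization: each outer step majorizes the concave
#' per-column per-class group penalty \eqn{\sum_j \sum_c
#' \sqrt{m_{cj}}} (where \eqn{m_{cj}} is the mass column j receives from
#' class c) by its tangent, yielding an adjusted-cost Sinkhorn problem.
#' With \code{etaGroup = 0} this is exactly plain Sinkhorn. In
#' semisupervised mode, couplings between source and target points of
#' different classes are additionally discouraged by a large finite cost
#' penalty.
#'
#' @param cost a [CostMatrix-class] or matrix
#' @param ps,pt marginal masses (default uniform)
#' @param sourceLabels per-source-row class in correct/incorrect
#' @param targetLabels per-target-column class; required in semisupervised
#'   mode only
#' @param config an [OTConfig-class]
#' @return a [TransportPlan-class] with class index sets attached
#' @export
groupLassoTransport <- function(cost, ps = NULL, pt = NULL, sourceLabels,
                                targetLabels = NULL, config = otConfig()) {
  validObject(config)
  J <- costValues(cost)
  ns <- nrow(J); nt <- ncol(J)
  if (length(sourceLabels) != ns)
    stop("sourceLabels must have one entry per source point")
  if (is.null(ps)) ps <- rep(1 / ns, ns)
  if (is.null(pt)) pt <- rep(1 / nt, nt)
  idx <- classIndexSets(sourceLabels)

  if (config@costNormalize) {
    med <- median(J[J > 0])
    if (is.finite(med) && med > 0) J <- J / med
  }
  if (config@labelMode == "semisupervised_target") {
    if (is.null(targetLabels))
      stop("semisupervised_target mode requires targetLabels")
    if (length(targetLabels) != nt)
      stop("targetLabels must have one entry per target point")
    classIndexSets(targetLabels)   # vocabulary check
    mask <- outer(as.character(sourceLabels), as.character(targetLabels), "!=")
    J <- J + mask * (10 * max(J))
  }

  lam <- config@lambdaEntropy
  eta <- config@etaGroup
  solveInner <- function(Jadj, ws = NULL)
    sinkhornPlan(Jadj, ps, pt, lambda = lam, maxIter = config@maxSinkhorn,
                 tol = config@marginalTol, warmStart = ws)
  plan <- solveInner(J)
  if (eta > 0) {
    eps <- 1e-6   # floors the MM weight so adjusted costs stay bounded
    for (outer_it in seq_len(config@maxOuter)) {
      tau <- plan@coupling
      W <- matrix(0, ns, nt)
      for (cl in names(idx)) {
        rows <- idx[[cl]]
        mcj <- colSums(tau[rows, , drop = FALSE])
        W[rows, ] <- matrix(0.5 / sqrt(eps + mcj), length(rows), nt,
                            byrow = TRUE)
      }
      nxt <- solveInner(J + eta * W, attr(plan, "potentials"))
      delta <- max(abs(nxt@coupling - tau))
      plan <- nxt
      if (delta < 1e-12) break
    }
  }
  plan@classIndex <- idx
  plan
}

#' Class purity of a transport plan's columns
#'
#' For each target column, the largest share of its mass contributed by a
#' single source class; returns the column-mass-weighted mean. 1 means
#' every target point is served by one class only.
#'
#' @param plan a [TransportPlan-class]
#' @param sourceLabels per-source-row class labels (defaults to the plan's
#'   stored index sets)
#' @return scalar in [1/nClasses, 1]
#' @export
classPurity <- function(plan, sourceLabels = NULL) {
  idx <- if (is.null(sourceLabels)) plan@classIndex
         else classIndexSets(sourceLabels)
  if (!length(idx)) stop("no class information available")
  tau <- plan@coupling
  perClass <- vapply(idx, function(rows)
    colSums(tau[rows, , drop = FALSE]), numeric(ncol(tau)))
  perClass <- matrix(perClass, ncol = length(idx))
  tot <- rowSums(perClass)
  keep <- tot > 0
  sum(apply(perClass[keep, , drop = FALSE], 1, max)) / sum(tot[keep])
}

#' Barycentric mapping of source points onto the target support
#'
#' Relocates each source point to the coupling-weighted average of the
#' target points: \eqn{\hat F_s = \mathrm{diag}(\tau 1)^{-1} \tau F_t}.
#' Every transported coordinate lies within the target's coordinate range.
#'
#' @param plan a [TransportPlan-class]
#' @param target the target [EmpiricalMeasure-class] (or point matrix)
#' @return a [TransportedFeatures-class]
#' @export
barycentricMap <- function(plan, target) {
  Ft <- if (is(target, "EmpiricalMeasure")) target@support else
    if (is.matrix(target)) target else matrix(target, ncol = 1)
  tau <- plan@coupling
  if (ncol(tau) != nrow(Ft))
    stop("plan columns must match the number of target points")
  rs <- rowSums(tau)
  zero <- which(rs == 0)
  if (length(zero))
    stop("zero row mass for source index ", paste(zero, collapse = ", "))
  pts <- (tau %*% Ft) / rs
  new("TransportedFeatures", points = pts, plan = plan)
}

#' Exact optimal transport by linear programming (small instances)
#'
#' Solves the unregularized Kantorovich problem exactly with the simplex
#' method, for use as an oracle against the entropic solver. One marginal
#' equality is dropped as redundant (masses balance).
#'
#' @param cost a [CostMatrix-class] or matrix; Ns x Nt with Ns*Nt <= 400
#' @param ps,pt marginal masses (default uniform)
#' @return a [TransportPlan-class]; the transport cost is in
#'   \code{attr(, "value")} and also recoverable as
#'   \code{sum(coupling(plan) * cost)}
#' @export
exactTransport <- function(cost, ps = NULL, pt = NULL) {
  J <- costValues(cost)
  ns <- nrow(J); nt <- ncol(J)
  if (ns * nt > 400) stop("instance too large for the LP oracle (Ns*Nt > 400)")
  if (is.null(ps)) ps <- rep(1 / ns, ns)
  if (is.null(pt)) pt <- rep(1 / nt, nt)
  if (abs(sum(ps) - sum(pt)) > 1e-9) stop("marginal masses must balance")
  nv <- ns * nt
  ## variable order: column-major vec of tau
  A <- matrix(0, ns + nt - 1, nv)
  for (i in seq_len(ns))
    A[i, i + ns * (seq_len(nt) - 1)] <- 1          # row sums
  for (j in seq_len(nt - 1))
    A[ns + j, (j - 1) * ns + seq_len(ns)] <- 1     # column sums (last dropped)
  b <- c(ps, pt[-nt])
  sol <- boot::simplex(a = as.vector(J), A3 = A, b3 = b, maxi = FALSE)
  if (sol$solved != 1) stop("LP oracle failed to solve")
  tau <- matrix(sol$soln, ns, nt)
  tau[tau < 0] <- 0
  plan <- new("TransportPlan", coupling = tau, sourceMass = ps,
              targetMass = pt, objective = numeric(0), classIndex = list(),
              converged = TRUE,
              marginalError = marginalViolation(tau, ps, pt))
  attr(plan, "value") <- unname(sol$value)
  plan
}

#' One-call domain adaptation between two feature sets
#'
#' Convenience wrapper used by the decoder: builds uniform empirical
#' measures over the source and target feature matrices (optionally
#' z-scored with the source statistics), computes the squared-Euclidean
#' cost, solves class-regularized transport, and barycentrically maps the
#' source onto the target support.
#'
#' @param sourceX,targetX numeric feature matrices
#' @param sourceLabels source class labels
#' @param targetLabels target labels (semisupervised mode only)
#' @param config an [OTConfig-class]
#' @return list with elements \code{mapped} (transported source matrix) and
#'   \code{plan}
#' @export
otAdapt <- function(sourceX, targetX, sourceLabels, targetLabels = NULL,
                    config = otConfig()) {
  if (config@standardize) {
    mu <- colMeans(sourceX)
    sg <- apply(sourceX, 2, sd); sg[sg == 0] <- 1
    sourceX <- scale(sourceX, mu, sg)
    targetX <- scale(targetX, mu, sg)
  }
  mu_s <- empiricalMeasure(sourceX)
  mu_t <- empiricalMeasure(targetX)
  J <- costMatrix(mu_s, mu_t)
  plan <- groupLassoTransport(J, mu_s@mass, mu_t@mass, sourceLabels,
                              targetLabels, config)
  mapped <- barycentricMap(plan, mu_t)
  list(mapped = transportedPoints(mapped), plan = plan)
}
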