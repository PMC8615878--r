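test_that("empirical measures normalize mass correctly", {
  m <- empiricalMeasure(matrix(rnorm(8), 4, 2))
  expect_equal(m@mass, rep(0.25, 4))
  expect_equal(empiricalMeasure(matrix(0, 1, 3))@mass, 1)
  expect_equal(empiricalMeasure(matrix(0, 3, 1), c(2, 2, 4))@mass,
               c(0.25, 0.25, 0.5))
  expect_error(empiricalMeasure(matrix(0, 2, 1), c(0, 0)), "all zero")
  expect_error(empiricalMeasure(matrix(0, 2, 1), c(-1, 2)), "nonnegative")
})

test_that("cost matrix is the exact pairwise squared Euclidean distance", {
  expect_equal(costMatrix(matrix(c(0, 0), 1), matrix(c(3, 4), 1))@values[1, 1],
               25)
  src <- matrix(rnorm(10), 5, 2); tgt <- matrix(rnorm(12), 6, 2)
  J <- costMatrix(src, tgt)@values
  ref <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) ref[i, j] <- sum((src[i, ] - tgt[j, ])^2)
  expect_equal(J, ref)
  expect_equal(diag(costMatrix(src, src)@values), numeric(5))
  expect_error(costMatrix(src, matrix(0, 2, 3)), "dimensionality")
})

test_that("sinkhorn solves forced and near-LP couplings", {
  # 1x1: the only feasible plan
  expect_equal(coupling(sinkhornPlan(matrix(5), lambda = 1))[1, 1], 1)
  # 2x2 with cost [[0,1],[1,0]]: small lambda recovers the diagonal vertex
  pl <- sinkhornPlan(matrix(c(0, 1, 1, 0), 2, 2), lambda = 0.01)
  expect_lt(max(abs(coupling(pl) - diag(2) / 2)), 1e-3)
  # symmetric cost with equal marginals gives a symmetric plan
  set.seed(3)
  A <- matrix(runif(9), 3, 3); Jsym <- (A + t(A)) / 2
  ps <- c(0.2, 0.3, 0.5)
  plS <- sinkhornPlan(Jsym, ps, ps, lambda = 0.5)
  expect_lt(max(abs(coupling(plS) - t(coupling(plS)))), 1e-8)
  expect_error(sinkhornPlan(matrix(1), lambda = 0), "lambda")
})

test_that("returned plans conserve marginals and are nonnegative", {
  for (seed in 1:5) {
    inst <- randomOTInstance(7, 5, seed = seed)
    set.seed(seed)
    ps <- runif(7); ps <- ps / sum(ps)
    pt <- runif(5); pt <- pt / sum(pt)
    for (lam in c(0.05, 1)) {
      pl <- sinkhornPlan(inst$cost, ps, pt, lambda = lam)
      expect_true(all(coupling(pl) >= 0))
      expect_lt(pl@marginalError, 1e-9)
      expect_equal(rowSums(coupling(pl)), ps, tolerance = 1e-12)
      expect_equal(colSums(coupling(pl)), pt, tolerance = 1e-12)
    }
  }
})

test_that("sinkhorn dual objective trace is monotone (block ascent)", {
  inst <- randomOTInstance(6, 6, seed = 9)
  pl <- sinkhornPlan(inst$cost, lambda = 0.2, traceEvery = 1)
  expect_gt(length(pl@objective), 3)
  expect_true(all(diff(pl@objective) >= -1e-10))
})

test_that("entropic transport approaches the exact LP optimum as lambda -> 0", {
  for (seed in 1:3) {
    set.seed(seed)
    J <- matrix(runif(16), 4, 4)
    oracle <- exactTransport(J)
    lpCost <- attr(oracle, "value")
    pl <- sinkhornPlan(J, lambda = 1e-3 * median(J), maxIter = 50000)
    skCost <- sum(coupling(pl) * J)
    expect_gte(skCost, lpCost - 1e-9)          # LP is a lower bound
    expect_lt((skCost - lpCost) / lpCost, 0.01)
  }
  # and at moderate lambda the LP bound still holds
  inst <- randomOTInstance(3, 3, seed = 2)
  o <- exactTransport(inst$cost)
  p <- sinkhornPlan(inst$cost, lambda = 0.5)
  expect_gte(sum(coupling(p) * inst$cost@values), attr(o, "value") - 1e-9)
})

test_that("the LP oracle solves forced matchings and respects size limits", {
  o <- exactTransport(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(attr(o, "value"), 0)
  expect_equal(coupling(o), diag(2) / 2)
  expect_lt(o@marginalError, 1e-9)
  expect_error(exactTransport(matrix(0, 30, 30)), "too large")
})

test_that("eta = 0 group transport reduces exactly to sinkhorn", {
  inst <- classClusterInstance()
  cfg <- otConfig(etaGroup = 0, labelMode = "unsupervised_target")
  a <- groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                           config = cfg)
  Jn <- inst$cost@values / median(inst$cost@values[inst$cost@values > 0])
  b <- sinkhornPlan(Jn, lambda = cfg@lambdaEntropy, tol = cfg@marginalTol)
  expect_lt(max(abs(coupling(a) - coupling(b))), 1e-9)
})

test_that("class purity of the coupling is nondecreasing in eta", {
  inst <- classClusterInstance()
  purities <- vapply(c(0, 0.1, 1, 10), function(eta) {
    cfg <- otConfig(etaGroup = eta, labelMode = "unsupervised_target")
    classPurity(groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                                    config = cfg))
  }, numeric(1))
  expect_true(all(diff(purities) >= -1e-9))
  # the headline setting eta = 10: >= 99% of every column's mass from one class
  cfg10 <- otConfig(etaGroup = 10, labelMode = "unsupervised_target")
  pl <- groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                            config = cfg10)
  tau <- coupling(pl)
  colPurity <- apply(tau, 2, function(col) {
    byClass <- vapply(split(col, inst$srcLab), sum, numeric(1))
    max(byClass) / sum(byClass)
  })
  expect_true(all(colPurity >= 0.99))
  expect_lt(pl@marginalError, 1e-9)
})

test_that("semisupervised label masking needs target labels and purifies", {
  inst <- classClusterInstance()
  cfg <- otConfig(labelMode = "semisupervised_target")
  expect_error(groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                                   config = cfg), "targetLabels")
  pl <- groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                            targetLabels = inst$tgtLab, config = cfg)
  expect_gt(classPurity(pl), 0.999)
  expect_error(groupLassoTransport(inst$cost, sourceLabels = rep("x", 20),
                                   config = cfg), "unknown label")
})

test_that("barycentric mapping averages target points by coupling weight", {
  # hand-computed 2x2 example in 1-D
  plan <- new("TransportPlan", coupling = matrix(c(0.3, 0.1, 0.2, 0.4), 2, 2),
              sourceMass = c(0.5, 0.5), targetMass = c(0.4, 0.6),
              objective = numeric(0), classIndex = list(), converged = TRUE,
              marginalError = 0)
  out <- transportedPoints(barycentricMap(plan, matrix(c(0, 10), 2, 1)))
  expect_equal(as.numeric(out), c(4, 8))
  # identity coupling carries source onto target row-for-row
  tgt <- matrix(rnorm(6), 3, 2)
  idPlan <- new("TransportPlan", coupling = diag(3) / 3,
                sourceMass = rep(1 / 3, 3), targetMass = rep(1 / 3, 3),
                objective = numeric(0), classIndex = list(),
                converged = TRUE, marginalError = 0)
  expect_equal(transportedPoints(barycentricMap(idPlan, tgt)), tgt)
  # zero row mass is refused with the row named
  zp <- idPlan; zp@coupling[2, ] <- 0
  expect_error(barycentricMap(zp, tgt), "source index 2")
})

test_that("transported points stay inside the target coordinate range", {
  for (seed in 1:4) {
    inst <- randomOTInstance(8, 6, seed = seed)
    pl <- sinkhornPlan(inst$cost, lambda = 0.3)
    mapped <- transportedPoints(barycentricMap(pl, inst$tgt))
    for (d in 1:2) {
      expect_gte(min(mapped[, d]), min(inst$tgt[, d]) - 1e-12)
      expect_lte(max(mapped[, d]), max(inst$tgt[, d]) + 1e-12)
    }
  }
})

test_that("permuting source points permutes plan rows and mapped features", {
  inst <- classClusterInstance(nPerClass = 5)
  cfg <- otConfig(etaGroup = 10, labelMode = "unsupervised_target")
  pl <- groupLassoTransport(inst$cost, sourceLabels = inst$srcLab,
                            config = cfg)
  m <- transportedPoints(barycentricMap(pl, inst$tgt))
  set.seed(1); perm <- sample(nrow(inst$src))
  costP <- costMatrix(inst$src[perm, ], inst$tgt)
  plP <- groupLassoTransport(costP, sourceLabels = inst$srcLab[perm],
                             config = cfg)
  mP <- transportedPoints(barycentricMap(plP, inst$tgt))
  expect_equal(coupling(plP), coupling(pl)[perm, ], tolerance = 1e-7)
  expect_equal(mP, m[perm, ], tolerance = 1e-7)
})
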