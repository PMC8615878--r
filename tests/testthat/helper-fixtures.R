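# Shared fixtures, built once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

fixFilter <- function() fixture("filter", designLowpassFir())

# small clean cohort for unit-level checks
fixSmallCohort <- function() fixture("smallCohort", {
  cc <- cohortConfig(nSubjects = 3, nTrials = 24, noiseSd = 1.5,
                     alphaAmp = 1, seed = 11)
  generateCohort(cc, identityShifts(3))
})

fixSmallFeatures <- function() fixture("smallFeatures",
  lapply(fixSmallCohort(), buildFeatures, spec = fixFilter()))

# the headline study-scale cohort: 8 subjects x 96 trials with moderate
# per-subject covariate shifts (used by the acceptance-level checks)
studyCohortConfig <- function(seed = 1) cohortConfig(seed = seed)

fixStudyCohort <- function() fixture("studyCohort", {
  cc <- studyCohortConfig()
  generateCohort(cc, makeCohortShifts(cc@nSubjects, seed = cc@seed + 101))
})

fixStudyFeatures <- function() fixture("studyFeatures",
  lapply(fixStudyCohort(), buildFeatures, spec = fixFilter()))

# seeded random transport instance generator
randomOTInstance <- function(ns, nt, d = 2, seed = 1) {
  set.seed(seed)
  src <- matrix(rnorm(ns * d), ns, d)
  tgt <- matrix(rnorm(nt * d), nt, d)
  list(src = src, tgt = tgt, cost = costMatrix(src, tgt))
}

# two well-separated class-pure clusters in source and target
classClusterInstance <- function(nPerClass = 10, sep = 4, seed = 42) {
  set.seed(seed)
  lab <- rep(c("correct", "incorrect"), each = nPerClass)
  src <- rbind(matrix(rnorm(nPerClass * 2, 0), ncol = 2),
               matrix(rnorm(nPerClass * 2, sep), ncol = 2))
  tgt <- rbind(matrix(rnorm(nPerClass * 2, 0.5), ncol = 2),
               matrix(rnorm(nPerClass * 2, sep + 0.5), ncol = 2))
  list(src = src, tgt = tgt, srcLab = lab, tgtLab = lab,
       cost = costMatrix(src, tgt))
}
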