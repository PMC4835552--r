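# Shared fixture: maternal-rich config for decay-clock checks.
decayFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(nMaternal = 60L, nZygotic = 10L, nStable = 10L,
                              seed = 77)
      truth <- simulateReference(cfg)$truth
      cache <<- list(cfg = cfg, truth = truth, hl = trueHalfLives(truth),
                     cls = trueClasses(truth))
    }
    cache
  }
})

test_that("log2 fold-changes follow replicate means and closed forms", {
  a <- matrix(c(8, 2, 0), 3, dimnames = list(c("g1", "g2", "g3"), "s1"))
  expect_equal(unname(foldChanges(log2FoldChanges(a, a))), c(0, 0, 0))
  b <- a; b["g1", ] <- 16
  fc <- foldChanges(log2FoldChanges(a, b, pseudocount = 1e-9))
  expect_equal(unname(fc["g1"]), 1, tolerance = 1e-6)
  expect_equal(unname(fc["g2"]), 0)

  # replicate means are taken before the ratio
  a2 <- cbind(s1 = c(g1 = 2), s2 = c(g1 = 6))  # mean 4
  b2 <- cbind(s1 = c(g1 = 8))
  expect_equal(unname(foldChanges(log2FoldChanges(a2, b2,
                                                  pseudocount = 1e-9))),
               1, tolerance = 1e-6)
  expect_error(log2FoldChanges(a, matrix(1, 1, dimnames = list("zz", "s"))),
               "empty")
})

test_that("noise-free fold-changes equal -dt/halflife exactly", {
  fx <- decayFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 2, noiseDispersion = 0)$query
  fc <- log2FoldChanges(qa, qb, pseudocount = 1e-12)
  expect_equal(foldChanges(fc)[names(fx$hl)], -35 / fx$hl, tolerance = 1e-6)
})

test_that("extent of reduction anticorrelates perfectly with half-life", {
  fx <- decayFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 2, noiseDispersion = 0)$query
  fit <- halfLifeCorrelation(log2FoldChanges(qa, qb, pseudocount = 1e-12),
                             fx$hl, fx$cls)
  expect_identical(fit@spearman, -1)
  expect_false(fit@degenerate)
  expect_identical(fit@nGenes, length(fx$hl))

  # dt = 0: all extents zero, correlation undefined, reported as 0 + flag
  fit0 <- halfLifeCorrelation(log2FoldChanges(qa, qa), fx$hl, fx$cls)
  expect_identical(fit0@spearman, 0)
  expect_true(fit0@degenerate)
})

test_that("shuffled half-lives show no correlation (permutation null)", {
  fx <- decayFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 5)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 6)$query
  fc <- log2FoldChanges(qa, qb, pseudocount = 1e-6)
  set.seed(99)
  rhos <- replicate(200, {
    shuffled <- setNames(sample(fx$hl), names(fx$hl))
    halfLifeCorrelation(fc, shuffled, fx$cls)@spearman
  })
  expect_gte(mean(abs(rhos) <= 0.3), 0.95)  # n = 60 null sd ~ 0.13
})

test_that("decay clock recovers planted offsets exactly without noise", {
  fx <- decayFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 2, noiseDispersion = 0)$query
  fc <- log2FoldChanges(qa, qb, pseudocount = 1e-12)
  fit <- estimateDeltaTimeDecay(fc, fx$hl, fx$cls)
  expect_equal(deltaT(fit), 35, tolerance = 1e-6)
  expect_lt(fit@residualSd, 1e-6)
  expect_identical(fit@nExcluded, 0L)

  # all fold-changes zero -> offset zero
  fit0 <- estimateDeltaTimeDecay(log2FoldChanges(qa, qa), fx$hl, fx$cls)
  expect_identical(deltaT(fit0), 0)

  # antisymmetry on the genes surviving the induction filter
  fcBA <- log2FoldChanges(qb, qa, pseudocount = 1e-12)
  fitBA <- estimateDeltaTimeDecay(fcBA, fx$hl, fx$cls)
  expect_equal(deltaT(fitBA), -35, tolerance = 1e-6)
  expect_gt(fitBA@nExcluded, 0L)  # short-lived genes look "induced" reversed

  # free-intercept mode absorbs a global normalization offset
  shifted <- new("FoldChangeTable", log2fc = foldChanges(fc) + 0.3,
                 pseudocount = 1e-12, conditions = c("A", "B"))
  fitFree <- estimateDeltaTimeDecay(shifted, fx$hl, fx$cls,
                                    fitMode = "free-intercept")
  expect_equal(deltaT(fitFree), 35, tolerance = 1e-6)
  expect_equal(fitFree@intercept, 0.3, tolerance = 1e-6)
})

test_that("fold-changes and fits are invariant to a common scale", {
  fx <- decayFixture()
  qa <- refAssay(simulateQuery(fx$cfg, 95, seed = 3)$query)
  qb <- refAssay(simulateQuery(fx$cfg, 130, seed = 4)$query)
  fc1 <- log2FoldChanges(qa, qb, pseudocount = 1e-9)
  fc2 <- log2FoldChanges(qa * 100, qb * 100, pseudocount = 1e-7)
  expect_equal(foldChanges(fc1), foldChanges(fc2), tolerance = 1e-5)
  f1 <- estimateDeltaTimeDecay(fc1, fx$hl, fx$cls)
  f2 <- estimateDeltaTimeDecay(fc2, fx$hl, fx$cls)
  expect_equal(deltaT(f1), deltaT(f2), tolerance = 1e-4)
})

test_that("the robust slope resists planted outliers", {
  fx <- decayFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 2, noiseDispersion = 0)$query
  fc <- foldChanges(log2FoldChanges(qa, qb, pseudocount = 1e-12))
  # corrupt 10% of the maternal genes downwards (evades the induction filter)
  bad <- names(fx$hl)[1:6]
  fc[bad] <- fc[bad] - 5
  corrupted <- new("FoldChangeTable", log2fc = fc, pseudocount = 1e-12,
                   conditions = c("A", "B"))
  ls <- estimateDeltaTimeDecay(corrupted, fx$hl, fx$cls)
  rb <- estimateDeltaTimeDecay(corrupted, fx$hl, fx$cls, robust = TRUE)
  expect_lt(abs(deltaT(rb) - 35), abs(deltaT(ls) - 35))
  expect_equal(deltaT(rb), 35, tolerance = 1)
})

test_that("the two clocks agree on decay-only simulated data", {
  cfg <- simulationConfig(seed = 42)
  sim <- simulateReference(cfg)
  ruler <- compileRuler(sim$reference, trueClasses(sim$truth))
  qa <- simulateQuery(cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(cfg, 130, seed = 2, noiseDispersion = 0)$query
  stage <- deltaT(deltaTime(estimateStage(qa, sim$reference, ruler),
                            estimateStage(qb, sim$reference, ruler)))
  decay <- deltaT(estimateDeltaTimeDecay(
    log2FoldChanges(qa, qb, pseudocount = 1e-12),
    trueHalfLives(sim$truth), trueClasses(sim$truth)))
  expect_lte(abs(stage - decay), 2)
})

test_that("insufficient usable genes raise errors", {
  fc <- new("FoldChangeTable", log2fc = c(m1 = -1, m2 = -0.5),
            pseudocount = 0.5, conditions = c("A", "B"))
  cls <- geneClasses(maternal = c("m1", "m2"))
  hl <- c(m1 = 30, m2 = 60)
  expect_error(halfLifeCorrelation(fc, hl, cls), ">= 3")
  expect_error(estimateDeltaTimeDecay(fc, hl, cls), ">= 3")
})
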