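# Shared fixture: a default-grid reference with its ruler.
stagerFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(nMaternal = 120L, nZygotic = 30L, nStable = 20L,
                              seed = 101)
      sim <- simulateReference(cfg)
      ruler <- compileRuler(sim$reference, trueClasses(sim$truth))
      cache <<- list(cfg = cfg, reference = sim$reference, truth = sim$truth,
                     ruler = ruler)
    }
    cache
  }
})

test_that("every reference column maps to its own stage with similarity 1", {
  fx <- stagerFixture()
  ests <- estimateStage(fx$reference, fx$reference, fx$ruler)
  for (j in seq_along(ests)) {
    sims <- similarityProfile(ests[[j]])
    expect_equal(unname(sims[j]), 1, tolerance = 1e-12)
    expect_identical(bestStages(ests[[j]]), stageLabels(fx$reference)[j])
    expect_lt(max(sims[-j]), sims[j])
    expect_equal(interpTimes(ests[[j]]),
                 unname(stageTimes(fx$reference)[j]), tolerance = 1e-9)
  }
})

test_that("rank reversal of a stage profile gives Spearman -1", {
  fx <- stagerFixture()
  genes <- rulerGenes(fx$ruler)
  v <- refAssay(fx$reference)[genes, 3L]
  reversed <- setNames(sort(v)[rank(-v, ties.method = "first")], genes)
  sims <- stageSimilarity(reversed, fx$reference, fx$ruler)
  expect_equal(unname(sims[3L]), -1, tolerance = 1e-12)
})

test_that("similarity is invariant to positive scaling of the query", {
  fx <- stagerFixture()
  q <- simulateQuery(fx$cfg, 112, seed = 5)$query
  s1 <- stageSimilarity(q, fx$reference, fx$ruler)
  s2 <- stageSimilarity(refAssay(q) * 7.3, fx$reference, fx$ruler)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("constant query profiles are rejected", {
  fx <- stagerFixture()
  genes <- rulerGenes(fx$ruler)
  flat <- setNames(rep(5, length(genes)), genes)
  expect_error(stageSimilarity(flat, fx$reference, fx$ruler), "constant")
})

test_that("normalization recovers planted scale factors via ruler genes", {
  fx <- stagerFixture()
  # query = 2x a reference column: factor 0.5, ruler genes restored
  q2 <- refAssay(fx$reference)[, 4L, drop = FALSE] * 2
  colnames(q2) <- "q"
  norm <- normalizeToReference(q2, fx$reference, fx$ruler)
  expect_equal(unname(SummarizedExperiment::colData(norm)$scaleFactor), 0.5, tolerance = 1e-9)
  expect_equal(refAssay(norm)[rulerGenes(fx$ruler), 1L],
               refAssay(fx$reference)[rulerGenes(fx$ruler), 4L],
               tolerance = 1e-9)

  # identity: a matching query gets factor 1
  q1 <- refAssay(fx$reference)[, 4L, drop = FALSE]
  colnames(q1) <- "q"
  expect_equal(unname(SummarizedExperiment::colData(normalizeToReference(
    q1, fx$reference, fx$ruler))$scaleFactor), 1, tolerance = 1e-9)

  # planted library-size multipliers at off-grid times, zero noise
  for (L in c(0.25, 0.8, 4)) {
    q <- simulateQuery(fx$cfg, 122, seed = 1, noiseDispersion = 0,
                       libraryFactors = L)$query
    f <- unname(SummarizedExperiment::colData(normalizeToReference(q, fx$reference,
                                             fx$ruler))$scaleFactor)
    expect_equal(f, 1 / L, tolerance = 0.02)
  }
  expect_error(normalizeToReference(q2[1:3, , drop = FALSE], fx$reference,
                                    fx$ruler), "ruler gene")
})

test_that("noise-free off-grid queries are recovered to grid resolution", {
  fx <- stagerFixture()
  q <- simulateQuery(fx$cfg, 132, seed = 1, noiseDispersion = 0)$query
  est <- estimateStage(q, fx$reference, fx$ruler)
  expect_lte(abs(interpTimes(est)[[1L]] - 132), 1)
  # a noise-free midpoint query lands on one of the flanking stages
  st <- stageTimes(fx$reference)
  qm <- simulateQuery(fx$cfg, (st[[3L]] + st[[4L]]) / 2, seed = 1,
                      noiseDispersion = 0)$query
  em <- estimateStage(qm, fx$reference, fx$ruler)
  expect_true(bestStages(em)[[1L]] %in% names(st)[3:4])
})

test_that("interpolated time is monotone in true time (noise-free)", {
  fx <- stagerFixture()
  times <- seq(62, 168, by = 7)
  ests <- vapply(times, function(tt)
    interpTimes(estimateStage(simulateQuery(fx$cfg, tt, seed = 1,
                                            noiseDispersion = 0)$query,
                              fx$reference, fx$ruler))[[1L]], numeric(1L))
  expect_true(all(diff(ests) >= 0))
  expect_lte(max(abs(ests - times)), 1)
})

test_that("parabola interpolation stays within a stage spacing of truth", {
  fx <- stagerFixture()
  q <- simulateQuery(fx$cfg, 110, seed = 1, noiseDispersion = 0)$query
  est <- estimateStage(q, fx$reference, fx$ruler, interpMethod = "parabola")
  expect_lte(abs(interpTimes(est)[[1L]] - 110), 10)
})

test_that("delta time is antisymmetric and exact on planted offsets", {
  fx <- stagerFixture()
  qa <- simulateQuery(fx$cfg, 95, seed = 1, noiseDispersion = 0)$query
  qb <- simulateQuery(fx$cfg, 130, seed = 2, noiseDispersion = 0)$query
  ea <- estimateStage(qa, fx$reference, fx$ruler)
  eb <- estimateStage(qb, fx$reference, fx$ruler)
  dtAB <- deltaTime(ea, eb)
  expect_equal(deltaT(dtAB), 35, tolerance = 2)
  expect_identical(deltaT(deltaTime(eb, ea)), -deltaT(dtAB))
  expect_identical(deltaT(deltaTime(ea, ea)), 0)

  other <- ReferenceTimecourse(refAssay(fx$reference),
                               stageLabels(fx$reference),
                               stageTimes(fx$reference) + 1)
  eo <- estimateStage(qa, other, fx$ruler)
  expect_error(deltaTime(ea, eo), "different reference")
})

test_that("stage-matched profiles interpolate geometrically", {
  fx <- stagerFixture()
  # exact stage: the column verbatim
  est <- estimateStage(refAssay(fx$reference)[, 5L, drop = FALSE],
                       fx$reference, fx$ruler)[[1L]]
  expect_equal(stageMatchedProfile(fx$reference, est),
               refAssay(fx$reference)[, 5L], tolerance = 1e-9)

  # closed form: midway between 100 and 25 is the geometric mean, 50
  vals <- rbind(g1 = c(100, 25), g2 = c(4, 16))
  ref <- ReferenceTimecourse(vals, c("a", "b"), c(0, 10))
  prof <- stageMatchedProfile(ref, 5)
  expect_equal(unname(prof), c(50, 8), tolerance = 1e-12)
  expect_warning(stageMatchedProfile(ref, 20), "clamped")

  # self-consistency: noise-free query matches its own matched profile
  q <- simulateQuery(fx$cfg, 126, seed = 1, noiseDispersion = 0)$query
  estq <- estimateStage(q, fx$reference, fx$ruler)[[1L]]
  matched <- stageMatchedProfile(fx$reference, estq)
  genes <- rulerGenes(fx$ruler)
  expect_equal(log2(matched[genes] + 0.5),
               log2(refAssay(q)[genes, 1L] + 0.5), tolerance = 0.05)
})

test_that("replicate estimates are summarized by the median", {
  fx <- stagerFixture()
  q <- simulateQuery(fx$cfg, 108, nReplicates = 5, seed = 9)$query
  ests <- estimateStage(q, fx$reference, fx$ruler)
  expect_length(ests, 5L)
  cons <- consensusEstimate(ests)
  expect_identical(interpTimes(cons), median(interpTimes(ests)))
})

test_that("bootstrap staging uncertainty behaves as expected", {
  fx <- stagerFixture()
  # noise-free exact-stage query: discrete staging has zero bootstrap sd
  q <- refAssay(fx$reference)[, 4L, drop = FALSE]
  colnames(q) <- "q"
  b0 <- bootstrapStage(q, fx$reference, fx$ruler, nBoot = 100, seed = 1,
                       interpolate = FALSE)
  expect_identical(b0@bootstrapSd, 0)
  # interpolated: still within grid jitter of zero
  b1 <- bootstrapStage(q, fx$reference, fx$ruler, nBoot = 100, seed = 1)
  expect_lte(b1@bootstrapSd, 1)
  # seed determinism
  b2 <- bootstrapStage(q, fx$reference, fx$ruler, nBoot = 100, seed = 1)
  expect_identical(b1@params$bootTimes, b2@params$bootTimes)

  # precision grows with ruler size (20 vs 200 genes, noisy query)
  cfg <- simulationConfig(seed = 42)
  sim <- simulateReference(cfg)
  ruler <- rulerGenes(compileRuler(sim$reference, trueClasses(sim$truth)))
  qn <- simulateQuery(cfg, 112, seed = 31)$query
  sdSmall <- bootstrapStage(qn, sim$reference, ruler[1:20],
                            nBoot = 100, seed = 5)@bootstrapSd
  sdLarge <- bootstrapStage(qn, sim$reference, ruler[1:200],
                            nBoot = 100, seed = 5)@bootstrapSd
  expect_lt(sdLarge, sdSmall)
})
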