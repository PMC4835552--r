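test_that("noise-free expression follows the decay and activation laws", {
  cfg <- smallConfig(seed = 3)
  truth <- simulateReference(cfg)$truth
  hl <- trueHalfLives(truth)
  m0 <- expectedExpression(cfg, names(hl), times = 0)[, 1L]

  # one half-life halves the abundance; three quarter it three times
  m_hl <- vapply(names(hl), function(g)
    expectedExpression(cfg, g, times = hl[[g]])[1L, 1L], numeric(1L))
  expect_equal(m_hl, m0 / 2, tolerance = 1e-12)
  m_3hl <- vapply(names(hl), function(g)
    expectedExpression(cfg, g, times = 3 * hl[[g]])[1L, 1L], numeric(1L))
  expect_equal(m_3hl, m0 / 8, tolerance = 1e-12)

  # logistic midpoint: zygotic genes sit at half their plateau at onset
  cl <- truth@geneClass
  zyg <- names(cl)[cl == "zygotic"]
  z_on <- expectedExpression(cfg, zyg, times = cfg@onsetTime)[, 1L]
  z_inf <- expectedExpression(cfg, zyg, times = 1e6)[, 1L]
  expect_equal(z_on, z_inf / 2, tolerance = 1e-9)

  # closed-form decay cross-checked by numerically integrating dm/dt
  skip_if_not_installed("deSolve")
  g <- names(hl)[1L]
  ode <- deSolve::ode(y = c(m = m0[[g]]), times = c(0, 60),
                      func = function(t, y, p) list(-log(2) / p * y),
                      parms = hl[[g]], method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(ode[2L, "m"]),
               expectedExpression(cfg, g, times = 60)[1L, 1L],
               tolerance = 1e-7)
})

test_that("maternal trajectories strictly decrease, zygotic strictly increase", {
  cfg <- smallConfig(seed = 9)
  grid <- seq(0, 240, by = 10)
  vals <- expectedExpression(cfg, times = grid)
  cl <- simulateReference(cfg)$truth@geneClass
  for (g in rownames(vals)) {
    d <- diff(vals[g, ])
    if (cl[[g]] == "maternal") expect_true(all(d < 0))
    else if (cl[[g]] == "zygotic") expect_true(all(d > 0))
    else expect_true(all(d == 0))
  }
})

test_that("noise-free decay conserves log2 ratios exactly", {
  cfg <- smallConfig(seed = 5)
  truth <- simulateReference(cfg)$truth
  hl <- trueHalfLives(truth)
  ta <- 130; tb <- 72.5
  va <- expectedExpression(cfg, names(hl), ta)[, 1L]
  vb <- expectedExpression(cfg, names(hl), tb)[, 1L]
  expect_equal(log2(va / vb), -(ta - tb) / hl, tolerance = 1e-10)
})

test_that("unknown gene ids and negative times are rejected by name", {
  cfg <- smallConfig()
  expect_error(expectedExpression(cfg, "nonexistent_gene", 10),
               "nonexistent_gene")
  expect_error(expectedExpression(cfg, times = -5), "times")
  expect_error(simulateQuery(cfg, trueTime = -1), "trueTime")
})

test_that("reference columns equal expected expression when noise is off", {
  cfg <- smallConfig(seed = 2)
  sim <- simulateReference(cfg)
  expect_identical(refAssay(sim$reference),
                   unname2 <- {
                     m <- expectedExpression(cfg, times = cfg@referenceTimes)
                     colnames(m) <- cfg@stageLabels
                     m
                   })
  expect_identical(unname(stageTimes(sim$reference)), cfg@referenceTimes)
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- smallConfig(seed = 11)
  expect_identical(simulateReference(cfg, noise = TRUE),
                   simulateReference(cfg, noise = TRUE))
  q1 <- simulateQuery(cfg, 100, nReplicates = 4, seed = 77)
  q2 <- simulateQuery(cfg, 100, nReplicates = 4, seed = 77)
  expect_identical(refAssay(q1$query), refAssay(q2$query))
  expect_equal(ncol(q1$query), 4L)
  expect_false(any(duplicated(t(refAssay(q1$query)))))
  # a different seed gives different noise
  q3 <- simulateQuery(cfg, 100, nReplicates = 4, seed = 78)
  expect_false(identical(refAssay(q1$query), refAssay(q3$query)))
})

test_that("realized half-lives follow the configured log-normal", {
  cfg <- simulationConfig(nMaternal = 200L, nZygotic = 5L, nStable = 5L,
                          seed = 21)
  hl <- trueHalfLives(simulateReference(cfg)$truth)
  expect_length(hl, 200L)
  expect_true(all(hl > 0))
  # two-sample style check against the stated distribution at alpha = 0.01
  ks <- ks.test(hl, "plnorm", meanlog = log(2) * cfg@halflifeLog2Mean,
                sdlog = log(2) * cfg@halflifeLog2Sd)
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate noise reproduces the reference; replicate means converge", {
  cfg <- smallConfig(seed = 4)
  sim <- simulateReference(cfg)
  q <- simulateQuery(cfg, trueTime = cfg@referenceTimes[3L], seed = 1,
                     noiseDispersion = 0)
  expect_equal(refAssay(q$query)[, 1L],
               setNames(refAssay(sim$reference)[, 3L], rownames(sim$reference)))

  qq <- simulateQuery(cfg, 100, nReplicates = 50, seed = 13,
                      noiseDispersion = 0.2)
  mu <- expectedExpression(cfg, times = 100)[, 1L]
  relErr <- abs(rowMeans(refAssay(qq$query)) - mu) / mu
  expect_gte(mean(relErr <= 0.05), 0.95)
})

test_that("count mode produces integer Poisson observations", {
  cfg <- smallConfig(seed = 6)
  q <- simulateQuery(cfg, 100, nReplicates = 3, seed = 2, mode = "counts",
                     libraryFactors = 10)
  vals <- refAssay(q$query)
  expect_true(all(vals == round(vals)))
  expect_identical(S4Vectors::metadata(q$query)$unit, "counts")
})

test_that("planted condition effects shift the expected mean", {
  cfg <- smallConfig(seed = 8)
  g <- rownames(simulateReference(cfg)$reference)[1L]
  q0 <- simulateQuery(cfg, 100, seed = 1, noiseDispersion = 0)
  q1 <- simulateQuery(cfg, 100, seed = 1, noiseDispersion = 0,
                      effectLog2 = setNames(1, g))
  expect_equal(refAssay(q1$query)[g, 1L], 2 * refAssay(q0$query)[g, 1L])
  other <- setdiff(rownames(q0$query), g)
  expect_equal(refAssay(q1$query)[other, ], refAssay(q0$query)[other, ])
  expect_error(simulateQuery(cfg, 100, effectLog2 = c(bogus_gene = 1)),
               "bogus_gene")
})
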