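test_that("a source sample identical to the single-target sample has value 1", {
  sp <- smallSplit(n = 5, d = 4, nTarget = 1)
  s <- sp$tgt   # single sample used as both source and target
  dv <- runDVGS(s, s, task = "classification",
                config = dvgsConfig(nIterations = 10, targetBatchSize = 1,
                                    baseSeed = 3, recordPerIteration = TRUE))
  expect_equal(unname(dataValues(dv)), 1, tolerance = 1e-12)
  expect_true(all(abs(perIteration(dv)[[1]] - 1) < 1e-12))
})

test_that("byte-identical source samples get identical values; all values in [-1,1]", {
  sp <- smallSplit(n = 40, d = 5, nTarget = 20)
  src <- list(X = rbind(sp$src$X, sp$src$X[3, ]),
              y = c(sp$src$y, sp$src$y[3]))
  dv <- runDVGS(src, sp$tgt, task = "classification",
                config = dvgsConfig(nIterations = 30, baseSeed = 1))
  v <- dataValues(dv)
  expect_identical(unname(v[3]), unname(v[41]))
  expect_true(all(v >= -1 & v <= 1))
})

test_that("recording does not perturb the SGD trajectory", {
  sp <- smallSplit(n = 20, d = 5, nTarget = 24)
  cfgDense <- dvgsConfig(nIterations = 24, similarityPeriod = 1, baseSeed = 9)
  cfgSparse <- dvgsConfig(nIterations = 24, similarityPeriod = 24, baseSeed = 9)
  d1 <- runDVGS(sp$src, sp$tgt, task = "classification", config = cfgDense)
  d2 <- runDVGS(sp$src, sp$tgt, task = "classification", config = cfgSparse)
  expect_identical(d1@extra$finalParameters, d2@extra$finalParameters)
})

test_that("period-T recording keeps floor(N/T) snapshots and the same value scale", {
  sp <- smallSplit(n = 30, d = 5, nTarget = 20)
  for (Tp in c(1L, 3L, 5L)) {
    dv <- runDVGS(sp$src, sp$tgt, task = "classification",
                  config = dvgsConfig(nIterations = 20, similarityPeriod = Tp,
                                      baseSeed = 2, recordPerIteration = TRUE))
    expect_equal(dv@nRecords, 20L %/% Tp)
    expect_equal(ncol(perIteration(dv)[[1]]), 20L %/% Tp)
    expect_equal(unname(dataValues(dv)),
                 unname(rowMeans(perIteration(dv)[[1]])))
  }
  expect_error(dvgsConfig(nIterations = 5, similarityPeriod = 6),
               "similarityPeriod")
})

test_that("multi-run values are the grand mean over runs and reproducible", {
  sp <- smallSplit(n = 25, d = 5, nTarget = 20)
  cfg2 <- dvgsConfig(nIterations = 16, nRuns = 2, baseSeed = 5,
                     recordPerIteration = TRUE)
  dv <- runDVGS(sp$src, sp$tgt, task = "classification", config = cfg2)
  manual <- rowMeans(cbind(perIteration(dv)[[1]], perIteration(dv)[[2]]))
  expect_equal(unname(dataValues(dv)), unname(manual))
  dv2 <- runDVGS(sp$src, sp$tgt, task = "classification", config = cfg2)
  expect_identical(dataValues(dv), dataValues(dv2))
  # runs differ from each other (fresh init per run)
  expect_false(identical(perIteration(dv)[[1]], perIteration(dv)[[2]]))
})

test_that("aggregateRuns pools by recorded-count weights", {
  mk <- function(vals, nrec) {
    new("DataValues", values = vals, nRecords = as.integer(nrec),
        method = "dvgs")
  }
  one <- mk(c(0.2, -0.1), 4L)
  expect_equal(dataValues(aggregateRuns(list(one))), c(0.2, -0.1))
  sym <- aggregateRuns(list(mk(c(0.5, 0.3), 3L), mk(c(-0.5, -0.3), 3L)))
  expect_equal(dataValues(sym), c(0, 0))
  wtd <- aggregateRuns(list(mk(c(1.0, 1.0), 2L), mk(c(0.4, 0.4), 1L)))
  expect_equal(dataValues(wtd), c(0.8, 0.8))
  expect_error(aggregateRuns(list(one, mk(c(1, 2, 3), 1L))), "source sizes")
})

test_that("fast and loop gradient paths give identical valuations", {
  sp <- smallSplit(n = 30, d = 5, nTarget = 16)
  base <- dvgsConfig(nIterations = 12, baseSeed = 4)
  loopCfg <- dvgsConfig(nIterations = 12, baseSeed = 4,
                        gradientMethod = "loop")
  vFast <- dataValues(runDVGS(sp$src, sp$tgt, task = "classification",
                              config = base))
  vLoop <- dataValues(runDVGS(sp$src, sp$tgt, task = "classification",
                              config = loopCfg))
  expect_equal(vFast, vLoop, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with clear errors", {
  sp <- smallSplit(n = 10, d = 5, nTarget = 5)
  expect_error(runDVGS(list(X = sp$src$X[0, , drop = FALSE], y = integer()),
                       sp$tgt, task = "classification"), "non-empty")
  expect_error(runDVGS(sp$src, list(X = sp$tgt$X[, 1:3], y = sp$tgt$y),
                       task = "classification"), "dimensionalities")
})
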