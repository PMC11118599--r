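test_that("random values are seeded, in (0,1), and null-calibrated", {
  r1 <- randomValues(1000, seed = 5)
  r2 <- randomValues(1000, seed = 5)
  expect_identical(dataValues(r1), dataValues(r2))
  expect_true(all(dataValues(r1) > 0 & dataValues(r1) < 1))
  expect_error(randomValues(0), "n")

  # AUROC against a 20% corruption mask is centred at 0.5 over reps
  aurocs <- vapply(1:25, function(s) {
    mask <- integer(500)
    mask[seq_len(100)] <- 1L
    corruptionAUROC(mask, randomValues(500, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})

test_that("leave-one-out matches the closed-form mean-predictor example", {
  # source targets {0, 10}, target {0}, negative MSE:
  # full model predicts 5 (score -25); drop y=0 -> predict 10 (score -100),
  # v1 = -25 - (-100) = 75; drop y=10 -> predict 0 (score 0), v2 = -25.
  src <- list(X = matrix(c(1, 2), 2, 1), y = c(0, 10))
  tgt <- list(X = matrix(3, 1, 1), y = 0)
  dv <- looValues(meanLearner(), src, tgt, metric = "negmse")
  expect_equal(unname(dataValues(dv)), c(75, -25))
  expect_equal(dv@extra$fullScore, -25)
})

test_that("leave-one-out values are symmetric for duplicated samples and shrink with redundancy", {
  tgt <- list(X = matrix(3, 1, 1), y = 0)
  # unique y=10 among {10, 0}: full mean 5 (score -25), drop it -> 0
  # (score 0), so v = -25
  srcU <- list(X = matrix(1:2, 2, 1), y = c(10, 0))
  vU <- dataValues(looValues(meanLearner(), srcU, tgt))
  expect_equal(unname(vU[1]), -25)
  # duplicated: {10, 10, 0}: full mean 20/3 (score -400/9), drop one 10
  # -> mean 5 (score -25), so v = -400/9 + 25 = -175/9
  srcD <- list(X = matrix(1:3, 3, 1), y = c(10, 10, 0))
  vD <- dataValues(looValues(meanLearner(), srcD, tgt))
  expect_equal(unname(vD[1]), unname(vD[2]))     # duplicates equal
  expect_equal(unname(vD[1]), -400 / 9 + 25)
  expect_lt(abs(vD[1]), abs(vU[1]))              # redundancy shrinks |value|
})

test_that("exact Shapley matches the independent enumeration oracle", {
  srcY <- c(0, 10)
  tgtY <- 0
  dv <- exactShapley(meanLearner(),
                     list(X = matrix(1:2, 2, 1), y = srcY),
                     list(X = matrix(3, 1, 1), y = tgtY))
  expect_equal(unname(dataValues(dv)), bruteForceShapleyMean(srcY, tgtY))
  expect_equal(unname(dataValues(dv)), c(37.5, -62.5))  # hand-computed

  srcY3 <- c(1, 5, -2)
  tgtY3 <- c(0, 2)
  dv3 <- exactShapley(meanLearner(),
                      list(X = matrix(1:3, 3, 1), y = srcY3),
                      list(X = matrix(1:2, 2, 1), y = tgtY3))
  expect_equal(unname(dataValues(dv3)), bruteForceShapleyMean(srcY3, tgtY3))
})

test_that("TMC Shapley approaches exact Shapley and satisfies efficiency on a 3-sample toy", {
  src <- list(X = matrix(1:3, 3, 1), y = c(1, 5, -2))
  tgt <- list(X = matrix(1:2, 2, 1), y = c(0, 2))
  exact <- dataValues(exactShapley(meanLearner(), src, tgt))
  # enumerating all 3! permutations with truncation 0 reproduces exact
  # Shapley
  est <- tmcShapley(meanLearner(), src, tgt,
                    config = shapleyConfig(truncationTolerance = 0,
                                           exhaustive = TRUE, seed = 11))
  expect_lt(max(abs(dataValues(est) - exact)), 0.01)
  expect_equal(est@extra$nPermutations, 6)
  # efficiency: sum of values ~ score(full) - score(empty)
  expect_lt(abs(sum(dataValues(est)) -
                (est@extra$fullScore - est@extra$nullScore)), 1e-8)
})

test_that("TMC Shapley gives near-equal values to identical samples (symmetry)", {
  src <- list(X = matrix(1, 4, 1), y = rep(3, 4))
  tgt <- list(X = matrix(1, 2, 1), y = c(2, 4))
  est <- tmcShapley(meanLearner(), src, tgt,
                    config = shapleyConfig(maxPermutations = 2000,
                                           truncationTolerance = 0,
                                           convergenceTolerance = 0,
                                           seed = 3))
  v <- dataValues(est)
  # exact Shapley gives all four samples 9/4; Monte-Carlo noise only
  expect_lt(diff(range(v)), 0.4)
  expect_equal(unname(mean(v)), 9 / 4, tolerance = 1e-8)  # efficiency/4
  expect_false(est@extra$converged)  # tolerance 0 never declares convergence
})

test_that("TMC Shapley reports early convergence under a loose tolerance", {
  src <- list(X = matrix(1, 4, 1), y = rep(3, 4))
  tgt <- list(X = matrix(1, 2, 1), y = c(2, 4))
  est <- tmcShapley(meanLearner(), src, tgt,
                    config = shapleyConfig(maxPermutations = 2000,
                                           truncationTolerance = 0,
                                           convergenceTolerance = 0.05,
                                           seed = 3))
  expect_true(est@extra$converged)
  expect_lt(est@extra$nPermutations, 2000)
})
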