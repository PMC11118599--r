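test_that("corruption AUROC hits its boundary cases and complement identity", {
  mask <- c(rep(0L, 8), rep(1L, 2))
  expect_equal(corruptionAUROC(mask, 1 - mask), 1)   # corrupted lowest
  expect_equal(corruptionAUROC(mask, mask), 0)       # inverted
  set.seed(4)
  v <- rnorm(10)
  expect_equal(corruptionAUROC(mask, v) + corruptionAUROC(mask, -v), 1)
  expect_error(corruptionAUROC(rep(0L, 5), rnorm(5)), "both classes")
  expect_error(corruptionAUROC(mask, rnorm(3)), "length")
})

test_that("AUROC is invariant under strictly monotone transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    mask <- rbinom(60, 1, 0.3)
    if (length(unique(mask)) < 2) next
    v <- rnorm(60)
    a <- corruptionAUROC(mask, v)
    expect_equal(corruptionAUROC(mask, exp(v)), a)       # monotone transform
    expect_equal(corruptionAUROC(mask, rank(v)), a)
    ref <- as.numeric(pROC::auc(pROC::roc(mask, -v, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("noise Spearman hits boundaries and monotone invariance", {
  phi <- c(0.1, 0.5, 0.9, 1.3, 2.0)
  expect_equal(noiseSpearman(phi, -phi), 1)
  expect_equal(noiseSpearman(phi, phi), -1)
  set.seed(2)
  v <- rnorm(5)
  expect_equal(noiseSpearman(phi, v), noiseSpearman(exp(phi), v))
  expect_equal(noiseSpearman(phi, v), noiseSpearman(phi, v^3 + 5 * v))
  expect_error(noiseSpearman(rep(1, 5), v), "constant")
  expect_error(noiseSpearman(phi[1:2], v[1:2]), "3 samples")
})

test_that("random values give null AUROC ~0.5 and null Spearman ~0", {
  aurocs <- numeric(20)
  rhos <- numeric(20)
  for (s in 1:20) {
    mask <- integer(1000)
    mask[1:200] <- 1L
    rv <- randomValues(1000, seed = 100 + s)
    aurocs[s] <- corruptionAUROC(mask, rv)
    phi <- withr::with_seed(200 + s, runif(1000))
    rhos[s] <- noiseSpearman(phi, rv)
  }
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
  expect_lt(abs(mean(rhos)), 0.026)
})

test_that("APC identities: identical, antipodal, and independent-noise replicates", {
  r <- rnorm(978)
  res1 <- apc(rbind(r, r), groups = c("g", "g"))
  expect_equal(unname(apcValues(res1)), 1)
  res2 <- apc(rbind(r, -r), groups = c("g", "g"))
  expect_equal(unname(apcValues(res2)), -1)
  set.seed(8)
  noise <- matrix(rnorm(4 * 978), 4, 978)
  res3 <- apc(noise, groups = rep("g", 4))
  expect_lt(abs(unname(apcValues(res3))), 0.1)
})

test_that("APC handles singleton groups, constant replicates, and shift/scale invariance", {
  set.seed(9)
  r <- rnorm(50)
  M <- rbind(r, r + rnorm(50, sd = 0.1), rep(1, 50), r, 3 * r + 7)
  res <- apc(M, groups = c("a", "a", "a", "b", "b"))
  v <- apcValues(res)
  # constant replicate drops its two pairs from group a's mean
  expect_equal(res@nDroppedPairs[1], 2L)
  expect_equal(unname(v["b"]), 1)             # positive affine invariance
  single <- apc(rbind(M, rnorm(50)), groups = c("a", "a", "a", "b", "b", "c"))
  expect_true(is.na(apcValues(single)["c"]))  # < 2 replicates -> NA
})

test_that("APC partition uses a strict threshold split", {
  res <- new("ApcResult", groupIds = c("g1", "g2", "g3"),
             apc = c(0.9, 0.5, 0.1), nReplicates = rep(3L, 3),
             nDroppedPairs = rep(0L, 3))
  p <- apcPartition(res, 0.5)
  expect_equal(p$high, "g1")
  expect_equal(p$low, c("g2", "g3"))          # 0.5 itself is low
  expect_equal(apcPartition(res, -1)$high, c("g1", "g2", "g3"))
  resNA <- new("ApcResult", groupIds = "g", apc = NA_real_,
               nReplicates = 1L, nDroppedPairs = 0L)
  expect_equal(apcPartition(resNA, 0.5)$undefined, "g")
})

test_that("filter-and-retrain has the contract shape and a no-op fraction 0", {
  sp <- smallSplit(n = 80, d = 5, nTarget = 40)
  lrn <- mlpLearner(hiddenDim = 10, epochs = 5)
  v <- seq_len(80) / 80
  fLow <- filterAndRetrain(v, sp$src, sp$tgt, lrn, metric = "auroc",
                           fractions = c(0, 0.2, 0.4), reps = 2, seed = 1)
  expect_equal(dim(curveScores(fLow)), c(2, 3))
  fHigh <- filterAndRetrain(v, sp$src, sp$tgt, lrn, metric = "auroc",
                            fractions = c(0, 0.2, 0.4),
                            direction = "remove_highest", reps = 2, seed = 1)
  # fraction 0 trains on all data in both directions: identical scores
  expect_equal(curveScores(fLow)[, 1], curveScores(fHigh)[, 1])
  df <- as.data.frame(fLow)
  expect_equal(nrow(df), 6)
  expect_error(filterAndRetrain(v, sp$src, sp$tgt, lrn,
                                fractions = c(0.1, 0.2)), "start at 0")
})

test_that("filtering truly corrupted labels out improves test AUROC", {
  sp <- smallSplit(n = 150, d = 6, separation = 4, seed = 13, nTarget = 80)
  fl <- flipLabels(sp$src$y, 0.2, seed = 14)
  srcC <- list(X = sp$src$X, y = fl$y)
  oracle <- 1 - fl$mask            # corrupted samples get the lowest values
  lrn <- mlpLearner(hiddenDim = 20, epochs = 20)
  fc <- filterAndRetrain(oracle, srcC, sp$tgt, lrn, metric = "auroc",
                         fractions = c(0, 0.2), reps = 2, seed = 2)
  m <- colMeans(curveScores(fc))
  expect_gt(m[2], m[1])
})
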