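test_that("cosine similarity identities: self, antipodal, orthogonal, zero-norm", {
  g <- c(0.3, -1.2, 2.5)
  expect_equal(cosineSimilarity(g, g), 1)
  expect_equal(cosineSimilarity(g, -g), -1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(0, 0), c(1, 2)), 0)
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)), "length")
  expect_error(cosineSimilarity(c(1, NA), c(1, 2)), "finite")
})

test_that("cosine similarity is invariant to positive rescaling", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(15)
    b <- rnorm(15)
    s <- cosineSimilarity(a, b)
    expect_true(abs(s) <= 1)
    expect_equal(cosineSimilarity(runif(1, 0.1, 100) * a, b), s)
    expect_equal(cosineSimilarity(a, runif(1, 0.1, 100) * b), s)
  }
})

test_that("analytic gradients match central finite differences", {
  sp <- smallSplit(n = 8, d = 4, nTarget = 5)
  m <- makeMLP(4, 4, 2, seed = 3)       # 4*4+4+4*2+2 = 30 parameters
  g <- targetBatchGradient(m, sp$src$X, sp$src$y)
  gn <- numericGradient(m, sp$src$X, sp$src$y)
  expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-4)

  a <- makeAutoencoder(5, 2, hiddenDim = 3, seed = 4)  # small AE
  Xa <- matrix(rnorm(4 * 5), 4, 5)
  ga <- targetBatchGradient(a, Xa)
  gna <- numericGradient(a, Xa)
  expect_lt(max(abs(ga - gna)) / max(abs(gna)), 1e-4)
})

test_that("linear one-parameter model has the textbook gradient", {
  # y_hat = w * x + b with w = 0, b = 0; squared error, x = 1, target = 2:
  # d/dw (w x - y)^2 = 2 (w x - y) x = -4
  lin <- feedForwardNet(c(1, 1), activation = "identity",
                        task = "reconstruction", seed = 0)
  lin <- setModelParameters(lin, c(0, 0))
  g <- perSampleGradients(lin, matrix(1), y = matrix(2))
  expect_equal(as.vector(g), c(-4, -4))  # dw and db both -2*(0-2)*1
  # at the loss minimum the gradient vanishes
  lin2 <- setModelParameters(lin, c(2, 0))
  expect_equal(as.vector(perSampleGradients(lin2, matrix(1), y = matrix(2))),
               c(0, 0))
})

test_that("duplicated samples give identical per-sample gradients", {
  sp <- smallSplit(n = 5, d = 4, nTarget = 5)
  m <- makeMLP(4, 6, 2, seed = 5)
  X2 <- rbind(sp$src$X[1, ], sp$src$X[1, ])
  G <- perSampleGradients(m, X2, c(sp$src$y[1], sp$src$y[1]))
  expect_identical(G[1, ], G[2, ])
})

test_that("batch gradient is the mean of per-sample gradients; class balance reweights", {
  sp <- smallSplit(n = 12, d = 4, nTarget = 5)
  m <- makeMLP(4, 5, 2, seed = 6)
  G <- perSampleGradients(m, sp$src$X, sp$src$y)
  expect_equal(targetBatchGradient(m, sp$src$X, sp$src$y), colMeans(G),
               tolerance = 1e-12)

  # batch of one sample equals that sample's gradient
  expect_equal(targetBatchGradient(m, sp$src$X[1, , drop = FALSE], sp$src$y[1]),
               G[1, ], tolerance = 1e-12)

  # unbalanced batch {3 x a (class 0), 1 x b (class 1)} with balancing
  # equals 0.5 grad(a) + 0.5 grad(b)
  a <- sp$src$X[which(sp$src$y == 0)[1], ]
  b <- sp$src$X[which(sp$src$y == 1)[1], ]
  bX <- rbind(a, a, a, b)
  by <- c(0L, 0L, 0L, 1L)
  ga <- perSampleGradients(m, matrix(a, 1), 0L)[1, ]
  gb <- perSampleGradients(m, matrix(b, 1), 1L)[1, ]
  expect_equal(targetBatchGradient(m, bX, by, classBalance = TRUE),
               0.5 * ga + 0.5 * gb, tolerance = 1e-12)
  # balancing off: k copies of one sample give that sample's gradient
  expect_equal(targetBatchGradient(m, rbind(a, a, a), c(0L, 0L, 0L)),
               ga, tolerance = 1e-12)
  expect_error(targetBatchGradient(m, sp$src$X[0, , drop = FALSE], integer()),
               "non-empty")
})

test_that("fast and loop similarity paths agree to 1e-5 on a 50-sample problem", {
  sp <- smallSplit(n = 50, d = 6, nTarget = 20)
  m <- makeMLP(6, 12, 2, seed = 7)
  ref <- targetBatchGradient(m, sp$tgt$X, sp$tgt$y)
  for (sim in c("cosine", "dot", "euclidean")) {
    sf <- gradientSimilarities(m, sp$src$X, sp$src$y, ref, similarity = sim,
                               method = "fast")
    sl <- gradientSimilarities(m, sp$src$X, sp$src$y, ref, similarity = sim,
                               method = "loop")
    expect_lt(max(abs(sf - sl)), 1e-5)
  }
  # reconstruction model too
  a <- makeAutoencoder(6, 2, seed = 8)
  refA <- targetBatchGradient(a, sp$tgt$X)
  expect_lt(max(abs(
    gradientSimilarities(a, sp$src$X, NULL, refA, method = "fast") -
    gradientSimilarities(a, sp$src$X, NULL, refA, method = "loop"))), 1e-5)
})

test_that("balanced class weights make each class contribute equally", {
  y <- c(0L, 0L, 0L, 1L)
  w <- balancedClassWeights(y, 2L)
  expect_equal(w[1] * 3, w[2] * 1)       # equal total class mass
  expect_equal(balancedClassWeights(c(0L, 1L), 3L)[3], 0)  # absent class
})
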