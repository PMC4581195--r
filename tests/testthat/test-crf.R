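test_that("unit label weights reduce the weighted potentials to the plain ones", {
  r <- randomModel(labelWeights = c(1, 1), seed = 3)
  top <- dcnnTop(r$model, r$features)
  U <- emissionWeights(r$model)
  Tm <- transitionWeights(r$model)
  for (i in c(1, 3, nrow(top))) for (a in 0:1) for (b in 0:1) {
    p <- weightedPotentials(r$model, top, i, a, b)
    expect_identical(p$phi, sum(U[a + 1, ] * top[i, ]))
    expect_identical(p$psi, if (i < nrow(top)) Tm[a + 1, b + 1] else 0)
  }
})

test_that("label weights scale the potentials exactly as printed", {
  r <- randomModel(labelWeights = c(0.07, 0.93), seed = 4)
  top <- dcnnTop(r$model, r$features)
  U <- emissionWeights(r$model)
  Tm <- transitionWeights(r$model)
  w <- c(0.07, 0.93)
  p <- weightedPotentials(r$model, top, 2, 1, 0)
  expect_equal(p$phi, w[2] * sum(U[2, ] * top[2, ]), tolerance = 1e-14)
  expect_equal(p$psi, w[2] * Tm[2, 1], tolerance = 1e-14)
  ## zero emission weights kill phi everywhere
  z <- r$model; z@emissionWeights[] <- 0
  for (i in 1:3) expect_identical(weightedPotentials(z, top, i, 1, 0)$phi, 0)
  expect_error(weightedPotentials(r$model, top, 2, 5, 0), "invalid label")
})

test_that("the path score is the sum of per-position potentials", {
  r <- randomModel(L = 4, labelWeights = c(0.7, 9.3), seed = 6)
  top <- dcnnTop(r$model, r$features[1:4, , drop = FALSE])
  y <- c(0L, 1L, 1L, 0L)
  manual <- 0
  for (i in 1:4) {
    p <- weightedPotentials(r$model, top, i, y[i], if (i < 4) y[i + 1] else NA)
    manual <- manual + p$phi + p$psi
  }
  expect_equal(sequenceScore(r$model, top, y), manual, tolerance = 1e-12)
  ## all parameters zero -> score 0; L = 1 -> emission only
  z <- newDeepCNFModel(r$arch, zero = TRUE)
  expect_identical(sequenceScore(z, dcnnTop(z, r$features[1:4, ]), y), 0)
  top1 <- top[1, , drop = FALSE]
  expect_equal(sequenceScore(r$model, top1, 1L),
               weightedPotentials(r$model, top1, 1, 1)$phi)
  expect_error(sequenceScore(r$model, top, c(0L, 1L)), "length")
})

test_that("partition function and marginals match exhaustive enumeration", {
  for (draw in 1:20) {
    r <- randomModel(L = sample(2:8, 1), layers = sample(1:2, 1),
                     labelWeights = if (draw %% 2) c(1, 1) else c(0.7, 9.3),
                     seed = draw, initRange = 0.6)
    top <- dcnnTop(r$model, r$features)
    oracle <- enumChain(r$model, top)
    expect_equal(partitionLog(r$model, top), oracle$logZ, tolerance = 1e-8)
    marg <- posteriorMarginals(r$model, r$features)
    expect_equal(unname(marg), unname(oracle$marginals), tolerance = 1e-8)
    expect_equal(rowSums(marg), rep(1, nrow(marg)), tolerance = 1e-10)
  }
})

test_that("conditional probabilities normalize over all label paths", {
  for (draw in 1:5) {
    r <- randomModel(L = 6, labelWeights = c(0.5, 9.5), seed = 30 + draw,
                     initRange = 0.5)
    paths <- as.matrix(expand.grid(rep(list(0:1), 6)))
    lp <- apply(paths, 1, function(y)
      conditionalLogProb(r$model, r$features, as.integer(y)))
    expect_true(all(lp <= 0))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
  }
})

test_that("degenerate chains behave: zero parameters and single residues", {
  arch <- DeepCNFArch(inputDim = 2, numHiddenLayers = 1, neuronsPerLayer = 2,
                      halfWindow = 1)
  z <- newDeepCNFModel(arch, zero = TRUE)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(partitionLog(z, dcnnTop(z, x)), 5 * log(2), tolerance = 1e-12)
  expect_equal(conditionalLogProb(z, x, rep(1L, 5)), -5 * log(2), tolerance = 1e-12)
  expect_equal(unname(posteriorMarginals(z, x)), matrix(0.5, 5, 2), tolerance = 1e-12)
  ## L = 1: logZ is the log-sum of the emission potentials
  r <- randomModel(L = 1, seed = 9)
  x1 <- r$features[1, , drop = FALSE]
  top1 <- dcnnTop(r$model, x1)
  phis <- sapply(0:1, function(a) weightedPotentials(r$model, top1, 1, a)$phi)
  expect_equal(partitionLog(r$model, top1),
               log(sum(exp(phis - max(phis)))) + max(phis), tolerance = 1e-12)
})

test_that("a strong emission pull raises that position's disorder marginal", {
  arch <- DeepCNFArch(inputDim = 4, numHiddenLayers = 1, neuronsPerLayer = 4,
                      halfWindow = 0)
  m <- newDeepCNFModel(arch, zero = TRUE)
  m@emissionWeights[2, ] <- 5  # pull toward disorder wherever activations are high
  x <- matrix(0, 7, 4); x[4, ] <- 10   # one position lights up
  marg <- posteriorMarginals(m, x)
  expect_gt(marg[4, "disorder"], 0.5)
})

test_that("log-space chains survive large parameters on long sequences", {
  arch <- DeepCNFArch(inputDim = 2, numHiddenLayers = 1, neuronsPerLayer = 3,
                      halfWindow = 1)
  m <- newDeepCNFModel(arch, seed = 11)
  m@emissionWeights[] <- withr::with_seed(12, runif(6, -50, 50))
  m@transitionWeights[] <- withr::with_seed(13, runif(4, -50, 50))
  x <- withr::with_seed(14, matrix(rnorm(2000 * 2), 2000, 2))
  top <- dcnnTop(m, x)
  lz <- partitionLog(m, top)
  expect_true(is.finite(lz))
  marg <- posteriorMarginals(m, x)
  expect_true(all(is.finite(marg)))
  expect_equal(rowSums(marg), rep(1, 2000), tolerance = 1e-9)
})

test_that("thresholding follows the >= convention with configurable threshold", {
  expect_equal(classifyDisorder(c(0.25, 0.15, 0.60), 0.2), c(1L, 0L, 1L))
  expect_equal(classifyDisorder(c(0.2, 0.9, 0.05), 0), rep(1L, 3))
  expect_equal(classifyDisorder(c(0.2, 0.99, 0.05), 1), rep(0L, 3))
  expect_error(classifyDisorder(c(0.5), 1.2), "threshold")
  ## matrix input uses the disorder column
  m <- cbind(order = c(0.9, 0.1), disorder = c(0.1, 0.9))
  expect_equal(classifyDisorder(m, 0.5), c(0L, 1L))
})

test_that("posterior path sampling tracks the exact marginals", {
  r <- randomModel(L = 5, seed = 21, initRange = 0.8, labelWeights = c(0.7, 9.3))
  marg <- posteriorMarginals(r$model, r$features)
  draws <- sampleLabelPath(r$model, r$features, n = 4000, seed = 99)
  freq <- colMeans(draws == 1L)
  expect_equal(freq, unname(marg[, "disorder"]), tolerance = 0.04)
})
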