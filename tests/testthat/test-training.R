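test_that("objective reduces to the known closed forms in degenerate settings", {
  arch <- DeepCNFArch(inputDim = 2, numHiddenLayers = 1, neuronsPerLayer = 2,
                      halfWindow = 1)
  z <- newDeepCNFModel(arch, labelWeights = c(0.7, 9.3), zero = TRUE)
  corp <- DisorderCorpus(list(matrix(rnorm(14), 7, 2)), list(c(0, 0, 1, 1, 1, 1, 0)))
  cfg <- trainingConfig()
  ## all parameters zero: every path equally likely, penalty vanishes
  expect_equal(dcnfObjective(z, corp, cfg), -7 * log(2), tolerance = 1e-12)
  ## without the penalty the objective is the pure weighted log-likelihood
  m <- newDeepCNFModel(arch, labelWeights = c(0.7, 9.3), seed = 2)
  cfg0 <- trainingConfig(l2Factor = 0)
  expect_equal(dcnfObjective(m, corp, cfg0),
               conditionalLogProb(m, corpusFeatures(corp)[[1]],
                                  corpusLabels(corp)[[1]]),
               tolerance = 1e-12)
  ## doubling every weight quadruples the quadratic penalty
  pen <- function(mm) dcnfObjective(mm, corp, cfg0) - dcnfObjective(mm, corp, cfg)
  m2 <- unflattenParams(m, 2 * flattenParams(m))
  expect_equal(pen(m2), 4 * pen(m), tolerance = 1e-10)
  expect_error(dcnfObjective(m, DisorderCorpus(list(), list()), cfg), "empty")
})

test_that("analytic gradients match central finite differences for 1-3 layer stacks", {
  corp <- randomCorpus(n = 3, L = 8, inputDim = 3, seed = 8)
  cfg <- trainingConfig(l2Factor = 5, labelWeightRatio = c(0.7, 9.3))
  for (layers in 1:3) {
    arch <- DeepCNFArch(inputDim = 3, numHiddenLayers = layers,
                        neuronsPerLayer = 3, halfWindow = 1)
    m <- newDeepCNFModel(arch, labelWeights = cfg$labelWeightRatio,
                         seed = 40 + layers, initRange = 0.3)
    g <- dcnfGradient(m, corp, cfg, flat = TRUE)
    fd <- fdGradient(m, corp, cfg)
    relErr <- max(abs(g - fd) / pmax(1, abs(fd)))
    expect_lt(relErr, 1e-4)
  }
  ## bias gradients are covered too when biases are enabled
  archB <- DeepCNFArch(inputDim = 3, numHiddenLayers = 2, neuronsPerLayer = 3,
                       halfWindow = 1, useBias = TRUE)
  mB <- newDeepCNFModel(archB, labelWeights = c(1, 2), seed = 50, initRange = 0.3)
  expect_lt(max(abs(dcnfGradient(mB, corp, cfg, flat = TRUE) -
                    fdGradient(mB, corp, cfg)) / pmax(1, abs(fdGradient(mB, corp, cfg)))),
            1e-4)
  ## gradient pieces come back parameter shaped
  parts <- dcnfGradient(mB, corp, cfg)
  expect_identical(dim(parts$convWeights[[1]]), dim(convWeights(mB)[[1]]))
  expect_identical(dim(parts$emissionWeights), dim(emissionWeights(mB)))
})

test_that("with unit label weights the model equals an independent unweighted CNF", {
  corp <- randomCorpus(n = 2, L = 6, inputDim = 3, seed = 15)
  cfg <- trainingConfig(l2Factor = 7, labelWeightRatio = c(1, 1))
  for (layers in 1:2) {
    arch <- DeepCNFArch(inputDim = 3, numHiddenLayers = layers,
                        neuronsPerLayer = 3, halfWindow = 1)
    m <- newDeepCNFModel(arch, labelWeights = c(1, 1), seed = 60 + layers,
                         initRange = 0.4)
    ref <- uwObjGrad(m, corp, cfg)
    expect_equal(dcnfObjective(m, corp, cfg), ref$objective, tolerance = 1e-10)
    expect_equal(dcnfGradient(m, corp, cfg, flat = TRUE), ref$gradient,
                 tolerance = 1e-10)
  }
})

test_that("fitting is deterministic, improves the objective, and reaches a stationary point", {
  corp <- randomCorpus(n = 4, L = 10, inputDim = 3, seed = 70)
  arch <- DeepCNFArch(inputDim = 3, numHiddenLayers = 1, neuronsPerLayer = 3,
                      halfWindow = 1)
  cfg <- trainingConfig(l2Factor = 10, maxIterations = 300,
                        convergenceTol = 1e-6, seed = 5)
  fit1 <- fitDeepCNF(corp, arch, cfg)
  fit2 <- fitDeepCNF(corp, arch, cfg)
  expect_identical(flattenParams(fit1), flattenParams(fit2))
  tr <- fitInfo(fit1)$trace
  expect_gt(tail(tr$objective, 1), tr$objective[1])
  ## first-order condition at the optimum found
  g <- dcnfGradient(fit1, corp, cfg, flat = TRUE)
  expect_lt(max(abs(g)), 1e-3)
  ## a written model file reloads bit-exactly
  f <- tempfile(fileext = ".model")
  writeDeepCNFModel(fit1, f)
  expect_identical(flattenParams(readDeepCNFModel(f)), flattenParams(fit1))
})

test_that("the L2 penalty can only lower the achievable optimum", {
  corp <- randomCorpus(n = 3, L = 8, inputDim = 3, seed = 80)
  arch <- DeepCNFArch(inputDim = 3, numHiddenLayers = 1, neuronsPerLayer = 2,
                      halfWindow = 1)
  fitPen <- fitDeepCNF(corp, arch, trainingConfig(l2Factor = 200, maxIterations = 200))
  fitFree <- fitDeepCNF(corp, arch, trainingConfig(l2Factor = 0, maxIterations = 200))
  ## compare pure likelihood-plus-penalty objectives on each one's own config
  expect_lte(fitInfo(fitPen)$finalObjective, fitInfo(fitFree)$finalObjective + 1e-6)
})

test_that("reciprocal-frequency weights swap the label frequencies", {
  mk <- function(y) DisorderCorpus(list(matrix(0, length(y), 1)), list(y))
  w <- reciprocalFrequencyWeights(mk(c(rep(0, 93), rep(1, 7))))
  expect_equal(unname(w), c(0.07, 0.93))
  expect_equal(unname(reciprocalFrequencyWeights(mk(c(0, 1, 0, 1)))), c(0.5, 0.5))
  expect_equal(unname(reciprocalFrequencyWeights(mk(c(rep(0, 8), rep(1, 2))))),
               c(0.2, 0.8))
  expect_error(reciprocalFrequencyWeights(mk(rep(0, 5))), "both")
})

test_that("k-fold splits are balanced, exhaustive and seed-deterministic", {
  f <- kfoldSplit(10, 10, seed = 1)
  expect_equal(sort(f), 1:10)
  f23 <- kfoldSplit(23, 10, seed = 2)
  expect_equal(sort(as.integer(table(f23))), c(rep(2L, 7), rep(3L, 3)))
  expect_identical(kfoldSplit(23, 10, seed = 2), f23)
  expect_false(identical(kfoldSplit(23, 10, seed = 3), f23))
  expect_error(kfoldSplit(5, 1), "folds")
  expect_error(kfoldSplit(5, 6), "folds")
})

test_that("held-out marginals of a refit model track the generating model", {
  ## generate chains from a known 1-layer model (pointwise window so the
  ## surface is well behaved), refit on 50 sequences, compare held-out
  ## marginals on 10 more
  inputDim <- 6
  arch <- DeepCNFArch(inputDim = inputDim, numHiddenLayers = 1,
                      neuronsPerLayer = 6, halfWindow = 0)
  gen <- newDeepCNFModel(arch, seed = 123, initRange = 0.8)
  gen@emissionWeights <- gen@emissionWeights * 4  # make labels informative
  n <- 60; L <- 100
  feats <- withr::with_seed(7, lapply(seq_len(n), function(.)
    matrix(rnorm(L * inputDim), L, inputDim)))
  labs <- lapply(seq_len(n), function(i)
    as.integer(sampleLabelPath(gen, feats[[i]], seed = 500 + i)))
  corp <- DisorderCorpus(feats, labs)
  fit <- fitDeepCNF(corp[1:50], arch,
                    trainingConfig(labelWeightRatio = c(1, 1), l2Factor = 20,
                                   maxIterations = 250, seed = 9))
  truth <- unlist(lapply(51:60, function(i)
    posteriorMarginals(gen, feats[[i]])[, "disorder"]))
  est <- unlist(lapply(51:60, function(i)
    posteriorMarginals(fit, feats[[i]])[, "disorder"]))
  expect_gt(cor(truth, est), 0.9)
})
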