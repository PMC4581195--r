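## Independent oracles: exhaustive path enumeration for the chain, central
## finite differences for the gradient, and the rank-statistic form of the
## AUC. These share no code with the implementation paths they check.

## Enumerate all D^L label paths; potentials recomputed here from the raw
## weight matrices, independent of the package's potential code.
enumChain <- function(model, top) {
  w <- labelWeights(model)
  U <- emissionWeights(model)
  Tm <- transitionWeights(model)
  L <- nrow(top)
  D <- length(w)
  paths <- as.matrix(expand.grid(rep(list(seq_len(D) - 1L), L)))
  score <- apply(paths, 1L, function(y) {
    s <- 0
    for (i in seq_len(L)) {
      a <- y[i] + 1L
      s <- s + w[a] * sum(U[a, ] * top[i, ])
      if (i < L) s <- s + w[a] * Tm[a, y[i + 1L] + 1L]
    }
    s
  })
  m <- max(score)
  logZ <- m + log(sum(exp(score - m)))
  p <- exp(score - logZ)
  marg <- sapply(seq_len(L), function(i)
    sapply(seq_len(D) - 1L, function(a) sum(p[paths[, i] == a])))
  list(logZ = logZ, marginals = t(marg), pathScores = score, paths = paths)
}

## Central finite differences of the training objective.
fdGradient <- function(model, corpus, config, step = 1e-5) {
  th <- flattenParams(model)
  vapply(seq_along(th), function(j) {
    e <- numeric(length(th)); e[j] <- step
    (dcnfObjective(unflattenParams(model, th + e), corpus, config) -
     dcnfObjective(unflattenParams(model, th - e), corpus, config)) / (2 * step)
  }, numeric(1L))
}

## Tie-corrected Mann-Whitney AUC via ranks.
rankAUC <- function(scores, truth) {
  r <- rank(scores)
  npos <- sum(truth == 1)
  nneg <- sum(truth == 0)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

## Small random model + feature matrix for property tests.
randomModel <- function(L = 6L, inputDim = 3L, layers = 2L, neurons = 4L,
                        halfWindow = 1L, labelWeights = c(1, 1), seed = 1L,
                        initRange = 0.4, activation = "sigmoid",
                        useBias = FALSE) {
  arch <- DeepCNFArch(inputDim = inputDim, numHiddenLayers = layers,
                      neuronsPerLayer = neurons, halfWindow = halfWindow,
                      activation = activation, useBias = useBias)
  model <- newDeepCNFModel(arch, labelWeights = labelWeights, seed = seed,
                           initRange = initRange)
  features <- withr::with_seed(seed + 1000L, matrix(rnorm(L * inputDim), L, inputDim))
  list(model = model, features = features, arch = arch)
}

## Random toy corpus of short sequences.
randomCorpus <- function(n = 3L, L = 8L, inputDim = 3L, seed = 2L) {
  withr::with_seed(seed, {
    feats <- lapply(seq_len(n), function(.) matrix(rnorm(L * inputDim), L, inputDim))
    labs <- lapply(seq_len(n), function(.) {
      y <- rbinom(L, 1L, 0.3)
      if (all(y == y[1L])) y[1L] <- 1L - y[1L]  # keep both classes present
      y
    })
    DisorderCorpus(feats, labs)
  })
}
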