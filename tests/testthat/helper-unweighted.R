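## An independently coded *unweighted* conditional neural field: naive
## per-position convolution loops and a scaled (non-log) forward-backward.
## With unit label weights the package's weighted path must reproduce these
## values; nothing here calls the package's dcnn/crf/training internals.

uwActivation <- function(arch) switch(arch@activation, sigmoid = function(x) 1/(1+exp(-x)), tanh = tanh)

uwForwardStack <- function(model, X) {
  arch <- architecture(model)
  h <- uwActivation(arch)
  A <- list(X)
  for (k in seq_len(arch@numHiddenLayers)) {
    W <- convWeights(model)[[k]]
    N <- arch@halfWindow[k]
    Lr <- nrow(A[[k]])
    Mout <- dim(W)[2L]; Min <- dim(W)[3L]
    S <- matrix(0, Lr, Mout)
    for (i in seq_len(Lr)) {
      acc <- numeric(Mout)
      for (oi in seq_len(2L * N + 1L)) {
        ii <- i + (oi - N - 1L)
        if (ii >= 1L && ii <= Lr)
          acc <- acc + matrix(W[oi, , ], Mout, Min) %*% A[[k]][ii, ]
      }
      S[i, ] <- acc
    }
    A[[k + 1L]] <- h(S)
  }
  A
}

## Scaled forward-backward; returns log-likelihood pieces and marginals.
uwChain <- function(U, Tm, H, y) {
  L <- nrow(H); D <- nrow(U)
  E <- exp(H %*% t(U))        # L x D emission factors
  Psi <- exp(Tm)
  ahat <- matrix(0, L, D); cs <- numeric(L)
  a <- E[1L, ]; cs[1L] <- sum(a); ahat[1L, ] <- a / cs[1L]
  if (L > 1L) for (i in 2L:L) {
    a <- as.numeric(ahat[i - 1L, ] %*% Psi) * E[i, ]
    cs[i] <- sum(a); ahat[i, ] <- a / cs[i]
  }
  logZ <- sum(log(cs))
  bhat <- matrix(0, L, D); bhat[L, ] <- 1
  if (L > 1L) for (i in (L - 1L):1L)
    bhat[i, ] <- as.numeric(Psi %*% (E[i + 1L, ] * bhat[i + 1L, ])) / cs[i + 1L]
  node <- ahat * bhat
  node <- node / rowSums(node)
  pair <- matrix(0, D, D)
  if (L > 1L) for (i in seq_len(L - 1L))
    pair <- pair + outer(ahat[i, ], E[i + 1L, ] * bhat[i + 1L, ]) * Psi / cs[i + 1L]
  sc <- sum(vapply(seq_len(L), function(i) sum(U[y[i] + 1L, ] * H[i, ]), 0))
  if (L > 1L) sc <- sc + sum(Tm[cbind(y[-L] + 1L, y[-1L] + 1L)])
  list(ll = sc - logZ, node = node, pair = pair)
}

## Unweighted objective and flat gradient with the same L2 convention as the
## package (lambda = l2Factor / total residues in per-residue mode).
uwObjGrad <- function(model, corpus, config) {
  arch <- architecture(model)
  U <- emissionWeights(model); Tm <- transitionWeights(model)
  D <- nrow(U)
  nres <- sum(vapply(corpusLabels(corpus), length, 1L))
  lam <- if (config$l2Mode == "per-residue") config$l2Factor / nres else config$l2Factor
  gU <- matrix(0, nrow(U), ncol(U))
  gT <- matrix(0, D, D)
  gW <- lapply(convWeights(model), function(a) array(0, dim(a)))
  obj <- 0
  hgrad <- switch(arch@activation,
                  sigmoid = function(a) a * (1 - a),
                  tanh = function(a) 1 - a^2)
  for (s in seq_along(corpusFeatures(corpus))) {
    X <- corpusFeatures(corpus)[[s]]
    y <- states(corpusLabels(corpus)[[s]])
    A <- uwForwardStack(model, X)
    H <- A[[length(A)]]
    ch <- uwChain(U, Tm, H, y)
    obj <- obj + ch$ll
    L <- nrow(H)
    emp <- matrix(0, L, D); emp[cbind(seq_len(L), y + 1L)] <- 1
    dPhi <- emp - ch$node
    gU <- gU + t(dPhi) %*% H
    pairEmp <- matrix(0, D, D)
    if (L > 1L) for (i in seq_len(L - 1L))
      pairEmp[y[i] + 1L, y[i + 1L] + 1L] <- pairEmp[y[i] + 1L, y[i + 1L] + 1L] + 1
    gT <- gT + pairEmp - ch$pair
    dA <- dPhi %*% U
    for (k in rev(seq_len(arch@numHiddenLayers))) {
      dS <- dA * hgrad(A[[k + 1L]])
      W <- convWeights(model)[[k]]
      N <- arch@halfWindow[k]
      Mout <- dim(W)[2L]; Min <- dim(W)[3L]
      dAin <- matrix(0, nrow(A[[k]]), ncol(A[[k]]))
      for (i in seq_len(L)) for (oi in seq_len(2L * N + 1L)) {
        ii <- i + (oi - N - 1L)
        if (ii >= 1L && ii <= L) {
          gW[[k]][oi, , ] <- gW[[k]][oi, , ] + outer(dS[i, ], A[[k]][ii, ])
          dAin[ii, ] <- dAin[ii, ] + as.numeric(t(matrix(W[oi, , ], Mout, Min)) %*% dS[i, ])
        }
      }
      dA <- dAin
    }
  }
  theta <- flattenParams(model)
  gradModel <- model
  gradModel@convWeights <- gW
  gradModel@emissionWeights <- gU
  gradModel@transitionWeights <- gT
  list(objective = obj - 0.5 * lam * sum(theta^2),
       gradient = flattenParams(gradModel) - lam * theta)
}
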