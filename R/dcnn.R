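## Deep convolutional stack: position-shared windowed linear maps with a
## pointwise nonlinearity, A^1 = X and H = A^{K+1}. Positions outside the
## chain contribute zero (zero padding), so every layer keeps L rows.

activationFun <- function(arch) {
  switch(arch@activation, sigmoid = sigmoid, tanh = tanh)
}

## Derivative expressed through the activation value itself.
activationGradFromValue <- function(arch, a) {
  switch(arch@activation,
         sigmoid = a * (1 - a),
         tanh = 1 - a * a)
}

#' Forward pass through the convolutional stack
#'
#' Computes every layer's activations for one sequence. Layer k + 1 at
#' position i is h(sum over offsets l in [-N_k, N_k] and source neurons j' of
#' A_{i+l}^k(j') * W_l^k(j, j')), with out-of-chain positions contributing
#' zero. The input features are layer 1; the top layer is the CRF's feature
#' function H.
#'
#' @param model a \code{\link{DeepCNFModel}}.
#' @param features L x inputDim numeric matrix of per-residue features.
#' @return list with \code{activations} (list of L x M_k matrices, input
#'   first, top layer last) and \code{top} (the top-layer matrix).
#' @examples
#' arch <- DeepCNFArch(inputDim = 4, numHiddenLayers = 1,
#'                     neuronsPerLayer = 3, halfWindow = 1)
#' m <- newDeepCNFModel(arch, zero = TRUE)
#' dcnnForward(m, matrix(rnorm(20), 5, 4))$top  # sigmoid(0) = 0.5 everywhere
#' @export
dcnnForward <- function(model, features) {
  arch <- model@arch
  features <- as.matrix(features)
  if (ncol(features) != arch@inputDim)
    stop(sprintf(
      "input layer: feature width %d does not match the architecture's input dimension %d",
      ncol(features), arch@inputDim))
  if (anyNA(features) || any(!is.finite(features)))
    stop("input layer: features contain missing or non-finite values")
  h <- activationFun(arch)
  acts <- vector("list", arch@numHiddenLayers + 1L)
  acts[[1L]] <- features
  a <- features
  for (k in seq_len(arch@numHiddenLayers)) {
    w <- model@convWeights[[k]]
    dms <- dim(w)
    if (dms[3L] != ncol(a))
      stop(sprintf("conv layer %d: weight source width %d does not match activation width %d",
                   k, dms[3L], ncol(a)))
    offsets <- seq.int(-arch@halfWindow[k], arch@halfWindow[k])
    s <- matrix(0, nrow(a), dms[2L])
    for (oi in seq_along(offsets)) {
      wl <- matrix(w[oi, , ], dms[2L], dms[3L])
      s <- s + shiftRowsZero(a %*% t(wl), offsets[oi])
    }
    if (arch@useBias)
      s <- sweep(s, 2L, model@biasWeights[[k]], "+")
    a <- h(s)
    acts[[k + 1L]] <- a
  }
  list(activations = acts, top = a)
}

#' Top-layer output of the convolutional stack
#'
#' @inheritParams dcnnForward
#' @return L x M_K matrix H of top-layer neuron outputs.
#' @export
dcnnTop <- function(model, features) dcnnForward(model, features)$top

## Backpropagate an error signal dTop = dL/dH through the stack.
## Returns per-layer conv-weight and bias gradients (dL/dW, dL/db).
dcnnBackprop <- function(model, forward, dTop) {
  arch <- model@arch
  acts <- forward$activations
  k <- arch@numHiddenLayers
  gradW <- vector("list", k)
  gradB <- vector("list", k)
  dA <- dTop
  for (layer in rev(seq_len(k))) {
    aOut <- acts[[layer + 1L]]
    aIn <- acts[[layer]]
    dS <- dA * activationGradFromValue(arch, aOut)
    w <- model@convWeights[[layer]]
    dms <- dim(w)
    offsets <- seq.int(-arch@halfWindow[layer], arch@halfWindow[layer])
    gw <- array(0, dim = dms)
    dIn <- matrix(0, nrow(aIn), ncol(aIn))
    for (oi in seq_along(offsets)) {
      l <- offsets[oi]
      gw[oi, , ] <- crossprod(dS, shiftRowsZero(aIn, l))
      wl <- matrix(w[oi, , ], dms[2L], dms[3L])
      dIn <- dIn + shiftRowsZero(dS, -l) %*% wl
    }
    gradW[[layer]] <- gw
    gradB[[layer]] <- colSums(dS)
    dA <- dIn
  }
  list(convWeights = gradW, biasWeights = gradB)
}
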