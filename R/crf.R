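## Weighted linear-chain CRF on top of the convolutional stack.
##
## Emission potential  Phi'(i, a) = w_a * sum_j U[a, j] H_j(i)
## Transition potential Psi'(a, b) = w_a * T[a, b]   (for i < L; zero at i = L)
## With all label weights equal to 1 these are the plain CNF potentials.

## Per-position emission and pairwise transition log-potentials.
logPotentials <- function(model, top) {
  w <- model@labelWeights
  phi <- sweep(top %*% t(model@emissionWeights), 2L, w, "*")
  psi <- sweep(model@transitionWeights, 1L, w, "*")
  list(phi = phi, psi = psi)
}

.checkLabelIndex <- function(a, d, what) {
  if (length(a) != 1L || is.na(a) || a < 0L || a >= d)
    stop(sprintf("invalid label index for %s: must be in 0..%d", what, d - 1L))
}

#' Weighted potential functions at one position
#'
#' Evaluates the weighted transition potential Psi' = T[a, b] * w[a] for the
#' adjacent pair (Y_i = a, Y_{i+1} = b) and the weighted emission potential
#' Phi' = w[a] * sum_j U[a, j] H_j(i). Labels use the 0 = order / 1 =
#' disorder coding. At the final position the transition contribution is
#' defined as zero (no right neighbour exists).
#'
#' @param model a \code{\link{DeepCNFModel}}.
#' @param top top-layer activation matrix from \code{\link{dcnnTop}}.
#' @param i chain position (1-based, 1 <= i <= L).
#' @param a label at position i (0-based state code).
#' @param b label at position i + 1 (ignored when i = L).
#' @return list with numeric \code{psi} and \code{phi}.
#' @export
weightedPotentials <- function(model, top, i, a, b = NA_integer_) {
  L <- nrow(top)
  d <- model@arch@numLabels
  if (i < 1L || i > L) stop(sprintf("position %d outside chain of length %d", i, L))
  .checkLabelIndex(a, d, "a")
  w <- model@labelWeights
  phi <- w[a + 1L] * sum(model@emissionWeights[a + 1L, ] * top[i, ])
  if (i < L) {
    .checkLabelIndex(b, d, "b")
    psi <- w[a + 1L] * model@transitionWeights[a + 1L, b + 1L]
  } else {
    psi <- 0
  }
  list(psi = psi, phi = phi)
}

.labelVector <- function(labels, L) {
  if (is(labels, "DisorderLabels")) {
    if (!all(labels@mask))
      stop("labels contain masked residues; compact them before scoring")
    y <- labels@states
  } else {
    y <- as.integer(labels)
  }
  if (length(y) != L)
    stop(sprintf("label length %d does not match chain length %d", length(y), L))
  if (anyNA(y)) stop("labels must be fully observed")
  y
}

#' Log score of one label path
#'
#' Sum over positions of the weighted emission and transition potentials for
#' the given labels: the log of the unnormalized chain probability.
#'
#' @inheritParams weightedPotentials
#' @param labels \code{\link{DisorderLabels}} (fully observed) or a 0/1
#'   integer vector of length L.
#' @return the log path score (a real number).
#' @export
sequenceScore <- function(model, top, labels) {
  y <- .labelVector(labels, nrow(top))
  pots <- logPotentials(model, top)
  L <- length(y)
  sc <- sum(pots$phi[cbind(seq_len(L), y + 1L)])
  if (L > 1L)
    sc <- sc + sum(pots$psi[cbind(y[-L] + 1L, y[-1L] + 1L)])
  sc
}

#' Log partition function of the chain
#'
#' Computes log Z(X) = log of the sum over all D^L label paths of the
#' exponentiated path score, by the forward recursion in log space.
#'
#' @inheritParams weightedPotentials
#' @return log Z(X), finite for finite parameters and activations.
#' @export
partitionLog <- function(model, top) {
  if (any(!is.finite(top)))
    stop("non-finite activations passed to the chain")
  pots <- logPotentials(model, top)
  .crfChain(pots$phi, pots$psi)$logZ
}

#' Conditional log-probability of a label path
#'
#' log P(Y | X) = path score minus log Z(X); always <= 0.
#'
#' @inheritParams dcnnForward
#' @param labels fully observed labels (see \code{\link{sequenceScore}}).
#' @return the conditional log-probability.
#' @export
conditionalLogProb <- function(model, features, labels) {
  top <- dcnnTop(model, features)
  sequenceScore(model, top, labels) - partitionLog(model, top)
}

#' Posterior per-residue marginals
#'
#' Forward-backward in log space. Row i holds P(Y_i = a | X) for each label;
#' every row sums to one. These are the probabilities a decision threshold is
#' applied to.
#'
#' @inheritParams dcnnForward
#' @param pairwise also return the pairwise marginals summed over adjacent
#'   positions (used by the training gradient).
#' @return L x D matrix of posterior probabilities (columns "order",
#'   "disorder" for the two-label model); with \code{pairwise = TRUE}, a list
#'   with \code{node}, \code{pairSums} and \code{logZ}.
#' @export
posteriorMarginals <- function(model, features, pairwise = FALSE) {
  top <- dcnnTop(model, features)
  if (any(!is.finite(top)))
    stop("non-finite activations passed to the chain")
  pots <- logPotentials(model, top)
  ch <- .crfChain(pots$phi, pots$psi)
  node <- ch$nodeMarginals
  if (model@arch@numLabels == 2L)
    colnames(node) <- c("order", "disorder")
  if (pairwise)
    list(node = node, pairSums = ch$pairMarginalSums, logZ = ch$logZ)
  else node
}

#' Threshold posterior marginals into calls
#'
#' A residue is called disordered when its posterior disorder probability is
#' greater than or equal to the threshold. The default threshold of 0.2 is
#' the released operating point (chosen for MCC on training data); ROC/AUC
#' evaluation is threshold free.
#'
#' @param marginals matrix from \code{\link{posteriorMarginals}} (the
#'   "disorder" column is used) or a numeric vector of disorder
#'   probabilities.
#' @param threshold decision threshold in [0, 1] (default 0.2).
#' @return integer vector of 0/1 calls.
#' @examples
#' classifyDisorder(c(0.25, 0.15, 0.60), threshold = 0.2)  # 1 0 1
#' @export
classifyDisorder <- function(marginals, threshold = 0.2) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  p <- if (is.matrix(marginals)) marginals[, "disorder"] else as.numeric(marginals)
  as.integer(p >= threshold)
}

#' Sample label paths from the posterior
#'
#' Forward-filter backward-sample: draws exact joint samples of the label
#' chain given the features. Used to generate data from a known model.
#'
#' @inheritParams dcnnForward
#' @param n number of paths to draw.
#' @param seed optional seed applied locally.
#' @return integer matrix (n x L) of 0-based label paths.
#' @export
sampleLabelPath <- function(model, features, n = 1L, seed = NULL) {
  top <- dcnnTop(model, features)
  pots <- logPotentials(model, top)
  ch <- .crfChain(pots$phi, pots$psi)
  la <- ch$logAlpha
  L <- nrow(la)
  d <- ncol(la)
  draw <- function() {
    y <- integer(L)
    pl <- exp(la[L, ] - max(la[L, ]))
    y[L] <- sample.int(d, 1L, prob = pl)
    if (L > 1L) for (i in (L - 1L):1L) {
      lp <- la[i, ] + pots$psi[, y[i + 1L]]
      y[i] <- sample.int(d, 1L, prob = exp(lp - max(lp)))
    }
    y - 1L
  }
  body <- function() t(vapply(seq_len(n), function(.) draw(), integer(L)))
  if (is.null(seed)) body() else withSeed(seed, body())
}
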