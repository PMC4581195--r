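## Weighted maximum-likelihood training by L-BFGS with an L2 penalty.
##
## The objective (to be maximized) is the sum over corpus sequences of the
## weighted conditional log-likelihood minus lambda/2 * ||theta||^2, where
## theta stacks the conv, emission and transition weights (never the label
## weights, which are hyperparameters). By default lambda = l2Factor divided
## by the total residue count, so the stated factor of 200 penalizes at the
## same per-residue strength on corpora of any size; the raw interpretation
## is selectable.

#' Training configuration
#'
#' @param l2Factor nonnegative L2 regularization factor (default 200).
#' @param labelWeightRatio positive weights (order, disorder); default
#'   c(0.7, 9.3), the reciprocal-frequency ratio for ~7\% disorder. Used as
#'   given, not rescaled: the potentials are linear in the weights, so only
#'   the ratio and the joint scale matter, and the convention here is to keep
#'   the printed numbers.
#' @param maxIterations L-BFGS iteration cap (default 100).
#' @param convergenceTol projected-gradient tolerance (default 1e-5).
#' @param seed seed for parameter initialization (default 42).
#' @param folds default number of cross-validation folds (default 10).
#' @param l2Mode "per-residue" (lambda = l2Factor / total residues, default)
#'   or "raw" (lambda = l2Factor).
#' @param initRange half width of the uniform parameter initialization
#'   (default 0.1).
#' @return a list of class \code{trainingConfig}.
#' @export
trainingConfig <- function(l2Factor = 200, labelWeightRatio = c(0.7, 9.3),
                           maxIterations = 100L, convergenceTol = 1e-5,
                           seed = 42L, folds = 10L,
                           l2Mode = c("per-residue", "raw"),
                           initRange = 0.1) {
  stopifnot(l2Factor >= 0, all(labelWeightRatio > 0), maxIterations >= 1)
  structure(list(
    l2Factor = l2Factor,
    labelWeightRatio = as.numeric(labelWeightRatio),
    maxIterations = as.integer(maxIterations),
    convergenceTol = convergenceTol,
    seed = as.integer(seed),
    folds = as.integer(folds),
    l2Mode = match.arg(l2Mode),
    initRange = initRange
  ), class = "trainingConfig")
}

corpusResidues <- function(corpus) {
  sum(vapply(corpus@labels, length, 1L))
}

.lambda <- function(config, corpus) {
  if (config$l2Mode == "per-residue")
    config$l2Factor / corpusResidues(corpus)
  else config$l2Factor
}

## Log-likelihood and its gradient for one sequence. Gradients follow the
## standard CRF expectations (empirical minus model counts), each scaled by
## the label weight it enters the potential with, then backpropagated
## through the conv stack for the W gradients.
.seqObjGrad <- function(model, features, y, wantGrad = TRUE) {
  fwd <- dcnnForward(model, features)
  top <- fwd$top
  pots <- logPotentials(model, top)
  ch <- .crfChain(pots$phi, pots$psi)
  L <- length(y)
  d <- model@arch@numLabels
  sc <- sum(pots$phi[cbind(seq_len(L), y + 1L)])
  if (L > 1L)
    sc <- sc + sum(pots$psi[cbind(y[-L] + 1L, y[-1L] + 1L)])
  ll <- sc - ch$logZ
  if (!is.finite(ll)) stop("non-finite objective contribution")
  if (!wantGrad) return(list(ll = ll))
  w <- model@labelWeights
  emp <- matrix(0, L, d)
  emp[cbind(seq_len(L), y + 1L)] <- 1
  dPhi <- emp - ch$nodeMarginals                    # L x d
  gradU <- sweep(crossprod(dPhi, top), 1L, w, "*")  # d x M, scaled by w_a
  pairEmp <- matrix(0, d, d)
  if (L > 1L) {
    tab <- table(factor(y[-L], levels = 0:(d - 1L)),
                 factor(y[-1L], levels = 0:(d - 1L)))
    pairEmp <- matrix(as.numeric(tab), d, d)
  }
  gradT <- sweep(pairEmp - ch$pairMarginalSums, 1L, w, "*")
  dTop <- dPhi %*% sweep(model@emissionWeights, 1L, w, "*")  # L x M
  conv <- dcnnBackprop(model, fwd, dTop)
  list(ll = ll, gradU = gradU, gradT = gradT,
       gradW = conv$convWeights, gradB = conv$biasWeights)
}

.corpusObjGrad <- function(model, corpus, config, wantGrad = TRUE) {
  arch <- model@arch
  lam <- .lambda(config, corpus)
  total <- 0
  if (wantGrad) {
    gW <- lapply(model@convWeights, function(a) array(0, dim(a)))
    gB <- lapply(model@biasWeights, function(b) rep(0, length(b)))
    gU <- matrix(0, nrow(model@emissionWeights), ncol(model@emissionWeights))
    gT <- matrix(0, arch@numLabels, arch@numLabels)
  }
  for (i in seq_along(corpus@features)) {
    res <- tryCatch(
      .seqObjGrad(model, corpus@features[[i]], corpus@labels[[i]]@states,
                  wantGrad = wantGrad),
      error = function(e) stop(sprintf("sequence '%s': %s", corpus@ids[i],
                                       conditionMessage(e))))
    total <- total + res$ll
    if (wantGrad) {
      for (k in seq_along(gW)) {
        gW[[k]] <- gW[[k]] + res$gradW[[k]]
        gB[[k]] <- gB[[k]] + res$gradB[[k]]
      }
      gU <- gU + res$gradU
      gT <- gT + res$gradT
    }
  }
  theta <- flattenParams(model)
  obj <- total - 0.5 * lam * sum(theta^2)
  if (!wantGrad) return(list(objective = obj))
  gradModel <- model
  gradModel@convWeights <- gW
  gradModel@biasWeights <- gB
  gradModel@emissionWeights <- gU
  gradModel@transitionWeights <- gT
  grad <- flattenParams(gradModel) - lam * theta
  list(objective = obj, gradient = grad,
       gradParts = list(convWeights = gW, biasWeights = gB,
                        emissionWeights = gU, transitionWeights = gT))
}

.checkCorpus <- function(corpus) {
  if (!is(corpus, "DisorderCorpus")) corpus <- DisorderCorpus(
    corpus$features, corpus$labels)
  if (length(corpus) == 0L) stop("empty corpus")
  corpus
}

#' Training objective (weighted penalized log-likelihood)
#'
#' Larger is better; \code{\link{fitDeepCNF}} maximizes this.
#'
#' @param model a \code{\link{DeepCNFModel}} (its labelWeights define the
#'   weighting).
#' @param corpus a \code{\link{DisorderCorpus}}.
#' @param config a \code{\link{trainingConfig}}.
#' @return the scalar objective.
#' @export
dcnfObjective <- function(model, corpus, config = trainingConfig()) {
  corpus <- .checkCorpus(corpus)
  .corpusObjGrad(model, corpus, config, wantGrad = FALSE)$objective
}

#' Analytic gradient of the training objective
#'
#' Exact gradient via forward-backward on the chain (empirical minus
#' expected sufficient statistics, each scaled by its label weight) and
#' backpropagation through the convolutional stack, minus the L2 term.
#'
#' @inheritParams dcnfObjective
#' @param flat return one flat numeric vector (the order of
#'   \code{\link{flattenParams}}) instead of a parameter-shaped list.
#' @return a list with convWeights / biasWeights / emissionWeights /
#'   transitionWeights gradients, or a flat vector.
#' @export
dcnfGradient <- function(model, corpus, config = trainingConfig(), flat = FALSE) {
  corpus <- .checkCorpus(corpus)
  res <- .corpusObjGrad(model, corpus, config, wantGrad = TRUE)
  if (flat) res$gradient else res$gradParts
}

#' Fit a weighted deep convolutional neural field
#'
#' Maximizes the penalized weighted log-likelihood with L-BFGS (history size
#' 10). Deterministic given the seed: the same corpus, architecture and
#' configuration reproduce the identical model. The returned model carries an
#' iteration log (objective and gradient norm per evaluation) in
#' \code{fitInfo}.
#'
#' @param corpus a \code{\link{DisorderCorpus}}.
#' @param arch a \code{\link{DeepCNFArch}}; by default the released
#'   configuration (2 layers x 50 neurons, window 11) at the corpus's feature
#'   width.
#' @param config a \code{\link{trainingConfig}}; its labelWeightRatio becomes
#'   the model's label weights.
#' @param verbose print the objective every few evaluations.
#' @return the fitted \code{\link{DeepCNFModel}}.
#' @export
fitDeepCNF <- function(corpus, arch = NULL, config = trainingConfig(),
                       verbose = FALSE) {
  corpus <- .checkCorpus(corpus)
  inputDim <- ncol(corpus@features[[1L]])
  if (is.null(arch)) arch <- DeepCNFArch(inputDim = inputDim)
  if (arch@inputDim != inputDim)
    stop(sprintf("architecture input width %d does not match corpus feature width %d",
                 arch@inputDim, inputDim))
  manifest <- colnames(corpus@features[[1L]])
  model0 <- newDeepCNFModel(arch, labelWeights = config$labelWeightRatio,
                            seed = config$seed, initRange = config$initRange,
                            featureManifest = if (is.null(manifest)) character() else manifest)
  theta0 <- flattenParams(model0)

  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  trace <- list()
  evalAt <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    m <- unflattenParams(model0, theta)
    res <- .corpusObjGrad(m, corpus, config, wantGrad = TRUE)
    cache$theta <- theta
    cache$res <- res
    trace[[length(trace) + 1L]] <<- c(res$objective, max(abs(res$gradient)))
    if (verbose && length(trace) %% 10L == 1L)
      message(sprintf("eval %4d  objective %.6f  |grad|_inf %.3e",
                      length(trace), res$objective, max(abs(res$gradient))))
    res
  }
  opt <- stats::optim(
    par = theta0,
    fn = function(th) -evalAt(th)$objective,
    gr = function(th) -evalAt(th)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = config$maxIterations, lmm = 10L,
                   factr = 1e7, pgtol = config$convergenceTol))
  if (!opt$convergence %in% c(0L, 1L))
    stop(sprintf("L-BFGS failed (code %d): %s", opt$convergence, opt$message))
  model <- unflattenParams(model0, opt$par)
  tr <- do.call(rbind, trace)
  model@fitInfo <- list(
    trace = data.frame(evaluation = seq_len(nrow(tr)), objective = tr[, 1L],
                       gradInfNorm = tr[, 2L]),
    convergence = opt$convergence,
    message = if (is.null(opt$message)) "" else opt$message,
    finalObjective = -opt$value,
    config = config)
  model
}

#' Reciprocal-frequency label weights
#'
#' For the two-label chain, returns per-label weights proportional to the
#' frequency of the opposite label, normalized to sum to one: with 93\%
#' order / 7\% disorder this gives (0.07, 0.93), so errors on the rare
#' disorder class cost proportionally more.
#'
#' @param corpus a \code{\link{DisorderCorpus}}.
#' @return named numeric weights (order, disorder).
#' @export
reciprocalFrequencyWeights <- function(corpus) {
  corpus <- .checkCorpus(corpus)
  y <- unlist(lapply(corpus@labels, function(l) l@states))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n0 == 0L || n1 == 0L)
    stop("corpus must contain both order and disorder residues")
  c(order = n1, disorder = n0) / (n0 + n1)
}

#' Seeded k-fold split
#'
#' Randomly partitions n items into folds whose sizes differ by at most one;
#' deterministic under the seed.
#'
#' @param n number of items, or a \code{\link{DisorderCorpus}}.
#' @param folds number of folds (2 <= folds <= n).
#' @param seed RNG seed.
#' @return integer fold assignment of length n.
#' @export
kfoldSplit <- function(n, folds = 10L, seed = 42L) {
  if (is(n, "DisorderCorpus")) n <- length(n)
  n <- as.integer(n)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop(sprintf("folds must be between 2 and %d", n))
  withSeed(seed, {
    sample(rep_len(seq_len(folds), n))
  })
}
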