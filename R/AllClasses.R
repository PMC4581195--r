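## Central S4 classes: architecture, model parameters, per-residue labels,
## training corpus, and the packaged amino-acid property tables.

## Canonical residue ordering (PSI-BLAST profile column order). The indicator
## block, the property tables and both profile blocks all use this ordering;
## parsers remap file-local orderings onto it.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABETICAL <- sort(AA_ORDER)

## Eight-state secondary structure (DSSP alphabet, L = loop/coil) and
## three-state solvent accessibility (buried / medium / exposed).
SS8_STATES <- c("H", "G", "I", "E", "B", "T", "S", "L")
ACC3_STATES <- c("B", "M", "E")

## Residue propensity sets: charged/hydrophilic residues favour disorder,
## neutral/hydrophobic residues favour order.
DISORDER_PROMOTING <- c("P", "E", "S", "Q", "K")
ORDER_PROMOTING <- c("C", "W", "I", "Y", "F", "L", "M", "H")

## Label convention: state 0 = order, state 1 = disorder (disorder is the
## positive class everywhere).
LABEL_ORDER <- 0L
LABEL_DISORDER <- 1L

MODEL_FILE_FORMAT <- "DisorderCNF-model"
MODEL_FILE_VERSION <- 1L

#' Architecture of a deep convolutional neural field
#'
#' Describes the fixed (non-trainable) structure of the model: the number of
#' convolutional hidden layers stacked between the per-residue input features
#' and the chain CRF, the number of neurons per layer, the half window of the
#' position-shared convolutions (window = 2 * halfWindow + 1), the activation
#' function, the number of chain labels and the input feature width.
#'
#' @slot numHiddenLayers number of convolutional transforms (>= 1); with one
#'   hidden layer the model reduces to a plain conditional neural field.
#' @slot neuronsPerLayer integer vector, one entry per hidden layer.
#' @slot halfWindow integer vector, one entry per hidden layer; layer k sees
#'   positions i - halfWindow[k] ... i + halfWindow[k].
#' @slot activation "sigmoid" or "tanh".
#' @slot numLabels number of chain states (2 for order/disorder).
#' @slot inputDim width of the per-residue feature vectors.
#' @slot useBias whether each convolutional layer adds a per-neuron bias
#'   (default FALSE: the canonical model has none).
#' @export
setClass("DeepCNFArch",
  slots = c(
    numHiddenLayers = "integer",
    neuronsPerLayer = "integer",
    halfWindow = "integer",
    activation = "character",
    numLabels = "integer",
    inputDim = "integer",
    useBias = "logical"
  )
)

setValidity("DeepCNFArch", function(object) {
  k <- object@numHiddenLayers
  msg <- character()
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "numHiddenLayers must be a single integer >= 1")
  if (length(object@neuronsPerLayer) != k || any(object@neuronsPerLayer < 1L))
    msg <- c(msg, "neuronsPerLayer must have one entry >= 1 per hidden layer")
  if (length(object@halfWindow) != k || any(object@halfWindow < 0L))
    msg <- c(msg, "halfWindow must have one entry >= 0 per hidden layer")
  if (!(object@activation %in% c("sigmoid", "tanh")))
    msg <- c(msg, "activation must be 'sigmoid' or 'tanh'")
  if (object@numLabels < 2L)
    msg <- c(msg, "numLabels must be >= 2")
  if (object@inputDim < 1L)
    msg <- c(msg, "inputDim must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a DeepCNFArch
#'
#' Defaults match the released configuration: two hidden layers of 50 neurons
#' each with an 11-residue window (halfWindow 5), sigmoid activation, two
#' labels.
#'
#' @param inputDim per-residue feature width.
#' @param numHiddenLayers number of convolutional layers.
#' @param neuronsPerLayer neurons per layer; recycled to numHiddenLayers.
#' @param halfWindow half window per layer; recycled to numHiddenLayers.
#' @param activation "sigmoid" (default) or "tanh".
#' @param numLabels number of chain labels (default 2).
#' @param useBias add per-neuron biases to each layer (default FALSE).
#' @return a \code{DeepCNFArch} object.
#' @examples
#' DeepCNFArch(inputDim = 129)
#' @export
DeepCNFArch <- function(inputDim, numHiddenLayers = 2L, neuronsPerLayer = 50L,
                        halfWindow = 5L, activation = c("sigmoid", "tanh"),
                        numLabels = 2L, useBias = FALSE) {
  activation <- match.arg(activation)
  k <- as.integer(numHiddenLayers)
  new("DeepCNFArch",
    numHiddenLayers = k,
    neuronsPerLayer = rep_len(as.integer(neuronsPerLayer), k),
    halfWindow = rep_len(as.integer(halfWindow), k),
    activation = activation,
    numLabels = as.integer(numLabels),
    inputDim = as.integer(inputDim),
    useBias = isTRUE(useBias)
  )
}

## Widths of the successive activation matrices A^1 .. A^{K+1}: input first,
## then one entry per hidden layer.
layerWidths <- function(arch) {
  c(arch@inputDim, arch@neuronsPerLayer)
}

#' Parameters of a weighted deep convolutional neural field
#'
#' Holds every trainable weight together with the fixed architecture and the
#' per-label weights used to counter class imbalance.
#'
#' @slot arch a \code{\link{DeepCNFArch}}.
#' @slot convWeights list of 3-d arrays, one per hidden layer k, with
#'   dimensions (2 * halfWindow[k] + 1) x neurons_out x neurons_in indexed by
#'   window offset, target neuron and source neuron.
#' @slot biasWeights list of numeric vectors (per-neuron biases; all zero and
#'   untouched unless \code{arch@useBias}).
#' @slot emissionWeights numLabels x topWidth matrix U connecting the top
#'   hidden layer to the label layer.
#' @slot transitionWeights numLabels x numLabels matrix T scoring adjacent
#'   label pairs.
#' @slot labelWeights strictly positive per-label weights w multiplying both
#'   potentials (order first, disorder second).
#' @slot featureManifest column names of the feature matrix the model was
#'   built for; assembling features under a different manifest fails.
#' @slot fitInfo list with optimizer diagnostics filled by
#'   \code{\link{fitDeepCNF}} (iteration trace, convergence status).
#' @export
setClass("DeepCNFModel",
  slots = c(
    arch = "DeepCNFArch",
    convWeights = "list",
    biasWeights = "list",
    emissionWeights = "matrix",
    transitionWeights = "matrix",
    labelWeights = "numeric",
    featureManifest = "character",
    fitInfo = "list"
  )
)

setValidity("DeepCNFModel", function(object) {
  arch <- object@arch
  k <- arch@numHiddenLayers
  d <- arch@numLabels
  widths <- layerWidths(arch)
  msg <- character()
  if (length(object@convWeights) != k)
    msg <- c(msg, sprintf("convWeights must hold %d arrays", k))
  else for (i in seq_len(k)) {
    want <- c(2L * arch@halfWindow[i] + 1L, widths[i + 1L], widths[i])
    got <- dim(object@convWeights[[i]])
    if (is.null(got) || !identical(as.integer(got), want))
      msg <- c(msg, sprintf(
        "conv layer %d: weight array must have dim (%s), got (%s)",
        i, paste(want, collapse = ","), paste(got, collapse = ",")))
  }
  if (length(object@biasWeights) != k)
    msg <- c(msg, sprintf("biasWeights must hold %d vectors", k))
  else for (i in seq_len(k))
    if (length(object@biasWeights[[i]]) != widths[i + 1L])
      msg <- c(msg, sprintf("conv layer %d: bias length mismatch", i))
  if (!identical(dim(object@emissionWeights), c(d, widths[k + 1L])))
    msg <- c(msg, sprintf("emissionWeights must be %d x %d", d, widths[k + 1L]))
  if (!identical(dim(object@transitionWeights), c(d, d)))
    msg <- c(msg, sprintf("transitionWeights must be %d x %d", d, d))
  if (length(object@labelWeights) != d || any(!is.finite(object@labelWeights)) ||
      any(object@labelWeights <= 0))
    msg <- c(msg, "labelWeights must be strictly positive, one per label")
  if (length(object@featureManifest) &&
      length(object@featureManifest) != arch@inputDim)
    msg <- c(msg, "featureManifest length must equal inputDim")
  if (length(msg)) msg else TRUE
})

#' Initialize a DeepCNFModel
#'
#' All trainable weights are drawn uniformly from [-initRange, initRange]
#' under the given seed, so initialization is reproducible; biases start at
#' zero.
#'
#' @param arch a \code{\link{DeepCNFArch}}.
#' @param labelWeights per-label weights (order, disorder); default c(1, 1),
#'   the unweighted model.
#' @param seed RNG seed for the initial draw (default 42).
#' @param initRange half width of the uniform initialization (default 0.1).
#' @param featureManifest optional feature column names to freeze into the
#'   model.
#' @param zero initialize every weight at exactly zero instead (handy for
#'   worked examples and oracles).
#' @return a \code{DeepCNFModel}.
#' @examples
#' m <- newDeepCNFModel(DeepCNFArch(inputDim = 10, neuronsPerLayer = 5))
#' architecture(m)
#' @export
newDeepCNFModel <- function(arch, labelWeights = rep(1, arch@numLabels),
                            seed = 42L, initRange = 0.1,
                            featureManifest = character(), zero = FALSE) {
  widths <- layerWidths(arch)
  k <- arch@numHiddenLayers
  d <- arch@numLabels
  draw <- function(n) {
    if (zero) rep(0, n) else stats::runif(n, -initRange, initRange)
  }
  build <- function() {
    conv <- vector("list", k)
    for (i in seq_len(k)) {
      dims <- c(2L * arch@halfWindow[i] + 1L, widths[i + 1L], widths[i])
      conv[[i]] <- array(draw(prod(dims)), dim = dims)
    }
    bias <- lapply(seq_len(k), function(i) rep(0, widths[i + 1L]))
    new("DeepCNFModel",
      arch = arch,
      convWeights = conv,
      biasWeights = bias,
      emissionWeights = matrix(draw(d * widths[k + 1L]), d, widths[k + 1L]),
      transitionWeights = matrix(draw(d * d), d, d),
      labelWeights = as.numeric(labelWeights),
      featureManifest = as.character(featureManifest),
      fitInfo = list())
  }
  if (zero) build() else withSeed(seed, build())
}

#' Per-residue order/disorder labels with a residue mask
#'
#' States follow the convention 0 = order, 1 = disorder. Residues excluded
#' from training/evaluation (annotation "N", no availability) carry state NA
#' and mask FALSE; the mask keeps downstream matrices aligned with the
#' original sequence.
#'
#' @slot states integer vector of 0/1 with NA at excluded positions.
#' @slot mask logical vector, TRUE where the residue is included.
#' @export
setClass("DisorderLabels",
  slots = c(states = "integer", mask = "logical")
)

setValidity("DisorderLabels", function(object) {
  msg <- character()
  if (length(object@states) != length(object@mask))
    msg <- c(msg, "states and mask must have the same length")
  else {
    if (!all(is.na(object@states) == !object@mask))
      msg <- c(msg, "excluded positions (mask FALSE) must carry state NA")
    ok <- object@states[object@mask]
    if (length(ok) && !all(ok %in% c(0L, 1L)))
      msg <- c(msg, "included states must be 0 (order) or 1 (disorder)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct DisorderLabels
#'
#' @param states integer-like vector of 0/1 states; NA marks excluded
#'   residues.
#' @param mask optional logical inclusion mask; defaults to !is.na(states).
#' @return a \code{DisorderLabels} object.
#' @examples
#' DisorderLabels(c(0, 0, NA, 1, 1, 1, 1))
#' @export
DisorderLabels <- function(states, mask = NULL) {
  states <- as.integer(states)
  if (is.null(mask)) mask <- !is.na(states)
  new("DisorderLabels", states = states, mask = as.logical(mask))
}

#' A training corpus of aligned feature/label pairs
#'
#' Items are stored after mask compaction: each feature matrix has one row
#' per included residue and its labels are fully observed.
#'
#' @slot features list of numeric matrices (rows = residues).
#' @slot labels list of \code{\link{DisorderLabels}}, fully observed.
#' @slot ids sequence identifiers.
#' @slot folds integer cross-validation fold per item (NA when unassigned).
#' @export
setClass("DisorderCorpus",
  slots = c(features = "list", labels = "list", ids = "character",
            folds = "integer")
)

setValidity("DisorderCorpus", function(object) {
  n <- length(object@features)
  msg <- character()
  if (length(object@labels) != n || length(object@ids) != n ||
      length(object@folds) != n)
    msg <- c(msg, "features, labels, ids and folds must have equal length")
  else for (i in seq_len(n)) {
    lab <- object@labels[[i]]
    if (!is(lab, "DisorderLabels"))
      msg <- c(msg, sprintf("labels[[%d]] is not DisorderLabels", i))
    else {
      if (!all(lab@mask))
        msg <- c(msg, sprintf("corpus item %d has unmasked residues; compact labels first", i))
      if (nrow(object@features[[i]]) != length(lab@states))
        msg <- c(msg, sprintf("item %d: feature rows != label length", i))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DisorderCorpus
#'
#' @param features list of per-sequence feature matrices (already compacted
#'   to included residues).
#' @param labels list of fully observed \code{\link{DisorderLabels}} (or
#'   plain 0/1 vectors, which are wrapped).
#' @param ids optional sequence identifiers.
#' @param folds optional fold assignment.
#' @return a \code{DisorderCorpus}.
#' @export
DisorderCorpus <- function(features, labels, ids = NULL, folds = NULL) {
  labels <- lapply(labels, function(l)
    if (is(l, "DisorderLabels")) l else DisorderLabels(l))
  n <- length(features)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_len(n))
  if (is.null(folds)) folds <- rep(NA_integer_, n)
  new("DisorderCorpus", features = features, labels = labels,
      ids = as.character(ids), folds = as.integer(folds))
}

#' Packaged amino-acid property tables
#'
#' Three lookup tables keyed by the 20 standard residues: a 7-column
#' physico-chemical table, an 11-column secondary-structure segment-endpoint
#' propensity table and a 40-column correlated contact potential table.
#' The copies shipped under \code{inst/extdata} are synthetic stand-ins (see
#' their provenance headers); users supply their own via
#' \code{\link{loadAminoAcidTables}}.
#'
#' @slot physChem 20 x 7 numeric matrix.
#' @slot ssEndpoint 20 x 11 numeric matrix.
#' @slot contactPotential 20 x 40 numeric matrix.
#' @export
setClass("AminoAcidTables",
  slots = c(physChem = "matrix", ssEndpoint = "matrix",
            contactPotential = "matrix")
)

setValidity("AminoAcidTables", function(object) {
  chk <- function(m, p, what) {
    if (!identical(dim(m), c(20L, p)))
      return(sprintf("%s must be 20 x %d", what, p))
    if (!identical(rownames(m), AA_ORDER))
      return(sprintf("%s rows must be keyed by the 20 standard residues", what))
    NULL
  }
  msg <- c(chk(object@physChem, 7L, "physChem"),
           chk(object@ssEndpoint, 11L, "ssEndpoint"),
           chk(object@contactPotential, 40L, "contactPotential"))
  if (length(msg)) msg else TRUE
})

#' Evolutionary profile for one sequence
#'
#' @slot pssm L x 20 position-specific scoring matrix (PSI-BLAST log-odds),
#'   columns in the canonical residue order.
#' @slot hhm L x 20 profile-HMM match-emission probabilities, same column
#'   order.
#' @export
setClass("SequenceProfile", slots = c(pssm = "matrix", hhm = "matrix"))

setValidity("SequenceProfile", function(object) {
  msg <- character()
  if (ncol(object@pssm) != 20L || ncol(object@hhm) != 20L)
    msg <- c(msg, "pssm and hhm must have 20 columns")
  if (nrow(object@pssm) != nrow(object@hhm))
    msg <- c(msg, "pssm and hhm must cover the same residues")
  if (any(!is.finite(object@pssm)) || any(!is.finite(object@hhm)))
    msg <- c(msg, "profile values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname SequenceProfile-class
#' @param pssm,hhm see the class slots.
#' @return a \code{SequenceProfile}.
#' @export
SequenceProfile <- function(pssm, hhm) {
  new("SequenceProfile", pssm = as.matrix(pssm), hhm = as.matrix(hhm))
}

#' Predicted local-structure probabilities for one sequence
#'
#' @slot ss8 L x 8 secondary-structure probability rows (columns
#'   H,G,I,E,B,T,S,L).
#' @slot acc3 L x 3 solvent-accessibility probability rows (columns B,M,E).
#' @export
setClass("StructurePrediction", slots = c(ss8 = "matrix", acc3 = "matrix"))

setValidity("StructurePrediction", function(object) {
  msg <- character()
  if (ncol(object@ss8) != 8L) msg <- c(msg, "ss8 must have 8 columns")
  if (ncol(object@acc3) != 3L) msg <- c(msg, "acc3 must have 3 columns")
  if (nrow(object@ss8) != nrow(object@acc3))
    msg <- c(msg, "ss8 and acc3 must cover the same residues")
  bad <- .badProbRows(object@ss8)
  if (length(bad)) msg <- c(msg, sprintf(
    "ss8 row %d does not form a probability distribution", bad[1L]))
  bad <- .badProbRows(object@acc3)
  if (length(bad)) msg <- c(msg, sprintf(
    "acc3 row %d does not form a probability distribution", bad[1L]))
  if (length(msg)) msg else TRUE
})

## Rows failing nonnegativity or the sum-to-1 tolerance (printed files are
## rounded, hence the loose 1e-3 band).
.badProbRows <- function(m, tol = 1e-3) {
  which(apply(m, 1L, function(r) any(r < 0) || abs(sum(r) - 1) > tol))
}

#' @rdname StructurePrediction-class
#' @param ss8,acc3 see the class slots.
#' @return a \code{StructurePrediction}.
#' @export
StructurePrediction <- function(ss8, acc3) {
  new("StructurePrediction", ss8 = as.matrix(ss8), acc3 = as.matrix(acc3))
}
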