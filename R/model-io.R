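## Parameter vectorization and the versioned text serialization of a model.

#' Flatten all trainable weights into one numeric vector
#'
#' Order: conv arrays layer by layer (array storage order), then per-layer
#' biases when the architecture uses them, then the emission matrix U, then
#' the transition matrix T. Label weights are hyperparameters, not trainable,
#' and are excluded.
#'
#' @param model a \code{\link{DeepCNFModel}}.
#' @return numeric vector of trainable parameters.
#' @export
flattenParams <- function(model) {
  arch <- model@arch
  parts <- list()
  for (k in seq_len(arch@numHiddenLayers)) {
    parts[[length(parts) + 1L]] <- as.numeric(model@convWeights[[k]])
    if (arch@useBias)
      parts[[length(parts) + 1L]] <- as.numeric(model@biasWeights[[k]])
  }
  parts[[length(parts) + 1L]] <- as.numeric(model@emissionWeights)
  parts[[length(parts) + 1L]] <- as.numeric(model@transitionWeights)
  unlist(parts, use.names = FALSE)
}

#' Rebuild a model from a flattened parameter vector
#'
#' @param model template \code{\link{DeepCNFModel}} supplying the
#'   architecture, label weights and manifest.
#' @param theta numeric vector as produced by \code{\link{flattenParams}}.
#' @return a \code{DeepCNFModel} with the weights replaced.
#' @export
unflattenParams <- function(model, theta) {
  arch <- model@arch
  widths <- layerWidths(arch)
  pos <- 0L
  take <- function(n) {
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  for (k in seq_len(arch@numHiddenLayers)) {
    dims <- c(2L * arch@halfWindow[k] + 1L, widths[k + 1L], widths[k])
    model@convWeights[[k]] <- array(take(prod(dims)), dim = dims)
    if (arch@useBias)
      model@biasWeights[[k]] <- take(widths[k + 1L])
  }
  d <- arch@numLabels
  model@emissionWeights <- matrix(take(d * widths[arch@numHiddenLayers + 1L]),
                                  d, widths[arch@numHiddenLayers + 1L])
  model@transitionWeights <- matrix(take(d * d), d, d)
  if (pos != length(theta))
    stop(sprintf("parameter vector length %d does not match the architecture (expected %d)",
                 length(theta), pos))
  model
}

#' Write a model to a versioned text file
#'
#' Plain-text serialization: a format/version header, the architecture
#' block, the label weights, the feature manifest and the flat weight vector
#' at full double precision, so a written model reloads bit-exactly.
#'
#' @param model a \code{\link{DeepCNFModel}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDeepCNFModel <- function(model, path) {
  arch <- model@arch
  theta <- flattenParams(model)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl(MODEL_FILE_FORMAT, MODEL_FILE_VERSION)
  wl("numHiddenLayers", arch@numHiddenLayers)
  wl("neuronsPerLayer", paste(arch@neuronsPerLayer, collapse = " "))
  wl("halfWindow", paste(arch@halfWindow, collapse = " "))
  wl("activation", arch@activation)
  wl("numLabels", arch@numLabels)
  wl("inputDim", arch@inputDim)
  wl("useBias", as.integer(arch@useBias))
  wl("labelWeights", paste(formatFull(model@labelWeights), collapse = " "))
  wl("manifest", length(model@featureManifest))
  if (length(model@featureManifest))
    writeLines(model@featureManifest, con)
  wl("weights", length(theta))
  writeLines(formatFull(theta), con)
  wl("END")
  invisible(path)
}

#' Read a model written by writeDeepCNFModel
#'
#' Fails loudly on a wrong format tag, an unsupported version or a weight
#' count inconsistent with the declared architecture.
#'
#' @param path model file.
#' @return a \code{\link{DeepCNFModel}}.
#' @export
readDeepCNFModel <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "[ \t]+")[[1L]]
  if (length(hdr) != 2L || hdr[1L] != MODEL_FILE_FORMAT)
    stop(sprintf("'%s' is not a %s file", path, MODEL_FILE_FORMAT))
  if (as.integer(hdr[2L]) != MODEL_FILE_VERSION)
    stop(sprintf("unsupported model file version %s (this build reads version %d)",
                 hdr[2L], MODEL_FILE_VERSION))
  idx <- 2L
  field <- function(name, n = 1L) {
    toks <- strsplit(lines[idx], "[ \t]+")[[1L]]
    if (toks[1L] != name)
      stop(sprintf("malformed model file: expected field '%s' at line %d", name, idx))
    idx <<- idx + 1L
    toks[-1L]
  }
  ## fields are read strictly in file order (field() advances a cursor)
  numHiddenLayers <- as.integer(field("numHiddenLayers"))
  neuronsPerLayer <- as.integer(field("neuronsPerLayer"))
  halfWindow <- as.integer(field("halfWindow"))
  activation <- field("activation")
  numLabels <- as.integer(field("numLabels"))
  inputDim <- as.integer(field("inputDim"))
  useBias <- as.integer(field("useBias")) == 1L
  arch <- DeepCNFArch(numHiddenLayers = numHiddenLayers,
                      neuronsPerLayer = neuronsPerLayer,
                      halfWindow = halfWindow, activation = activation,
                      numLabels = numLabels, inputDim = inputDim,
                      useBias = useBias)
  w <- as.numeric(field("labelWeights"))
  nman <- as.integer(field("manifest"))
  manifest <- character()
  if (nman > 0L) {
    manifest <- lines[idx:(idx + nman - 1L)]
    idx <- idx + nman
  }
  nw <- as.integer(field("weights"))
  theta <- as.numeric(lines[idx:(idx + nw - 1L)])
  idx <- idx + nw
  if (!identical(lines[idx], "END"))
    stop("malformed model file: missing END terminator")
  template <- newDeepCNFModel(arch, labelWeights = w, zero = TRUE,
                              featureManifest = manifest)
  model <- tryCatch(unflattenParams(template, theta), error = function(e)
    stop(sprintf("model file '%s': weight block does not match the declared architecture (%s)",
                 path, conditionMessage(e))))
  validObject(model)
  model
}
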