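## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for DisorderCNF objects
#' @description Slot accessors for the S4 classes; user code should use these
#'   rather than reaching into slots.
#' @param object,x an object of the documented class.
#' @param value replacement value.
#' @param i index.
#' @param j,...,drop ignored (list-style subsetting).
NULL

#' @rdname accessors
#' @export
setGeneric("architecture", function(object) standardGeneric("architecture"))
#' @rdname accessors
#' @export
setMethod("architecture", "DeepCNFModel", function(object) object@arch)

#' @rdname accessors
#' @export
setGeneric("convWeights", function(object) standardGeneric("convWeights"))
#' @rdname accessors
#' @export
setMethod("convWeights", "DeepCNFModel", function(object) object@convWeights)

#' @rdname accessors
#' @export
setGeneric("emissionWeights", function(object) standardGeneric("emissionWeights"))
#' @rdname accessors
#' @export
setMethod("emissionWeights", "DeepCNFModel", function(object) object@emissionWeights)

#' @rdname accessors
#' @export
setGeneric("transitionWeights", function(object) standardGeneric("transitionWeights"))
#' @rdname accessors
#' @export
setMethod("transitionWeights", "DeepCNFModel", function(object) object@transitionWeights)

#' @rdname accessors
#' @export
setGeneric("labelWeights", function(object) standardGeneric("labelWeights"))
#' @rdname accessors
#' @export
setMethod("labelWeights", "DeepCNFModel", function(object) object@labelWeights)

#' @rdname accessors
#' @export
setGeneric("featureManifest", function(object) standardGeneric("featureManifest"))
#' @rdname accessors
#' @export
setMethod("featureManifest", "DeepCNFModel", function(object) object@featureManifest)

#' @rdname accessors
#' @export
setGeneric("fitInfo", function(object) standardGeneric("fitInfo"))
#' @rdname accessors
#' @export
setMethod("fitInfo", "DeepCNFModel", function(object) object@fitInfo)

#' @rdname accessors
#' @export
setGeneric("states", function(object) standardGeneric("states"))
#' @rdname accessors
#' @export
setMethod("states", "DisorderLabels", function(object) object@states)

#' @rdname accessors
#' @export
setGeneric("residueMask", function(object) standardGeneric("residueMask"))
#' @rdname accessors
#' @export
setMethod("residueMask", "DisorderLabels", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("includedStates", function(object) standardGeneric("includedStates"))
#' @rdname accessors
#' @export
setMethod("includedStates", "DisorderLabels",
          function(object) object@states[object@mask])

#' @rdname accessors
#' @export
setMethod("length", "DisorderLabels", function(x) length(x@states))

#' @rdname accessors
#' @export
setGeneric("corpusFeatures", function(object) standardGeneric("corpusFeatures"))
#' @rdname accessors
#' @export
setMethod("corpusFeatures", "DisorderCorpus", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("corpusLabels", function(object) standardGeneric("corpusLabels"))
#' @rdname accessors
#' @export
setMethod("corpusLabels", "DisorderCorpus", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("sequenceIds", function(object) standardGeneric("sequenceIds"))
#' @rdname accessors
#' @export
setMethod("sequenceIds", "DisorderCorpus", function(object) object@ids)

#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setMethod("foldAssignment", "DisorderCorpus", function(object) object@folds)

#' @rdname accessors
#' @export
setGeneric("foldAssignment<-", function(object, value) standardGeneric("foldAssignment<-"))
#' @rdname accessors
#' @export
setMethod("foldAssignment<-", "DisorderCorpus", function(object, value) {
  object@folds <- rep_len(as.integer(value), length(object@features))
  validObject(object)
  object
})

#' @rdname accessors
#' @export
setMethod("length", "DisorderCorpus", function(x) length(x@features))

#' @rdname accessors
#' @export
setMethod("[", "DisorderCorpus", function(x, i, j, ..., drop = TRUE) {
  new("DisorderCorpus", features = x@features[i], labels = x@labels[i],
      ids = x@ids[i], folds = x@folds[i])
})

setMethod("show", "DeepCNFArch", function(object) {
  cat(sprintf(
    "DeepCNFArch: %d hidden layer(s), neurons [%s], window [%s], %s, %d labels, input width %d%s\n",
    object@numHiddenLayers,
    paste(object@neuronsPerLayer, collapse = ","),
    paste(2L * object@halfWindow + 1L, collapse = ","),
    object@activation, object@numLabels, object@inputDim,
    if (object@useBias) ", with biases" else ""))
})

setMethod("show", "DeepCNFModel", function(object) {
  show(object@arch)
  cat(sprintf("DeepCNFModel: %d trainable parameters, label weights [%s]\n",
              length(flattenParams(object)),
              paste(format(object@labelWeights), collapse = ":")))
  if (length(object@fitInfo))
    cat(sprintf("  fitted: final objective %.6g after %d evaluations\n",
                utils::tail(object@fitInfo$trace$objective, 1L),
                nrow(object@fitInfo$trace)))
})

setMethod("show", "DisorderLabels", function(object) {
  s <- object@states
  cat(sprintf(
    "DisorderLabels: %d residues (%d disorder, %d order, %d excluded)\n",
    length(s), sum(s == 1L, na.rm = TRUE), sum(s == 0L, na.rm = TRUE),
    sum(is.na(s))))
})

setMethod("show", "DisorderCorpus", function(object) {
  n <- length(object)
  res <- sum(vapply(object@labels, length, 1L))
  dis <- sum(vapply(object@labels, function(l) sum(l@states == 1L), 1L))
  cat(sprintf(
    "DisorderCorpus: %d sequences, %d residues (%.1f%% disorder)%s\n",
    n, res, if (res) 100 * dis / res else 0,
    if (all(is.na(object@folds))) "" else
      sprintf(", %d folds", length(unique(stats::na.omit(object@folds))))))
})

setMethod("show", "AminoAcidTables", function(object) {
  cat("AminoAcidTables: 20 x (7 + 11 + 40) residue property tables\n")
})

setMethod("show", "SequenceProfile", function(object) {
  cat(sprintf("SequenceProfile: %d residues (PSSM + HHM, 20 columns each)\n",
              nrow(object@pssm)))
})

setMethod("show", "StructurePrediction", function(object) {
  cat(sprintf("StructurePrediction: %d residues (SS8 + ACC3 probabilities)\n",
              nrow(object@ss8)))
})
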