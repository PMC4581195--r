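## Corpus assembly from a training manifest, and end-to-end prediction.

#' Build a training corpus from a manifest
#'
#' The manifest is a tab-separated table with one row per sequence and
#' columns id, fasta, pssm, hhm, ss8, acc3, labels and fold (paths relative
#' to the manifest's directory; profile/structure columns may be empty when
#' the corresponding feature class is not requested). Sequences are read
#' from FASTA, annotations converted to labels under the CASP rule, features
#' assembled for the requested classes, and residues masked as unavailable
#' dropped, so every corpus item is fully observed.
#'
#' @param manifestPath path to the manifest TSV.
#' @param classes feature classes to assemble (subset of "ami", "evo",
#'   "struct").
#' @param tables amino-acid tables for the "ami" block.
#' @return a \code{\link{DisorderCorpus}}.
#' @export
buildCorpus <- function(manifestPath, classes = c("ami", "evo", "struct"),
                        tables = loadAminoAcidTables()) {
  base <- dirname(manifestPath)
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("id", "fasta", "labels")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop(sprintf("manifest is missing column(s): %s", paste(miss, collapse = ", ")))
  resolve <- function(p) ifelse(is.na(p) | p == "", NA_character_,
                                file.path(base, p))
  fastaCache <- new.env(parent = emptyenv())
  annCache <- new.env(parent = emptyenv())
  getFasta <- function(p) {
    if (is.null(fastaCache[[p]])) {
      if (!file.exists(p)) stop(sprintf("FASTA file not found: %s", p))
      fastaCache[[p]] <- readFastaSequences(p)
    }
    fastaCache[[p]]
  }
  getAnn <- function(p) {
    if (is.null(annCache[[p]])) {
      if (!file.exists(p)) stop(sprintf("label file not found: %s", p))
      annCache[[p]] <- readAnnotations(p)
    }
    annCache[[p]]
  }
  features <- vector("list", nrow(man))
  labels <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$id[i]
    seqs <- getFasta(resolve(man$fasta[i]))
    if (!(id %in% names(seqs)))
      stop(sprintf("sequence '%s' not found in %s", id, man$fasta[i]))
    sequence <- seqs[[id]]
    anns <- getAnn(resolve(man$labels[i]))
    if (!(id %in% names(anns)))
      stop(sprintf("labels for '%s' not found in %s", id, man$labels[i]))
    lab <- labelFromAnnotation(anns[[id]])
    if (length(lab) != nchar(sequence))
      stop(sprintf("'%s': annotation length %d != sequence length %d",
                   id, length(lab), nchar(sequence)))
    profile <- NULL
    if ("evo" %in% classes) {
      pp <- resolve(man$pssm[i]); hp <- resolve(man$hhm[i])
      if (is.na(pp) || is.na(hp))
        stop(sprintf("'%s': evolution features requested but no pssm/hhm path in manifest", id))
      if (!file.exists(pp)) stop(sprintf("PSSM file not found: %s", pp))
      if (!file.exists(hp)) stop(sprintf("HHM file not found: %s", hp))
      profile <- SequenceProfile(parsePSSM(pp, sequence), parseHHM(hp))
    }
    struct <- NULL
    if ("struct" %in% classes) {
      sp <- resolve(man$ss8[i]); ap <- resolve(man$acc3[i])
      if (is.na(sp) || is.na(ap))
        stop(sprintf("'%s': structure features requested but no ss8/acc3 path in manifest", id))
      if (!file.exists(sp)) stop(sprintf("SS8 file not found: %s", sp))
      if (!file.exists(ap)) stop(sprintf("ACC3 file not found: %s", ap))
      struct <- StructurePrediction(readStructProbs(sp, 8L),
                                    readStructProbs(ap, 3L))
    }
    fm <- assembleFeatures(sequence, tables = tables, profile = profile,
                           struct = struct, classes = classes)
    cmp <- dropMaskedResidues(fm, lab)
    features[[i]] <- cmp$features
    labels[[i]] <- cmp$labels
  }
  folds <- if ("fold" %in% names(man)) as.integer(man$fold) else
    rep(NA_integer_, nrow(man))
  DisorderCorpus(features, labels, ids = man$id, folds = folds)
}

#' Predict per-residue disorder for one sequence
#'
#' Assembles the feature classes the model was trained with (from its
#' manifest), verifies the manifest matches, and returns the posterior
#' disorder probability and the thresholded call for every residue.
#'
#' @param model a fitted \code{\link{DeepCNFModel}}.
#' @param sequence the protein sequence.
#' @param profile a \code{\link{SequenceProfile}} if the model uses
#'   evolution features.
#' @param struct a \code{\link{StructurePrediction}} if the model uses
#'   structure features.
#' @param tables amino-acid tables.
#' @param threshold decision threshold (default 0.2).
#' @param id sequence identifier stamped into the result.
#' @return data.frame with columns id, pos, residue, prob, call.
#' @export
predictDisorder <- function(model, sequence, profile = NULL, struct = NULL,
                            tables = loadAminoAcidTables(), threshold = 0.2,
                            id = "query") {
  manifest <- model@featureManifest
  if (!length(manifest))
    stop("model carries no feature manifest; cannot verify inputs")
  classes <- unique(sub("_.*$", "", manifest))
  if ("evo" %in% classes && is.null(profile))
    stop("missing feature class: the model needs evolution features (supply a profile)")
  if ("struct" %in% classes && is.null(struct))
    stop("missing feature class: the model needs structure features (supply a structure prediction)")
  fm <- assembleFeatures(sequence, tables = tables, profile = profile,
                         struct = struct, classes = classes)
  if (!identical(colnames(fm), manifest))
    stop("assembled feature columns do not match the model's feature manifest")
  marg <- posteriorMarginals(model, fm)
  prob <- marg[, "disorder"]
  data.frame(id = id, pos = seq_len(nrow(fm)),
             residue = normalizeResidues(sequence),
             prob = prob, call = classifyDisorder(prob, threshold),
             stringsAsFactors = FALSE)
}
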