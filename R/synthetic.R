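## Seeded synthetic corpus generator: imbalanced order/disorder label chains
## with a realistic segment-length mixture, plus format-valid FASTA, PSSM,
## HHM and SS8/ACC3 files whose content carries a tunable amount of label
## signal. Everything other modules consume can be produced here, so the
## whole pipeline trains and evaluates offline.

## Segment-length mixture over the four length bins, defaulting to the
## fragment-count proportions of a crystallographic training set
## (492 : 226 : 45 : 19 over 1-5 / 6-15 / 16-25 / >25).
DEFAULT_SEGMENT_MIXTURE <- c(`1-5` = 492, `6-15` = 226, `16-25` = 45,
                             `>25` = 19) / 782

#' Synthetic-corpus configuration
#'
#' Defaults describe the emulated study conditions: 100 sequences of 200
#' residues, ~7\% disordered residues, the segment-length mixture above,
#' planted feature signal of strength 3, no unavailable residues, disorder
#' segments kept away from the chain termini.
#'
#' @param nSequences number of sequences.
#' @param lengthRange min/max sequence length (inclusive).
#' @param disorderFraction target pooled fraction of disordered residues.
#' @param segmentMixture probabilities over the four length bins 1-5, 6-15,
#'   16-25, >25 (must sum to 1).
#' @param signalStrength nonnegative; how strongly residue composition,
#'   profiles and structure probabilities encode the hidden labels (0 = no
#'   signal).
#' @param naRate per-residue probability of an N (not available) mark on
#'   observed positions.
#' @param allowTerminal permit disorder segments touching a chain end
#'   (default FALSE so non-terminal segment statistics are exercised
#'   cleanly).
#' @param seed RNG seed.
#' @return list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nSequences = 100L, lengthRange = c(200L, 200L),
                            disorderFraction = 0.07,
                            segmentMixture = DEFAULT_SEGMENT_MIXTURE,
                            signalStrength = 3, naRate = 0,
                            allowTerminal = FALSE, seed = 42L) {
  stopifnot(nSequences >= 1, length(lengthRange) == 2L,
            lengthRange[1L] >= 10L, lengthRange[2L] >= lengthRange[1L],
            disorderFraction >= 0, disorderFraction < 1,
            length(segmentMixture) == 4L,
            abs(sum(segmentMixture) - 1) < 1e-8,
            signalStrength >= 0, naRate >= 0, naRate < 1)
  structure(list(
    nSequences = as.integer(nSequences),
    lengthRange = as.integer(lengthRange),
    disorderFraction = disorderFraction,
    segmentMixture = as.numeric(segmentMixture),
    signalStrength = signalStrength,
    naRate = naRate,
    allowTerminal = isTRUE(allowTerminal),
    seed = as.integer(seed)
  ), class = "syntheticConfig")
}

## Draw one segment length: bin from the mixture, length uniform within the
## bin (the open-ended bin uses 26..60).
.drawSegmentLength <- function(mixture) {
  lo <- c(1L, 6L, 16L, 26L)
  hi <- c(5L, 15L, 25L, 60L)
  b <- sample.int(4L, 1L, prob = mixture)
  sample(lo[b]:hi[b], 1L)
}

## One annotation string: place non-overlapping, non-adjacent disorder
## segments until the per-sequence residue target is met (the last segment is
## truncated to the remainder so the pooled fraction tracks the target).
## Segments of length >= 4 are written as runs of D; shorter segments use the
## coordinate-missing mark X, which the labeling rule also calls disordered,
## so annotations round-trip exactly through labelFromAnnotation.
.oneAnnotation <- function(config) {
  L <- if (config$lengthRange[1L] == config$lengthRange[2L])
    config$lengthRange[1L] else
    sample(config$lengthRange[1L]:config$lengthRange[2L], 1L)
  ann <- rep("O", L)
  target <- round(config$disorderFraction * L)
  placed <- 0L
  blocked <- rep(FALSE, L)  # segment positions plus a one-residue buffer
  tries <- 0L
  while (placed < target && tries < 200L) {
    tries <- tries + 1L
    len <- min(.drawSegmentLength(config$segmentMixture), target - placed)
    loStart <- if (config$allowTerminal) 1L else 2L
    hiStart <- if (config$allowTerminal) L - len + 1L else L - len
    if (hiStart < loStart) next
    start <- sample(loStart:hiStart, 1L)
    span <- start:(start + len - 1L)
    if (any(blocked[span])) next
    ann[span] <- if (len >= 4L) "D" else "X"
    blocked[max(1L, start - 1L):min(L, start + len)] <- TRUE
    placed <- placed + len
  }
  if (config$naRate > 0) {
    obs <- which(ann == "O")
    flip <- obs[stats::runif(length(obs)) < config$naRate]
    ann[flip] <- "N"
  }
  paste(ann, collapse = "")
}

#' Generate annotation strings and labels
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{annotations} (named character vector over
#'   O/D/N/X) and \code{labels} (list of \code{\link{DisorderLabels}}).
#' @export
generateDisorderLabels <- function(config = syntheticConfig()) {
  withSeed(config$seed, .generateLabelsInner(config))
}

.generateLabelsInner <- function(config) {
  ids <- sprintf("synth%03d", seq_len(config$nSequences))
  ann <- vapply(ids, function(.) .oneAnnotation(config), "")
  names(ann) <- ids
  labels <- lapply(ann, labelFromAnnotation)
  list(annotations = ann, labels = labels)
}

## Residue sampling probabilities for one label state: disorder-promoting
## residues (P,E,S,Q,K) are enriched in disordered segments and
## order-promoting residues (C,W,I,Y,F,L,M,H) in ordered ones, with the
## log-enrichment proportional to signalStrength.
.residueLogits <- function(state, signal) {
  s <- numeric(20L)
  s[AA_ORDER %in% DISORDER_PROMOTING] <- 0.5
  s[AA_ORDER %in% ORDER_PROMOTING] <- -0.5
  dir <- if (state == 1L) 1 else -1
  signal * dir * s
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.oneSequenceData <- function(states, signal) {
  L <- length(states)
  st <- ifelse(is.na(states), 0L, states)  # unavailable residues: no signal bias
  seqChars <- character(L)
  pssm <- matrix(0L, L, 20L)
  hhm <- matrix(0, L, 20L)
  ss8 <- matrix(0, L, 8L)
  acc3 <- matrix(0, L, 3L)
  dirSign <- ifelse(st == 1L, 1, -1)
  base <- numeric(20L)
  base[AA_ORDER %in% DISORDER_PROMOTING] <- 0.5
  base[AA_ORDER %in% ORDER_PROMOTING] <- -0.5
  for (i in seq_len(L)) {
    logits <- signal * dirSign[i] * base
    seqChars[i] <- sample(AA_ORDER, 1L, prob = .softmax(logits))
    pssm[i, ] <- round(stats::rnorm(20L, 0, 2) + 1.5 * signal * dirSign[i] * base)
    p <- .softmax(stats::rnorm(20L, 0, 0.7) + 0.4 * signal * dirSign[i] * base)
    hhm[i, ] <- p
    aSS <- rep(1, 8L)
    if (st[i] == 1L) aSS[SS8_STATES == "L"] <- 1 + 1.2 * signal
    else aSS[SS8_STATES %in% c("H", "E")] <- 1 + 0.6 * signal
    g <- stats::rgamma(8L, shape = aSS)
    ss8[i, ] <- g / sum(g)
    aACC <- rep(1, 3L)
    if (st[i] == 1L) aACC[ACC3_STATES == "E"] <- 1 + 1.2 * signal
    else aACC[ACC3_STATES == "B"] <- 1 + 0.6 * signal
    g <- stats::rgamma(3L, shape = aACC)
    acc3[i, ] <- g / sum(g)
  }
  colnames(pssm) <- AA_ORDER
  colnames(hhm) <- AA_ORDER
  colnames(ss8) <- SS8_STATES
  colnames(acc3) <- ACC3_STATES
  list(sequence = paste(seqChars, collapse = ""), pssm = pssm, hhm = hhm,
       ss8 = ss8, acc3 = acc3)
}

#' Generate a complete synthetic data set on disk
#'
#' Writes, under \code{dir}: \code{sequences.fasta}, \code{labels.tsv}
#' (O/D/N/X annotation strings), per-sequence \code{profiles/<id>.pssm},
#' \code{.hhm}, \code{.ss8}, \code{.acc3} files in the exact dialects the
#' package parsers consume, and \code{manifest.tsv} tying them together (one
#' row per sequence: id, file paths, fold). All randomness is governed by
#' \code{config$seed}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
generateSyntheticData <- function(config = syntheticConfig(), dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  withSeed(config$seed, {
    gen <- .generateLabelsInner(config)
    ids <- names(gen$annotations)
    seqs <- character(length(ids))
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      id <- ids[i]
      dat <- .oneSequenceData(states(gen$labels[[i]]), config$signalStrength)
      seqs[i] <- dat$sequence
      pssmPath <- file.path("profiles", paste0(id, ".pssm"))
      hhmPath <- file.path("profiles", paste0(id, ".hhm"))
      ss8Path <- file.path("profiles", paste0(id, ".ss8"))
      acc3Path <- file.path("profiles", paste0(id, ".acc3"))
      writePSSMFile(dat$sequence, dat$pssm, file.path(dir, pssmPath))
      writeHHMFile(id, dat$sequence, dat$hhm, file.path(dir, hhmPath))
      writeStructProbs(dat$sequence, dat$ss8, file.path(dir, ss8Path))
      writeStructProbs(dat$sequence, dat$acc3, file.path(dir, acc3Path))
      rows[[i]] <- data.frame(id = id, fasta = "sequences.fasta",
                              pssm = pssmPath, hhm = hhmPath,
                              ss8 = ss8Path, acc3 = acc3Path,
                              labels = "labels.tsv", fold = NA_integer_,
                              stringsAsFactors = FALSE)
    }
    names(seqs) <- ids
    writeFastaSequences(seqs, file.path(dir, "sequences.fasta"))
    writeAnnotations(gen$annotations, file.path(dir, "labels.tsv"))
    manifest <- do.call(rbind, rows)
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  invisible(file.path(dir, "manifest.tsv"))
}

#' Write a PSI-BLAST-style ASCII PSSM
#'
#' @param sequence the protein sequence.
#' @param pssm L x 20 integer score matrix (canonical residue column order).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePSSMFile <- function(sequence, pssm, path) {
  res <- strsplit(sequence, "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", AA_ORDER), collapse = " "))), con)
  for (i in seq_len(nrow(pssm)))
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(pssm[i, ])),
                            collapse = " ")), con)
  writeLines("", con)
  invisible(path)
}

#' Write an HH-suite-style HHM profile
#'
#' Match emissions are stored as round(-1000 * log2(p)) with "*" for
#' probabilities below 2^-20; columns are written in alphabetical residue
#' order as HH-suite does.
#'
#' @param id sequence identifier.
#' @param sequence the protein sequence.
#' @param hhm L x 20 emission-probability matrix (canonical column order).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHHMFile <- function(id, sequence, hhm, path) {
  res <- strsplit(sequence, "")[[1L]]
  if (is.null(colnames(hhm))) colnames(hhm) <- AA_ORDER
  m <- hhm[, AA_ALPHABETICAL, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("HHsearch 1.5",
               paste("NAME ", id),
               paste("LENG ", nrow(m)),
               paste("HMM   ", paste(AA_ALPHABETICAL, collapse = "\t")),
               paste0("      ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                                        "D->M", "D->D", "Neff", "Neff_I",
                                        "Neff_D"), collapse = "\t"))), con)
  enc <- function(p) {
    ifelse(p < 2^-20, "*", as.character(round(-1000 * log2(p))))
  }
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(res[i], i, enc(m[i, ]), i), collapse = "\t"), con)
    writeLines(paste(c("", rep("0", 10L)), collapse = "\t"), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write an SS8 or ACC3 probability TSV
#'
#' @param sequence the protein sequence.
#' @param probs L x 8 or L x 3 probability matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructProbs <- function(sequence, probs, path) {
  res <- strsplit(sequence, "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#pos\tres\t", paste(colnames(probs), collapse = "\t")), con)
  for (i in seq_len(nrow(probs)))
    writeLines(paste(c(i, res[i], sprintf("%.4f", probs[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}
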