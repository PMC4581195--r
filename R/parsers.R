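## Parsers for the external file dialects: PSI-BLAST ASCII PSSM, HH-suite
## HHM, SS8/ACC3 probability TSVs, FASTA (via Biostrings), annotation and
## prediction tables.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastaSequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the first score block of the standard PSI-BLAST matrix layout:
#' header lines, then one row per residue holding the position index, the
#' residue letter and 20 integer log-odds scores in the column order
#' A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @param path PSSM file.
#' @param sequence optional sequence; when given, row count and residue
#'   letters are cross-checked against it.
#' @return L x 20 numeric matrix (columns in the canonical residue order).
#' @export
parsePSSM <- function(path, sequence = NULL) {
  lines <- readLines(path)
  rows <- list()
  letters20 <- c(AA_ORDER, "X", "B", "Z", "U", "O", "J")
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    if (length(toks) < 2L) next
    if (!grepl("^[0-9]+$", toks[1L])) next
    if (!(toks[2L] %in% letters20)) next
    if (length(toks) < 22L)
      stop(sprintf("malformed PSSM row at line %d: expected 20 scores after the residue letter",
                   ln))
    vals <- suppressWarnings(as.numeric(toks[3L:22L]))
    if (anyNA(vals))
      stop(sprintf("malformed PSSM row at line %d: non-numeric score", ln))
    rows[[length(rows) + 1L]] <- list(pos = as.integer(toks[1L]),
                                      res = toks[2L], scores = vals)
  }
  if (!length(rows))
    stop(sprintf("no PSSM rows found in %s", path))
  m <- do.call(rbind, lapply(rows, `[[`, "scores"))
  colnames(m) <- AA_ORDER
  resLetters <- vapply(rows, `[[`, "", "res")
  if (!is.null(sequence)) {
    seqRes <- normalizeResidues(sequence)
    if (nrow(m) != length(seqRes))
      stop(sprintf("PSSM has %d rows but the sequence has %d residues",
                   nrow(m), length(seqRes)))
    fileRes <- normalizeResidues(resLetters)
    bad <- which(fileRes != seqRes)
    if (length(bad))
      stop(sprintf("PSSM residue '%s' does not match sequence residue '%s' at position %d",
                   fileRes[bad[1L]], seqRes[bad[1L]], bad[1L]))
  }
  attr(m, "residues") <- resLetters
  m
}

#' Parse an HH-suite HHM profile
#'
#' Reads the match-emission block: lines between the "HMM" header and the
#' "//" terminator whose first token is a residue letter and second token a
#' position index, each carrying 20 emission fields. Fields are stored as
#' -1000 * log2(p) ("*" meaning no emission, probability 0) and are
#' converted back to probabilities.
#'
#' @param path HHM file.
#' @return L x 20 numeric matrix of match-emission probabilities, columns
#'   remapped to the canonical residue order.
#' @export
parseHHM <- function(path) {
  lines <- readLines(path)
  start <- which(grepl("^HMM\\b", lines))
  if (!length(start))
    stop(sprintf("no HMM block found in %s", path))
  start <- start[1L]
  hdr <- strsplit(trimws(lines[start]), "[ \t]+")[[1L]][-1L]
  if (length(hdr) < 20L)
    hdr <- AA_ALPHABETICAL  # some writers put the letters on their own line
  cols <- hdr[seq_len(20L)]
  rows <- list()
  terminated <- FALSE
  for (ln in (start + 1L):length(lines)) {
    line <- lines[ln]
    if (grepl("^//", line)) { terminated <- TRUE; break }
    toks <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(toks) < 22L) next
    if (!grepl("^[A-Z]$", toks[1L]) || !grepl("^[0-9]+$", toks[2L])) next
    fields <- toks[3L:22L]
    p <- numeric(20L)
    for (j in seq_len(20L)) {
      if (fields[j] == "*") {
        p[j] <- 0
      } else {
        v <- suppressWarnings(as.numeric(fields[j]))
        if (is.na(v))
          stop(sprintf("non-numeric emission field '%s' at line %d of %s",
                       fields[j], ln, path))
        p[j] <- 2^(-v / 1000)
      }
    }
    rows[[length(rows) + 1L]] <- p
  }
  if (!terminated)
    stop(sprintf("HHM block in %s is missing its '//' terminator", path))
  if (!length(rows))
    stop(sprintf("no match-emission rows found in %s", path))
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  m[, AA_ORDER, drop = FALSE]
}

#' Read predicted structure probabilities from TSV
#'
#' Layout: comment lines starting with '#', then one row per residue with
#' the position, optionally the residue letter, and the state probabilities
#' (8 columns for secondary structure, 3 for solvent accessibility).
#'
#' @param path TSV file.
#' @param states number of probability columns (8 or 3).
#' @return L x states numeric matrix.
#' @export
readStructProbs <- function(path, states) {
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= states + 2L && !is.numeric(tab[[2L]]))
    tab <- tab[, -2L, drop = FALSE]
  if (ncol(tab) < states + 1L)
    stop(sprintf("%s: expected position plus %d probability columns", path, states))
  m <- as.matrix(tab[, 2L:(states + 1L), drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- if (states == 8L) SS8_STATES else
    if (states == 3L) ACC3_STATES else NULL
  rownames(m) <- NULL
  bad <- .badProbRows(m)
  if (length(bad))
    stop(sprintf("%s: row %d does not form a probability distribution", path, bad[1L]))
  m
}

#' Read per-sequence coordinate annotations
#'
#' Accepts either two-column lines "id  OODDXN..." or a two-column TSV with
#' a header; strings run over O (observed), D (coordinates missing), N (not
#' available) and X (coordinate-missing mark).
#'
#' @param path annotation file.
#' @return named character vector of annotation strings.
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop(sprintf("annotation line %d has no id/string pair", bad[1L]))
  ids <- vapply(toks, `[[`, "", 1L)
  ann <- toupper(vapply(toks, `[[`, "", 2L))
  if (identical(tolower(ids[1L]), "id")) { ids <- ids[-1L]; ann <- ann[-1L] }
  stats::setNames(ann, ids)
}

#' Write per-sequence coordinate annotations
#'
#' @param annotations named character vector over O/D/N/X.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  writeLines(paste(names(annotations), annotations, sep = "\t"), path)
  invisible(path)
}

#' Write per-residue disorder predictions
#'
#' The common disorder-predictor tabular layout: one line per residue with
#' sequence id, position, residue letter, posterior disorder probability and
#' the binary call; masked residues carry probability NA and the call ".".
#' Header comments stamp the threshold and seed.
#'
#' @param predictions list (one element per sequence) of data.frames with
#'   columns id, pos, residue, prob, call.
#' @param path output file.
#' @param header named character vector stamped as '# key: value' lines.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(predictions, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# DisorderCNF predictions (version %s)",
                     as.character(utils::packageVersion("DisorderCNF"))), con)
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines("# id\tpos\tresidue\tprob\tcall", con)
  tab <- do.call(rbind, predictions)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s", tab$id, tab$pos, tab$residue,
                     ifelse(is.na(tab$prob), "NA", sprintf("%.6f", tab$prob)),
                     as.character(tab$call)), con)
  invisible(path)
}

#' Read predictions written by writePredictions
#'
#' @param path prediction file.
#' @return data.frame with columns id, pos, residue, prob, call.
#' @export
readPredictions <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "pos", "residue", "prob", "call"))
  tab$prob <- suppressWarnings(as.numeric(tab$prob))
  tab
}
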