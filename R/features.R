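## Per-residue feature construction: 129 = 78 amino-acid + 40 evolution +
## 11 structure columns. Column names carry a class prefix (ami_, evo_,
## struct_) so feature-class ablations are column subsets, and the full set
## of names is the manifest frozen into every model.

#' Load the amino-acid property tables
#'
#' Reads the three lookup tables (7-column physico-chemical, 11-column
#' secondary-structure endpoint propensity, 40-column correlated contact
#' potential) from tab-separated files named \code{aa_physchem7*.tsv},
#' \code{aa_ss_endpoint11*.tsv} and \code{aa_contact_potential40*.tsv}. The
#' copies shipped with the package are deterministic synthetic stand-ins
#' (the canonical values live in the literature); point \code{path} at a
#' directory with replacement files to use real tables.
#'
#' @param path directory containing the three files; default: the packaged
#'   copies.
#' @return an \code{\link{AminoAcidTables}} object.
#' @export
loadAminoAcidTables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", package = "DisorderCNF")
  readOne <- function(pattern, p) {
    f <- list.files(path, pattern = pattern, full.names = TRUE)
    if (length(f) != 1L)
      stop(sprintf("expected exactly one file matching '%s' under %s", pattern, path))
    tab <- utils::read.delim(f, comment.char = "#", row.names = 1L)
    m <- as.matrix(tab)
    if (!all(AA_ORDER %in% rownames(m)))
      stop(sprintf("%s: rows must cover the 20 standard residues", f))
    m <- m[AA_ORDER, , drop = FALSE]
    if (ncol(m) != p)
      stop(sprintf("%s: expected %d columns, found %d", f, p, ncol(m)))
    m
  }
  new("AminoAcidTables",
      physChem = readOne("^aa_physchem7.*\\.tsv$", 7L),
      ssEndpoint = readOne("^aa_ss_endpoint11.*\\.tsv$", 11L),
      contactPotential = readOne("^aa_contact_potential40.*\\.tsv$", 40L))
}

## Normalize a sequence to a character vector over the 20 residues plus X.
## Rare non-standard letters (B, Z, U, O, J) collapse to X; anything else is
## an error naming the offending position.
normalizeResidues <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  res <- toupper(as.character(sequence))
  res[res %in% c("B", "Z", "U", "O", "J")] <- "X"
  bad <- which(!(res %in% c(AA_ORDER, "X")))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d", res[bad[1L]], bad[1L]))
  res
}

#' Amino-acid related features (78 columns)
#'
#' Column layout (fixed): 20-column residue indicator, 7 physico-chemical
#' values, 11 secondary-structure endpoint propensities, 40 correlated
#' contact potentials. For the unknown residue X the indicator block is all
#' zero and each table lookup is replaced by the table's column mean.
#'
#' @param sequence protein sequence (string or character vector).
#' @param tables an \code{\link{AminoAcidTables}} object.
#' @return L x 78 matrix with \code{ami_}-prefixed column names.
#' @export
aaFeatures <- function(sequence, tables = loadAminoAcidTables()) {
  res <- normalizeResidues(sequence)
  L <- length(res)
  ind <- matrix(0, L, 20L, dimnames = list(NULL, paste0("ami_aa_", AA_ORDER)))
  known <- res != "X"
  ind[cbind(which(known), match(res[known], AA_ORDER))] <- 1
  lookup <- function(tab, prefix) {
    out <- matrix(rep(colMeans(tab), each = L), L, ncol(tab))
    out[known, ] <- tab[res[known], , drop = FALSE]
    colnames(out) <- paste0(prefix, seq_len(ncol(tab)))
    out
  }
  cbind(ind,
        lookup(tables@physChem, "ami_pc_"),
        lookup(tables@ssEndpoint, "ami_ssend_"),
        lookup(tables@contactPotential, "ami_ccp_"))
}

#' Evolution related features (40 columns)
#'
#' PSSM log-odds scores squashed elementwise through the sigmoid (bounded
#' inputs keep the conv stack stable), followed by the 20 HHM match-emission
#' probabilities taken as they are.
#'
#' @param profile a \code{\link{SequenceProfile}}.
#' @param squash "sigmoid" (default) or "none" for the raw PSSM scores.
#' @return L x 40 matrix with \code{evo_}-prefixed column names.
#' @export
evoFeatures <- function(profile, squash = c("sigmoid", "none")) {
  squash <- match.arg(squash)
  p <- profile@pssm
  if (squash == "sigmoid") p <- sigmoid(p)
  colnames(p) <- paste0("evo_pssm_", AA_ORDER)
  h <- profile@hhm
  colnames(h) <- paste0("evo_hhm_", AA_ORDER)
  cbind(p, h)
}

#' Structure related features (11 columns)
#'
#' The 8 predicted secondary-structure probabilities and the 3 predicted
#' solvent-accessibility probabilities, passed through unchanged after
#' validating that every row is a probability distribution (within a 1e-3
#' tolerance for printed rounding).
#'
#' @param sp a \code{\link{StructurePrediction}}.
#' @return L x 11 matrix with \code{struct_}-prefixed column names.
#' @export
structFeatures <- function(sp) {
  ss8 <- sp@ss8
  acc3 <- sp@acc3
  colnames(ss8) <- paste0("struct_ss8_", SS8_STATES)
  colnames(acc3) <- paste0("struct_acc_", ACC3_STATES)
  cbind(ss8, acc3)
}

#' Assemble the per-residue feature matrix
#'
#' Concatenates the requested feature classes in the fixed order amino-acid,
#' evolution, structure. The full model uses all three (width 129 = 78 + 40
#' + 11); the sequence-only model ("ami" alone) uses 78. Requesting a class
#' without its inputs is an error -- missing blocks are never silently
#' zero-filled.
#'
#' @param sequence protein sequence (string or character vector).
#' @param tables an \code{\link{AminoAcidTables}} (needed for "ami").
#' @param profile a \code{\link{SequenceProfile}} (needed for "evo").
#' @param struct a \code{\link{StructurePrediction}} (needed for "struct").
#' @param classes subset of c("ami", "evo", "struct").
#' @return L x width numeric matrix whose column names are the feature
#'   manifest.
#' @export
assembleFeatures <- function(sequence, tables = loadAminoAcidTables(),
                             profile = NULL, struct = NULL,
                             classes = c("ami", "evo", "struct")) {
  classes <- match.arg(classes, c("ami", "evo", "struct"), several.ok = TRUE)
  res <- normalizeResidues(sequence)
  L <- length(res)
  blocks <- list()
  if ("ami" %in% classes)
    blocks$ami <- aaFeatures(res, tables)
  if ("evo" %in% classes) {
    if (is.null(profile))
      stop("evolution features requested but no sequence profile supplied")
    if (nrow(profile@pssm) != L)
      stop(sprintf("profile covers %d residues but the sequence has %d",
                   nrow(profile@pssm), L))
    blocks$evo <- evoFeatures(profile)
  }
  if ("struct" %in% classes) {
    if (is.null(struct))
      stop("structure features requested but no structure prediction supplied")
    if (nrow(struct@ss8) != L)
      stop(sprintf("structure prediction covers %d residues but the sequence has %d",
                   nrow(struct@ss8), L))
    blocks$struct <- structFeatures(struct)
  }
  out <- do.call(cbind, blocks[c("ami", "evo", "struct")[c("ami", "evo", "struct") %in% names(blocks)]])
  rownames(out) <- NULL
  out
}

## Column subset of a feature matrix by class prefixes (for ablation grids).
featureClassColumns <- function(featureMatrix, classes) {
  keep <- grepl(paste0("^(", paste(classes, collapse = "|"), ")_"),
                colnames(featureMatrix))
  featureMatrix[, keep, drop = FALSE]
}
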