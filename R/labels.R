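## CASP-convention disorder labeling from missing-coordinate annotations.

#' Label residues from a coordinate annotation
#'
#' Applies the CASP convention: maximal runs of coordinate-lacking residues
#' (annotation D or X) longer than three residues are disordered, runs of
#' three or fewer are ordered ("longer than three" is read strictly, so four
#' residues is the shortest disordered run). Residues marked X are forced to
#' disorder afterwards regardless of run length, and residues marked N (not
#' available) are masked out entirely. N residues are removed before the
#' run-length computation, so a run interrupted only by N counts as one run;
#' the mask keeps the result aligned with the original sequence and the
#' attached \code{indexMap} gives each original position's index after
#' compaction (NA for masked residues).
#'
#' @param annotation character vector of single characters, or one string,
#'   over O/D/N/X.
#' @return a \code{\link{DisorderLabels}} with attribute \code{indexMap}.
#' @examples
#' states(labelFromAnnotation("OODDDDO"))   # run of 4 -> disorder
#' states(labelFromAnnotation("OODDDO"))    # run of 3 -> order
#' states(labelFromAnnotation("OONXO"))     # N masked, X disordered
#' @export
labelFromAnnotation <- function(annotation) {
  if (length(annotation) == 1L && nchar(annotation) > 1L)
    annotation <- strsplit(annotation, "")[[1L]]
  ann <- toupper(as.character(annotation))
  if (!length(ann)) stop("empty annotation")
  bad <- which(!(ann %in% c("O", "D", "N", "X")))
  if (length(bad))
    stop(sprintf("unknown annotation character '%s' at position %d",
                 ann[bad[1L]], bad[1L]))
  keep <- ann != "N"
  sub <- ann[keep]
  lacking <- sub %in% c("D", "X")
  st <- integer(length(sub))
  if (length(sub)) {
    r <- rle(lacking)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths))
      if (r$values[j] && r$lengths[j] > 3L)
        st[starts[j]:ends[j]] <- 1L
  }
  st[sub == "X"] <- 1L
  states <- rep(NA_integer_, length(ann))
  states[keep] <- st
  out <- DisorderLabels(states, mask = keep)
  map <- rep(NA_integer_, length(ann))
  map[keep] <- seq_len(sum(keep))
  attr(out, "indexMap") <- map
  out
}

#' Drop masked residues from aligned features and labels
#'
#' @param features L x p feature matrix over the full sequence.
#' @param labels a \code{\link{DisorderLabels}} of the same length.
#' @return list with the compacted \code{features}, fully observed
#'   \code{labels} and the old-to-new \code{indexMap}.
#' @export
dropMaskedResidues <- function(features, labels) {
  if (nrow(features) != length(labels))
    stop(sprintf("features cover %d residues but labels %d",
                 nrow(features), length(labels)))
  keep <- labels@mask
  map <- rep(NA_integer_, length(keep))
  map[keep] <- seq_len(sum(keep))
  list(features = features[keep, , drop = FALSE],
       labels = DisorderLabels(labels@states[keep]),
       indexMap = map)
}

DISORDER_LENGTH_BINS <- data.frame(
  bin = c("1-5", "6-15", "16-25", ">25"),
  lo = c(1L, 6L, 16L, 26L),
  hi = c(5L, 15L, 25L, .Machine$integer.max),
  stringsAsFactors = FALSE)

#' Length-binned statistics of non-terminal disordered regions
#'
#' Counts disordered segments that touch neither end of their (compacted)
#' chain, binned by length into 1-5, 6-15, 16-25 and >25 residues, reporting
#' both the number of fragments and the number of residues per bin.
#'
#' @param labels a \code{\link{DisorderLabels}} or a list of them.
#' @return data.frame with columns bin, fragments, residues.
#' @export
disorderSegmentStats <- function(labels) {
  if (is(labels, "DisorderLabels")) labels <- list(labels)
  frag <- integer(nrow(DISORDER_LENGTH_BINS))
  res <- integer(nrow(DISORDER_LENGTH_BINS))
  for (lab in labels) {
    y <- includedStates(lab)
    if (!length(y)) next
    r <- rle(y == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      if (starts[j] == 1L || ends[j] == length(y)) next  # terminal segment
      len <- r$lengths[j]
      b <- which(len >= DISORDER_LENGTH_BINS$lo & len <= DISORDER_LENGTH_BINS$hi)
      frag[b] <- frag[b] + 1L
      res[b] <- res[b] + len
    }
  }
  data.frame(bin = DISORDER_LENGTH_BINS$bin, fragments = frag,
             residues = res, stringsAsFactors = FALSE)
}
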