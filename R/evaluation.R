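## Evaluation metrics for imbalanced per-residue binary classification:
## precision, balanced accuracy, Matthews correlation, ROC curve and AUC.
## Disorder (state 1) is the positive class; the default convention pools
## residues across sequences.

#' Confusion counts from calls and truth
#'
#' @param calls 0/1 predicted labels (pooled vector, or list of vectors).
#' @param truth 0/1 true labels, same shape.
#' @return list of class \code{ConfusionCounts} with TP, FP, TN, FN
#'   (positive class = disorder).
#' @export
confusionCounts <- function(calls, truth) {
  calls <- unlist(calls)
  truth <- .poolTruth(truth)
  if (length(calls) != length(truth))
    stop("calls and truth must have the same length")
  keep <- !is.na(calls) & !is.na(truth)
  calls <- calls[keep]; truth <- truth[keep]
  structure(list(
    TP = sum(calls == 1L & truth == 1L),
    FP = sum(calls == 1L & truth == 0L),
    TN = sum(calls == 0L & truth == 0L),
    FN = sum(calls == 0L & truth == 1L)
  ), class = "ConfusionCounts")
}

.poolTruth <- function(truth) {
  if (is(truth, "DisorderLabels")) return(includedStates(truth))
  if (is.list(truth))
    return(unlist(lapply(truth, .poolTruth)))
  as.integer(truth)
}

#' Precision TP / (TP + FP)
#'
#' @param counts a \code{\link{confusionCounts}} result.
#' @return precision in [0, 1]; NA (with a warning) when no residue was
#'   called positive, since the ratio is undefined there.
#' @export
precisionScore <- function(counts) {
  if (counts$TP + counts$FP == 0L) {
    warning("precision undefined: no positive calls")
    return(NA_real_)
  }
  counts$TP / (counts$TP + counts$FP)
}

#' Balanced accuracy 0.5 * (sensitivity + specificity)
#'
#' 0.5 * (TP/(TP+FN) + TN/(TN+FP)); equals 0.5 for any constant predictor on
#' mixed data, which makes it robust to the ~93:7 class imbalance.
#'
#' @inheritParams precisionScore
#' @return balanced accuracy in [0, 1]; NA when either class is empty.
#' @export
balancedAccuracy <- function(counts) {
  if (counts$TP + counts$FN == 0L || counts$TN + counts$FP == 0L) {
    warning("balanced accuracy undefined: one class is empty")
    return(NA_real_)
  }
  0.5 * (counts$TP / (counts$TP + counts$FN) +
         counts$TN / (counts$TN + counts$FP))
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FP)(TP+FN)(TN+FN)), in [-1, 1].
#'
#' @inheritParams precisionScore
#' @return MCC; NA when any marginal sum is zero (undefined denominator).
#' @export
matthewsCC <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tn + fp) * (tp + fn) * (tn + fn)
  if (den == 0) {
    warning("MCC undefined: a confusion-table margin is zero")
    return(NA_real_)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the sorted distinct scores with the
#' "predicted probability >= threshold is positive" convention and
#' integrates the curve by the trapezoidal rule. The result equals the
#' tie-corrected Mann-Whitney statistic (ties between a positive and a
#' negative contribute one half).
#'
#' @param scores per-residue disorder probabilities (vector or list, pooled).
#' @param truth 0/1 truth, \code{\link{DisorderLabels}}, or a list of either.
#' @return list with \code{curve} (data.frame threshold/fpr/tpr) and
#'   \code{auc}; both NA (with a warning) when truth holds one class only.
#' @examples
#' rocAUC(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAUC <- function(scores, truth) {
  scores <- unlist(scores)
  truth <- .poolTruth(truth)
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  npos <- sum(truth == 1L)
  nneg <- sum(truth == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("ROC undefined: truth contains a single class")
    return(list(curve = NULL, auc = NA_real_))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  cumPos <- cumsum(t == 1L)
  cumNeg <- cumsum(t == 0L)
  last <- cumsum(rle(s)$lengths)  # index of the last residue at each threshold
  tpr <- c(0, cumPos[last] / npos)
  fpr <- c(0, cumNeg[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(curve = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Threshold with the best MCC
#'
#' Sweeps the distinct scores as candidate thresholds (>= convention) and
#' returns the one maximizing the Matthews correlation; ties are broken
#' toward the lowest threshold, so the choice is deterministic. This mirrors
#' how a deployment threshold is picked on training data.
#'
#' @inheritParams rocAUC
#' @return list with \code{threshold} and \code{mcc}.
#' @export
bestMCCThreshold <- function(scores, truth) {
  scores <- unlist(scores)
  truth <- .poolTruth(truth)
  thr <- sort(unique(scores))
  best <- c(threshold = NA_real_, mcc = -Inf)
  for (t in thr) {
    m <- suppressWarnings(matthewsCC(confusionCounts(as.integer(scores >= t), truth)))
    if (!is.na(m) && m > best["mcc"] + 1e-12)
      best <- c(threshold = t, mcc = m)
  }
  as.list(best)
}

#' Pooled evaluation of predictions against truth
#'
#' Computes the full metric suite at a decision threshold plus the
#' threshold-free AUC. Residues are pooled across sequences by default; pass
#' \code{perSequence = TRUE} for a per-sequence table instead.
#'
#' @inheritParams rocAUC
#' @param threshold decision threshold for the thresholded metrics
#'   (default 0.2, the released operating point).
#' @param perSequence return one metric row per sequence (scores/truth must
#'   then be lists).
#' @return one-row data.frame (or one row per sequence) with auc, precision,
#'   bacc, mcc and the confusion counts.
#' @export
evaluatePredictions <- function(scores, truth, threshold = 0.2,
                                perSequence = FALSE) {
  one <- function(s, t) {
    s <- unlist(s); t <- .poolTruth(t)
    cc <- confusionCounts(classifyDisorder(s, threshold), t)
    data.frame(auc = suppressWarnings(rocAUC(s, t)$auc),
               precision = suppressWarnings(precisionScore(cc)),
               bacc = suppressWarnings(balancedAccuracy(cc)),
               mcc = suppressWarnings(matthewsCC(cc)),
               TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN)
  }
  if (perSequence) {
    stopifnot(is.list(scores), is.list(truth), length(scores) == length(truth))
    out <- do.call(rbind, Map(one, scores, truth))
    rownames(out) <- NULL
    out
  } else one(scores, truth)
}
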