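## Cross-validated experiment grid over layer counts, label-weight ratios
## and feature-class subsets, mirroring the tuning tables of the original
## study at whatever corpus scale is supplied.

#' Run a cross-validated experiment grid
#'
#' For every combination of layer count, label-weight ratio and
#' feature-class subset, trains on all folds but one and evaluates pooled
#' AUC, MCC, balanced accuracy and precision on the held-out fold. Feature
#' classes are selected by column-name prefix, so the corpus must carry the
#' standard manifest prefixes (ami_/evo_/struct_).
#'
#' @param corpus a \code{\link{DisorderCorpus}} with fold assignments (or
#'   pass \code{folds} to assign them here).
#' @param layers integer vector of hidden-layer counts to try.
#' @param weightRatios list of length-2 numeric label-weight ratios.
#' @param featureClasses named list of feature-class subsets, e.g.
#'   \code{list(all = c("ami","evo","struct"), ami = "ami")}.
#' @param folds number of folds to assign when the corpus has none.
#' @param neurons,halfWindow architecture settings shared across the grid.
#' @param config a \code{\link{trainingConfig}} (its labelWeightRatio is
#'   overridden per grid point).
#' @param threshold decision threshold for the thresholded metrics.
#' @param verbose print one line per grid point.
#' @return tidy data.frame: one row per (layers, ratio, classes, fold) with
#'   auc, mcc, bacc, precision.
#' @export
runExperimentGrid <- function(corpus, layers = c(1L, 2L, 3L),
                              weightRatios = list(c(0.7, 9.3)),
                              featureClasses = list(all = c("ami", "evo", "struct")),
                              folds = NULL, neurons = 50L, halfWindow = 5L,
                              config = trainingConfig(), threshold = 0.2,
                              verbose = FALSE) {
  corpus <- .checkCorpus(corpus)
  if (!is.null(folds))
    foldAssignment(corpus) <- kfoldSplit(length(corpus), folds, config$seed)
  fa <- foldAssignment(corpus)
  if (all(is.na(fa)))
    stop("corpus has no fold assignment; pass folds= or set foldAssignment()")
  if (any(!layers %in% 1:3))
    stop("layers must be drawn from 1, 2, 3")
  for (r in weightRatios)
    if (length(r) != 2L || any(r <= 0))
      stop("each weight ratio must be two positive numbers")
  if (is.null(names(featureClasses)))
    names(featureClasses) <- vapply(featureClasses, paste, "", collapse = "+")
  out <- list()
  for (cname in names(featureClasses)) {
    cls <- featureClasses[[cname]]
    if (!all(cls %in% c("ami", "evo", "struct")))
      stop(sprintf("unknown feature class in grid entry '%s'", cname))
    sub <- corpus
    sub@features <- lapply(corpus@features, featureClassColumns, classes = cls)
    if (ncol(sub@features[[1L]]) == 0L)
      stop(sprintf("grid entry '%s' selects no feature columns", cname))
    for (K in layers) for (r in weightRatios) {
      cfg <- config
      cfg$labelWeightRatio <- r
      arch <- DeepCNFArch(inputDim = ncol(sub@features[[1L]]),
                          numHiddenLayers = K, neuronsPerLayer = neurons,
                          halfWindow = halfWindow)
      for (f in sort(unique(stats::na.omit(fa)))) {
        train <- sub[fa != f & !is.na(fa)]
        test <- sub[fa == f]
        model <- fitDeepCNF(train, arch, cfg)
        scores <- lapply(test@features, function(x)
          posteriorMarginals(model, x)[, "disorder"])
        met <- evaluatePredictions(scores, test@labels, threshold = threshold)
        if (verbose)
          message(sprintf("grid: %s layers=%d ratio=%s fold=%d AUC=%.3f",
                          cname, K, paste(r, collapse = ":"), f, met$auc))
        out[[length(out) + 1L]] <- data.frame(
          classes = cname, layers = K,
          ratio = paste(r, collapse = ":"), fold = f,
          auc = met$auc, mcc = met$mcc, bacc = met$bacc,
          precision = met$precision, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a grid result over folds
#'
#' @param results data.frame from \code{\link{runExperimentGrid}}.
#' @return one row per configuration with the arithmetic mean of every
#'   metric over folds.
#' @export
summarizeGrid <- function(results) {
  key <- interaction(results$classes, results$layers, results$ratio, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    data.frame(classes = d$classes[1L], layers = d$layers[1L],
               ratio = d$ratio[1L], nFolds = nrow(d),
               auc = mean(d$auc), mcc = mean(d$mcc), bacc = mean(d$bacc),
               precision = mean(d$precision), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
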