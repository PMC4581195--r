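test_that("label generation is seed-deterministic and hits the imbalance target", {
  cfg <- syntheticConfig()  # 100 sequences, L = 200, 7% target
  g1 <- generateDisorderLabels(cfg)
  g2 <- generateDisorderLabels(cfg)
  expect_identical(g1$annotations, g2$annotations)
  y <- unlist(lapply(g1$labels, includedStates))
  frac <- mean(y == 1L)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.09)
  ## a zero target produces an all-order corpus
  g0 <- generateDisorderLabels(syntheticConfig(nSequences = 5, disorderFraction = 0))
  expect_true(all(unlist(lapply(g0$labels, includedStates)) == 0L))
  ## different seeds differ
  g3 <- generateDisorderLabels(syntheticConfig(seed = 43))
  expect_false(identical(g1$annotations, g3$annotations))
})

test_that("disorder segments stay non-terminal unless allowed", {
  cfg <- syntheticConfig(nSequences = 40, lengthRange = c(60L, 80L),
                         disorderFraction = 0.15, seed = 3)
  labs <- generateDisorderLabels(cfg)$labels
  firstLast <- unlist(lapply(labs, function(l) {
    y <- includedStates(l); c(y[1], y[length(y)])
  }))
  expect_true(all(firstLast == 0L))
})

test_that("annotations round-trip through the CASP labeling rule", {
  ## every generated annotation, relabeled, reproduces the generator's labels
  g <- generateDisorderLabels(syntheticConfig(nSequences = 10, seed = 8,
                                              naRate = 0.01))
  for (id in names(g$annotations)) {
    relab <- labelFromAnnotation(g$annotations[[id]])
    expect_identical(states(relab), states(g$labels[[id]]))
  }
})

test_that("generated files parse back consistently (full pipeline contract)", {
  dir <- tempfile("synthdata")
  cfg <- syntheticConfig(nSequences = 4, lengthRange = c(40L, 60L), seed = 11)
  manifest <- generateSyntheticData(cfg, dir)
  expect_true(file.exists(manifest))
  corpus <- buildCorpus(manifest)
  expect_s4_class(corpus, "DisorderCorpus")
  expect_length(corpus, 4)
  expect_identical(ncol(corpusFeatures(corpus)[[1]]), 129L)
  ## and a profile parses with matching length against its FASTA entry
  seqs <- readFastaSequences(file.path(dir, "sequences.fasta"))
  id <- names(seqs)[1]
  pssm <- parsePSSM(file.path(dir, "profiles", paste0(id, ".pssm")), seqs[[id]])
  expect_identical(nrow(pssm), nchar(seqs[[id]]))
  hhm <- parseHHM(file.path(dir, "profiles", paste0(id, ".hhm")))
  expect_identical(nrow(hhm), nchar(seqs[[id]]))
  ## generation under the same seed is byte-reproducible
  dir2 <- tempfile("synthdata")
  generateSyntheticData(cfg, dir2)
  expect_identical(readLines(file.path(dir, "sequences.fasta")),
                   readLines(file.path(dir2, "sequences.fasta")))
  expect_identical(readLines(file.path(dir, "profiles", paste0(id, ".pssm"))),
                   readLines(file.path(dir2, "profiles", paste0(id, ".pssm"))))
})

test_that("zero signal strength decouples residue composition from labels", {
  dir <- tempfile("null")
  cfg <- syntheticConfig(nSequences = 30, lengthRange = c(150L, 150L),
                         disorderFraction = 0.2, signalStrength = 0, seed = 21)
  generateSyntheticData(cfg, dir)
  seqs <- readFastaSequences(file.path(dir, "sequences.fasta"))
  anns <- readAnnotations(file.path(dir, "labels.tsv"))
  res <- unlist(strsplit(paste(seqs[names(anns)], collapse = ""), ""))
  y <- unlist(lapply(anns, function(a) states(labelFromAnnotation(a))))
  keep <- !is.na(y)
  tab <- table(res[keep], y[keep])
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("label/feature mutual information rises with signal strength", {
  mi <- sapply(c(0, 1.5, 3), function(s) {
    g <- withr::with_seed(31, {
      cfg <- syntheticConfig(nSequences = 20, lengthRange = c(150L, 150L),
                             disorderFraction = 0.2, signalStrength = s,
                             seed = 31)
      labs <- DisorderCNF:::.generateLabelsInner(cfg)
      dat <- lapply(labs$labels, function(l)
        DisorderCNF:::.oneSequenceData(states(l), s))
      list(labels = labs$labels, dat = dat)
    })
    y <- unlist(lapply(g$labels, includedStates))
    res <- unlist(Map(function(d, l) strsplit(d$sequence, "")[[1]][residueMask(l)],
                      g$dat, g$labels))
    tab <- table(res, y) / length(y)
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(pmax(tab, 1e-12) / outer(px, py)), na.rm = TRUE)
  })
  expect_true(all(diff(mi) > 0))
})
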