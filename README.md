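# DisorderCNF

Per-residue prediction of intrinsically disordered protein regions (IDRs)
with a **weighted deep convolutional neural field**: a stack of
position-shared convolutional layers feeding a linear-chain conditional
random field (CRF) whose potentials carry per-label weights to counter the
~93 : 7 order : disorder class imbalance.

The package is for structural bioinformaticians who want a self-contained,
trainable order/disorder labeler: feature construction from sequence,
evolutionary profiles (PSI-BLAST PSSM, HH-suite HHM) and predicted local
structure (SS8/ACC3); CASP-convention labeling from missing-coordinate
annotations; exact maximum-likelihood training; threshold-free ROC/AUC
evaluation plus precision, balanced accuracy and MCC; a seeded synthetic
corpus generator so everything runs offline; and a command-line interface.

## The model

For a chain of length L with feature vectors X_i and labels
Y_i ∈ {0 = order, 1 = disorder}:

    P(Y | X) = exp( Σ_i [ Ψ'(Y,X,i) + Φ'(Y,X,i) ] ) / Z(X)

    Ψ'(Y,X,i) = Σ_{a,b} T_{a,b} · w_a · δ(Y_i = a) δ(Y_{i+1} = b)
    Φ'(Y,X,i) = Σ_{a,j} U_{a,j} · H_j(X,i,W) · w_a · δ(Y_i = a)

H_j(X,i,W) is the top layer of a deep convolutional stack with
position-shared windowed weights (default: two layers of 50 neurons,
window 11, sigmoid). The per-label weights w (default 0.7 : 9.3, the
reciprocal-frequency ratio at ~7% disorder) scale both potentials during
training *and* prediction, so errors on the rare disorder class cost
proportionally more. Training maximizes the L2-penalized weighted
conditional log-likelihood by L-BFGS with the exact forward-backward /
backpropagation gradient; inference is forward-backward in log space.
See `vignettes/weighted-deepcnf-methods.Rmd` for the full account.

## Worked example

Generate a small synthetic corpus, train, and evaluate held-out sequences:

```r
library(DisorderCNF)

dataDir <- file.path(tempdir(), "idr_demo")
cfg <- syntheticConfig(nSequences = 12, lengthRange = c(80L, 80L),
                       disorderFraction = 0.15, signalStrength = 2, seed = 7)
manifest <- generateSyntheticData(cfg, dataDir)
corpus <- buildCorpus(manifest)
corpus
#> DisorderCorpus: 12 sequences, 960 residues (15.0% disorder)

model <- fitDeepCNF(corpus[1:10],
                    arch = DeepCNFArch(inputDim = 129, numHiddenLayers = 2,
                                       neuronsPerLayer = 10),
                    config = trainingConfig(maxIterations = 60))
model
#> DeepCNFArch: 2 hidden layer(s), neurons [10,10], window [11,11], sigmoid, 2 labels, input width 129
#> DeepCNFModel: 15314 trainable parameters, label weights [0.7:9.3]
#>   fitted: final objective -2.60908 after 76 evaluations

test <- corpus[11:12]
scores <- lapply(corpusFeatures(test), function(x)
  posteriorMarginals(model, x)[, "disorder"])
evaluatePredictions(scores, corpusLabels(test), threshold = 0.2)
#>         auc precision      bacc       mcc TP FP  TN FN
#> 1 0.9659926 0.9583333 0.9754902 0.9509804 23  1 135  1
```

The `auc` column is the area under the ROC curve over the pooled held-out
residues (1 = perfect ranking of disordered above ordered residues, 0.5 =
random); `precision`, `bacc` (balanced accuracy) and `mcc` are computed
from the confusion table at the 0.2 decision threshold — the operating
point used for deployment, chosen by best training-set MCC. On this
planted-signal toy corpus the two-layer model ranks 23 of the 24
disordered held-out residues above the threshold with one false positive.

The same pipeline is available from a shell:

```sh
disordercnf generate --out data --n 12 --length 80 --seed 7
disordercnf train    --manifest data/manifest.tsv --out model.txt --maxit 60
disordercnf predict  --model model.txt --manifest data/manifest.tsv --out preds.tsv
disordercnf eval     --predictions preds.tsv --manifest data/manifest.tsv --out report.tsv
```

## Notes

* The amino-acid property tables under `inst/extdata` are deterministic
  **synthetic stand-ins** (see their headers); supply real tables with
  `loadAminoAcidTables(path)` for work on real proteins.
* Structure and profile inputs are file contracts (PSI-BLAST ASCII PSSM,
  HH-suite HHM, SS8/ACC3 TSV); this package does not run the upstream
  predictors.
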