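---
title: "Weighted deep convolutional neural fields for order/disorder prediction: model and methods"
author: "DisorderCNF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted deep convolutional neural fields: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisorderCNF)
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments with no stable
tertiary structure. Operationally they are annotated from crystal
structures: residues whose atomic coordinates are missing. Predicting
per-residue order/disorder from sequence is a binary sequence-labeling
problem with two defining difficulties: the labels of adjacent residues are
strongly interdependent (disorder comes in long runs), and the classes are
heavily imbalanced (~7% of residues are disordered), so an unweighted
maximum-likelihood model drifts toward calling everything ordered.

## The model

DisorderCNF implements a weighted deep convolutional neural field: a stack
of position-shared convolutional layers beneath a linear-chain conditional
random field (CRF). For a chain of length $L$ with per-residue feature
vectors $X_i$ and labels $Y_i \in \{0 = \text{order}, 1 =
\text{disorder}\}$:

$$P(Y \mid X) \;=\; \frac{1}{Z(X)} \exp\!\Big(\sum_{i=1}^{L}
\big[\Psi'(Y, X, i) + \Phi'(Y, X, i)\big]\Big)$$

with weighted transition and emission potentials

$$\Psi'(Y,X,i) = \sum_{a,b} T_{a,b}\, w_a\, \delta(Y_i = a)\,\delta(Y_{i+1} = b),
\qquad
\Phi'(Y,X,i) = \sum_{a,j} U_{a,j}\, H_j(X,i,W)\, w_a\, \delta(Y_i = a).$$

$H_j(X,i,W)$ is neuron $j$ of the top convolutional layer at position $i$.
Each layer applies a position-shared windowed linear map followed by a
pointwise nonlinearity,

$$A^{k+1}_i(j) = h\Big(\sum_{l=-N_k}^{N_k} \sum_{j'} A^{k}_{i+l}(j')\,
W^k_l(j, j')\Big), \qquad A^1 = X,$$

so the receptive field grows with depth and medium-range sequence context
informs every label. $w_a$ is a fixed per-label weight that scales both
potentials; with $w \equiv 1$ the model is a plain conditional neural
field, a reduction the test suite verifies against an independently coded
unweighted implementation.

### Numerical conventions

* **Boundary padding.** The windowed sum references positions outside
  $[1, L]$; out-of-range activations contribute zero. This keeps $L$
  positions at every layer and is the standard convention for
  position-shared convolutions.
* **Transition at the last position.** The pair potential needs $Y_{i+1}$,
  so its contribution at $i = L$ is defined as zero (the usual linear-chain
  convention).
* **Log-space chains.** The partition function, posterior marginals and
  pairwise marginals are computed by forward-backward entirely in log space
  (a small compiled kernel), so chains of thousands of residues with
  parameter magnitudes up to ~50 stay finite; the suite checks $L = 2000$.
* **Biases.** The canonical layer map has no bias term; a per-neuron bias
  is available behind `DeepCNFArch(useBias = TRUE)` and is off by default
  so the default model matches the equations exactly.
* **Activation.** `sigmoid` by default, `tanh` selectable.
* **Weighting at prediction.** The label weights enter the potentials
  identically at training and at inference: predicted marginals come from
  the same weighted model that was trained. This keeps a single consistent
  probabilistic model. Whether $w_a$ should additionally weight the second
  label of a transition pair is an open modeling choice; the implementation
  weights by the first label only, exactly as the potentials above read.

## Training

`fitDeepCNF()` maximizes the penalized weighted conditional log-likelihood

$$\mathcal{L}(\theta) = \sum_{\text{sequences}} \log P(Y \mid X; \theta)
\;-\; \frac{\lambda}{2}\lVert\theta\rVert^2$$

by L-BFGS (history size 10) with the exact analytic gradient: empirical
minus expected sufficient statistics from forward-backward, each scaled by
its label weight, backpropagated through the convolutional stack. The
gradient is validated against central finite differences (step $10^{-5}$,
max relative error $< 10^{-4}$) for one-, two- and three-layer stacks.

Parameters that matter:

| parameter | default | meaning |
|---|---|---|
| `labelWeightRatio` | 0.7 : 9.3 | per-label weights (order : disorder); the reciprocal-frequency ratio for ~7% disorder. Used as printed, not rescaled: potentials are linear in $w$, so only the ratio and joint scale matter, and the scale convention is fixed at these values. |
| `l2Factor` | 200 | regularization factor. Interpreted per residue: $\lambda = \texttt{l2Factor} / (\text{total residues})$, so the same factor penalizes at the same strength on corpora of any size; `l2Mode = "raw"` selects the literal $\lambda = \texttt{l2Factor}$ reading. |
| `numHiddenLayers` | 2 | convolutional depth (1 = plain CNF) |
| `neuronsPerLayer` | 50 | width of each hidden layer |
| window | 11 | $2 N_k + 1$ with `halfWindow = 5` |
| threshold | 0.2 | decision threshold on the disorder marginal, the operating point chosen by best training MCC; ROC/AUC evaluation is threshold-free |

Convergence uses `optim`'s standard L-BFGS-B criteria (`factr = 1e7`,
`pgtol = convergenceTol`, default $10^{-5}$). A looser relative-improvement
stop of $10^{-6}\lvert\mathcal{L}\rvert$ was considered and rejected: on
log-likelihood surfaces summing thousands of residues it halts long before
the marginals stabilize. Fits are deterministic given the seed — the
uniform $[-0.1, 0.1]$ initialization is the only randomness — and a refit
with the same seed reproduces the model file byte for byte. Label weights
are hyperparameters, never trained and never penalized.

`reciprocalFrequencyWeights()` returns weights proportional to the swapped
label frequencies, normalized to sum to one (93% order / 7% disorder gives
0.07 : 0.93). The name follows the field's usage; note the values are the
swapped frequencies themselves — true reciprocals ($1/0.93, 1/0.07$) have
the same ratio ordering but a different joint scale, and the printed
convention is the one implemented.

## Features

The full feature vector has 129 columns per residue, assembled in a fixed,
manifest-frozen order:

* **Amino-acid block (78):** a 20-column residue indicator, 7
  physico-chemical values, 11 secondary-structure segment-endpoint
  propensities and 40 correlated contact potentials. The three lookup
  tables shipped under `inst/extdata` are deterministic synthetic
  stand-ins, clearly marked in their provenance headers — the canonical
  values live in the published literature and users supply them via
  `loadAminoAcidTables(path)`. The unknown residue X (to which B/Z/U/O/J
  collapse) gets a zero indicator and column-mean lookups.
* **Evolution block (40):** 20 PSI-BLAST PSSM log-odds scores squashed
  elementwise through the sigmoid (bounded inputs keep the conv stack
  stable; the raw scale is selectable) and 20 HH-suite HHM match-emission
  probabilities used as probabilities. The PSSM log-odds block (not the
  percentage block) and the HHM match emissions (not transitions) are the
  chosen columns.
* **Structure block (11):** 8 predicted secondary-structure and 3 predicted
  solvent-accessibility probabilities, passed through unchanged after
  validating each row sums to one within $10^{-3}$ (printed files are
  rounded). Structure predictions come from files, not bundled predictors:
  running the upstream tools is outside this package's scope.

Every model records the feature column names it was trained with;
prediction refuses inputs whose assembled manifest differs, and missing
optional blocks are an error, never silently zero-filled.

## Labels

`labelFromAnnotation()` implements the CASP convention: maximal runs of
coordinate-lacking residues longer than three are disordered, runs of three
or fewer are ordered ("longer than three" read strictly: four residues is
the shortest disordered run, and both sides of the boundary are tested).
Residues marked X (coordinates missing) are forced to disorder after the
run rule — so an isolated X is a length-1 disorder call — and residues
marked N (not available) are removed before the run computation and masked
out, with an index map so predictions re-project onto the original
numbering. The interaction of short X runs with the length rule is not
fully pinned down by the convention; X-dominates is this package's
documented choice.

## The synthetic corpus generator

`generateSyntheticData()` emulates the study conditions so the whole
pipeline trains and evaluates offline: by default 100 sequences of 200
residues with a 7% pooled disorder fraction and non-terminal disorder
segments drawn from a length mixture over the bins 1–5 / 6–15 / 16–25 /
>25 in proportions 492 : 226 : 45 : 19 (the fragment-count distribution of
a crystallographic training corpus). The last segment of a sequence is
truncated so the realized fraction tracks the target; segments shorter than
four residues are emitted as X marks (which the labeling rule calls
disordered), so annotations round-trip exactly through
`labelFromAnnotation()`.

Feature signal is planted with strength `signalStrength` (default 3, the
recovery-experiment condition): disorder-promoting residues (P, E, S, Q, K)
are enriched in disordered segments and order-promoting residues (C, W, I,
Y, F, L, M, H) in ordered ones; PSSM scores and HHM emissions shift the
same way; SS8 rows are Dirichlet draws with the coil state boosted in
disorder (helix/strand in order) and ACC3 rows boost exposure in disorder.
At `signalStrength = 0` composition is independent of the labels (the
suite checks this with a chi-square test), and label/feature mutual
information rises monotonically with the strength.

What the generator does *not* emulate: real evolutionary correlation along
the chain, profile column covariance, length-dependent disorder propensity
at the termini, or any biophysics. Passing the planted-signal tests shows
the estimator recovers signal that is present in the stated feature
channels; it says nothing about accuracy on real proteins, which depends on
real profiles and structure predictions.

## Problem sizes used by the tests and the acceptance script

Desk-scale sizes were chosen so each check measures what it claims:

* Exact-inference checks enumerate all $2^L$ paths for $L \le 8$ over 20
  random parameter draws (tolerance $10^{-8}$).
* Gradient checks run a 3-sequence, length-10 toy corpus for 1–3 layers.
* The recovery experiment uses the generator defaults (100 × 200 residues,
  signal 3), 80 training / 20 held-out sequences, and an 80-iteration
  L-BFGS budget: the default two-layer model and a one-layer model are
  compared by held-out AUC.
* The label-weighting comparison (0.7:9.3 vs 5:5 at threshold 0.5) runs on
  the same corpus shape at `signalStrength = 1.2`. At strength 3 the task
  is separable enough that both weightings sit at the balanced-accuracy
  ceiling and the comparison is degenerate; at moderate signal the
  unweighted fit leaves disorder marginals below the 0.5 threshold and the
  weighting effect is measurable — the regime the weighting exists for.
* The feature-class ablation grid uses 30 × 100-residue sequences at
  signal 1.2 with 2 folds for the same reason: every class stays below a
  perfect AUC, so "all features at least match any single class" is an
  informative comparison rather than a tie at 1.0.
* The parameter-recovery property samples labels from a known one-layer
  model with a pointwise (window-1) layer. With a wide window the
  likelihood surface is rough enough that refits land in local optima with
  held-out marginal correlation ~0.85; the pointwise generator isolates
  the estimation question from the non-convexity question.

## Known limitations

* The shipped amino-acid tables are placeholders; results on real data
  require the real tables and real PSSM/HHM/SS8/ACC3 inputs.
* Training is full-batch L-BFGS; stochastic or Hessian-free training and
  direct AUC optimization are out of scope.
* The two-label chain is hard-coded in spirit (the code is generic in D,
  but tooling, thresholds and reports assume order/disorder).
* Per-position (unshared) convolution weights and GPU execution are
  non-goals.
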