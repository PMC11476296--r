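---
title: "Predicting protamines from sequence: methods and design notes"
author: "ProtamineScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protamines from sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtamineScan)
```

## The problem

Protamines are short nuclear proteins — typically 25–70 residues — in which
arginine often exceeds half of the sequence, with serine, lysine and
cysteine making up much of the rest. They replace histones during
spermatogenesis and hypercondense sperm DNA. Confirmed protamines are rare
relative to the proteome, so a sequence-based classifier must cope with (a)
a representation that captures both composition and local order, and (b) a
minority class a fraction of the size of the background class. This package
provides the full pipeline: featurization, two class-balancing strategies,
a multi-classifier benchmarking harness, and a prediction interface.

## The PseAAC descriptor

Each sequence of length $L$ over the 20 standard residues becomes a
$20 + \lambda$ vector (type-I pseudo amino acid composition). The first 20
components are scaled residue frequencies, the rest encode sequence order
through lagged physicochemical correlation:

$$\theta_k = \frac{1}{L-k}\sum_{i=1}^{L-k}\Theta(R_i, R_{i+k}),\qquad
\Theta(a,b) = \tfrac13\sum_{p=1}^{3}\left(h_p(a) - h_p(b)\right)^2,$$

where $h_1, h_2, h_3$ are hydrophobicity (Tanford/Chou scale),
hydrophilicity (Hopp–Woods) and side-chain mass, each standardized to zero
mean and unit *population* standard deviation over the 20 residues. With
$D = 1 + w\sum_{k=1}^{\lambda}\theta_k$,

$$x_u = f_u / D \;(u \le 20), \qquad x_{20+k} = w\,\theta_k / D,$$

so all components are non-negative and sum to exactly 1 — the vectors are
machine-learning-ready without further scaling.

Parameters, defaults, and why:

- **$\lambda = 10$** (components 21–30). Validation therefore requires
  $L \ge \lambda + 1$, so the last correlation factor averages over at
  least one pair; sequences shorter than 11 residues are rejected with
  `TOO_SHORT` rather than padded.
- **$w = 0.05$** balances the correlation block against composition. This
  is the conventional default of Chou-style PseAAC implementations; both
  $\lambda$ and $w$ are exposed as arguments everywhere.
- **Non-standard residues** (B, J, O, U, X, Z) fail validation with
  `NONSTANDARD_RESIDUE` and a logged skip. The property tables cover only
  the 20 standard residues; silent substitution would quietly distort the
  correlation block.
- **Frequencies use denominator $L$**, the full sequence length.

The implementation precomputes the $20 \times 20$ matrix of
$\Theta(a,b)$ values once per property table, making featurization linear
in sequence length. The test suite pins the dialect against an independent
scalar-loop reimplementation of the same formulas to $10^{-6}$ on 100
random sequences.

## Class balancing

**SMOTE.** The minority class is grown to the majority count; each
synthetic row is $x + u \cdot (x_{nn} - x)$ with $u \sim U(0,1)$, $x$ a
uniformly drawn minority row and $x_{nn}$ one of its $k = 5$ Euclidean
nearest minority neighbours. Synthetic rows are therefore convex
combinations — they never extrapolate past the minority envelope — and
every output row carries a `provenance` tag (`real` / `smote`), so
original rows are verifiably untouched.

**Tabular GAN.** A generator (noise 100 → dense 128 → 128 → 30, LeakyReLU
$\alpha = 0.01$, dropout 0.5 between hidden layers, linear output) and a
discriminator (30 → 128 → 128 → 1, sigmoid) are trained adversarially
under binary cross-entropy with Adam ($\mathrm{lr} = 2\times10^{-4}$,
$\beta_1 = 0.5$), 1000 epochs of minibatches of 30 over the minority rows.
The dense-network machinery (Glorot initialization, inverted dropout,
Adam, backpropagation) is implemented directly in matrix form — the
networks are small enough that a full 1000-epoch schedule on a couple of
hundred rows takes on the order of two minutes on one CPU.

Design choices where the architecture leaves room:

- *Epoch definition*: one pass of shuffled minibatches over the real
  minority rows; discriminator and generator are each updated once per
  minibatch (discriminator on real-vs-fake with targets 1/0, generator
  through the frozen discriminator with target 1).
- *Dropout* is active only in the network currently being updated; the
  frozen discriminator used for the generator step, and all sampling, run
  in inference mode.
- *Output activation*: linear, with samples clipped to $[0,1]$ at sampling
  time — PseAAC features live there — then rounded to 3 decimals to match
  the precision of featurized data. Real rows are never rounded.
- *Augmentation scope*: the minority class only. `augmentBoth = TRUE`
  additionally synthesizes majority-class rows, which is useful for
  distributional QC of both classes (see `pcaCompare()`) but is not part
  of the modeling protocol.

Note that GAN rows, unlike SMOTE rows, need not sum to 1: the generator
approximates the minority distribution rather than interpolating inside
it, and its samples show the greater dispersion typical of adversarial
generators. `pcaCompare()` projects real and synthetic rows onto shared
principal components to make that dispersion visible.

## Benchmarking protocol

`runExperiment()` evaluates any subset of the eight-entry registry under a
stratified 80/20 split plus stratified 10-fold cross-validation on the
training portion (fold summary = unweighted fold mean; the split rounds
toward the training side). Two leakage regimes are explicit:

- **paper**: augment the *whole* dataset, then split. Synthetic
  neighbours of test points can enter training, which inflates apparent
  performance. This regime reproduces the common augment-then-split
  protocol and is the default.
- **safe**: split first; augmentation is fit on training data only — and,
  during cross-validation, within each fold's training part only.

Both are labeled in the report's config echo; a property test asserts the
expected trend (safe ≤ paper on average over ≥ 10 seeds) rather than a
per-seed inequality, since individual seeds are noisy.

Backends are the field-standard R implementations: `randomForest`,
`xgboost`, `nnet`, `class::knn`, `e1071` (naive Bayes, RBF-SVM) and a
binomial GLM. The histogram gradient-boosting entry (`"lightgbm"`) uses
xgboost's histogram method with leaf-wise growth and 31 leaves, the
LightGBM growth strategy. Hyperparameters are backend defaults except
where a backend has no default (the MLP's hidden layer: 32 units, decay
$10^{-4}$, 200 iterations); every resolved value is echoed into the
report. Scores are native class probabilities everywhere except kNN,
where the score is the neighbour vote fraction. The decision threshold is
0.5 and ties go to YES.

## Metrics

Accuracy, sensitivity, precision, F1 and FPR are computed from the
confusion counts; Cohen's $\kappa$ from observed vs chance agreement
($P_e$ from the marginals); MCC in its four-factor product form. Any
ratio with a zero denominator — including $\kappa$ at $P_e = 1$ and MCC
with a zero factor — is reported as 0 with the metric named in a
`degenerate` flag, rather than NaN. AUC uses the Mann–Whitney rank
statistic (midranks under ties), which equals trapezoidal integration of
the ROC curve over the full threshold sweep and is exact under ties; the
step-curve points are still emitted for plotting. The suite checks the
bundle against brute-force arithmetic on 1000 random tables and the AUC
against the $O(n^2)$ pairwise statistic.

## The synthetic benchmark

`simulateProtamineBenchmark()` draws positives of 25–70 residues i.i.d.
with arginine probability 0.6 (protamine-like; roughly half the residues
or more are R in real protamines) and the remaining mass over a
background tilted 4:1 toward S, K, C, G and V, the residues protamines
are otherwise enriched in. Negatives are 50–300 residues from an
average-proteome (SwissProt-like) composition — mildly non-uniform on
purpose, so the negative class is not a degenerate uniform strawman.
Under these settings the pooled arginine frequency in positives is about
three-fold (or more) that of any other residue, matching the
position-frequency structure real protamine sets display, and the two
classes are linearly separable in PseAAC space with high probability at
$n = 100$.

What the generator does *not* emulate: positional structure (real
protamines concentrate arginine in the N-terminal and central regions —
see `positionFrequencyMatrix()` for the diagnostic), phosphorylation-site
serine clustering, and cross-species homology between nearby sequences.
Consequently, a pipeline passing on this benchmark demonstrates that the
machinery is correct and that separable composition signals are
recovered, not that real-data performance will match: curated sequence
sets are harder and more heterogeneous.

## Problem sizes and numerical choices

The test suite runs the full GAN schedule (1000 epochs, batch 30) on a
221-row, 30-feature minority matrix, and the end-to-end benchmark on a
balanced 200/200 simulated set — sizes chosen to mirror a realistic
curated-protamine scale while keeping the whole suite comfortably
runnable on a laptop. The GAN point-mass recovery test (all training rows
identical) asserts a mean absolute error of the generator mean below
0.05 at the full schedule; the calibration run at those exact settings
observed ~0.005, so the tolerance carries a ten-fold margin. Degenerate
inputs are rejected loudly: empty FASTA records, single-class balancing
inputs, minority counts not exceeding $k$, non-finite losses, and feature
width mismatches at prediction time all raise with explicit messages.

## Known limitations

- The PseAAC dialect (scales, $w$, normalization) is pinned by tests, but
  other published PseAAC variants (amphiphilic type-II, different scales)
  are out of scope.
- The GAN has no convergence diagnostics beyond the loss traces; mode
  collapse must be judged with `pcaCompare()`.
- Metrics are binary-only; no confidence intervals are attached.
- Model serialization uses plain `saveRDS()` with no cross-version format
  guarantee.
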