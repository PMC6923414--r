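---
title: "Methods: a two-stage sequence-based predictor of protein secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage sequence-based predictor of protein secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Proteins reach the extracellular space by two broadly different routes. The
classic route is directed by an N-terminal signal peptide — a short,
tripartite element with a positively charged n-region, a hydrophobic
h-region and a polar c-region whose −1 and −3 positions (relative to the
cleavage site) carry small residues. A second, heterogeneous group of
proteins is exported without any recognizable N-terminal signal;
this unconventional protein secretion (UPS) has no known sequence motif, so
predicting it from sequence requires global physicochemical characteristics
rather than motif matching.

`secretr` implements this as a cascade. Stage one is a three-class
classifier of the N-terminal 70 residues that separates signal-peptide
proteins (SP), proteins with a transmembrane helix within those 70 residues
(TM70 — whose hydrophobic stretch mimics an h-region and is the classic
confounder), and everything else (IN_CELL). Only proteins called IN_CELL
proceed to stage two, which scores UPS against intracellular background from
eight physicochemical features. SP and TM70 calls are final; every protein
ends with exactly one of four categories.

## Stage one: a compact convolutional classifier

Input windows are the first 70 residues, one-hot encoded as a 70 × 20 binary
matrix over the alphabetically ordered amino-acid alphabet
(`ACDEFGHIKLMNPQRSTVWY`; the ordering is a package constant). Sequences
shorter than 70 residues are zero-padded at the C-terminal end — an all-zero
row is the natural "absent residue" under one-hot coding and keeps tensor
shapes fixed. Ambiguity codes (B, Z, J, X, U, O) also map to all-zero rows
under the default `mask` validation policy, so real proteome FASTA files run
end to end; a `strict` policy is available for training-data hygiene.

The network is deliberately small:

1. a channel-reduction convolution: five kernels, each spanning all 20
   residue channels at a single position, compress the input to five feature
   maps of length 70 (interpretable as learned physicochemical scales such
   as hydrophobicity or charge), ReLU, no pooling;
2. a one-dimensional convolution of `n_motif_kernels = 64` kernels of length
   `motif_kernel_length = 15` running along the position axis — 15 residues
   is long enough to span an h-region together with parts of its flanks;
3. global max pooling over positions (one scalar per kernel) and ReLU. Max
   pooling and ReLU commute here, so the order is immaterial;
4. one dense layer of 64 units (ReLU), then a softmax over the three
   classes.

The forward pass, backpropagation and the Adam optimizer are implemented in
vectorized R linear algebra inside the package; because the input is
one-hot, the first convolution reduces to a column gather, and the second is
an im2col matrix product, so training is fast enough for desk-scale use
without compiled code. Backpropagation is verified against central-difference
numerical gradients in the test suite (the check randomizes the bias
initialisation first: exactly-zero biases sit on the ReLU kink, where
two-sided differences are invalid).

### Training and regularisation

Optimisation uses Adam (learning rate 2e-3), mini-batches of 32, a
class-weighted cross-entropy (weights inversely proportional to class
frequency, protecting minority-class MCC under imbalanced training sets), an
L2 weight penalty of 0.01 on all convolutional and dense weights, at most 60
epochs with early stopping (patience 10) on the validation loss, and two
independently initialised restarts per fit with the better validation loss
kept. The weight decay and restarts are the two choices that matter most in
practice: the network has enough capacity to memorize a few hundred training
windows within ~15 epochs, and without the penalty held-out performance
saturates well below what the planted structure supports; restarts guard
against occasional poor initialisations. Restart selection and early
stopping only ever see the inner validation partition, never test data.

### Nested cross-validation and the ensemble

Training uses stratified 5-fold outer × 4-fold inner nested
cross-validation. For each outer fold, four networks are trained on the
inner training partitions, each early-stopped on its own inner validation
fold; the 5 × 4 = 20 members together form the final ensemble. Prediction
averages the members' softmax vectors (an unweighted convex combination, so
averaged scores still sum to 1) and takes the argmax, with exact ties broken
toward IN_CELL — the conservative choice, since an IN_CELL call merely
routes the protein to stage two rather than asserting a signal. Outer test
folds are never touched during the training or selection of their members;
their micro-averaged MCC is the honest performance estimate the package
reports.

## Stage two: physicochemical features and a boosted classifier

### The 61-feature description

Every protein is described by 61 features: the 20 amino-acid composition
frequencies (count over total length; non-standard residues count in the
denominator only), the average molecular weight in Daltons (Expasy average
residue masses plus one water, 18.015 Da; non-standard residues contribute
the mean standard-residue mass), and the frequencies of five residue groups
(hydrophobic {A,V,L,I,M,F,W,C}, polar {S,T,N,Q,Y,H}, positively charged
{K,R,H}, negatively charged {D,E}, small {A,G,S,C,T,P,D,N,V}) in each of
eight segments: the whole sequence, the N-terminal 15/30/45, the C-terminal
15/30/45, and the middle remainder (empty for sequences of ≤ 90 residues;
empty segments yield frequency 0 by convention). The segment boundaries and
group memberships are package constants and are configurable; the counts
20 + 1 + 5 × 8 = 61 are invariant under the default scheme.

The classifier itself uses an eight-feature subset: molecular weight; the
small, hydrophobic and positively-charged frequencies in the C-terminal 15
residues ("the C-terminus" is identified with the shortest, most local
C-terminal segment); the positively-charged frequency over the whole
sequence; and the tryptophan, phenylalanine and arginine compositions. The
subset is a pure column selection — never recomputed — so it is numerically
identical to the corresponding entries of the full vector.

### Feature selection machinery

Although the final subset is fixed, the package ships the machinery that
produces such subsets, so the selection is reproducible on new data:

* `rank_importance()` averages impurity importances over many independently
  seeded random forests (each repetition normalized to sum to 1 before
  averaging; 500 repetitions by default, 25 trees each — many small forests
  give the averaging its stability).
* `rank_drift()` addresses sample-selection bias: it relabels rows by their
  dataset of origin (training vs independent) and runs the same
  forest-importance procedure on that origin label. Features that score high
  discriminate *datasets* rather than *classes* and should be avoided. The
  paperwork behind drifting features names the phenomenon but not an
  algorithm; origin-classification importance is this package's
  reconstruction, chosen because it reuses the exact importance machinery
  and needs no distributional assumptions.
* `best_one_search()` is greedy forward selection: starting from the empty
  set it repeatedly adds the candidate that maximizes the cross-validated
  MCC of a reference gradient-boosted classifier, stopping when no candidate
  improves the MCC or a size budget is reached. The CV fold split is fixed
  across steps so scores along the path are comparable, and the path MCC is
  non-decreasing by construction.

### Oversampling

UPS training sets are small and imbalanced (the motivating geometry is 96
positives against 345 negatives). The minority class is oversampled inside
each training partition only — never validation or test partitions, so no
synthetic row can leak across CV folds. Three schemes are provided:
`repeated` (cyclic duplication to exact balance), `smote` (each synthetic
positive is `a + λ(b − a)`, `λ ~ U(0,1)`, between a positive `a` and one of
its k = 5 nearest positive neighbours; neighbours are found on standardized
features, interpolation happens in raw feature space), and `adasyn` (as
SMOTE, but synthetics per positive are proportional to the fraction of
majority examples among its k nearest neighbours in the full data;
largest-remainder apportionment makes the counts sum exactly to the
deficit). Negative rows are never altered by any scheme.

### Model fitting, selection and calibration

Three model families are available — penalized-free logistic regression,
random forests, and gradient-boosted trees (the default and the family the
method was designed around; grid: depth {2,3,4} × rounds {50,100,200} ×
learning rate {0.05,0.1}). A grid-searched nested cross-validation (5 outer
× 4 inner = 20 runs per hyperparameter setting) trains every setting on
every inner partition and scores it on the matching inner validation
partition; the setting with the best mean test MCC wins. Outer-fold refits
with the winning setting give honest per-fold MCCs, and their pooled
out-of-fold scores double as the calibration data — a split that is
guaranteed disjoint from each scoring model's training rows without
sacrificing any data.

Calibration maps raw scores to probabilities by Platt scaling (`sigmoid`: a
logistic regression of the outcome on the raw score) or isotonic regression
(`isotonic`: pool-adjacent-violators with linear interpolation between
knots). Both maps are monotone, but isotonic regression is only *weakly*
monotone: scores falling into one pooled block would be collapsed to a
single value, introducing ties the raw model distinguishes and thereby
perturbing rank statistics such as AUC. The package therefore blends every
calibrated score with a vanishingly small linear component of the raw score
(coefficient 1e-6), making the map strictly increasing on [0, 1]: ranks —
and hence ROC curves — are exactly preserved, at a probability distortion
bounded by 1e-6 (far below any meaningful calibration resolution). The same
blend guards the sigmoid against floating-point saturation at 0 and 1. The
decision threshold on the calibrated score defaults to 0.5 and is exposed
everywhere.

## Evaluation metrics

Accuracy, sensitivity (TPR), specificity (TNR) and the Matthews correlation
coefficient follow their standard confusion-matrix formulas; MCC returns 0
when any denominator factor vanishes (the standard convention, keeping model
selection well defined on degenerate folds), and counts are held as doubles
so products cannot overflow below 1e9 examples. The three-class
micro-averaged MCC sums the one-vs-rest TP/FP/TN/FN of each class from a
single prediction run and applies the binary formula to the summed counts.
ROC AUC uses the rank (Mann–Whitney) formulation with ties counted one half.
A caution surfaced by the brute-force tests: the two-class micro-average
coincides with the binary MCC only when the confusion matrix is symmetric
(TP = TN, FP = FN); in general the two statistics differ, so the package
always reports which one it computed.

## The synthetic-sequence generator

The generator plants exactly the discriminative structure the two
classifiers assume, so that training, selection and evaluation are testable
without downloads:

* **SP** records carry a tripartite prefix: an n-region of 1–5 residues
  drawn from {K, R} with probability 0.6 (background otherwise), an h-region
  of 7–15 residues drawn uniformly from the hydrophobic set, and a c-region
  of 3–7 polar residues with the −1 and −3 positions forced into the small
  set. Region boundaries are recorded in the record description.
* **TM70** records carry a 19–23 residue hydrophobic stretch starting within
  the first 40 residues (so it lies entirely inside the 70-residue window)
  and no signal prefix.
* **IN_CELL** records are background only.
* **UPS** positives differ from background purely through composition: the
  arginine probability is multiplied by 2.5, the K/H probabilities by 1.5
  (then renormalized), and lengths are scaled by 0.6 (hence lower molecular
  weight). These defaults are moderate shifts — strong enough to be
  learnable at a few hundred examples, weak enough that single sequences
  still look like ordinary proteins.

Background composition is uniform over the 20 residues by default (an
average-proteome option is provided); lengths are uniform on 80–400
residues so every default segment is non-degenerate. Everything is
deterministic under the configuration seed. `generate_drifted_copy()` plants
covariate shift for testing the drift ranking: composition features are
shifted by probabilistic residue replacement calibrated in
standard-deviation units of the input set, molecular weight by
appending/trimming background residues.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: realistic residue correlations along the chain,
homology structure between records, cleavage-site sequence logos beyond the
−1/−3 constraint, signal anchors, the composition overlap between true UPS
proteins and the intracellular proteome, or annotation noise. Performance
numbers on synthetic conditions are sanity floors for the machinery, not
forecasts of proteome accuracy.

## Problem sizes and reproducibility

The shipped evaluation uses desk-scale sizes chosen to exercise every code
path at comfortable statistical power: n = 600 (200 per class) for the
stage-one nested CV plus an equally sized label-permuted control; n = 400
(200/200) for stage-two training; 96/345 for the oversampling geometry;
120/120 with 20 seeded repetitions for drift recovery; 100/100 held-out
records for the calibration check. All fold splits, initialisations, batch
orders and generator draws derive from explicit integer seeds; identical
seeds give identical results, including across the bundled
`scripts/acceptance.R`, which regenerates every quantity from scratch.

## Known limitations

* Stage one is trained and validated on eukaryotic-style signal anatomy;
  prokaryotic signal peptides (e.g. twin-arginine motifs) are out of scope.
* Cleavage-site *position* is not predicted — only the presence of a signal.
* The CNN hyperparameters of the originally published model are not public;
  this package's defaults are its own, selected by inner-CV behaviour on
  synthetic conditions, and benchmark figures against external tools are
  out of scope.
* The drift-ranking algorithm and the best-one stopping rule are
  reconstructions (documented above) of procedures that are only named, not
  specified, in the source literature.
* Structure-derived features are deliberately excluded; the description is
  sequence-only.
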