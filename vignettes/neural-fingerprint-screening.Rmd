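---
title: "Neural fingerprint-based virtual screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural fingerprint-based virtual screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Structure-based virtual screening docks a large compound library against a
protein target and keeps the molecules with the most favourable predicted
binding free energy, ΔG°~bind~(aq) in kcal/mol (more negative = tighter
binding). Docking is the bottleneck: a surrogate classifier that reads only
the molecular structure (a SMILES string) and predicts whether a molecule
would land in the low-energy tail lets a user triage much larger libraries
and dock only the promising fraction. In a screening funnel the cost of
discarding a true binder (a false negative) far exceeds the cost of
carrying a decoy forward, so the models here are selected recall-first.

`nfscreen` implements that surrogate as a *trainable* molecular
fingerprint: a graph-convolutional analog of the extended-connectivity
(ECFP/Morgan) fingerprint in which the two non-differentiable steps of the
classical algorithm are replaced by smooth maps, so the representation
itself is optimized by the classification loss.

## The model

**Molecular graph.** A SMILES string is parsed (RDKit, behind a batch
subprocess bridge) and canonicalized, and the molecule becomes three
matrices: per-atom features (element one-hot over
{C, N, O, S, P, F, Cl, Br, I, other}, heavy-atom degree 0–5, attached-H
count 0–4, formal charge, aromaticity flag; 23 columns), per-bond features
(order one-hot single/double/triple/aromatic, conjugation, ring membership;
6 columns), and the adjacency structure linking them. Hydrogens are
implicit — they appear as a count feature, not as nodes — which keeps
graphs at heavy-atom size. Elements outside the vocabulary map to a
reserved slot rather than failing, so a screening table never crashes on an
exotic ion.

**Convolutional fingerprint.** Let r⁰~a~ be atom *a*'s feature vector. For
each layer *l* = 1..L the atom's state is combined with its neighbourhood,

> v~a~ = r^l−1^~a~ ⊕ Σ~u∈N(a)~ r^l−1^~u~ ⊕ Σ~b∋a~ bond~b~,
> r^l^~a~ = σ(v~a~ H~l~ + h~l~),

the sigmoid playing the role of ECFP's neighbourhood *hash*. At every
depth *l* = 0..L (including the raw input layer) each atom emits a
softmax over the K fingerprint positions — the smooth replacement of the
*array-indexing* step that sets a bit in the classical algorithm:

> i^l^~a~ = softmax(r^l^~a~ W~l~ + c~l~),

and the fingerprint is the vector sum of every atom's contribution at every
depth. Two consequences are load-bearing and tested: the entries of a
fingerprint always sum to n~atoms~·(L+1) (each softmax row sums to one),
and sum-pooling makes the fingerprint exactly invariant to atom relabelling.
Since every step is differentiable, a perturbation of any weight moves the
fingerprint continuously — there are no hash-style discontinuities, which
is the point of the construction.

**Classifier and joint training.** The fingerprint feeds a small
fully-connected head (default K → 100 → 100 → 1, ReLU, dropout on the
hidden activations) ending in a sigmoid hit probability. The loss is
binary cross-entropy, minimized by Adam, and — this is the central design
point — the gradient flows through the head *and* through every hidden and
output weight of the fingerprint, so the representation is trained for the
specific target rather than fixed a priori. All weights are initialized
Xavier-normal (variance 2/(fan~in~+fan~out~), a good match for sigmoid
activations) and all biases to the constant 0.01.

The reverse-mode gradients are derived and implemented by hand in this
package (no autodiff engine); their correctness oracle is central finite
differences, which the test suite applies to every fingerprint and head
parameter of a small molecule/model pair at relative tolerance 1e−4.

## Data pipeline

A score table (`smiles`, `dG_kcal_mol`) is split at random into 70/15/15
train/validation/test. The hit threshold is the percentile of the
*training* energies only — using whole-dataset quantiles would leak
validation/test information into the labels — and a record is a hit iff
its energy is strictly below the threshold, so under ties the realized hit
fraction never exceeds the requested 5/10/20%. Because weakly binding
molecules greatly outnumber tight binders, the training split is rebalanced
by oversampling: hits are duplicated uniformly at random until the classes
sit at exactly 50/50. Validation and test splits are never altered.

Duplicate molecules in a score table collapse to their most negative
energy; unparsable rows are dropped and counted.

## Evaluation

Precision TP/(TP+FP), recall TP/(TP+FN), and their harmonic mean F1 are
computed from exact confusion counts; when no hits are predicted, precision
is reported as `NA` — an explicit "undefined" flag — because a silent zero
would corrupt grid-search ranking. ROC curves sweep every distinct score
as a threshold and the trapezoidal AUC equals the Mann–Whitney concordance
probability (ties at one half); PR-AUC uses stepwise (average-precision)
interpolation. The predictive enrichment probability (PEP) restricts to
true hits and reports, per 0.01 kcal/mol energy bin (half-away-from-zero
rounding; empty bins omitted), the fraction the model recovers; its
count-weighted mean over bins — the aggregate PEP — is identical to recall,
an identity the tests assert.

## Hyperparameter search and selection

`grid_search()` trains one model per Cartesian-product combination over
{weight decay, learning rate, dropout, batch size, fingerprint length} and
ranks by validation recall, breaking ties on precision and then on the mean
binding free energy of the predicted hits (more negative preferred). The
defaults — depth L = 3 (an ECFP4-like radius), fingerprint length 512 with
{128, 512, 1024} as the usual search values, hidden widths 100/100, early
stopping on validation loss with patience 10 — are package choices where
the underlying procedure leaves them open; epoch budget, stopping rule and
head depth have no canonical values and are exposed in `train_config()`.
Weight decay is folded into the Adam gradient (the classical Adam + L2
coupling). Dropout applies to the head's hidden layers only.

## The Morgan baseline

`train_morgan()` plugs the classical hashed Morgan fingerprint (default
radius 2, 1024 bits, computed by RDKit) into the *same* head, loss,
optimizer, oversampling and early stopping. Its fingerprint has no
trainable parameters, so the comparison in `compare_architectures()` —
identical split, identical threshold, test-set precision/recall/ROC-AUC per
architecture — isolates the value of making the representation trainable.
The comparison is deliberately single-pass: no iterative library-reduction
protocol is implemented.

## The synthetic generator

Real docked libraries cannot ship with a package, so `synth_config()` /
`simulate_screen()` emulate one. Molecules are assembled from a fixed
fragment grammar (mono- and di-substituted five- and six-membered ring
scaffolds over {C, N, O, S, F, Cl}), which guarantees RDKit-valid SMILES by
construction; output is deduplicated on canonical form and the generator
resamples until the requested number of distinct molecules is reached.
Energies follow an additive model:

> ΔG = base + Σ motif offsets + N(0, noise_sd²),

with defaults base −6.5 kcal/mol, noise 0.5 kcal/mol, and three
pharmacophore-like motifs detected by SMARTS match — sulfonamide (−3.5),
carboxylic acid (−3.0), nitrile (−2.5 kcal/mol). Substituent slots draw a
motif with probability 0.10, which after di-substitution and deduplication
leaves roughly three molecules in ten carrying at least one motif. With a
20% hit threshold the hit set then lies almost entirely inside the
motif-bearing tail: the task is provably learnable from structure (a
logistic regression on motif indicators alone reaches ROC-AUC ≥ 0.95, a
floor the tests establish before any neural model is blamed), while the
exact hit/non-hit boundary inside the tail remains noise-limited, as in
real docking scores. The graded offsets also give the ranking problem
within the tail some structure.

What the generator does *not* emulate: the chemical diversity of a real
purchasable library, docking physics, pose-dependent scores, activity
cliffs, or assay noise correlated with molecular size. A model passing the
synthetic recovery test has demonstrated that the architecture and
gradients work end to end — not that it would enrich a real campaign.

## Numerical choices and degenerate inputs

* Softmax rows are computed with row-max subtraction; binary cross-entropy
  uses the stable `max(z,0) − zy + log1p(exp(−|z|))` form.
* Seeds control initialization, shuffling, dropout masks, splits and
  oversampling; identical seed + data reproduce a run exactly, and
  checkpoints (RDS) reload bit-exactly.
* A single-atom molecule is a valid graph (no bonds, empty neighbourhood
  sums); an all-equal energy vector yields zero hits under the strict
  threshold; a batch is stacked as one block-diagonal graph, so batched and
  per-molecule fingerprints agree to machine precision.
* Bond features enter the convolution from layer 1 (the layer-0
  representation is pure atom features); with one shared weight matrix per
  layer this is the simplest consistent reading, and degree-specific
  weights are intentionally out of scope.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are stable: 2,000 distinct
molecules, a 2 × 2 grid (learning rate × dropout) at fingerprint length
128, 25-epoch budget with patience 10, and a 15-epoch Morgan baseline.
On this task the recall-maximizing grid-search model typically reaches
test recall ≳ 0.95 and ROC-AUC ≳ 0.95; both architectures are reported on
the identical test split.

## Known limitations

* SMILES handling requires a Python RDKit on the PATH; the bridge is
  batched (one subprocess per call), so per-molecule loops should go
  through the vectorised entry points.
* The fingerprint trainer is pure R; it is comfortable at
  10³–10⁴ molecules and minutes of CPU, not at millions.
* Stereochemistry is ignored by the featurization (enantiomers collapse).
* `hit_fraction = 1` makes every record a hit and leaves nothing to rank;
  oversampling requires at least one hit and one non-hit in training.
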