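---
title: "Methods: a voting-filtered ensemble QSAR workflow for hepatotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a voting-filtered ensemble QSAR workflow for hepatotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(diliqsar)
```

## The problem and the model

Drug-induced liver injury (DILI) is a leading cause of attrition in drug
development, and its mechanisms are heterogeneous enough that no single
descriptor or learner captures the endpoint well. `diliqsar` treats DILI
prediction as a binary QSAR problem and follows a curation-heavy design
philosophy: most of the machinery exists to improve the *training data* —
structure normalization, tiered label merging, class balancing, and a
cross-validated voting filter for probable mislabels — before a deliberately
conventional classifier bench is applied and fused by probability averaging.

The statistical model is simple by construction. Eight base classifiers
each emit a positive-class probability; the ensemble score is their
unweighted arithmetic mean and the decision threshold is 0.5, with ties
classified positive (favoring sensitivity, the costlier error direction for
a hepatotoxicity screen). All evaluation is by stratified 10-fold
cross-validation with pooled out-of-fold predictions; we pool rather than
average per-fold metrics because pooling gives integer confusion counts for
the whole set and is insensitive to fold-level class imbalance at small n.

## Structure standardization

Each input SMILES is processed as follows:

1. stereochemical annotations are cleared (`@`, `/`, `\`) — DILI labels
   attach to the parent scaffold, and stereo-collapsed keys let salt forms
   and enantiomers deduplicate to one record;
2. the string is split into components; the largest organic component is
   kept as the parent, so counterions, water and solvents are dropped;
3. the parent is rejected if it contains elements outside
   {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I} (the conventional organic
   QSAR whitelist — the set of "metal and rare atoms" is not enumerable from
   first principles, so a fixed documented whitelist is used), if it
   contains no carbon (inorganic), or if two or more components each carry
   at least four carbons (a true mixture rather than a salt form);
4. protonation states are neutralized by adding/removing explicit protons
   only — no bond edits, so quaternary ammonium and other non-protic charges
   are left intact;
5. the result is canonicalized with Open Babel; the stereo-free canonical
   SMILES doubles as the structure key.

Ordering matters: the element whitelist is judged *after* counterion
stripping, because a sodium salt must standardize to its parent acid rather
than be discarded for containing sodium. Mixture/inorganic judgment also
happens after stripping for the same reason. The full pass is idempotent —
re-standardizing an already-standardized record changes nothing — which the
test suite asserts on a fixture covering every branch.

Admission bounds are strict as stated: fewer than 4 carbons or molecular
weight above 900 (average atomic masses on the standardized parent) reject a
record; exactly 4 carbons and exactly MW 900 pass.

## The 85-descriptor surrogate set

The reference descriptor set for this class of model is proprietary and not
published as a list, so the package ships its own named, versioned set
(`diliqsar-85-v1`): 30 physicochemical and 55 topological descriptors. The
four descriptors known to matter for hepatotoxicity models — molecular
weight, ClogP, molar refractivity and molecular polarizability — are
mandatory members. ClogP, MR, TPSA and H-bond counts come from Open Babel's
atom-contribution models; polarizability is estimated from molar
refractivity via the Lorentz–Lorenz proportionality (α ≈ 0.3925 · MR, with
MR in cm³/mol and α in Å3), a documented surrogate. The topological block is
computed on the hydrogen-suppressed graph of the canonical stereo-free
SMILES: counts and fractions (rings by cyclomatic number, aromatic atoms and
rings, rotatable bonds as non-ring single bonds between non-terminal atoms,
sp³/sp²/sp carbons from bond orders), distance-based indices (Wiener,
hyper-Wiener, Harary, Balaban J, eccentricities, Petitjean shape), and
connectivity indices (Zagreb, Randić χ, valence-corrected χ via Kier–Hall
deltas, kappa shape indices). Because every value is computed on the
canonical form, descriptor computation is invariant to how the input SMILES
was written; values are deterministic and rows with any non-finite entry are
excluded from modeling with a logged id.

Fingerprints are genuine Open Babel FP2 — hashed linear paths up to 7 bonds
over 1024 bits — with optional OR-folding to shorter lengths. A molecule
with no eligible path (methane) takes the all-zero fingerprint, and two
all-zero fingerprints compare at Tanimoto 1 by convention (degenerate
molecules are "identical", and the mean pairwise similarity of a dataset
stays defined).

## Feature filters

Two unsupervised filters, both with threshold 0.95: a feature is removed
when its modal value covers more than 95% of compounds (strictly greater —
exactly 0.95 is retained), and then a greedy scan in the fixed canonical
column order removes the later-ordered member of every pair with
|Pearson r| > 0.95. Absolute correlation is used because an anti-correlated
feature is exactly as redundant as a correlated one. Keeping the
earlier-ordered column makes the filter deterministic and idempotent; after
the pass no retained pair exceeds the cutoff, which is re-asserted by
recomputing the full correlation matrix. On the reference data these filters
took 85 descriptors to 55; with this package's surrogate descriptors the
surviving count will differ, so the exact "55" is not a test gate —
the filters' *properties* are.

## Kennard–Stone balancing

Negatives usually outnumber positives in curated hepatotoxicity data. All
positives are kept and the negatives are reduced to the target count with
the classic Kennard–Stone max–min algorithm: seed with the two
farthest-apart points, then repeatedly add the candidate whose minimum
distance to the selected set is largest. Distances are Euclidean on
z-scored retained descriptors — z-scoring prevents MW-scale features from
dominating the metric. Ties take the lowest row index (and the seed pair is
reported in row order), making the algorithm fully deterministic; the
implementation is verified against an exhaustive per-step max–min oracle on
every random instance with n ≤ 12. Excluded negatives are kept as a
disjoint reverse-validation pool rather than discarded.

## The voting filter

Literature-derived labels are noisy. The voting filter runs the full
eight-classifier bench under stratified 10-fold CV (one shared fold
partition, so classifiers are comparable), scores each compound 1 per
classifier whose out-of-fold prediction matches its label, and removes
compounds scoring below 2 of 8. Out-of-fold rather than resubstitution
predictions are used so that the filter measures generalizable
disagreement, not memorization. Removal is monotone in the threshold, and a
compound predicted correctly by at least `min_score` classifiers is never
removed. On synthetic data with planted label flips, flipped rows score
near 0 while clean rows average above 7 — the separation the filter relies
on.

## The classifier bench

The eight roles mirror a standard WEKA 3.8 default bench, with two
documented surrogates where no common open-source counterpart exists:

| role | implementation | key settings |
|---|---|---|
| naive_bayes | Gaussian naive Bayes (e1071) | defaults |
| knn | 1-nearest neighbor (class) | k = 1 |
| kstar_like | distance-weighted neighbors (in-package) | k = 25, exp(−d/h) weights |
| adaboost | AdaBoost.M1 on CART stumps (in-package) | 10 iterations |
| bagging | bootstrap-aggregated CART trees (in-package) | 10 replicates |
| decision_tree | CART (rpart) | cp = 0.01 |
| random_forest | randomForest | 100 trees (30 in fast profile) |
| mlp_deep | 1-hidden-layer softmax net (nnet) | 10 units, decay 0.01 |

The `kstar_like` learner stands in for the entropic instance-based Kstar: it
is in the same family (lazy, distance-weighted, all-neighbors influence)
and reproducible. `mlp_deep` stands in for a deep-learning library run with
defaults whose exact architecture is unspecified; a small fully-connected
network on standardized inputs is the faithful CPU-only reduction. No
hyperparameter optimization is performed anywhere — the bench is
deliberately default-parameterized, and alternative fusion rules beyond the
mean are out of scope.

Every stochastic learner draws its RNG stream from a sub-seed derived from
the master seed (fold-and-learner indexed), so a fixed seed reproduces every
probability bit-for-bit without disturbing the caller's RNG state.

`modeling_control()` exposes two profiles. `"standard"` is the default;
`"fast"` shrinks only learner sizes (30-tree forest, 5-unit/40-iteration
network) and exists for experiments that refit the whole bench hundreds of
times, such as Y-randomization; decision rules and the roster are unchanged.

## Evaluation and Y-randomization

Metrics are exact confusion-matrix arithmetic; when a class is absent the
affected metric is reported as undefined rather than silently zeroed. AUC is
computed twice — by midranks (Mann–Whitney, ties at half credit) and by
trapezoidal threshold sweep — and the function errors if the two disagree
beyond 1e-9, so every reported AUC carries its own cross-check.
`reconstruct_confusion()` inverts printed sensitivity/specificity and class
sizes back to integer confusion counts (rounding to the nearest integer and
warning when the printed rate is inconsistent with any integer), which is
how the package reproduces published comparison tables without the
underlying predictions.

Y-randomization permutes the label vector once per run over the whole set —
a permutation preserves class counts by construction — and reruns the
entire CV pipeline per permutation, 100 runs by default. On balanced data
the expected accuracy is 0.5 with run-to-run SD on the order of
√(0.25/n) (≈ 0.014 at n = 1254; the observed SD is slightly larger because
learner stochasticity adds variance). This chance-level behaviour holds
whether or not the unpermuted data carry signal.

## The synthetic generator

`generate_synthetic_dataset()` emulates a post-descriptor modeling table,
not molecules: informative features are unit-variance Gaussians whose class
means differ by `signal` SDs (each informative feature carries the full
separation, so the recovered standardized mean difference per feature equals
`signal`); redundant columns copy informative ones plus N(0, 0.08) noise
(population r ≈ 0.997, reliably above the 0.95 filter); near-constant
columns have modal frequency ≈ 0.97; label noise flips a recorded random
subset. A Gaussian class-conditional model was chosen because its Bayes
error is available in closed form — at signal 3 a single feature already
yields Φ(1.5) ≈ 0.933 accuracy, which grounds the "strong-signal ⇒ CV
accuracy > 0.9" check. What the generator does *not* emulate: real
descriptor marginals (heavy tails, integer-valued counts, block correlation
structure), so passing tests demonstrate pipeline correctness and
calibration at known truth, not clinical performance on real chemistry.

The default dimensions (n = 1254, 55 features, 636/618 class split) mirror
the reference modeling set for hepatotoxicity, so chance-level experiments
run at realistic size.

## Numerical choices and degenerate inputs

* Classification ties (probability exactly 0.5) go to positive.
* Two all-zero fingerprints: Tanimoto 1 (documented convention).
* Kennard–Stone with duplicate rows: zero distances are legal; the lowest
  index wins ties.
* Single-heavy-atom molecules: the SDF toolkit rejects bond-free molecules,
  so the graph falls back to the SMILES token parse; such molecules are
  size-rejected upstream in any full run.
* Metrics identities are asserted to 1e-12; the AUC dual computation to
  1e-9.
* Problem sizes in the test suite are chosen to keep the full suite at a
  few minutes while leaving the chance-level experiment at full dimensions
  (1254 × 55, 100 permutation runs with the fast profile).

## Known limitations

* Descriptor values are surrogates: models trained here are not numerically
  comparable to ones built on proprietary descriptor implementations, and
  the exact post-filter descriptor count differs from the reference 55.
* Label semantics are binary; severity grading and dose dependence are out
  of scope.
* Name/CAS-to-structure resolution is not attempted — inputs must carry
  structures.
* The voting filter assumes mislabels are *hard to predict correctly*; a
  systematically mislabeled chemical series would evade it.
* No applicability-domain estimate is provided; predictions far outside the
  training chemical space are extrapolations.
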