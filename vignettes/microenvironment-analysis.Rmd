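---
title: "Voxel-based analysis of protein microenvironments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based analysis of protein microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroEnvNet)
```

## The model

A protein site is characterized by its *microenvironment*: the arrangement
of atoms in a local neighborhood around a position of interest.  MicroEnvNet
implements a voxel-based pipeline for learning which of the 20 amino acids
best fits a given microenvironment, and for turning the resulting prediction
statistics into amino-acid substitution scores and mutation-effect
predictions.

The pipeline is:

1. **Sampling.** A 3D grid with 10 Å spacing is anchored at the minimum
   x/y/z corner of the structure's bounding box and spans it
   (`sampleGrid()`).  For each grid point the residue owning the nearest
   atom becomes the center residue (`pickCenterResidue()`, ties broken by
   lowest atom serial).
2. **Frame alignment.** Each center residue defines a local right-handed
   orthonormal frame from its backbone: the N–CA and C–CA bonds span the
   x–y plane, and the plane normal whose dot product with CA→Cβ is positive
   is the +z axis (`buildFrame()`).  Because the x direction within the
   plane is not pinned down by that constraint alone, the package fixes
   x = unit(N−CA); any fixed convention preserves the goal of the
   alignment, which is that the extracted neighborhood is invariant under
   global rotations and translations of the structure.
3. **Box extraction.** A 20 Å cube centered on the Cβ atom (virtual for
   glycine) is cut out in frame coordinates; the half-open convention
   `[-10, 10)³` makes the later voxel assignment unambiguous.  All side
   chain atoms of the center residue — including Cβ — are removed, and the
   box is labeled with the removed residue type (`extractBox()`).  Cβ
   centering maximizes the observable footprint of the missing side chain
   while remaining comparable across all 20 amino acids.
4. **Voxelization.** Atoms of the four channel elements (O, C, N, S) are
   discretized into 1 Å voxels (occupancy capped at 1 — at this resolution
   two heavy atoms in one voxel indicate unphysical geometry, and a cap
   event is logged), then each channel is convolved with a unit-mass
   Gaussian approximating atom connectivity and electron delocalization
   (`voxelize()`).  Hydrogens are not represented: their positions are
   essentially determined by the heavy atoms.
5. **Normalization.** Channel-wise per-position means computed on the
   training set only are subtracted from every split (`fitNormalizer()` /
   `applyNormalizer()`).
6. **Classification.** A deep 3D convolutional network maps the
   (4, 20, 20, 20) tensor to 20 class scores.  The default stack is
   Conv(100, 3³) → Conv(200, 3³) → MaxPool(2) → Conv(400, 3³) → MaxPool(2)
   → Dense(10800→1000) → Dense(1000→100) → linear softmax classifier, with
   ReLU activations and dropout 0.3 after each convolutional and dense
   layer.  The receptive field of a neuron in the final pooling layer is
   12 voxels = 12 Å, so predictions integrate local features up to that
   spatial range within the 20 Å box (`receptiveField()`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| grid spacing | 10 Å | density of sampled box centers |
| box size | 20 Å | local neighborhood edge length |
| voxel size | 1 Å | spatial resolution of the channel tensor |
| σ (C, N, O, S) | 1.70, 1.55, 1.52, 1.80 Å | Gaussian widths = Bondi van der Waals radii |
| batch size | 20 | SGD mini-batch |
| dropout | 0.3 | applied after conv/dense activations (inverted dropout) |
| learning rate | 0.01 | constant SGD step; configurable per run |
| validation carve | 1:19 | validation:train ratio on the balanced training set |
| test family fraction | 0.05 | fraction of protein families held out |

The Gaussian width is stated in the underlying method only as "the average
van der Waals radius" of each element; the package adopts the Bondi radii
above and leaves them configurable.  The kernel is normalized to unit mass
and truncated at 2σ (rounded up to whole voxels): a unit-mass kernel
conserves per-channel atom counts (up to truncation and boundary loss),
which keeps channel sums interpretable; an amplitude-1 kernel is the
documented alternative.

## Dataset construction

Balancing follows the least-abundant-class rule: the rarest amino-acid
class is kept in full and every other class is subsampled without
replacement to that count (`balanceDataset()`).  Validation examples are
drawn from the balanced training set at 1:19 (`carveValidation()`); the
draw is class-stratified with a largest-remainder allocation so that the
total is exactly `floor(n/20)` while every class stays within one example
of the target fraction.  Stratification is this package's choice — a plain
random draw is also consistent with the procedure's description, but
stratification preserves the balance the earlier step just established.

Train/test splitting is by protein family: whole families are assigned to
one side (`splitFamilies()`, floor semantics: 5% of 3890 families gives
194 test families), so no test structure shares a family with any training
structure.  Sequence-similarity filtering (e.g. CD-HIT at 40%) is treated
as an external preprocessing step; `assignStructures()` accepts an
exclusion list of structure identifiers.

## Substitution matrices from confusion statistics

With the raw confusion counts `M[i, j]` (true class i predicted j) over an
evaluation set:

* **S_freq** is a log-odds matrix: with `p(i,j) = M[i,j]/ΣM` and marginals
  `q_row(i)`, `q_col(j)`, the asymmetric score is
  `log(p(i,j)/(q_row(i)·q_col(j)))`, symmetrized by averaging with its
  transpose (`sFreq()`).  Unlike alignment-derived matrices the underlying
  odds ratio is genuinely asymmetric — confusion from i to j depends on the
  network's propensity to predict j — hence the explicit symmetrization.
* **S_dot** measures profile similarity: the row- and column-stochastic
  normalizations of M are L2-normalized per row/column and
  `S_dot[i,j] = log(dot(Row_i, Row_j) + dot(Col_i, Col_j))` (`sDot()`).
  By Cauchy–Schwarz the diagonal is exactly log 2 and dominates every
  off-diagonal entry.

Numerical choices: natural logarithms throughout, and log arguments floored
at 1e-10 for empty cells (both flagged in the result metadata).  Neither
choice can affect matrix comparisons: `compareMatrices()` reports the
Pearson R-value of paired entries, which is invariant under affine
transformations of either matrix.  Because all matrices involved are
symmetric, the default comparison pairs each unique entry once (upper
triangle including the diagonal); the full 400-cell pairing is available
via `cells = "full"` and differs only in how strongly the diagonal is
weighted.  Under the unique-entry convention the bundled BLOSUM62 and
PAM250 reproduce their published correlation (R ≈ 0.872); the full-cell
convention yields ≈ 0.84.

Knowledge-based group accuracy (`groupAccuracy()`) counts a prediction as
correct when it lands in the same biochemical group as the truth.  The
default partition — nonpolar aliphatic {A,V,L,I,M}, aromatic {F,W,Y},
polar uncharged {S,T,N,Q}, positive {K,R,H}, negative {D,E}, special
{C,G,P} — is one conventional choice among several in the literature; it
is fully configurable (JSON), and reported results should state the scheme
used.  Hierarchical clustering of row-normalized confusion matrices uses
Ward linkage on Euclidean distances (`hclust` method `ward.D2`, the
distance-based Ward variant used by scipy).

## Mutation-effect classification

For a point variant (e.g. G77A), side-chain-stripped boxes are extracted at
the variant site in the wild-type and mutant structures
(`extractVariantPair()`); the trained network yields predicted labels WP
and MP.  Feature sets are score-matrix lookups in a fixed order:
6-Feature = [S(WT,WP), S(WT,MT), S(WT,MP), S(WP,MT), S(WP,MP), S(MT,MP)];
3-Feature keeps the first, second and fourth; 1-Feature is [S(WT,MT)]
(`buildMutationFeatures()`).  `cvClassify()` runs stratified 4-fold cross
validation of a Lasso regression (prediction thresholded at 0.5 against
effects coded destabilizing = 1, neutral = 0) or an RBF-kernel SVM, with
features standardized on training folds only.  Regularization strengths
are not pinned down by the method description; the defaults are λ = 0.01
(Lasso), C = 1 and γ = 1/d (SVM), always echoed in the result.  The
bundled fixture (`loadT4Variants()`) transcribes the 40 T4 lysozyme point
mutants with literature-assigned destabilizing/neutral effects.

## Atom importance maps

`importanceMap()` computes the gradient of the true class's pre-softmax
score with respect to the input tensor at the observed input, multiplies it
elementwise by the input (so that, to first order, a voxel's score
approximates the effect of zeroing it), takes absolute values, and min-max
normalizes to [0, 100] over all positions and channels of the example.
Three underdetermined details are resolved as follows, each configurable:
the class score is the pre-softmax logit (the post-softmax probability is
available via `score = "probability"`); per-atom scores sum the normalized
voxel scores over the atom's Gaussian smoothing support in its own channel
(`mode = "nearest"` restricts to the atom's voxel) and are rescaled so the
maximum atom is 100; all-zero maps are defined as zero rather than NaN.
`exportBfactor()` writes the scores into PDB B-factor columns for
rendering.

## The synthetic generator, and what passing tests show

Real training data for this method are tens of thousands of curated
domains.  For testing, `syntheticStructure()` generates helix-like chains
of rigid backbone templates (ideal CA trace: radius 2.3 Å, 100°/residue,
1.5 Å rise) with uniformly drawn residue types, optional coordinate noise,
and a guaranteed 1.2 Å minimum interatomic separation; the structures parse
and round-trip as PDB.  `makePlantedTask()` builds balanced classification
tasks whose classes are deterministic atom motifs placed *in the local
frame* within 5 Å of the box center — this is what makes the end-to-end
pipeline testable, because the planted signal survives frame alignment —
plus distractor atoms drawn uniformly in the 6–10 Å shell.  At zero noise
the task is exactly separable (a nearest-centroid baseline reaches 1.0);
at σ = 0.3 Å a scaled-down network (Conv(8,3³) → Pool → Conv(16,3³) →
Dense(32), 200 examples per class over 4 classes) exceeds 0.80 validation
accuracy within 10 epochs of SGD at the default rate.

These fixtures emulate the *shape* of real data, not its content: they have
no tertiary packing, rotamers, chain breaks, crystallographic artifacts or
realistic amino-acid composition.  Passing tests therefore demonstrate that
the geometry, featurization, learning and derivation machinery are correct
and invariant as claimed — not that paper-scale accuracies on real proteins
are reproduced, which requires the full PDB-derived corpus and long GPU
training.  The problem sizes used throughout the suite (hundreds of
examples, networks of 8–16 filters) were chosen as the smallest at which
each property is meaningfully exercised.

## Numerical and design notes

* Weight initialization is He-scaled Gaussian, seeded; the optimizer is
  SGD with an L2 penalty and optional classical momentum (default 0); the
  loss is categorical cross-entropy on softmax outputs.  Learning-rate
  schedules are deliberately absent; the constant rate is a config knob.
* With the unit-mass smoothing kernel, voxel values are of order 0.01, so
  gradients through He-initialized layers are poorly conditioned for plain
  SGD.  `fitNormalizer(scale = TRUE)` therefore optionally stores the
  global standard deviation of the centered training values and rescales
  inputs to unit variance; the default remains zero-mean-only.  The
  rescaling is a numerical conditioning choice — it changes no decision
  boundary the network can express — and the learnability demonstration
  uses it.
* The virtual Cβ for glycine is constructed analytically from N/CA/C
  (1.53 Å bond, N–CA–CB = C–CA–CB = 110.5°, L-chirality branch) instead of
  averaging superimposed Cβ atoms from a reference set: it is deterministic
  and needs no reference data.  Frames degenerate when N, CA, C are
  collinear (cross-product norm < 1e-6), which is reported as an error.
* Waters, other HETATM records, hydrogens and non-standard residues are
  excluded at parse time; alternate locations keep blank or "A"; only the
  first model of multi-model files is used.  Whether hetero atoms
  contributed to boxes in the original data preparation is not stated; the
  exclusion here is explicit, not inferred intent.
* Boxes may legitimately be empty (flagged with a warning).  Confusion
  rows with no examples are left at zero and flagged rather than
  renormalized.
* Tensor and checkpoint archives are serialized as RDS with plain TSV for
  boxes, confusion tables and matrices; all text formats are stable across
  platforms.
* Known limitations: no rotational data augmentation; no partial-charge or
  property channels; multi-chain handling keeps all retained atoms of the
  parsed structure in every box; the CLI trains desk-scale networks only.

## Reproducing the bundled checks

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the architecture's receptive field from the layer stack.  The testthat
suite covers each module against independent oracles (brute-force
convolution loops, naive formula-by-formula substitution derivations,
Lance–Williams agglomeration, finite-difference gradients) and the
invariances discussed above.
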