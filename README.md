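# MicroEnvNet

Structure-based analysis of protein microenvironments with 3D convolutional
networks, for structural bioinformaticians and protein engineers who want to
ask: *which amino acid best fits this spot in a structure, and what does
that imply for mutations?*

## What it does

A protein site is represented by the raw atom distribution in a 20 Å box
around the Cβ atom of a residue, aligned to a backbone-derived local frame
(N–CA and C–CA span the x–y plane; the plane normal with positive dot
product onto CA→Cβ is +z) and stripped of the center residue's side chain.
The box is discretized into 1 Å voxels over four element channels
(O, C, N, S), Gaussian-smoothed with per-element van der Waals widths, and
fed to a deep 3D CNN

```
Conv(100,3³) → Conv(200,3³) → Pool(2) → Conv(400,3³) → Pool(2)
             → Dense(10800→1000) → Dense(1000→100) → Softmax(20)
```

trained with SGD (batch 20, dropout 0.3, L2) to predict the removed
side-chain type — the amino acid most compatible with the microenvironment.

From the prediction confusion counts `M[i,j]` the package derives two
20×20 substitution matrices:

* `S_freq[i,j] = sym( log p(i,j) / (q_row(i) q_col(j)) )` — a log-odds
  matrix over joint vs marginal prediction frequencies, symmetrized by
  averaging with its transpose;
* `S_dot[i,j] = log( ⟨Row_i, Row_j⟩ + ⟨Col_i, Col_j⟩ )` — log summed cosine
  similarities of L2-normalized confusion row/column profiles (diagonal
  exactly log 2).

These feed cross-validated Lasso/SVM classifiers of mutation effects
(destabilizing vs neutral) via score lookups such as
`6-Feature = [S(WT,WP), S(WT,MT), S(WT,MP), S(WP,MT), S(WP,MP), S(MT,MP)]`,
with the 40 T4 lysozyme variants bundled as a reference fixture.
Gradient×input atom importance maps explain individual predictions and
export to PDB B-factors.

A synthetic-structure generator (helix-like PDB chains, planted
frame-anchored atom motifs) makes the whole pipeline testable offline.

## Worked example

```r
library(MicroEnvNet)

s <- syntheticStructure(30, seed = 1, noise = 0.05)
s
#> ProteinStructure synthetic -- 30 residues, 149 atoms (source: synthetic)

boxes <- extractAllBoxes(s, spacing = 10)   # grid-sampled local boxes
length(boxes)
#> [1] 22
boxes[[1]]
#> MicroenvBox [H] 48 atoms, center residue A:2:. of synthetic

g <- voxelize(boxes[[1]])                   # (4, 20, 20, 20) channel tensor
setNames(apply(g@data, 1, sum), g@channels)
#>        O        C        N        S
#>  7.72759 26.96954 10.60300  0.00000

receptiveField(defaultVoxelNetLayers())
#> [1] 12
```

The box around residue 2 is labeled `H`: its histidine side chain was
removed and becomes the training label.  Channel sums track the atom counts
per element (up to smoothing loss at the box faces).  The receptive field
of the final pooling layer is 12 voxels = 12 Å: predictions integrate local
features up to that range inside the 20 Å box.

Comparing the bundled standard matrices by least-squares R-value:

```r
compareMatrices(loadStandardMatrix("BLOSUM62"), loadStandardMatrix("PAM250"))
#> [1] 0.8716942
```

A command-line wrapper over the same functions lives at
`inst/scripts/microenv` (`synth`, `extract`, `voxelize`, `dataset`,
`train`, `predict`, `eval`, `substmat`, `substmat-compare`, `mutscan`,
`saliency`).

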