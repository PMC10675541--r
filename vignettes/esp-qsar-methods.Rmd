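---
title: "Volumetric ESP descriptors for 3D-QSAR: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric ESP descriptors for 3D-QSAR: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(espqsar)
```

## The modelling problem

Blocking the hERG potassium channel is a classic off-target liability:
compounds that inhibit it prolong the cardiac QT interval, so an early,
cheap estimate of hERG inhibitory potency (pIC50, the negative decadic
logarithm of the molar IC50) is valuable in triage.  espqsar implements a
3D-QSAR pipeline whose molecular descriptor is the *volumetric*
electrostatic potential (ESP): every molecule is represented by the ESP
values at all nodes of a common rectangular grid, not just at surface
points or at pharmacophore features.  Because a volumetric field
descriptor is meaningful only when all molecules sit in a consistent
pose, the heart of the method is a field-based rigid alignment, and
because molecules of very different size cannot be posed consistently
against one template, the dataset is first partitioned into
molecular-weight bands that are modelled independently.

The pipeline, per weight band, is

1. **partition & split** — contiguous 50-amu bins over 250–600 amu
   (seven bands); each band is split 4:1 into training and test sets
   (56:14 at the 70-molecule band size the method was designed around);
2. **template alignment** — the heaviest member is the template; every
   other member is rigidly rotated/translated to maximize the cross
   correlation between the template's ESP and its own charge density;
3. **descriptors** — each aligned molecule's ESP is solved from its
   charge density on the common descriptor grid and flattened to a
   K-vector;
4. **reduction** — PCA fitted on the training rows reduces K (about
   1.2 million at production grid spacing) to as many scores as training
   molecules;
5. **regression** — a sigmoid feed-forward network (56 × 35 × 1 by
   default, no biases) maps scores to min–max-normalized pIC50;
6. **validation** — coefficients of determination for both sets plus the
   external-predictivity statistic whose denominator uses the training
   mean; 0.6 is the conventional qualification threshold.

## Fields and units

Charge density and potential live on uniform, isotropic grids
(`grid_spec`).  The package works in elementary charges and Angstrom
with Coulomb constant 1, so a point charge q has potential q/r and the
alignment score E = ∭ φ ρ dV carries units e²/Å·Å³.  The potential is
defined by the free-space (isolated-system) solution of Poisson's
equation: `solve_poisson()` convolves the density with the 1/r kernel
spectrally on a grid zero-padded twofold per axis, which avoids the
periodic-image artifacts a plain FFT Poisson solve would introduce; the
singular kernel cell is replaced by the self-potential of an
equal-volume uniformly charged sphere.  On a 64³ grid the solution
matches the analytic Gaussian-charge potential q·erf(r/σ√2)/r to 0.03 %
beyond 3σ; the sign convention (positive charge, positive potential) is
fixed here once and only relative ESP patterns matter downstream.

### The density backend

The production method this package models derives densities from ab
initio wavefunctions.  espqsar's default backend is instead an analytic
**promolecule** density: atom-centered Gaussians weighted by per-atom
partial charges, with width σ = 0.5 × the element's Bondi van der Waals
radius.  It is signed (it integrates to the molecule's net charge, not
its electron count), cheap, and exercises every downstream stage with
realistic spatial structure.  When externally computed densities exist
they enter through `cube_backend()` as Gaussian cube files; nothing
downstream changes.  The 0.5 width factor is a shape choice, not a fit:
it keeps neighbouring atomic Gaussians overlapping at bonding distances
without washing out atomic detail.

## Alignment

The common box of a band (`build_common_box`) takes, per axis, the
largest van der Waals extent among the members plus a 2.7 Å margin,
read as one margin per axis, and is centered on the origin;
node count is floor(edge/spacing) + 1.  Defaults are 0.106 Å spacing for
alignment and twice that (0.212 Å, an exact stride-2 subgrid) for
descriptors.

Rotations are sampled deterministically from the Hopf fibration of the
quaternion sphere: the base 2-sphere by a spherical Fibonacci lattice,
the circular fiber by a golden-ratio sequence.  This gives any requested
number of near-Haar-uniform rotations (2000 by default) with the
identity first and no random seed; the sampled set's maximum
nearest-neighbour geodesic gap stays below the ideal uniform spacing
times two, and in practice within ~1 % of ideal at n = 2000.

For each rotamer the target's density — computed once in its starting
pose — is resampled by trilinear interpolation (values outside the
original support are zero), and the cross-correlation with the
template's ESP over *all* integer-cell translations comes from one
zero-padded FFT product.  Zero padding makes the correlation linear, not
circular: density cannot leak across box faces.  Two implementation
choices worth knowing:

* score ties are broken deterministically (lower rotamer index, then
  lexicographically smallest translation);
* rotamer pairs are packed into a single complex FFT (one field in the
  real part, one in the imaginary part), which halves the transform
  count without changing any value beyond roundoff.

The search is exhaustive over rotamers × translations; there is no
gradient refinement, and translations stay on the grid.  The alignment
functional is maximized as stated — same-sign overlap of template ESP
with target density; a normalized variant was considered and left out
because the package follows the plain functional, and the score's
meaning as a similarity (rather than physical interaction energy) is
documented at `best_alignment()`.

Planted-transform recovery (`plant_transform` + `best_alignment`) is the
package's oracle for this stage: a pose constructed as the exact
preimage of the search's rotate-then-translate move is recovered exactly
in our tests (20/20 seeded trials on a 32³ grid with 128 rotamers; the
contract demands 19/20 with ≤ 1 cell error).

## Descriptors and PCA

ESP descriptors are solved on the descriptor grid directly from the
aligned molecule's density and flattened x-fastest.  PCA is fitted on
training rows only (mean-centering is assumed; whether the original
method centered is not stated, and centering is the defensible default),
with components sign-fixed by their largest-magnitude loading.  The
number of scores defaults to the training-set size; since centered data
have rank at most n−1, the last score is identically zero and is kept as
a zero feature so the regression input width stays fixed.

## The network

The regression model is deliberately small and literal: hidden layer
H = sgm(I·w_in), output O = sgm(H·w_out), **no bias terms** (a
config flag could add them, but the default architecture has none,
matching the two-sum composition that defines the model), sigmoid
(1+e^-x)^-1 throughout, targets min–max normalized to [0, 1] from the
*training* activities only.  Training is full-batch gradient descent on
F = Σ (D − O)², with analytically derived backpropagation gradients
(verified against central finite differences to 1e-6 relative), seeded
uniform [-0.5, 0.5] initialization, momentum 0.9, and an optional
bold-driver step control (accept + grow 5 % on non-increase; reject,
halve and reset momentum on increase) that makes the accepted-step loss
trace monotone.  Training stops at F ≤ 1e-4 — the convergence criterion
of the model — or at an iteration cap, needed because noisy targets have
a loss floor far above the criterion.

Two consequences of these faithful choices deserve flags:

* **endpoint saturation** — the extreme training molecules map to
  normalized targets 0 and 1, which a sigmoid can only approach;
  reaching F ≤ 1e-4 therefore forces large output-layer weights.
* **range limitation** — predictions are always strictly inside the
  training activity range; the model cannot extrapolate potency.

### Input conditioning

Raw PCA scores span orders of magnitude across components, and with the
fixed [-0.5, 0.5] weight initialization the hidden layer starts deep in
saturation.  The pipeline therefore rescales *all* scores by one global
factor so the largest training-score magnitude is 0.1
(`qsar_config(input_scale = 0.1)`), which is exactly a choice of input
units (it is folded back into the stored first-layer weights), keeps
initial pre-activations in the sigmoid's near-linear region, and — unlike
per-component standardization, which amplifies the uninformative
components — preserves the relative weighting PCA established.  On the
noiseless synthetic benchmark this choice is the difference between
test-set recovery of ~0.5–0.9 and ≥ 0.92 in every band.

## Validation statistics

`r_squared()` implements 1 − SSE/SST (the coefficient of determination
— often loosely called a squared Pearson correlation, from which it
differs for biased predictions), and `r2_pred()` the external
predictivity form whose denominator deviates observed test values from
the *training* mean.  Both are affine-invariant; metrics are always
computed on denormalized pIC50.  Reports flag qualification at
r2_pred ≥ 0.6 and carry the two largest absolute residuals, supporting
the outlier-exclusion style of analysis.

## The synthetic benchmark

`make_benchmark()` generates the study conditions the package is tested
under: seven weight bands of 70 molecules (490 total) spanning
250–600 amu, each molecule a rigid cluster of C/N/O/S/Cl atoms within a
9 Å ball with zero-sum partial charges in [-0.5, 0.5] e, masses within
±2.5 amu of targets spread across each band.  Activities come from a
*linear teacher* acting on the leading five PCA scores of the true ESP
descriptors, min–max mapped into pIC50 3.5–9.0 (inside the 2.40–9.41
span observed in real hERG data) plus optional Gaussian noise.  Default
grids are the desk profile's (0.4 Å alignment spacing), so the truth is
computed in the same feature space the desk pipeline sees.

Because the teacher consumes descriptors of the *generated poses*, the
benchmark isolates the descriptor/PCA/network stages from alignment:
molecules are emitted already posed in the common frame and the
recovery runs use `align = "skip"`.  Realigning them against a template
would move them off the poses that defined the truth and conflate
alignment behaviour with regression behaviour.  Alignment quality is
instead tested directly by planted-transform recovery, and
`hard_mode = TRUE` produces a variant where every non-template molecule
is rigidly perturbed *after* truth generation so the full
align-then-model path can be exercised.

What passing these tests shows — and does not.  The synthetic molecules
are not bonded chemical structures, their densities are promolecule
sums rather than wavefunction densities, and the teacher is exactly
(log-)linear in descriptor space with homoscedastic noise.  Recovery
results therefore validate the machinery (fields, alignment search,
PCA, training, statistics), not the chemical accuracy of promolecule
ESP descriptors for real hERG data.

## Problem sizes and numerical choices

The package's own test and benchmark scale (the "desk" profile) uses
0.4 Å alignment grids (0.8 Å descriptors), 128 rotamers, and a 50 000-
iteration training cap; these sizes make a full 490-molecule benchmark
run take about a minute while leaving every algorithmic path identical
to the production profile (0.106 Å, 2000 rotamers, 200 000 iterations).
The desk profile is a scaled-down setting, not a faithful reproduction
of production resolution.

Other numerical details: grids store values x-fastest; the Poisson and
correlation transforms use R's mixed-radix FFT on 2× zero-padded
arrays; trilinear resampling treats points outside the source support
as zero density; tie-breaks (alignment pose, template selection) are
deterministic; all stochastic steps (split, weight initialization,
synthetic generation) consume explicit integer seeds and restore the
caller's RNG state.  Weight-band edges are half-open intervals
(250, 300], …, (550, 600] with 250 closed into the first band, so no
real-valued weight falls between bands; boundary convention for weights
exactly on a band edge is this package's decision, as is excluding
out-of-range molecules with a warning rather than forcing them into
edge bands.

## Known limitations

* Single-conformer rigid alignment: torsional flexibility and
  protonation states are out of scope, and misassigned conformers
  propagate directly into descriptors.
* The promolecule density is a stand-in; predictions on real data
  should use imported quantum-chemical cube files.
* In-vacuo electrostatics: no dielectric or solvent screening.
* Predictions cannot leave the training activity range (sigmoid
  output); bands with narrow training spans clip aggressively.
* Model serialization is JSON/CSV plain text; descriptor matrices at
  production K (~1.2 M columns) are better regenerated than stored.
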