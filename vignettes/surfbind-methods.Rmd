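---
title: "surfbind: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{surfbind: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`surfbind` predicts nucleic-acid binding function and binding sites from
protein molecular-surface meshes. This vignette is the package's account of
the science inside it: the probabilistic model, the surface features, the
network architecture, the synthetic benchmark, and the choices we made where
the design was genuinely open. It states no empirical numbers beyond those
the test suite and the acceptance script themselves compute.

## The probabilistic binding model

A protein surface is a triangle mesh `G = {V, E}` with per-vertex features
`X_V` and per-directed-edge features `X_E`. For **segmentation** the model
is a per-vertex Bernoulli distribution `q(y_i | G, X_V, X_E; theta)` with
`y_i = 1` on binding sites; parameters are shared across vertices and
meshes, and are fit by minimizing the cross-entropy
`-sum_G sum_i [p_i log q_i + (1 - p_i) log(1 - q_i)]` over a labelled
dataset ([cross_entropy()] implements the mean-reduced form, clamping
probabilities at `1e-7`). For **classification** the same encoder feeds a
global pooling layer and the label is per mesh. Decision labels are
`y_hat = 1` iff `q >= tau_p`; `tau_p` is chosen per model — by maximizing F1
on training predictions for segmentation models (class-imbalanced data), or
fixed at 0.5 for classification models (balanced data). Residue-level
probabilities are the max over the vertices of each residue's surface; a
residue with no surface vertices is reported as buried rather than scored.

Ground-truth site labels use a distance rule: a residue is positive iff any
of its atoms lies within 5.0 Å of any nucleic-acid atom. Annotation-database
labelling is out of scope; the distance rule is applied uniformly.

## Surface meshes

Meshes come from two routes. External meshes (e.g. from a solvent-excluded
surface generator) are imported via OFF or ASCII-PLY and re-oriented by a
winding-consistency pass plus a signed-volume test, so normals always point
outward. In-repo meshes are generated as a Gaussian-density isosurface: the
density `rho(x) = sum_i exp(-(||x - x_i||^2 - r_i^2) / sigma^2)` crosses the
default iso level 1 exactly at the van der Waals radius of an isolated
atom, and marching tetrahedra on a regular grid (default spacing 0.8 Å,
`sigma` = 1 Å) extract a closed, manifold, consistently oriented mesh. The
decomposition of each grid cell into six tetrahedra guarantees closedness;
triangle winding is fixed per-tetrahedron so the normal points from the
high-density (interior) to the low-density side. Van der Waals radii follow
an element-keyed table in the spirit of the AMBER parameter sets; any
hydrogen with a zero table radius is floored at 0.6 Å. A shrink-factor
setting of an external skin-surface mesher is treated as configuration
metadata of imported meshes, not reimplemented.

Vertices are mapped to their nearest atom (and that atom's residue), with a
2.5 Å cutoff and nearest-atom fallback — the same rule used for feature
mapping, so the two stay consistent.

## Vertex and edge features

Atom- and residue-level quantities are pushed onto vertices by
inverse-distance weighting over atoms within 2.5 Å (`w = 1/d`), falling
back to the nearest atom and copying exactly when a vertex coincides with
an atom centre. The 18 structural features:

* **PH1, PH2** — electrostatic potential and normal field. The in-repo
  model is a Debye–Hückel screened Coulomb sum,
  `phi = 332.0637 / eps_solvent * sum q_i exp(-kappa d)/d` kcal/mol/e, with
  `kappa` from the ionic strength (default 0.15 M, 298 K) and solvent
  dielectric 78.5; the interior dielectric (default 2.0) is carried as
  metadata for parity with imported Poisson–Boltzmann output, which can
  replace these columns (provenance is tracked per column). Distances are
  clamped at 0.1 Å. Partial charges come from a deliberately compact
  packaged set (a backbone dipole plus formal side-chain charges); a full
  force-field charge set can be supplied instead.
* **AF1–AF5** — Atchley factors, broadcast residue → atoms → vertices.
* **SAP** — spatial aggregation propensity: for each atom, the sum over
  side-chain atoms within 5 Å of residue hydrophobicity (Black–Mould
  normalized scale centred at glycine) times relative side-chain exposure
  (Shrake–Rupley SASA over reference maximum accessibilities). The
  neighbourhood radius is configurable; 5 Å is the canonical choice.
* **HBA, HBD** — indicator features from a packaged table of hydrogen-bond
  acceptor and donor heavy atoms (backbone N donates except proline;
  backbone O accepts; side-chain lists per residue).
* **CV1–CV3** — circular variance `1 - ||sum u_i||/N` of unit vectors from
  the vertex to atoms within 7.5, 15 and 30 Å. Atoms, not mesh vertices,
  are the occupying points — the feature measures how much of the
  surrounding ball the molecular volume fills; it is 0 when no atom is in
  range.
* **MC** — mean curvature from the cotangent-Laplacian mean-curvature
  normal with barycentric vertex areas, signed by the outward normal
  (convex positive). Boundary vertices of open meshes are flagged and
  excluded.
* **HK1–HK4** — heat kernel signatures
  `sum_k exp(-lambda_k t) phi_k(v)^2` from the lowest 64 eigenpairs of the
  Laplace–Beltrami operator (cotangent stiffness halved, lumped barycentric
  mass; a dense symmetric eigensolve, adequate for meshes up to a few
  thousand vertices). The four diffusion times are log-spaced so that the
  diffusion distance `sqrt(4t)` spans roughly 3–20 Å, matching the
  multi-scale design of the other geometric features; HKS columns are
  min-max normalized per mesh.

MSA features (PSSM1–20, HMM1–30) are parsed, never computed: PSI-BLAST
ASCII PSSM log-odds are squashed to (0, 1) by the logistic function (the
exact published transform is unstated; the logistic is our choice and is
recorded as such), and HHblits `.hhm` integer codes decode as
`2^(-x/1000)` with `*` as probability 0 (Neff fields divide by 1000).
Length mismatches against the chain raise alignment errors with offsets.

Edge features are the edge length and three angles (edge–normal at both
endpoints, normal–normal), in degrees, for both directions of every mesh
edge. All vertex and edge features are exactly invariant under rigid
motions, which is what makes the networks isometry-invariant end to end.

## Network architecture

Defaults mirror the reference design: depth 3, radii 5.0/7.5/10.0 Å,
FPS ratio 0.5, unpooling k = 3, hidden width 32 (configurable; the test
suite uses width 16 for speed). Each level selects centroids by farthest
point sampling, builds a directed radial graph from all current vertices to
the centroids, and applies a crystal-graph convolution twice — first fine →
coarse, then between centroids. The convolution computes, per edge,
`z = [x_i, x_j, e_ij]`, a sigmoid gate and a softplus filter from two
learned affine maps, message `m = gate * filter`, and aggregates incoming
messages per centroid as a learned linear combination of min, max, mean and
population-stdev pooling added residually to the centroid's activation.
Centroids with no neighbours pass through unchanged (zeros would otherwise
leak into the statistics on sparse coarse levels). Input features are
standardized with training-set statistics stored in the checkpoint, then
lifted linearly to the hidden width.

Two details depart from a literal reading and are deliberate:

* **FPS start and tie-breaks.** The networks must be invariant both to
  rigid motions and to vertex reordering. A seeded random *index* start
  breaks permutation invariance; a lexicographic-coordinate start breaks
  rotation invariance. We therefore rank vertices by distance from the
  point-set centroid — a quantity invariant to both — let the seed select a
  rank, and break greedy ties by the same rank. With generic coordinates
  this coincides with lowest-index tie-breaking after canonical ordering.
* **Attention-pool scaling.** Global attention pooling is exactly
  `r = sum_i sigma(f(x_i)) x_i` (and is exported as such), but the network
  inserts a fixed 1/n rescaling between the pool and the MLP head. The
  rescaling is absorbable into the head weights, so the function class is
  unchanged; without it the head input scales with the number of coarse
  vertices and saturates the softmax at initialization, which reliably
  stalls training.

The segmentation decoder unpools coarse features by inverse-distance
weighted k-NN interpolation (exact copy at coincident points), concatenates
the skip connection from the matching encoder level, and mixes through a
linear + softplus layer; the final concatenation feeds a two-layer MLP
acting as a 1×1 convolution, then softmax. The classification head applies
the attention pool at the coarsest level and a two-layer MLP.

All gradients are hand-derived and verified against central finite
differences in the test suite (the min/max pooling subgradient distributes
evenly among ties; the stdev gradient is defined as 0 at zero variance).
Training uses Adam (defaults lr 0.01 segmentation / 0.002 classification in
the reference experiments, batch of one mesh, seeded shuffling) with early
stopping on validation loss, patience 10 by default. Cross-validated
ensembles use stratified folds, keep the best-by-validation-loss replicate
per fold, Platt-scale each kept model on its validation fold, and predict
with the mean calibrated probability (majority vote for calls; the mean
probability is reported alongside).

Platt scaling fits `sigmoid(a s + b)` with the smoothed targets
`(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` by L-BFGS-B with `a > 0` enforced, so
calibration is always order-preserving.

## Attribution

**Grouped permutation importance** permutes a named group of feature
columns along the vertex dimension — one shared permutation per mesh per
round, preserving within-group covariation — and reports the change in
AUROC (negative = important), averaged over rounds. **Grad-CAM** takes the
gradient of a target-class output with respect to the activations of a
chosen encoder level (default: the final, coarsest convolution), pools it
along the feature dimension (the plain pooled gradient by default, with a
switch for the classic gradient-times-activation weighting), rectifies,
interpolates back to full resolution through the stored k-NN unpooling
maps, and min-max normalizes to [0, 1]; the high-attribution mask keeps the
top quartile by default. Two implementation notes: the backward pass starts
from the logit difference, which equals the probability gradient up to the
positive factor `p(1-p)` — identical after normalization but finite when
the predicted probability saturates; and rectification before
normalization is our assumption (the convention is unstated in the source
description).

## The planted-signal benchmark

Real training data (co-crystal-derived meshes with distance-rule labels)
requires large structure downloads, so the package ships a generator whose
defaults define its reference study conditions: 642-vertex near-spheres of
radius 15 Å (vertex spacing ≈ 2 Å, comparable to a real surface mesh of a
small domain), each deformed by a smooth radial bump field of relative SD
1.5% — real surfaces are never perfect spheres, and the bumps also remove
the exact symmetries under which farthest point sampling has no
isometry-invariant tie-break; a geodesic cap covering 20% of the surface as
the planted "binding site"; six feature columns in three groups of two, built as
standard-normal fields smoothed by two rounds of one-ring averaging
(restandardized to unit SD) plus iid noise of SD 0.25; a per-mesh baseline
offset of SD 0.25 on every column; and a +2 SD shift of the two
signal-carrying columns inside the patch. Segmentation datasets plant a
patch in every mesh (vertex labels = membership, ≈ 20% positive);
classification datasets plant patches in exactly half the meshes (labels =
presence). Reference experiments use 40 training and 10 test meshes; the
zero-effect null is scored on 40 held-out meshes because the pooled vertex
AUROC of a 10-mesh null has chance variability comparable to the width of
the interval being checked.

Two generator choices deserve their rationale. The smoothing mimics the
spatially correlated feature fields real surfaces exhibit, which is what
convolutions exploit. The baseline offset mimics between-protein variation
of feature levels, and it is what makes the attribution experiments
meaningful: without it, the mesh mean of a shifted column separates the
classes perfectly and survives vertex permutation, so permutation
importance is identically zero regardless of what the model learned; with
a large offset (SD ≈ 1) the 40-mesh classification task becomes unstable to
train. SD 0.25 leaves the mean informative but insufficient, so models must
and do use the spatial concentration.

What passing these tests shows — and what it does not: the planted task has
exactly one informative spatial scale, clean labels, uniform topology
(genus-0 spheres of identical resolution) and features with known
distributions. Recovery there validates the machinery (features, pooling
hierarchy, gradients, calibration, attribution), not biological accuracy on
real co-crystal data, whose feature correlations, label noise and size
diversity are far richer.

## Numerical choices and degenerate inputs

Probabilities are clamped at `1e-7` in logs; stdev pooling uses the
population convention and returns 0 for single messages; empty
neighbourhoods pass the centroid through; coincident points copy exactly in
unpooling and atom→vertex mapping (thresholds 1e-8 and 1e-6 respectively);
electrostatic distances clamp at 0.1 Å; zero-area faces are skipped with a
warning; duplicate isosurface vertices are merged before use; max-F1
threshold ties resolve to the largest candidate (the conservative call);
"best model" within a fold means lowest validation loss. Checkpoints are
JSON with full-precision numbers, so a saved and reloaded model reproduces
its predictions bit-for-bit.

## Problem sizes

The shipped experiments are sized for a single CPU: 642-vertex meshes, 40
training meshes, hidden width 16, and at most 40 epochs — a few minutes per
trained model. Dense eigensolves cap practical heat-kernel meshes at a few
thousand vertices; beyond that an iterative solver would be the natural
replacement. The networks themselves scale linearly in edges and have been
run on meshes an order of magnitude larger.

## Known limitations

The Debye–Hückel potential ignores the dielectric boundary (no reaction
field), so absolute values differ from a Poisson–Boltzmann solver —
imported per-vertex potentials are first-class replacements and the
provenance column records which route produced the numbers. The packaged
charge set is minimal; protonation states are not assigned. PDB parsing
reads fixed columns of ATOM/HETATM records only (no mmCIF, no assembly
expansion beyond what the file contains). Profile parsing expects the
standard PSI-BLAST and HHblits dialects. The mesh generator is a Gaussian
surface, not a true solvent-excluded surface: deep crevices are slightly
smoothed relative to a rolling-probe surface, which is why imported meshes
remain supported everywhere.
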