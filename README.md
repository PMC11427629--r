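# surfbind

Prediction of nucleic-acid (NA) binding from protein molecular-surface
meshes. `surfbind` answers two questions about a protein structure:

* **Binding function** — does this protein bind DNA or RNA at all?
  (whole-mesh classification)
* **Binding site** — which surface patches, and hence which residues, form
  the binding interface? (per-vertex segmentation, max-pooled to residues)

Both predictions are made by graph neural networks operating directly on a
triangulated solvent-excluded-surface mesh, using only features that are
invariant under rotation and translation, so the predictions are too.

## The model

A protein surface is a graph `G = {V, E}` of mesh vertices and triangle
edges. Each vertex carries 18 structural features — electrostatic potential
and normal field (PH1, PH2), Atchley factors (AF1–AF5), spatial aggregation
propensity (SAP), hydrogen-bond acceptor/donor proximity (HBA, HBD),
circular variance at 7.5/15/30 Å (CV1–CV3), mean curvature (MC) and heat
kernel signatures (HK1–HK4) — plus, for binding-site models, 50 sequence
profile features parsed from PSI-BLAST PSSMs and HHblits profile HMMs. Each
directed edge carries four rotation-invariant features: length, the two
edge–normal angles and the normal–normal angle.

The network is a graph U-Net. The encoder repeats, three times: farthest
point sampling (ratio α = 0.5) → a radial graph joining every vertex to
centroids within r = 5.0, 7.5, 10.0 Å → two crystal-graph convolutions
(gated edge-conditioned messages aggregated by a learned combination of
min/max/mean/stdev pooling, with a residual update). For segmentation, a
decoder restores full resolution by k = 3 nearest-neighbour unpooling with
concatenated skip connections and a two-layer MLP produces per-vertex
Bernoulli probabilities; for classification, global attention pooling
`r = Σ_i σ(f(x_i)) x_i` feeds an MLP head. Training minimizes cross-entropy
with Adam and early stopping; ensembles use stratified cross-validation
with per-model Platt calibration and max-F1 (segmentation) or 0.5
(classification) decision thresholds. Model interpretation is provided by
grouped feature-permutation importance and Grad-CAM spatial attribution
over the mesh.

The forward and backward passes, optimizer and all layers are implemented
in plain R matrix code; mesh isosurfacing is a small C++ routine.

## Worked example

```r
library(surfbind)

# a deterministic toy helical protein and its Gaussian-density surface mesh
st   <- make_toy_structure(8, seed = 2)
mesh <- generate_surface(st, grid_spacing = 0.8)
mesh
#> SurfaceMesh: 3188 vertices, 6372 faces, normals present

X <- compute_feature_table(st, mesh)
dim(X)
#> [1] 3188   18

# label binding residues from (here: synthetic) nucleic-acid coordinates
na  <- fake_na_atoms(st, residue = 3, offset = 4.0)
lab <- label_binding(st, na, cutoff = 5.0, mesh = mesh)
which(lab$residue == 1)
#> [1] 3
```

Training and attribution on the planted-signal benchmark (40 training
meshes, 642 vertices each, two of six features shifted +2 SD inside a
planted surface patch):

```r
tr <- make_planted_dataset(planted_spec(n_meshes = 40, seed = 101), "segmentation")
te <- make_planted_dataset(planted_spec(n_meshes = 10, seed = 102), "segmentation")
cfg <- layer_config(width = 16)
model <- train(tr, cfg, "segmentation", lr = 0.01, epochs = 15, patience = 5, seed = 1)
probs <- segmentation_forward(te[[1]]$mesh, te[[1]]$X, model)[, 2]
metrics(probs, te[[1]]$y)$AUROC
#> [1] 0.9996636
```

The vertex AUROC of 0.9997 says the trained network almost perfectly
separates patch vertices from background on an unseen mesh; the acceptance
suite checks the same quantity pooled over all ten held-out meshes against
its 0.95 bar.

A thin command-line tool is installed as `exec/surfbind` with subcommands
`mesh`, `featurize`, `predict`, `attribute` and `fixtures`; run it without
arguments for usage.

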