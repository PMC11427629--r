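# Shared fixtures and helpers for the test suite. Everything is generated in
# code; nothing is read from disk.

# a minimal three-atom PDB (one alanine residue); columns follow the fixed
# PDB layout
tiny_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C")
}

# seeded random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# single-atom AtomicStructure at the origin
point_structure <- function(radius = 1.5, charge = 1) {
  structure(list(
    atoms = data.frame(serial = 1L, name = "C", resname = "ALA", chain = "A",
                       resno = 1L, x = 0, y = 0, z = 0, element = "C",
                       radius = radius, charge = charge,
                       stringsAsFactors = FALSE),
    chains = "A", residue = 1L), class = "AtomicStructure")
}

# small layer config used for fast network tests (coarse meshes)
test_config <- function(width = 8) {
  layer_config(width = width, head_hidden = 8, radii = c(6, 9, 12))
}

# tiny planted item on a 162-vertex sphere
tiny_planted <- function(n = 2, seed = 1, task = "segmentation", effect = 2) {
  make_planted_dataset(
    planted_spec(n_meshes = n, subdivisions = 2, radius = 15,
                 patch_radius = 12, effect_size = effect, seed = seed),
    task)
}
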