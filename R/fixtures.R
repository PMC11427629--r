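# Synthetic-data generators with analytic ground truth, plus brute-force
# oracles used by the test suite. The planted-patch generator emulates the
# statistical structure of surface-labelled training data: smooth correlated
# vertex features, imbalanced patch labels, and a designated feature group
# carrying the signal.

# ---- canonical meshes ------------------------------------------------------

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(1 + t^2)
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(V = V, F = F)
}

.subdivide <- function(V, F) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mids <- new.env()
  newV <- V
  getmid <- function(a, b) {
    k <- key(a, b)
    id <- mids[[k]]
    if (is.null(id)) {
      newV <<- rbind(newV, (V[a, ] + V[b, ]) / 2)
      id <- nrow(newV)
      mids[[k]] <- id
    }
    id
  }
  newF <- matrix(0L, 0, 3)
  for (f in seq_len(nrow(F))) {
    a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
  }
  list(V = newV, F = newF)
}

.icosphere <- function(subdiv, radius = 1) {
  m <- .icosahedron()
  for (i in seq_len(subdiv)) m <- .subdivide(m$V, m$F)
  V <- m$V / sqrt(rowSums(m$V^2)) * radius
  list(V = V, F = m$F)
}

#' Canonical meshes with analytic ground truth
#'
#' * `sphere`: icosphere; analytic normals `v/||v||`, mean curvature `1/R`.
#' * `plane`: uniformly triangulated square grid; mean curvature 0,
#'   normal-normal angles 0, edge-normal angles 90 degrees on interior edges.
#' * `cylinder`: open tube; interior mean curvature `1/(2R)`.
#' * `pocketed_sphere`: sphere with a smooth spherical-cap indentation of
#'   relative depth `depth`; depth 0 reproduces the sphere.
#'
#' @param shape One of `"sphere"`, `"plane"`, `"cylinder"`,
#'   `"pocketed_sphere"`.
#' @param resolution Icosphere subdivisions (sphere/pocketed_sphere, min 1),
#'   or grid divisions per side/rings (plane, cylinder).
#' @param size Sphere radius, plane side length, or cylinder radius (A).
#' @param depth Pocket depth as a fraction of the radius (pocketed_sphere).
#' @param length Cylinder length (defaults to `4 * size`).
#' @return A `SurfaceMesh` with normals and an attribute `truth` (list with
#'   analytic values where defined: `normals`, `mean_curvature`, `area`).
#' @export
make_canonical_mesh <- function(shape = c("sphere", "plane", "cylinder",
                                          "pocketed_sphere"),
                                resolution = 3, size = 1, depth = 0.3,
                                length = NULL) {
  shape <- match.arg(shape)
  if (shape %in% c("sphere", "pocketed_sphere") && resolution < 1)
    stop("resolution must be >= 1")
  if (shape == "sphere") {
    m <- .icosphere(resolution, size)
    mesh <- compute_normals(surface_mesh(m$V, m$F), fix_orientation = FALSE)
    truth <- list(normals = m$V / size, mean_curvature = 1 / size,
                  area = 4 * pi * size^2)
  } else if (shape == "pocketed_sphere") {
    m <- .icosphere(resolution, 1)
    theta <- acos(pmin(pmax(m$V[, 3], -1), 1))  # angle from +z pocket axis
    t0 <- pi / 3
    bump <- ifelse(theta < t0, (cos(pi * theta / t0) + 1) / 2, 0)
    r <- size * (1 - depth * bump)
    mesh <- compute_normals(surface_mesh(m$V * r, m$F),
                            fix_orientation = FALSE)
    truth <- list(pocket_axis = c(0, 0, 1), depth = depth)
  } else if (shape == "plane") {
    n <- resolution
    g <- seq(0, size, length.out = n + 1)
    V <- cbind(rep(g, n + 1), rep(g, each = n + 1), 0)
    idx <- function(i, j) (j - 1) * (n + 1) + i
    F <- matrix(0L, 0, 3)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      F <- rbind(F, c(a, b, c), c(a, c, d))
    }
    mesh <- surface_mesh(V, F)
    mesh$normals <- matrix(rep(c(0, 0, 1), each = nrow(V)), ncol = 3)
    truth <- list(mean_curvature = 0, normal = c(0, 0, 1))
  } else {  # cylinder
    nu <- max(3 * resolution, 12)
    len <- if (is.null(length)) 4 * size else length
    nv <- max(resolution, 8)
    ang <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
    zs <- seq(-len / 2, len / 2, length.out = nv + 1)
    V <- do.call(rbind, lapply(zs, function(z)
      cbind(size * cos(ang), size * sin(ang), z)))
    idx <- function(i, j) (j - 1) * nu + ((i - 1) %% nu) + 1
    F <- matrix(0L, 0, 3)
    for (j in seq_len(nv)) for (i in seq_len(nu)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      F <- rbind(F, c(a, b, c), c(a, c, d))
    }
    mesh <- surface_mesh(V, F)
    mesh$normals <- cbind(V[, 1], V[, 2], 0) / size
    truth <- list(mean_curvature = 1 / (2 * size), axis = c(0, 0, 1))
  }
  attr(mesh, "truth") <- truth
  mesh
}

# ---- toy structures --------------------------------------------------------

#' Generate a toy helical protein structure
#'
#' Alpha-helix-like backbone (N, CA, C, O per residue plus a CB pseudo
#' side-chain atom for non-glycine residues) with seeded random residue
#' identities and small coordinate jitter. Round-trips losslessly through
#' [write_pdb()] / [load_structure()].
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed.
#' @param jitter Coordinate noise SD in A (default 0.05).
#' @return An `AtomicStructure`.
#' @export
make_toy_structure <- function(n_residues, seed = 0L, jitter = 0.05) {
  stopifnot(n_residues >= 1)
  set.seed(as.integer(seed))
  resnames <- sample(.standard_residues, n_residues, replace = TRUE)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    phi <- (i - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * (i - 1))
    out_dir <- c(cos(phi), sin(phi), 0)
    pos <- list(N = ca + c(-0.8, 0.6, -0.7), CA = ca,
                C = ca + c(0.9, 0.4, 0.6), O = ca + c(1.2, 1.0, 1.3),
                CB = ca + 1.5 * out_dir)
    atomset <- c("N", "CA", "C", "O", if (resnames[i] != "GLY") "CB")
    for (an in atomset) {
      serial <- serial + 1L
      p <- pos[[an]] + rnorm(3, sd = jitter)
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = an, resname = resnames[i], chain = "A",
        resno = i, x = p[1], y = p[2], z = p[3],
        element = substr(an, 1, 1), stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  rt <- default_radius_table()
  atoms$radius <- unname(rt[atoms$element])
  atoms$radius[is.na(atoms$radius) | atoms$radius == 0] <- 0.6
  atoms$charge <- partial_charges(atoms$resname, atoms$name)
  rk <- paste(atoms$chain, atoms$resno, atoms$resname, sep = "|")
  structure(list(atoms = atoms, chains = "A",
                 residue = match(rk, unique(rk))),
            class = "AtomicStructure")
}

#' Place fake nucleic-acid atoms near a residue
#'
#' Puts `n_atoms` points at the given distance from the residue's CA atom,
#' along the outward direction from the structure centroid, for exercising
#' [label_binding()].
#'
#' @param structure An `AtomicStructure`.
#' @param residue Residue index to target.
#' @param offset Distance from the residue CA in A.
#' @param n_atoms Number of points (default 1).
#' @return Matrix (n_atoms x 3) of coordinates.
#' @export
fake_na_atoms <- function(structure, residue, offset, n_atoms = 1) {
  a <- structure$atoms
  sel <- which(structure$residue == residue & a$name == "CA")
  if (!length(sel)) sel <- which(structure$residue == residue)[1]
  ca <- c(a$x[sel[1]], a$y[sel[1]], a$z[sel[1]])
  ctr <- colMeans(atom_xyz(structure))
  u <- ca - ctr
  u[3] <- 0
  nu <- sqrt(sum(u^2))
  u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
  t(vapply(seq_len(n_atoms), function(j) ca + (offset + 0.0 * j) * u,
           numeric(3)))
}

# ---- planted datasets ------------------------------------------------------

#' Specification of a planted surface-patch dataset
#'
#' Defaults define the package's reference study conditions: 642-vertex
#' icospheres of radius 15 A, a patch covering 20% of the surface, two of
#' six smooth unit-SD feature columns shifted by `effect_size` inside the
#' patch, and balanced classes for classification.
#'
#' @param n_meshes Number of meshes.
#' @param subdivisions Icosphere subdivisions (3 -> 642 vertices).
#' @param radius Sphere radius in A.
#' @param patch_radius Geodesic patch radius in A; the spherical-cap area
#'   fraction must stay below one half.
#' @param feature_names All feature column names.
#' @param affected Names of the signal-carrying columns.
#' @param effect_size Mean shift inside the patch, in SD units (>= 0).
#' @param noise_sd SD of iid noise added to the smooth field.
#' @param offset_sd SD of the per-mesh baseline offset applied to every
#'   column (emulates between-protein variation of feature levels).
#' @param bump_sd Relative SD of the smooth radial bump field applied to
#'   each mesh (real surfaces are never perfect spheres; the bumps also
#'   make the geometry generic, with no exact symmetries).
#' @param class_balance Fraction of patch-bearing meshes (classification).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List of class `PlantedDatasetSpec`.
#' @export
planted_spec <- function(n_meshes = 50, subdivisions = 3, radius = 15,
                         patch_radius = 0.927 * 15,
                         feature_names = paste0("S", 1:6),
                         affected = c("S1", "S2"),
                         effect_size = 2, noise_sd = 0.25, offset_sd = 0.25,
                         bump_sd = 0.015, class_balance = 0.5, seed = 0L) {
  stopifnot(effect_size >= 0, all(affected %in% feature_names))
  frac <- (1 - cos(patch_radius / radius)) / 2
  if (frac <= 0 || frac >= 0.5) stop("patch larger than a hemisphere")
  structure(list(n_meshes = n_meshes, subdivisions = subdivisions,
                 radius = radius, patch_radius = patch_radius,
                 feature_names = feature_names, affected = affected,
                 effect_size = effect_size, noise_sd = noise_sd,
                 offset_sd = offset_sd, bump_sd = bump_sd,
                 class_balance = class_balance, seed = as.integer(seed),
                 patch_fraction = frac),
            class = "PlantedDatasetSpec")
}

# one-ring adjacency list of a mesh
.ring_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$V)
  split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
}

#' Generate a planted surface-patch dataset
#'
#' Each mesh is an icosphere; base features are standard-normal fields
#' smoothed by two rounds of one-ring averaging (mimicking the smooth
#' surface-feature fields of real proteins), restandardized to unit SD, plus
#' iid noise. Inside a randomly centred geodesic patch, the affected columns
#' are shifted by the effect size. Labels are patch membership
#' (segmentation) or patch presence (classification; patch-free meshes carry
#' no shift).
#'
#' @param spec A [planted_spec()].
#' @param task `"segmentation"` (every mesh has a patch, per-vertex labels)
#'   or `"classification"` (per-mesh labels, patch presence drawn with the
#'   class balance).
#' @return List of dataset items (`mesh`, `X`, `y`, `patch`, `center`), with
#'   attribute `positive_fraction`.
#' @export
make_planted_dataset <- function(spec,
                                 task = c("segmentation", "classification")) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "PlantedDatasetSpec"))
  set.seed(spec$seed)
  base <- .icosphere(spec$subdivisions, spec$radius)
  mesh0 <- compute_normals(surface_mesh(base$V, base$F),
                           fix_orientation = FALSE)
  nb <- .ring_neighbors(mesh0)
  n <- nrow(mesh0$V)
  smooth1 <- function(v) {
    vapply(seq_len(n), function(i) mean(c(v[i], v[nb[[i]]])), numeric(1))
  }
  # stratified class assignment: exact class counts, seeded order
  npos <- round(spec$class_balance * spec$n_meshes)
  patch_flags <- sample(rep(c(TRUE, FALSE),
                            c(npos, spec$n_meshes - npos)))
  dirs <- mesh0$V / spec$radius  # unit directions of the base sphere
  items <- vector("list", spec$n_meshes)
  for (m in seq_len(spec$n_meshes)) {
    has_patch <- if (task == "segmentation") TRUE else patch_flags[m]
    # smooth radial bumps: each mesh is a generic near-sphere
    eps <- smooth1(smooth1(rnorm(n)))
    eps <- (eps - mean(eps)) / stats::sd(eps)
    rad <- spec$radius * (1 + spec$bump_sd * eps)
    mesh_m <- compute_normals(surface_mesh(dirs * rad, mesh0$F),
                              fix_orientation = FALSE)
    center <- sample(n, 1)
    ang <- acos(pmin(pmax(as.numeric(dirs %*% dirs[center, ]), -1), 1))
    patch <- (ang * spec$radius) <= spec$patch_radius
    X <- sapply(spec$feature_names, function(fn) {
      z <- rnorm(n)
      z <- smooth1(smooth1(z))
      z <- (z - mean(z)) / stats::sd(z)
      z <- z + rnorm(n, sd = spec$noise_sd)
      z <- z / stats::sd(z)
      # per-mesh baseline offset: feature levels vary between meshes (as
      # they do between proteins), so the mesh mean alone is a poor class
      # signal and models must use the spatial concentration
      z <- z + rnorm(1, sd = spec$offset_sd)
      if (has_patch && fn %in% spec$affected) z[patch] <- z[patch] + spec$effect_size
      z
    })
    colnames(X) <- spec$feature_names
    y <- if (task == "segmentation") as.integer(patch) else
      as.integer(has_patch)
    items[[m]] <- list(mesh = mesh_m, X = X, y = y,
                       patch = patch & has_patch, center = center)
  }
  pf <- if (task == "segmentation") {
    mean(unlist(lapply(items, function(it) it$y)))
  } else mean(vapply(items, function(it) it$y, numeric(1)))
  attr(items, "positive_fraction") <- pf
  items
}

# ---- brute-force oracles (test references) --------------------------------

#' Monte-Carlo circular-variance oracle
#'
#' Estimates the continuum circular variance at a reference vertex from
#' uniform samples of an occupying region: the full unit ball (vertex at the
#' centre) or the half ball `z < 0` (vertex at the boundary-plane centre).
#'
#' @param shape `"ball"` or `"half_ball"`.
#' @param n_samples Number of uniform samples.
#' @param seed Integer seed.
#' @return Estimated circular variance.
#' @export
cv_montecarlo <- function(shape = c("ball", "half_ball"), n_samples = 1e5,
                          seed = 0L) {
  shape <- match.arg(shape)
  set.seed(as.integer(seed))
  m <- 0L
  acc <- c(0, 0, 0)
  while (m < n_samples) {
    p <- matrix(runif(3 * 2 * (n_samples - m), -1, 1), ncol = 3)
    keep <- rowSums(p^2) <= 1
    if (shape == "half_ball") keep <- keep & p[, 3] < 0
    p <- p[keep, , drop = FALSE]
    if (nrow(p) == 0) next
    take <- min(nrow(p), n_samples - m)
    p <- p[seq_len(take), , drop = FALSE]
    u <- p / sqrt(rowSums(p^2))
    acc <- acc + colSums(u)
    m <- m + take
  }
  1 - sqrt(sum(acc^2)) / n_samples
}

#' Exhaustive farthest-point-sampling oracle
#'
#' Direct greedy definition on the full distance matrix with lowest-index
#' tie-breaking; no shared code with [farthest_point_sample()].
#'
#' @param V Coordinate matrix.
#' @param ratio Sampling ratio.
#' @param start Start index (1-based).
#' @return Integer indices in selection order.
#' @export
fps_exhaustive <- function(V, ratio, start = 1L) {
  V <- as.matrix(V)
  n <- nrow(V)
  D <- as.matrix(stats::dist(V))
  m <- ceiling(ratio * n)
  sel <- start
  while (length(sel) < m) {
    mind <- apply(D[, sel, drop = FALSE], 1, min)
    best <- max(mind)
    if (best <= 0) break
    sel <- c(sel, which(mind == best)[1])  # which() returns lowest index
  }
  as.integer(sel)
}

#' Brute-force radial-graph oracle
#'
#' Double-loop edge enumeration used as the reference for
#' [build_radial_graph()].
#'
#' @param V Coordinate matrix.
#' @param centroids Centroid vertex indices.
#' @param radius Neighbourhood radius.
#' @return data.frame with columns `from` and `to_vertex`, ordered.
#' @export
radial_graph_bruteforce <- function(V, centroids, radius) {
  V <- as.matrix(V)
  from <- integer(0); to <- integer(0)
  for (ci in centroids) {
    for (j in seq_len(nrow(V))) {
      if (j == ci) next
      if (sqrt(sum((V[j, ] - V[ci, ])^2)) <= radius + 1e-12) {
        from <- c(from, j); to <- c(to, ci)
      }
    }
  }
  out <- data.frame(from = from, to_vertex = to)
  out[order(out$to_vertex, out$from), ]
}

#' Write a fixture set to a directory
#'
#' Emits a toy PDB, a canonical sphere OFF mesh and a planted feature TSV,
#' for the command-line `fixtures` subcommand and for external tooling.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(dir, seed = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_toy_structure(8, seed = seed)
  p1 <- file.path(dir, "toy_protein.pdb")
  write_pdb(st, p1)
  mesh <- make_canonical_mesh("sphere", resolution = 2, size = 10)
  p2 <- file.path(dir, "sphere.off")
  write_mesh(mesh, p2)
  ds <- make_planted_dataset(planted_spec(n_meshes = 1, seed = seed))
  p3 <- file.path(dir, "planted_features.tsv")
  write_feature_table(ds[[1]]$X, p3)
  invisible(c(p1, p2, p3))
}
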