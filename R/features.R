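# Structural vertex features: atom -> vertex mapping, chemical features,
# circular variance, mean curvature, heat kernel signatures, electrostatics,
# and assembly into the named FeatureTable.

#' Map per-atom values onto mesh vertices
#'
#' Inverse-distance weighted average over atoms within `cutoff` of each
#' vertex: `sum(f_a / d_a) / sum(1 / d_a)`. Vertices with no atom in range
#' take the nearest atom's value; a vertex coincident with an atom centre
#' (d < 1e-6 A) copies that atom's value exactly.
#'
#' @param structure An `AtomicStructure`.
#' @param mesh A `SurfaceMesh`.
#' @param values Numeric vector or matrix of per-atom values (rows = atoms).
#' @param cutoff Distance cutoff in A (default 2.5).
#' @return Per-vertex vector or matrix of mapped values.
#' @export
map_atom_to_vertices <- function(structure, mesh, values, cutoff = 2.5) {
  vals <- as.matrix(values)
  if (any(!is.finite(vals))) stop("per-atom values must be finite")
  A <- atom_xyz(structure)
  P <- mesh$V
  n <- nrow(P)
  out <- matrix(0, n, ncol(vals))
  bs <- max(1L, floor(2e6 / nrow(A)))
  for (s in seq(1L, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    D2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(A^2), "+") -
      2 * P[s:e, , drop = FALSE] %*% t(A)
    D <- sqrt(pmax(D2, 0))
    W <- ifelse(D <= cutoff, 1 / pmax(D, 1e-12), 0)
    coin <- D < 1e-6
    nearest <- max.col(-D, ties.method = "first")
    for (ii in seq_len(e - s + 1L)) {
      if (any(coin[ii, ])) {
        out[s + ii - 1L, ] <- vals[which(coin[ii, ])[1], ]
      } else if (sum(W[ii, ]) > 0) {
        out[s + ii - 1L, ] <- (W[ii, ] %*% vals) / sum(W[ii, ])
      } else {
        out[s + ii - 1L, ] <- vals[nearest[ii], ]
      }
    }
  }
  if (is.null(dim(values))) drop(out) else out
}

#' Chemical per-atom features
#'
#' Atchley factors AF1-AF5 (residue-level, broadcast to atoms), hydrogen-bond
#' acceptor/donor indicators HBA/HBD from the packaged atom lookup, and
#' spatial aggregation propensity SAP. SAP of an atom sums, over side-chain
#' atoms within `sap_radius`, the product of residue hydrophobicity
#' (Gly-centred Black-Mould scale) and relative side-chain exposure.
#' Non-standard residues contribute zeros with a warning.
#'
#' @param structure An `AtomicStructure`.
#' @param sap_radius SAP neighbourhood radius in A (default 5).
#' @param sasa Optional precomputed per-atom SASA (A^2).
#' @return Matrix (atoms x 8) with columns AF1..AF5, SAP, HBA, HBD.
#' @export
chemical_features <- function(structure, sap_radius = 5, sasa = NULL) {
  a <- structure$atoms
  std <- a$resname %in% .standard_residues
  if (!all(std)) {
    warning("non-standard residue(s) ",
            paste(unique(a$resname[!std]), collapse = ", "),
            ": chemical features set to 0")
  }
  af <- matrix(0, nrow(a), 5, dimnames = list(NULL, paste0("AF", 1:5)))
  af[std, ] <- .atchley[a$resname[std], , drop = FALSE]

  acc_tab <- hbond_table("acceptor"); don_tab <- hbond_table("donor")
  hba <- as.numeric(a$name %in% acc_tab[["*"]])
  hbd <- as.numeric(a$name %in% don_tab[["*"]] & a$resname != "PRO")
  for (i in which(std)) {
    rn <- a$resname[i]
    if (a$name[i] %in% acc_tab[[rn]]) hba[i] <- 1
    if (a$name[i] %in% don_tab[[rn]]) hbd[i] <- 1
  }

  # SAP: hydrophobic exposure summed over nearby side-chain atoms
  if (is.null(sasa)) sasa <- atom_sasa(structure)
  expo <- residue_exposure(structure, sasa)
  expo[is.na(expo)] <- 0
  hyd <- hydrophobicity_table()[a$resname]
  hyd[is.na(hyd)] <- 0
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA")
  side <- which(!(a$name %in% backbone) & std)
  xyz <- atom_xyz(structure)
  sap <- numeric(nrow(a))
  if (length(side)) {
    contrib <- hyd[side] * expo[structure$residue[side]]
    S <- xyz[side, , drop = FALSE]
    bs <- max(1L, floor(2e6 / length(side)))
    for (s in seq(1L, nrow(a), by = bs)) {
      e <- min(nrow(a), s + bs - 1L)
      D2 <- outer(rowSums(xyz[s:e, , drop = FALSE]^2), rowSums(S^2), "+") -
        2 * xyz[s:e, , drop = FALSE] %*% t(S)
      sap[s:e] <- as.numeric((D2 <= sap_radius^2) %*% contrib)
    }
  }
  cbind(af, SAP = sap, HBA = hba, HBD = hbd)
}

#' Circular variance of mesh vertices
#'
#' `CV(v) = 1 - ||sum(u_i)|| / N` over unit vectors from the vertex to the
#' occupying points (atom centres) within `radius`. Near 0 for protruding
#' points, near 1 for points buried in pockets; defined as 0 when no point is
#' in range.
#'
#' @param mesh A `SurfaceMesh`.
#' @param structure An `AtomicStructure`, or directly an N x 3 matrix of
#'   occupying points.
#' @param radius Neighbourhood radius in A.
#' @return Numeric vector of per-vertex CV values in `[0, 1]`.
#' @export
circular_variance <- function(mesh, structure, radius) {
  stopifnot(radius > 0)
  A <- if (inherits(structure, "AtomicStructure")) atom_xyz(structure)
       else as.matrix(structure)
  P <- mesh$V
  n <- nrow(P)
  out <- numeric(n)
  bs <- max(1L, floor(2e6 / nrow(A)))
  for (s in seq(1L, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    for (ii in s:e) {
      d <- sweep(A, 2, P[ii, ])
      dd <- sqrt(rowSums(d^2))
      sel <- dd <= radius & dd > 1e-9
      N <- sum(sel)
      if (N == 0) { out[ii] <- 0; next }
      u <- d[sel, , drop = FALSE] / dd[sel]
      out[ii] <- 1 - sqrt(sum(colSums(u)^2)) / N
    }
  }
  pmin(pmax(out, 0), 1)
}

# cotangent stiffness matrix (dense, N x N) and barycentric vertex areas
.cotan_laplacian <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  n <- nrow(V)
  W <- matrix(0, n, n)
  area <- numeric(n)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  fa <- sqrt(rowSums(face_normals_raw(V, F)^2))
  for (c3 in corners) {
    k <- F[, c3[1]]; i <- F[, c3[2]]; j <- F[, c3[3]]
    u <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
    w <- V[j, , drop = FALSE] - V[k, , drop = FALSE]
    cosk <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    sink <- sqrt(rowSums(cr^2))
    cot <- cosk / pmax(sink, 1e-12)
    ij <- cbind(i, j)
    W[ij] <- W[ij] + cot
    W[ij[, c(2, 1)]] <- W[ij[, c(2, 1)]] + cot
  }
  acc <- rowsum(rep(fa / 3, 3), c(F[, 1], F[, 2], F[, 3]))
  area[as.integer(rownames(acc))] <- acc
  L <- diag(rowSums(W)) - W
  list(L = L, area = area)
}

# boundary vertices of an open mesh (edges bordering exactly one face)
.boundary_vertices <- function(mesh) {
  cnt <- edge_face_counts(mesh)
  open_edges <- names(cnt)[cnt == 1L]
  if (!length(open_edges)) return(integer(0))
  unique(as.integer(unlist(strsplit(open_edges, " "))))
}

#' Discrete mean curvature
#'
#' Cotangent-Laplacian mean-curvature normal, signed by the outward vertex
#' normal: positive on convex surfaces, negative in concave pockets. Boundary
#' vertices of open meshes are flagged through the `"boundary"` attribute and
#' assigned 0.
#'
#' @param mesh A `SurfaceMesh` with normals.
#' @return Numeric vector of per-vertex mean curvature (1/A), with attribute
#'   `boundary` (integer vertex indices).
#' @export
mean_curvature <- function(mesh) {
  if (is.null(mesh$normals)) mesh <- compute_normals(mesh, fix_orientation = FALSE)
  cl <- .cotan_laplacian(mesh)
  Hvec <- (cl$L %*% mesh$V) / (2 * pmax(cl$area, 1e-12))
  H <- sqrt(rowSums(Hvec^2)) / 2
  s <- sign(rowSums(Hvec * mesh$normals))
  s[s == 0] <- 1
  out <- H * s
  bnd <- .boundary_vertices(mesh)
  out[bnd] <- 0
  attr(out, "boundary") <- bnd
  out
}

#' Heat kernel signatures
#'
#' `HKS(v, t) = sum_k exp(-lambda_k t) phi_k(v)^2` from the smallest
#' `n_eigen` eigenpairs of the Laplace-Beltrami operator (cotangent stiffness
#' with lumped barycentric mass). The four default diffusion times are
#' log-spaced so the diffusion distance `sqrt(4t)` spans roughly 3-20 A.
#'
#' @param mesh A `SurfaceMesh`.
#' @param n_eigen Number of eigenpairs (default 64, minimum 32).
#' @param scales Diffusion times; default 4 log-spaced values covering
#'   3-20 A diffusion distances.
#' @param normalize Min-max normalize each scale per mesh (default TRUE).
#' @return Matrix (vertices x scales); columns HK1..HK4 for the default
#'   scales. Attribute `"eigenvalues"` carries the eigenvalues used.
#' @export
heat_kernel_signature <- function(mesh, n_eigen = 64, scales = NULL,
                                  normalize = TRUE) {
  if (n_eigen < 32) stop("n_eigen must be at least 32")
  if (is.null(scales)) scales <- exp(seq(log(3^2 / 4), log(20^2 / 4), length.out = 4))
  cl <- .cotan_laplacian(mesh)
  m <- pmax(cl$area, 1e-12)
  # .cotan_laplacian returns the full (cot a + cot b) weights; the FEM
  # stiffness of the Laplace-Beltrami operator is half that
  S <- (cl$L / 2) / sqrt(outer(m, m))
  S <- (S + t(S)) / 2
  ei <- tryCatch(eigen(S, symmetric = TRUE),
                 error = function(e) stop("eigen-solver failure: try a higher mesh resolution"))
  n <- nrow(S)
  k <- min(n_eigen, n)
  sel <- n:(n - k + 1)  # smallest eigenvalues
  lam <- pmax(ei$values[sel], 0)
  phi <- ei$vectors[, sel, drop = FALSE] / sqrt(m)
  hks <- sapply(scales, function(t) as.numeric(phi^2 %*% exp(-lam * t)))
  colnames(hks) <- paste0("HK", seq_along(scales))
  attr(hks, "eigenvalues") <- lam
  if (normalize) {
    rng <- apply(hks, 2, range)
    hks <- sweep(hks, 2, rng[1, ])
    den <- rng[2, ] - rng[1, ]
    den[den == 0] <- 1
    hks <- sweep(hks, 2, den, "/")
  }
  hks
}

# Debye screening constant (1/A) for a 1:1 electrolyte at 298.15 K
.debye_kappa <- function(ionic_strength, eps_solvent) {
  if (ionic_strength <= 0) return(0)
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23; T <- 298.15
  e <- 1.602176634e-19; NA_ <- 6.02214076e23
  lambda_m <- sqrt(eps_solvent * eps0 * kB * T /
                     (2 * NA_ * e^2 * ionic_strength * 1000))
  1 / (lambda_m * 1e10)
}

#' Screened-Coulomb surface electrostatics
#'
#' Debye-Hueckel model of the electrostatic potential and field at mesh
#' vertices: `phi(x) = C sum_i q_i exp(-kappa d_i) / d_i` with
#' `C = 332.0637 / eps_solvent` (kcal/mol/e) and the screening constant
#' `kappa` derived from the ionic strength at 298 K. PH2 is the normal
#' component of the electric field, `-grad(phi) . n`. Distances are clamped
#' to 0.1 A for vertices coincident with an atom centre. Per-vertex values
#' from an external Poisson-Boltzmann solver may be supplied instead when
#' assembling a feature table (see [compute_feature_table()]).
#'
#' @param structure An `AtomicStructure` with charges.
#' @param mesh A `SurfaceMesh` with normals.
#' @param ionic_strength Bulk 1:1 ion concentration in mol/L (default 0.15).
#' @param eps_interior Interior dielectric constant (default 2.0); recorded
#'   as metadata (attribute `eps_interior`) for parity with imported
#'   solver output.
#' @param eps_solvent Solvent dielectric constant (default 78.5).
#' @return Matrix (vertices x 2) with columns PH1 (potential, kcal/mol/e) and
#'   PH2 (normal field, kcal/mol/e/A).
#' @export
electrostatics <- function(structure, mesh, ionic_strength = 0.15,
                           eps_interior = 2.0, eps_solvent = 78.5) {
  if (is.null(mesh$normals)) mesh <- compute_normals(mesh, fix_orientation = FALSE)
  q <- structure$atoms$charge
  A <- atom_xyz(structure)
  P <- mesh$V
  kap <- .debye_kappa(ionic_strength, eps_solvent)
  C <- 332.0637 / eps_solvent
  n <- nrow(P)
  ph1 <- numeric(n); ph2 <- numeric(n)
  bs <- max(1L, floor(1e6 / nrow(A)))
  for (s in seq(1L, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    dx <- outer(P[s:e, 1], A[, 1], "-")
    dy <- outer(P[s:e, 2], A[, 2], "-")
    dz <- outer(P[s:e, 3], A[, 3], "-")
    D <- pmax(sqrt(dx^2 + dy^2 + dz^2), 0.1)
    ek <- exp(-kap * D)
    ph1[s:e] <- C * as.numeric((ek / D) %*% q)
    # dphi/dd = C q e^{-kd} (-k d - 1)/d^2 along the unit separation vector
    gmag <- C * ek * (-kap * D - 1) / D^2
    gx <- (gmag * dx / D) %*% q
    gy <- (gmag * dy / D) %*% q
    gz <- (gmag * dz / D) %*% q
    nn <- mesh$normals[s:e, , drop = FALSE]
    ph2[s:e] <- -(gx * nn[, 1] + gy * nn[, 2] + gz * nn[, 3])
  }
  out <- cbind(PH1 = ph1, PH2 = ph2)
  attr(out, "eps_interior") <- eps_interior
  out
}

#' Assemble the per-vertex feature table
#'
#' Computes the 18 structural features (PH1, PH2, AF1-5, SAP, HBA, HBD,
#' CV1-3, MC, HK1-4) and, when residue profiles are supplied, the 50 MSA
#' features (PSSM1-20, HMM1-30). Atom- and residue-level features are mapped
#' onto vertices by inverse-distance weighting with a 2.5 A cutoff.
#'
#' @param structure An `AtomicStructure`.
#' @param mesh A `SurfaceMesh` with normals and vertex maps.
#' @param pssm,hhm Optional `ResidueProfile` objects from [parse_pssm()] /
#'   [parse_hhm()].
#' @param cv_radii Circular-variance radii in A (default 7.5, 15, 30).
#' @param n_eigen Eigenpairs for the heat kernel signatures.
#' @param import_potential Optional vertices x 2 matrix of externally solved
#'   PH1/PH2 values; marked with provenance `"imported"`.
#' @param features Optional subset of feature names to compute.
#' @return Numeric matrix (vertices x features) with a `provenance`
#'   attribute naming each column `computed`, `parsed` or `imported`.
#' @export
compute_feature_table <- function(structure, mesh, pssm = NULL, hhm = NULL,
                                  cv_radii = c(7.5, 15, 30), n_eigen = 64,
                                  import_potential = NULL, features = NULL) {
  if (is.null(mesh$normals)) mesh <- compute_normals(mesh, fix_orientation = FALSE)
  if (is.null(mesh$vertex_residue)) mesh <- map_mesh_to_structure(mesh, structure)
  want <- if (is.null(features)) structural_feature_names() else features
  cols <- list(); prov <- character(0)

  if (any(c("PH1", "PH2") %in% want)) {
    if (!is.null(import_potential)) {
      ph <- as.matrix(import_potential)
      colnames(ph) <- c("PH1", "PH2")
      pprov <- "imported"
    } else {
      ph <- electrostatics(structure, mesh)
      pprov <- "computed"
    }
    for (nm in intersect(c("PH1", "PH2"), want)) {
      cols[[nm]] <- ph[, nm]; prov[nm] <- pprov
    }
  }
  chemnames <- c(paste0("AF", 1:5), "SAP", "HBA", "HBD")
  if (any(chemnames %in% want)) {
    chem <- chemical_features(structure)
    mapped <- map_atom_to_vertices(structure, mesh, chem)
    colnames(mapped) <- colnames(chem)
    for (nm in intersect(chemnames, want)) {
      cols[[nm]] <- mapped[, nm]; prov[nm] <- "computed"
    }
  }
  cvnames <- paste0("CV", seq_along(cv_radii))
  for (k in seq_along(cv_radii)) {
    if (cvnames[k] %in% want) {
      cols[[cvnames[k]]] <- circular_variance(mesh, structure, cv_radii[k])
      prov[cvnames[k]] <- "computed"
    }
  }
  if ("MC" %in% want) {
    mc <- mean_curvature(mesh)
    cols[["MC"]] <- as.numeric(mc); prov["MC"] <- "computed"
  }
  if (any(paste0("HK", 1:4) %in% want)) {
    hks <- heat_kernel_signature(mesh, n_eigen = n_eigen)
    for (k in 1:4) {
      nm <- paste0("HK", k)
      if (nm %in% want) { cols[[nm]] <- hks[, k]; prov[nm] <- "computed" }
    }
  }
  if (!is.null(pssm)) {
    pm <- profile_to_vertices(structure, mesh, pssm)
    for (nm in colnames(pm)) { cols[[nm]] <- pm[, nm]; prov[nm] <- "parsed" }
  }
  if (!is.null(hhm)) {
    hm <- profile_to_vertices(structure, mesh, hhm)
    for (nm in colnames(hm)) { cols[[nm]] <- hm[, nm]; prov[nm] <- "parsed" }
  }
  X <- do.call(cbind, cols)
  if (any(!is.finite(X))) stop("non-finite feature values produced")
  attr(X, "provenance") <- prov
  X
}

#' Write a feature table as TSV
#' @param X Feature matrix from [compute_feature_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(X, path) {
  df <- as.data.frame(X)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
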