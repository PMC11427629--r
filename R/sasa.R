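# Shrake-Rupley solvent-accessible surface area.

# rotate points into the principal-axis frame with deterministic axis signs
# (largest third moment positive; right-handedness restored on axis 3)
.pca_canonical <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  if (nrow(Xc) < 3) return(Xc)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)$vectors
  Y <- Xc %*% ev
  for (d in 1:3) if (sum(Y[, d]^3) < 0) Y[, d] <- -Y[, d]
  Y
}

# quasi-uniform unit-sphere points (golden-spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley numerical SASA: test points on each atom's solvent-expanded
#' sphere are counted as accessible when outside every neighbouring expanded
#' sphere.
#'
#' Atoms are first rotated into a PCA-canonical frame (principal axes of the
#' coordinate covariance, signs fixed by third-moment convention) so the
#' numerical result is invariant under rigid motions of the input.
#'
#' @param structure An `AtomicStructure`.
#' @param probe Probe radius in A (default 1.4, water).
#' @param n_points Test points per atom (default 92).
#' @return Numeric vector of per-atom SASA (A^2).
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 92) {
  xyz <- .pca_canonical(atom_xyz(structure))
  r <- structure$atoms$radius + probe
  n <- nrow(xyz)
  sp <- .sphere_points(n_points)
  out <- numeric(n)
  # neighbour prefilter via pairwise distances
  D2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > r[j]^2
        if (!any(acc)) break
      }
      nacc <- sum(acc)
    } else nacc <- n_points
    out[i] <- 4 * pi * r[i]^2 * nacc / n_points
  }
  out
}

#' Relative residue solvent exposure
#'
#' Residue SASA divided by the packaged theoretical maximum accessible
#' surface area, clipped to `[0, 1]`. Non-standard residues get NA.
#'
#' @param structure An `AtomicStructure`.
#' @param sasa Optional precomputed per-atom SASA.
#' @return Numeric vector, one value per residue.
#' @export
residue_exposure <- function(structure, sasa = atom_sasa(structure)) {
  rs <- as.numeric(rowsum(sasa, structure$residue))
  rt <- residue_table(structure)
  mx <- .max_asa[rt$resname]
  pmin(pmax(rs / mx, 0), 1)
}
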