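# Rotationally invariant edge features: edge length, the angle the edge makes
# with the surface normal at each endpoint, and the normal-normal angle.
# On a flat patch the normal-normal angle is 0 deg and both edge-normal
# angles are 90 deg; on a sphere they vary systematically with distance.

# angle in degrees between row vectors of A and B
.angle_deg <- function(A, B) {
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  c_ <- pmin(pmax(num / den, -1), 1)
  acos(c_) * 180 / pi
}

#' Compute the four edge features of a mesh
#'
#' For every directed edge (both directions of every undirected mesh edge):
#' the edge length (A), the angle between the edge vector and the normal at
#' the source vertex, the angle at the target vertex, and the angle between
#' the two vertex normals, all in degrees. All four are invariant under rigid
#' motions of the mesh.
#'
#' @param mesh A `SurfaceMesh` with normals (see [compute_normals()]).
#' @return data.frame with columns `from`, `to`, `length`, `angle_src`,
#'   `angle_dst`, `angle_nn` of class `EdgeFeatureSet`.
#' @export
compute_edge_features <- function(mesh) {
  if (is.null(mesh$normals)) stop("mesh normals required; run compute_normals()")
  e <- mesh_edges(mesh)
  e <- rbind(e, e[, c(2, 1)])
  ef <- edge_features_for(mesh$V, mesh$normals, e[, 1], e[, 2])
  out <- data.frame(from = e[, 1], to = e[, 2], ef)
  class(out) <- c("EdgeFeatureSet", "data.frame")
  out
}

# shared kernel also used for GNN radial graphs: features of edges from -> to
edge_features_for <- function(V, normals, from, to) {
  d <- V[to, , drop = FALSE] - V[from, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9)) stop("coincident edge endpoints")
  data.frame(length = len,
             angle_src = .angle_deg(d, normals[from, , drop = FALSE]),
             angle_dst = .angle_deg(d, normals[to, , drop = FALSE]),
             angle_nn = .angle_deg(normals[from, , drop = FALSE],
                                   normals[to, , drop = FALSE]))
}
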