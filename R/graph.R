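# Point-cloud graph primitives: farthest point sampling, radial graph
# construction, KNN unpooling, and the pooling hierarchy used by the
# networks.
#
# FPS needs a deterministic start and tie-break that survive both rigid
# motions and vertex reordering (the networks must be invariant to both), so
# vertices are ranked by distance from the point-set centroid - a quantity
# unchanged by rigid motions and independent of vertex order - and the seed
# selects a rank. Ties in the greedy step are broken by the same rank.

.canonical_rank <- function(V) {
  ctr <- colMeans(V)
  d <- sqrt(rowSums(sweep(V, 2, ctr)^2))
  # farthest-from-centroid gets rank 1; residual index order only breaks
  # exact duplicates
  ord <- order(-d, seq_len(nrow(V)))
  rk <- integer(nrow(V))
  rk[ord] <- seq_len(nrow(V))
  rk
}

#' Farthest point sampling
#'
#' Greedy subset selection: starting from a seed-determined vertex, each
#' successive pick maximizes the minimum distance to the already-selected
#' set. Coincident duplicates of selected points are never re-selected.
#'
#' @param V N x 3 coordinate matrix.
#' @param ratio Sampling ratio in (0, 1]; `ceiling(ratio * N)` points are
#'   returned.
#' @param seed Integer seed selecting the start vertex via its canonical
#'   (centroid-distance) rank.
#' @param start Optional explicit start index (1-based), overriding `seed`.
#' @return Integer vector of selected vertex indices, in selection order.
#' @export
farthest_point_sample <- function(V, ratio, seed = 0L, start = NULL) {
  V <- as.matrix(V)
  n <- nrow(V)
  if (n == 0L) stop("empty point set")
  stopifnot(ratio > 0, ratio <= 1)
  rk <- .canonical_rank(V)
  if (is.null(start)) start <- which(rk == (as.integer(seed) %% n) + 1L)
  m <- ceiling(ratio * n)
  sel <- integer(m)
  sel[1] <- start
  mind <- sqrt(rowSums(sweep(V, 2, V[start, ])^2))
  i <- 1L
  while (i < m) {
    best <- max(mind)
    if (best <= 0) break  # only coincident duplicates remain
    cand <- which(mind == best)
    nxt <- cand[which.min(rk[cand])]
    i <- i + 1L
    sel[i] <- nxt
    mind <- pmin(mind, sqrt(rowSums(sweep(V, 2, V[nxt, ])^2)))
  }
  sel[seq_len(i)]
}

#' Build a directed radial graph
#'
#' Joins every vertex `j` to each centroid `i` with `||V_j - V_i|| <= radius`
#' and `j != i`; edges point from neighbour to centroid.
#'
#' @param V N x 3 coordinate matrix.
#' @param centroids Integer indices of centroid vertices.
#' @param radius Neighbourhood radius.
#' @return List of class `RadialGraph`: `from` (vertex index), `to` (index
#'   into `centroids`), `to_vertex` (centroid vertex index), `centroids`,
#'   `radius`.
#' @export
build_radial_graph <- function(V, centroids, radius) {
  stopifnot(radius > 0)
  V <- as.matrix(V)
  C <- V[centroids, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  bs <- max(1L, floor(4e6 / max(1L, nrow(C))))
  for (s in seq(1L, nrow(V), by = bs)) {
    e <- min(nrow(V), s + bs - 1L)
    D2 <- outer(rowSums(V[s:e, , drop = FALSE]^2), rowSums(C^2), "+") -
      2 * V[s:e, , drop = FALSE] %*% t(C)
    hit <- which(D2 <= radius^2 + 1e-12, arr.ind = TRUE)
    j <- hit[, 1] + s - 1L
    keep <- j != centroids[hit[, 2]]
    from <- c(from, j[keep])
    to <- c(to, hit[keep, 2])
  }
  ord <- order(to, from)
  structure(list(from = from[ord], to = to[ord],
                 to_vertex = centroids[to[ord]],
                 centroids = centroids, radius = radius),
            class = "RadialGraph")
}

# attach normalized edge features and grouped-aggregation bookkeeping
.prepare_graph <- function(g, V, normals, n_cent) {
  ef <- edge_features_for(V, normals, g$from, g$to_vertex)
  g$ef <- cbind(ef$length / g$radius, ef$angle_src / 180,
                ef$angle_dst / 180, ef$angle_nn / 180)
  g$n_cent <- n_cent
  g$cnt <- tabulate(g$to, nbins = n_cent)
  maxdeg <- max(g$cnt, 1L)
  # IDX[i, j]: id of the j-th edge into centroid i (padded with nE + 1)
  idx <- matrix(length(g$to) + 1L, n_cent, maxdeg)
  if (length(g$to)) {
    pos <- sequence(rle(g$to)$lengths)
    idx[cbind(g$to, pos)] <- seq_along(g$to)
  }
  g$IDX <- idx
  g
}

#' KNN unpooling weights
#'
#' For each fine point, finds the `k` nearest coarse points and returns
#' inverse-distance weights (normalized to sum 1). A fine point coincident
#' with a coarse point (d < 1e-8) copies that coarse point exactly.
#'
#' @param coarse_V,fine_V Coordinate matrices.
#' @param k Number of neighbours (default 3, capped at the coarse count).
#' @return List with `idx` (n_fine x k coarse indices) and `w` (weights).
#' @export
knn_unpool_map <- function(coarse_V, fine_V, k = 3) {
  coarse_V <- as.matrix(coarse_V); fine_V <- as.matrix(fine_V)
  k <- min(k, nrow(coarse_V))
  n <- nrow(fine_V)
  idx <- matrix(1L, n, k); w <- matrix(0, n, k)
  bs <- max(1L, floor(4e6 / nrow(coarse_V)))
  for (s in seq(1L, n, by = bs)) {
    e <- min(n, s + bs - 1L)
    D2 <- outer(rowSums(fine_V[s:e, , drop = FALSE]^2), rowSums(coarse_V^2), "+") -
      2 * fine_V[s:e, , drop = FALSE] %*% t(coarse_V)
    for (ii in seq_len(e - s + 1L)) {
      o <- order(D2[ii, ])[seq_len(k)]
      d <- sqrt(pmax(D2[ii, o], 0))
      idx[s + ii - 1L, ] <- o
      if (d[1] < 1e-8) {
        w[s + ii - 1L, ] <- c(1, rep(0, k - 1))
      } else {
        ww <- 1 / d
        w[s + ii - 1L, ] <- ww / sum(ww)
      }
    }
  }
  list(idx = idx, w = w)
}

#' KNN unpooling of features
#'
#' Distance-weighted mean of the `k` nearest coarse-point features.
#'
#' @param coarse_V Coarse coordinates.
#' @param coarse_feats Coarse feature matrix (rows follow `coarse_V`).
#' @param fine_V Fine coordinates to interpolate onto.
#' @param k Number of neighbours (default 3).
#' @return n_fine x ncol(coarse_feats) matrix.
#' @export
knn_unpool <- function(coarse_V, coarse_feats, fine_V, k = 3) {
  m <- knn_unpool_map(coarse_V, fine_V, k)
  apply_unpool(m, as.matrix(coarse_feats))
}

apply_unpool <- function(map, feats) {
  out <- matrix(0, nrow(map$idx), ncol(feats))
  for (j in seq_len(ncol(map$idx))) {
    out <- out + map$w[, j] * feats[map$idx[, j], , drop = FALSE]
  }
  out
}

# transpose of apply_unpool: scatter fine gradients back to coarse rows
apply_unpool_t <- function(map, grad_fine, n_coarse) {
  out <- matrix(0, n_coarse, ncol(grad_fine))
  for (j in seq_len(ncol(map$idx))) {
    acc <- rowsum(map$w[, j] * grad_fine, map$idx[, j])
    ids <- as.integer(rownames(acc))
    out[ids, ] <- out[ids, ] + acc
  }
  out
}

#' Default layer configuration
#'
#' Depth 3, radii 5.0/7.5/10.0 A, sampling ratio 0.5, two convolutions per
#' layer, KNN unpooling with k = 3, hidden width 32.
#'
#' @param depth Number of pooling levels.
#' @param radii Per-level convolution radii (A), strictly increasing.
#' @param ratio FPS sampling ratio.
#' @param k Unpooling neighbour count.
#' @param width Hidden feature width.
#' @param head_hidden Hidden width of the MLP heads.
#' @return List of class `LayerConfig`.
#' @export
layer_config <- function(depth = 3, radii = c(5.0, 7.5, 10.0), ratio = 0.5,
                         k = 3, width = 32, head_hidden = 32) {
  stopifnot(length(radii) == depth, all(diff(radii) > 0),
            ratio > 0, ratio <= 1, k >= 1, width >= 1)
  structure(list(depth = depth, radii = radii, ratio = ratio, k = k,
                 width = width, head_hidden = head_hidden),
            class = "LayerConfig")
}

#' Build the pooling hierarchy of a mesh
#'
#' Precomputes, per level: FPS centroids, the neighbour->centroid radial
#' graph (fine to coarse), the centroid-to-centroid radial graph used by the
#' second convolution of the level, normalized edge features for both, and
#' the KNN unpooling map back to the finer level. The hierarchy depends only
#' on geometry, so it is computed once per mesh and reused across epochs.
#'
#' @param mesh A `SurfaceMesh` with normals.
#' @param config A [layer_config()].
#' @param seed Integer seed controlling FPS starts.
#' @return List of class `MeshHierarchy`.
#' @export
build_hierarchy <- function(mesh, config = layer_config(), seed = 0L) {
  if (is.null(mesh$normals)) mesh <- compute_normals(mesh, fix_orientation = FALSE)
  P <- mesh$V; Nrm <- mesh$normals
  levels <- vector("list", config$depth)
  for (l in seq_len(config$depth)) {
    cidx <- farthest_point_sample(P, config$ratio, seed = seed + l - 1L)
    gA <- build_radial_graph(P, cidx, config$radii[l])
    gA <- .prepare_graph(gA, P, Nrm, length(cidx))
    Pc <- P[cidx, , drop = FALSE]; Nc <- Nrm[cidx, , drop = FALSE]
    gB <- build_radial_graph(Pc, seq_len(nrow(Pc)), config$radii[l])
    gB <- .prepare_graph(gB, Pc, Nc, nrow(Pc))
    up <- knn_unpool_map(Pc, P, config$k)
    levels[[l]] <- list(cidx = cidx, gA = gA, gB = gB, unpool = up,
                        n_fine = nrow(P), n_coarse = nrow(Pc))
    P <- Pc; Nrm <- Nc
  }
  structure(list(levels = levels, config = config, seed = seed,
                 n_vertices = nrow(mesh$V)),
            class = "MeshHierarchy")
}
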