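# SurfaceMesh container, OFF/PLY import/export, normals and orientation.

#' Construct a SurfaceMesh
#'
#' @param V N x 3 numeric matrix of vertex coordinates (A).
#' @param F M x 3 integer matrix of triangle vertex indices (1-based).
#' @param normals Optional N x 3 matrix of unit vertex normals.
#' @param vertex_atom Optional vertex -> atom index map.
#' @param vertex_residue Optional vertex -> residue index map.
#' @return Object of class `SurfaceMesh`.
#' @export
surface_mesh <- function(V, F, normals = NULL, vertex_atom = NULL,
                         vertex_residue = NULL) {
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  F <- as.matrix(F)
  storage.mode(F) <- "integer"
  stopifnot(ncol(V) == 3, ncol(F) == 3)
  if (nrow(F) && (min(F) < 1L || max(F) > nrow(V)))
    stop("face indices out of range")
  structure(list(V = V, F = F, normals = normals,
                 vertex_atom = vertex_atom, vertex_residue = vertex_residue),
            class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s\n", nrow(x$V), nrow(x$F),
              if (is.null(x$normals)) "" else ", normals present"))
  invisible(x)
}

#' Undirected edge list of a mesh
#' @param mesh A `SurfaceMesh`.
#' @return 2-column integer matrix of unique undirected edges (i < j).
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$F
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# counts of faces bordering each undirected edge (2 everywhere on a closed mesh)
edge_face_counts <- function(mesh) {
  F <- mesh$F
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is every connected component of the mesh closed?
#' @param mesh A `SurfaceMesh`.
#' @return Logical: TRUE iff every undirected edge borders exactly two faces.
#' @export
is_closed_mesh <- function(mesh) all(edge_face_counts(mesh) == 2L)

#' Connected components of mesh vertices
#' @param mesh A `SurfaceMesh`.
#' @return Integer vector of component ids per vertex.
#' @export
mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$V) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Euler characteristic per component
#' @param mesh A `SurfaceMesh`.
#' @return Named integer vector V - E + F per connected component.
#' @export
euler_characteristic <- function(mesh) {
  comp <- mesh_components(mesh)
  fcomp <- comp[mesh$F[, 1]]
  e <- mesh_edges(mesh)
  ecomp <- comp[e[, 1]]
  vc <- table(comp); ec <- table(ecomp); fc <- table(fcomp)
  ids <- names(vc)
  out <- as.integer(vc[ids]) - as.integer(ec[ids]) + as.integer(fc[ids])
  names(out) <- ids
  out
}

# per-face area-scaled normals (cross product / 2)
face_normals_raw <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1]) / 2
}

#' Total surface area of a mesh
#' @param mesh A `SurfaceMesh`.
#' @return Numeric area (A^2).
#' @export
mesh_area <- function(mesh) {
  fn <- face_normals_raw(mesh$V, mesh$F)
  sum(sqrt(rowSums(fn^2)))
}

#' Signed enclosed volume of a closed mesh
#' @param mesh A `SurfaceMesh`.
#' @return Numeric signed volume; positive for outward orientation.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  a <- V[F[, 1], , drop = FALSE]; b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Enforce consistent outward orientation
#'
#' Makes face windings consistent within each connected component (by
#' propagation over the face adjacency graph) and then flips whole closed
#' components whose signed volume is negative, so normals point outward.
#'
#' @param mesh A `SurfaceMesh`.
#' @return `SurfaceMesh` with consistently wound, outward-facing triangles.
#' @export
orient_mesh <- function(mesh) {
  F <- mesh$F
  nf <- nrow(F)
  if (nf == 0L) return(mesh)
  # face adjacency over shared undirected edges
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  fid <- rep(seq_len(nf), 3L)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  ord <- order(key)
  key <- key[ord]; fid2 <- fid[ord]; dirkey <- paste(he[, 1], he[, 2])[ord]
  grp <- cumsum(!duplicated(key))
  cnt <- tabulate(grp)
  first <- which(!duplicated(grp))
  pair <- which(cnt == 2L)
  i1 <- first[pair]; i2 <- i1 + 1L
  adj_a <- fid2[i1]; adj_b <- fid2[i2]
  # consistent winding <=> the shared edge appears in opposite directions
  same <- dirkey[i1] != dirkey[i2]
  flip <- rep(NA, nf)
  src <- c(adj_a, adj_b); dst <- c(adj_b, adj_a); ok2 <- c(same, same)
  ord2 <- order(src)
  src <- src[ord2]; dst <- dst[ord2]; ok2 <- ok2[ord2]
  # CSR-style adjacency: nbr_start[f]..nbr_end[f] index into dst/ok2
  deg <- tabulate(src, nbins = nf)
  nbr_end <- cumsum(deg); nbr_start <- nbr_end - deg + 1L
  for (s in seq_len(nf)) {
    if (!is.na(flip[s])) next
    flip[s] <- FALSE
    queue <- s; qi <- 1L
    while (qi <= length(queue)) {
      f <- queue[qi]; qi <- qi + 1L
      if (deg[f] == 0L) next
      for (i in nbr_start[f]:nbr_end[f]) {
        g <- dst[i]
        if (is.na(flip[g])) {
          flip[g] <- if (ok2[i]) flip[f] else !flip[f]
          queue <- c(queue, g)
        }
      }
    }
  }
  F[flip, c(2, 3)] <- F[flip, c(3, 2)]
  out <- mesh; out$F <- F
  # flip whole components with inward orientation
  comp <- mesh_components(out)
  for (cc in unique(comp)) {
    fsel <- comp[F[, 1]] == cc
    sub <- surface_mesh(out$V, F[fsel, , drop = FALSE])
    if (all(edge_face_counts(sub) == 2L) && mesh_volume(sub) < 0) {
      F[fsel, c(2, 3)] <- F[fsel, c(3, 2)]
    }
  }
  out$F <- F
  out$normals <- NULL
  out
}

#' Compute outward unit vertex normals
#'
#' Area-weighted average of incident face normals. The mesh orientation is
#' first made consistent and outward via [orient_mesh()] when the mesh is
#' closed. Zero-area faces are skipped with a warning.
#'
#' @param mesh A `SurfaceMesh`.
#' @param fix_orientation Run the orientation fix first (default TRUE).
#' @return `SurfaceMesh` with a `normals` matrix of unit vectors.
#' @export
compute_normals <- function(mesh, fix_orientation = TRUE) {
  if (fix_orientation) mesh <- orient_mesh(mesh)
  V <- mesh$V; F <- mesh$F
  fn <- face_normals_raw(V, F)
  fa <- sqrt(rowSums(fn^2))
  if (any(fa == 0)) {
    warning(sprintf("skipping %d zero-area face(s)", sum(fa == 0)))
    fn <- fn[fa > 0, , drop = FALSE]
    F <- F[fa > 0, , drop = FALSE]
  }
  n <- matrix(0, nrow(V), 3)
  idx <- c(F[, 1], F[, 2], F[, 3])
  fn3 <- rbind(fn, fn, fn)
  acc <- rowsum(fn3, idx)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  mesh$normals <- n / len
  mesh
}

#' Apply a rigid motion to a mesh
#' @param mesh A `SurfaceMesh`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return Transformed mesh (normals rotated if present).
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$V <- sweep(mesh$V %*% t(R), 2, -t)
  if (!is.null(mesh$normals)) mesh$normals <- mesh$normals %*% t(R)
  mesh
}

#' Read a mesh from OFF or PLY
#'
#' Supports OFF and ASCII PLY with triangular faces.
#'
#' @param path File path; format inferred from content/extension.
#' @return A `SurfaceMesh`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[1])
  if (identical(first, "OFF")) return(.read_off(lines))
  if (identical(first, "ply")) return(.read_ply(lines))
  stop("unrecognized mesh format (expected OFF or ascii PLY)")
}

.read_off <- function(lines) {
  body <- lines[-1]
  body <- body[!grepl("^\\s*(#|$)", body)]
  counts <- scan(text = body[1], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vlines <- body[2:(1 + nv)]
  V <- matrix(scan(text = vlines, quiet = TRUE), ncol = 3, byrow = TRUE)
  flines <- body[(2 + nv):(1 + nv + nf)]
  ftok <- lapply(strsplit(trimws(flines), "\\s+"), as.numeric)
  sz <- vapply(ftok, function(x) x[1], numeric(1))
  if (any(sz != 3)) stop("non-triangular face in OFF file")
  F <- t(vapply(ftok, function(x) x[2:4], numeric(3))) + 1
  surface_mesh(V, F)
}

.read_ply <- function(lines) {
  hend <- which(trimws(lines) == "end_header")[1]
  if (is.na(hend)) stop("PLY header missing end_header")
  header <- lines[1:hend]
  fmt <- grep("^format", header, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ascii PLY supported")
  el <- grep("^element", header)
  nv <- nf <- 0
  for (i in el) {
    tok <- strsplit(trimws(header[i]), "\\s+")[[1]]
    if (tok[2] == "vertex") nv <- as.integer(tok[3])
    if (tok[2] == "face") nf <- as.integer(tok[3])
  }
  body <- lines[(hend + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vtok, function(x) as.numeric(x[1:3]), numeric(3)))
  ftok <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.numeric)
  sz <- vapply(ftok, function(x) x[1], numeric(1))
  if (any(sz != 3)) stop("non-triangular face in PLY file")
  F <- t(vapply(ftok, function(x) x[2:4], numeric(3))) + 1
  surface_mesh(V, F)
}

#' Write a mesh to OFF or ASCII PLY
#'
#' @param mesh A `SurfaceMesh`.
#' @param path Output file; format from extension (`.off` or `.ply`).
#' @param quality Optional per-vertex scalar written as a PLY `quality`
#'   property (e.g. attribution scores).
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, quality = NULL) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$V; F <- mesh$F
  if (ext == "off") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(V), nrow(F)), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(V)),
             "property float x", "property float y", "property float z")
    if (!is.null(quality)) hdr <- c(hdr, "property float quality")
    hdr <- c(hdr, sprintf("element face %d", nrow(F)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    if (is.null(quality)) {
      writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    } else {
      writeLines(sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], quality), con)
    }
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  } else stop("unsupported mesh extension: ", ext)
  invisible(path)
}
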