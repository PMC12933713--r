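#' Triangulated surface mesh
#'
#' Container for a molecular surface: vertex coordinates in Angstrom,
#' triangle faces (1-based vertex indices, counter-clockwise seen from
#' outside), unit vertex normals and, once assigned, the nearest residue of
#' every vertex.
#'
#' @param vertices numeric V x 3 matrix of coordinates (Angstrom).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param normals optional V x 3 matrix of vertex normals; recomputed from
#'   the face geometry (area-weighted) when `NULL` or degenerate.
#' @param nearest_residue optional integer vector (length V) of residue row
#'   indices into the owning structure's residue table.
#' @return An object of class `surfibs_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, nearest_residue = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop_surfibs("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop_surfibs(sprintf("face index out of range: max index %d for %d vertices",
                         max(faces), nrow(vertices)))
  if (!all(is.finite(vertices))) stop_surfibs("non-finite vertex coordinates")
  mesh <- structure(
    list(vertices = vertices, faces = faces, normals = NULL,
         nearest_residue = nearest_residue),
    class = "surfibs_mesh")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    nrm <- sqrt(rowSums(normals^2))
    if (all(nrm > 1e-8)) mesh$normals <- normals / nrm
  }
  if (is.null(mesh$normals)) mesh$normals <- vertex_normals(mesh)
  mesh
}

#' @export
print.surfibs_mesh <- function(x, ...) {
  cat(sprintf("<surfibs_mesh> %d vertices, %d faces, chi = %d%s\n",
              nrow(x$vertices), nrow(x$faces), euler_characteristic(x),
              if (is.null(x$nearest_residue)) "" else ", residues assigned"))
  invisible(x)
}

# area-weighted vertex normals from face geometry
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- matrix(0, nrow(V), 3)
  if (nrow(F) > 0) {
    a <- V[F[, 1], , drop = FALSE]
    b <- V[F[, 2], , drop = FALSE]
    c <- V[F[, 3], , drop = FALSE]
    fn <- cross3(b - a, c - a) # length = 2 * face area
    for (j in 1:3) {
      for (d in 1:3) {
        acc <- rowsum(fn[, d], F[, j])
        idx <- as.integer(rownames(acc))
        n[idx, d] <- n[idx, d] + acc[, 1]
      }
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Mesh summaries
#'
#' `euler_characteristic()` returns V - E + F; `mesh_area()` the total
#' triangle area; `mesh_edges()` the unique undirected edges with their
#' Euclidean lengths.
#'
#' @param mesh a [surface_mesh()].
#' @return integer scalar, numeric scalar, and a 3-column matrix
#'   (`i`, `j`, `length`) respectively.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' @rdname euler_characteristic
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  fn <- cross3(V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE],
               V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE])
  sum(sqrt(rowSums(fn^2))) / 2
}

#' @rdname euler_characteristic
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e[, 1] * 2^26 + e[, 2]), , drop = FALSE]
  V <- mesh$vertices
  len <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  cbind(i = e[, 1], j = e[, 2], length = len)
}

# signed volume of a closed mesh (positive if faces wind counter-clockwise
# seen from outside)
signed_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c))) / 6
}

# make winding consistent across each connected face component (BFS over
# shared edges) and, for closed meshes, globally outward
normalize_winding <- function(mesh) {
  F <- mesh$faces
  nf <- nrow(F)
  if (nf == 0) return(mesh)
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  keys <- c(ekey(F[, 1], F[, 2]), ekey(F[, 2], F[, 3]), ekey(F[, 3], F[, 1]))
  fid <- rep(seq_len(nf), 3)
  adj <- split(fid, keys)
  nbr <- vector("list", nf)
  for (fs in adj) {
    if (length(fs) == 2) {
      nbr[[fs[1]]] <- c(nbr[[fs[1]]], fs[2])
      nbr[[fs[2]]] <- c(nbr[[fs[2]]], fs[1])
    }
  }
  # directed-edge set per face, regenerated lazily after flips
  seen <- logical(nf)
  flip <- logical(nf)
  dir_edges <- function(f, flipped) {
    tri <- F[f, ]
    if (flipped) tri <- tri[c(1, 3, 2)]
    rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
  }
  for (start in seq_len(nf)) {
    if (seen[start]) next
    seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      f <- queue[[1]]
      queue <- queue[-1]
      ef <- dir_edges(f, flip[f])
      for (g in nbr[[f]]) {
        if (seen[g]) next
        eg <- dir_edges(g, FALSE)
        # consistent orientation traverses the shared edge in opposite order
        shared_same <- FALSE
        for (p in 1:3) for (q in 1:3)
          if (ef[p, 1] == eg[q, 1] && ef[p, 2] == eg[q, 2]) shared_same <- TRUE
        flip[g] <- shared_same
        seen[g] <- TRUE
        queue <- c(queue, g)
      }
    }
  }
  if (any(flip)) F[flip, ] <- F[flip, c(1, 3, 2)]
  mesh$faces <- F
  if (is_closed(mesh) && signed_volume(mesh) < 0) mesh$faces <- F[, c(1, 3, 2)]
  mesh$normals <- vertex_normals(mesh)
  mesh
}

is_closed <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  ekey <- paste0(pmin(F[, c(1, 2, 3)], F[, c(2, 3, 1)]), "_",
                 pmax(F[, c(1, 2, 3)], F[, c(2, 3, 1)]))
  all(table(ekey) == 2)
}

# drop vertices not referenced by any face, remapping indices
drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  mesh$normals <- mesh$normals[used, , drop = FALSE]
  if (!is.null(mesh$nearest_residue))
    mesh$nearest_residue <- mesh$nearest_residue[used]
  mesh$faces <- matrix(map[mesh$faces], ncol = 3)
  mesh
}

# keep the largest connected component (vertex connectivity through faces)
largest_component <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  fkeep <- rowSums(matrix(mesh$faces %in% keep, ncol = 3)) == 3
  mesh$faces <- mesh$faces[fkeep, , drop = FALSE]
  drop_unreferenced(mesh)
}
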