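# Geodesic patch decomposition: Dijkstra distances along mesh edges,
# radius-9 patches capped at 100 members, and 2-D geodesic polar
# coordinates via classical MDS with a random reference axis.

#' Geodesic edge set of a mesh
#'
#' The mesh edges plus one shortcut per interior edge: the two triangles
#' adjacent to an edge are unfolded into a common plane and their opposite
#' vertices are connected with the unfolded straight-line distance whenever
#' that segment actually crosses the shared edge. Dijkstra on this
#' augmented graph tracks true surface geodesics far better than the bare
#' edge graph (the lattice-direction bias of edge paths largely cancels).
#'
#' @param mesh a [surface_mesh()].
#' @return matrix with columns `i`, `j`, `length`.
#' @export
geodesic_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  F <- mesh$faces
  V <- mesh$vertices
  # opposite vertices of each interior edge
  ekey <- c(F[, 1] * 2^26 + F[, 2], F[, 2] * 2^26 + F[, 3], F[, 3] * 2^26 + F[, 1])
  ekey2 <- c(F[, 2] * 2^26 + F[, 1], F[, 3] * 2^26 + F[, 2], F[, 1] * 2^26 + F[, 3])
  opp <- c(F[, 3], F[, 1], F[, 2])
  key_u <- pmin(ekey, ekey2)
  ord <- order(key_u)
  ku <- key_u[ord]; op <- opp[ord]
  first <- !duplicated(ku)
  starts <- which(first)
  lens <- diff(c(starts, length(ku) + 1))
  two <- starts[lens == 2]
  if (length(two) == 0) return(e)
  k2 <- ku[two]
  a <- floor(k2 / 2^26); b <- k2 - a * 2^26
  c1 <- op[two]; c2 <- op[two + 1]
  L <- sqrt(rowSums((V[a, , drop = FALSE] - V[b, , drop = FALSE])^2))
  d2 <- function(p, q) rowSums((V[p, , drop = FALSE] - V[q, , drop = FALSE])^2)
  # unfold both triangles about the shared edge a-b
  xc <- (d2(a, c1) + L^2 - d2(b, c1)) / (2 * L)
  yc <- sqrt(pmax(d2(a, c1) - xc^2, 0))
  xd <- (d2(a, c2) + L^2 - d2(b, c2)) / (2 * L)
  yd <- -sqrt(pmax(d2(a, c2) - xd^2, 0))
  xstar <- xc + (xd - xc) * yc / pmax(yc - yd, 1e-12)
  ok <- xstar >= 0 & xstar <= L & yc > 1e-12 & yd < -1e-12
  sc <- cbind(i = pmin(c1, c2)[ok], j = pmax(c1, c2)[ok],
              length = sqrt((xc - xd)^2 + (yc - yd)^2)[ok])
  rbind(e, sc)
}

mesh_graph <- function(mesh) {
  e <- geodesic_edges(mesh)
  g <- igraph::graph_from_edgelist(cbind(e[, "i"], e[, "j"]), directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  igraph::E(g)$weight <- e[, "length"]
  g
}

#' Geodesic distances from a source vertex
#'
#' Shortest-path distance along the surface, computed with Dijkstra's
#' algorithm on the [geodesic_edges()] graph (mesh edges weighted by
#' Euclidean length plus unfolded across-edge shortcuts) and truncated at
#' `cap`.
#'
#' @param mesh a [surface_mesh()].
#' @param source source vertex index (1-based).
#' @param cap truncation radius in Angstrom (default 9).
#' @param graph optional precomputed mesh graph (internal reuse).
#' @return named numeric vector: distances of all vertices within `cap`,
#'   names are vertex indices.
#' @export
geodesic_distances <- function(mesh, source, cap = 9, graph = NULL) {
  nv <- nrow(mesh$vertices)
  if (source < 1 || source > nv) stop_surfibs("source vertex out of range")
  g <- graph %||% mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = source, algorithm = "dijkstra"))
  keep <- which(d <= cap)
  setNames(d[keep], keep)
}

#' Extract a geodesic patch around a center vertex
#'
#' Members are the vertices within `radius` geodesic distance of the
#' center, keeping at most `max_points` nearest by geodesic distance (ties
#' by vertex index), sorted by distance with the center first. The feature
#' matrix is gathered per member and its ddc column is recomputed
#' patch-relative. Patches smaller than `max_points` are padded with
#' mask = FALSE, rho = radius, theta = 0 and zero features.
#'
#' @param mesh a [surface_mesh()].
#' @param features feature tibble from [assemble_features()] (or any table
#'   with the five feature columns; one row per vertex).
#' @param center center vertex index.
#' @param radius geodesic patch radius, Angstrom (default 9).
#' @param max_points member cap (default 100).
#' @param graph,distances optional precomputed graph / distance row.
#' @return a `surfibs_patch`: list with center, members, rho, theta (NA
#'   until [polar_coordinates()]), members x 5 feature matrix, mask and
#'   n_real.
#' @export
extract_patch <- function(mesh, features, center, radius = 9, max_points = 100,
                          graph = NULL, distances = NULL) {
  nv <- nrow(mesh$vertices)
  if (center < 1 || center > nv) stop_surfibs("center vertex out of range")
  d <- distances %||% {
    g <- graph %||% mesh_graph(mesh)
    as.numeric(igraph::distances(g, v = center, algorithm = "dijkstra"))
  }
  if (!is.finite(d[center])) stop_surfibs("center vertex is isolated")
  cand <- which(d <= radius)
  ord <- order(d[cand], cand)
  cand <- cand[ord]
  members <- head(cand, max_points)
  n_real <- length(members)
  fm <- as.matrix(as.data.frame(features)[members, FEATURE_NAMES])
  patch <- structure(
    list(center = center,
         members = c(members, rep(center, max_points - n_real)),
         rho = c(d[members], rep(radius, max_points - n_real)),
         theta = rep(NA_real_, max_points),
         features = rbind(fm, matrix(0, max_points - n_real, 5)),
         mask = c(rep(TRUE, n_real), rep(FALSE, max_points - n_real)),
         radius = radius, n_real = n_real),
    class = "surfibs_patch")
  colnames(patch$features) <- FEATURE_NAMES
  patch$features[, "ddc"] <- distance_dependent_curvature(patch, mesh, radius)
  patch
}

#' Geodesic polar coordinates of a patch
#'
#' Pairwise geodesic distances among the real members are computed by
#' Dijkstra restricted to the patch-induced submesh and embedded in 2-D by
#' classical metric MDS; the angular coordinate is the atan2 angle of each
#' member in that plane, measured from a uniformly random reference
#' direction drawn from `rng_seed`. The radial coordinate keeps the
#' Dijkstra distances (not the embedding radii). Patches with fewer than 3
#' real members get theta = 0. The chirality of the embedding is left
#' unresolved; the network's angular max pooling absorbs it.
#'
#' @param patch a `surfibs_patch`.
#' @param mesh the owning [surface_mesh()].
#' @param rng_seed integer seed for the random 0-degree reference axis.
#' @param edges optional precomputed `geodesic_edges(mesh)` (internal reuse).
#' @return the patch with `theta` filled (radians in [0, 2 pi); padding 0).
#' @export
polar_coordinates <- function(patch, mesh, rng_seed = 0, edges = NULL) {
  m <- patch$members[patch$mask]
  n <- length(m)
  patch$theta <- rep(0, length(patch$members))
  if (n < 3) return(patch)
  D <- submesh_pairwise(mesh, m, edges)
  xy <- suppressWarnings(stats::cmdscale(D, k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, nrow(xy), 2 - ncol(xy)))
  ref <- with_seed(rng_seed, runif(1, 0, 2 * pi))
  rel <- sweep(xy, 2, xy[1, ]) # center the plane on the patch center
  th <- atan2(rel[, 2], rel[, 1]) - ref
  patch$theta[seq_len(n)] <- th %% (2 * pi)
  patch
}

submesh_pairwise <- function(mesh, members, edges = NULL) {
  e <- edges %||% geodesic_edges(mesh)
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  keep <- inset[e[, "i"]] & inset[e[, "j"]]
  es <- e[keep, , drop = FALSE]
  idx <- integer(nrow(mesh$vertices))
  idx[members] <- seq_along(members)
  g <- igraph::make_empty_graph(n = length(members), directed = FALSE)
  if (nrow(es) > 0) {
    g <- igraph::add_edges(g, rbind(idx[es[, "i"]], idx[es[, "j"]]))
    igraph::E(g)$weight <- es[, "length"]
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(D))) {
    # rare: members disconnected inside the disc; fall back to chord length
    eu <- as.matrix(stats::dist(mesh$vertices[members, , drop = FALSE]))
    D[!is.finite(D)] <- eu[!is.finite(D)]
  }
  D
}

#' Decompose a whole surface into overlapping patches
#'
#' One patch per vertex, with shared precomputation of the mesh graph and
#' all-source Dijkstra distances. Per-patch reference axes are drawn from
#' `seed` (one independent substream per center).
#'
#' @inheritParams extract_patch
#' @param seed integer seed for the random reference axes.
#' @param centers vertex indices to use as patch centers (default: all).
#' @return a `surfibs_patch_set`: list of patches plus the member/mask/
#'   rho/theta matrices and the (V*K) x 5 member-feature matrix consumed by
#'   the network.
#' @export
surface_patches <- function(mesh, features, radius = 9, max_points = 100,
                            seed = 0, centers = NULL) {
  nv <- nrow(mesh$vertices)
  centers <- centers %||% seq_len(nv)
  g <- mesh_graph(mesh)
  e <- geodesic_edges(mesh)
  D <- igraph::distances(g, v = centers, algorithm = "dijkstra")
  patches <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    p <- extract_patch(mesh, features, centers[i], radius, max_points,
                       distances = D[i, ])
    patches[[i]] <- polar_coordinates(p, mesh, sub_seed(seed, centers[i]),
                                      edges = e)
  }
  as_patch_set(patches, radius, max_points)
}

as_patch_set <- function(patches, radius, max_points) {
  K <- max_points
  members <- t(vapply(patches, function(p) p$members, integer(K)))
  mask <- t(vapply(patches, function(p) as.numeric(p$mask), numeric(K)))
  rho <- t(vapply(patches, function(p) p$rho, numeric(K)))
  theta <- t(vapply(patches, function(p) p$theta, numeric(K)))
  feat <- do.call(rbind, lapply(patches, function(p) p$features))
  structure(list(patches = patches,
                 centers = vapply(patches, function(p) p$center, integer(1)),
                 members = members, mask = mask, rho = rho, theta = theta,
                 feat = feat, radius = radius, max_points = K,
                 version = "1"),
            class = "surfibs_patch_set")
}

#' @export
print.surfibs_patch_set <- function(x, ...) {
  cat(sprintf("<surfibs_patch_set> %d patches, radius %.1f A, cap %d, mean real members %.1f\n",
              length(x$patches), x$radius, x$max_points, mean(rowSums(x$mask))))
  invisible(x)
}

#' Serialize a patch set to / from a JSON archive
#'
#' One archive per protein: center ids, member ids, rho, theta, mask,
#' features and a format version field.
#'
#' @param patch_set a `surfibs_patch_set`.
#' @param path output path (`.json`).
#' @return `read_patches()` returns the patch set.
#' @export
write_patches <- function(patch_set, path) {
  x <- patch_set[c("centers", "members", "mask", "rho", "theta", "feat",
                   "radius", "max_points", "version")]
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version)) stop_surfibs("patch archive missing version field")
  K <- x$max_points
  patches <- lapply(seq_along(x$centers), function(i) {
    structure(list(center = x$centers[i], members = x$members[i, ],
                   rho = x$rho[i, ], theta = x$theta[i, ],
                   features = matrix(x$feat[(i - 1) * K + seq_len(K), ], ncol = 5,
                                     dimnames = list(NULL, FEATURE_NAMES)),
                   mask = as.logical(x$mask[i, ]), radius = x$radius,
                   n_real = sum(x$mask[i, ])),
              class = "surfibs_patch")
  })
  ps <- as_patch_set(patches, x$radius, K)
  ps$version <- x$version
  ps
}
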