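#' Surface generation configuration
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.5, a
#'   water-sized probe).
#' @param target_edge_length remeshing target edge length in Angstrom
#'   (default 1.0).
#' @param grid_spacing isosurface grid spacing in Angstrom (default 0.6).
#' @param blend_sigma Gaussian blending width of the smooth atom-sphere
#'   union, Angstrom (default 1.0); larger values smooth crevices more.
#' @param atom_radii named vector of van der Waals radii per element symbol;
#'   elements not listed fall back to `default_radius`.
#' @param default_radius fallback atomic radius, Angstrom.
#' @param keep_all_components keep every connected surface component instead
#'   of only the largest.
#' @return a list of class `surfibs_surface_config`.
#' @export
surface_config <- function(probe_radius = 1.5, target_edge_length = 1.0,
                           grid_spacing = 0.6, blend_sigma = 1.0,
                           atom_radii = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                                          P = 1.8, H = 1.2),
                           default_radius = 1.7,
                           keep_all_components = FALSE) {
  if (probe_radius <= 0 || target_edge_length <= 0 || grid_spacing <= 0)
    stop_surfibs("probe_radius, target_edge_length and grid_spacing must be positive")
  structure(list(probe_radius = probe_radius,
                 target_edge_length = target_edge_length,
                 grid_spacing = grid_spacing, blend_sigma = blend_sigma,
                 atom_radii = atom_radii, default_radius = default_radius,
                 keep_all_components = keep_all_components),
            class = "surfibs_surface_config")
}

#' Build a molecular surface mesh from a structure
#'
#' Extracts the iso-level-1 surface of a smooth Gaussian union of heavy-atom
#' spheres inflated by the probe radius (a solvent-accessible-like
#' envelope), then remeshes it to the target edge length. Only heavy atoms
#' contribute; by default only the largest connected component is kept.
#'
#' @param structure a `surfibs_structure` with at least one heavy atom.
#' @param config a [surface_config()].
#' @param regularized remesh to `target_edge_length` after extraction
#'   (default `TRUE`).
#' @return a closed, outward-oriented [surface_mesh()] enclosing all
#'   heavy-atom centers.
#' @export
build_surface <- function(structure, config = surface_config(), regularized = TRUE) {
  heavy <- structure$atoms[structure$atoms$is_heavy, ]
  if (nrow(heavy) == 0) stop_surfibs("structure has no heavy atoms")
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  radii <- unname(config$atom_radii[heavy$element])
  radii[is.na(radii)] <- config$default_radius
  radii <- radii + config$probe_radius
  h <- config$grid_spacing
  if (nrow(xyz) > 2) {
    sv <- svd(scale(xyz, scale = FALSE))$d
    if (sv[2] < h / 2 && sv[3] < h / 2)
      stop_surfibs("degenerate structure: atoms collinear within grid spacing")
  }
  margin <- max(radii) + 3 * config$blend_sigma + 2 * h
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  field <- gaussian_density_grid_cpp(xyz, radii, config$blend_sigma, lo, h, dims)
  # log density is near-linear in distance close to the level set, so linear
  # edge interpolation lands on the sphere union with little radial bias
  field <- pmax(log(pmax(field, 1e-13)), -30)
  iso <- marching_tetrahedra_cpp(field, dims, lo, h, 0.0)
  mesh <- surface_mesh(iso$vertices, iso$faces + 1L)
  if (!config$keep_all_components) mesh <- largest_component(mesh)
  if (regularized) mesh <- regularize(mesh, config$target_edge_length)
  mesh
}

#' Remesh a surface toward a uniform target edge length
#'
#' Iterated incremental remeshing: long-edge split, short-edge collapse,
#' valence-equalizing edge flips, and tangential Laplacian smoothing. The
#' Euler characteristic of a closed mesh is preserved; the median output
#' edge length lands within about 25% of the target.
#'
#' @param mesh a [surface_mesh()].
#' @param target_edge_length target edge length, Angstrom.
#' @param iterations remeshing sweeps (default 5).
#' @return the remeshed [surface_mesh()].
#' @export
regularize <- function(mesh, target_edge_length, iterations = 5) {
  e <- mesh_edges(mesh)
  if (target_edge_length >= max(e[, "length"]) * 1.01 &&
      target_edge_length > max(dist_bbox(mesh)))
    stop_surfibs("target edge length exceeds mesh diameter")
  V <- mesh$vertices
  F <- mesh$faces
  for (it in seq_len(iterations)) {
    sp <- split_long_edges(V, F, 4 / 3 * target_edge_length)
    V <- sp$V; F <- sp$F
    cl <- collapse_short_edges(V, F, 4 / 5 * target_edge_length,
                               4 / 3 * target_edge_length)
    V <- cl$V; F <- cl$F
    if (nrow(V) < 16) stop_surfibs("mesh collapsed below 16 vertices")
    F <- flip_edges(V, F)
    V <- tangential_smooth(V, F, lambda = 0.25)
  }
  out <- surface_mesh(V, F)
  drop_unreferenced(out)
}

dist_bbox <- function(mesh) apply(mesh$vertices, 2, function(v) diff(range(v)))

edge_table <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# numeric edge key (supports meshes up to 2^26 vertices exactly)
ekey_num <- function(a, b) pmin(a, b) * 2^26 + pmax(a, b)

unique_edge_table <- function(F) {
  e <- edge_table(F)
  e[!duplicated(e[, 1] * 2^26 + e[, 2]), , drop = FALSE]
}

# map from undirected edge key to the adjacent face ids (sorted lookup)
edge_face_map <- function(F) {
  key <- c(ekey_num(F[, 1], F[, 2]), ekey_num(F[, 2], F[, 3]), ekey_num(F[, 3], F[, 1]))
  fid <- rep(seq_len(nrow(F)), 3)
  o <- order(key)
  key <- key[o]; fid <- fid[o]
  first <- !duplicated(key)
  starts <- which(first)
  list(keys = key[starts], starts = starts,
       lens = diff(c(starts, length(key) + 1)), fids = fid)
}

edge_faces <- function(map, key) {
  i <- match(key, map$keys)
  if (is.na(i)) return(integer(0))
  map$fids[map$starts[i] + seq_len(map$lens[i]) - 1]
}

split_long_edges <- function(V, F, lmax) {
  repeat {
    e <- unique_edge_table(F)
    len <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
    long <- which(len > lmax)
    if (length(long) == 0) break
    long <- long[order(len[long], decreasing = TRUE)]
    touched <- logical(nrow(F))
    emap <- edge_face_map(F)
    ekey <- ekey_num(e[, 1], e[, 2])
    newV <- list(); newF <- list(); drop <- logical(nrow(F))
    for (ei in long) {
      fs <- edge_faces(emap, ekey[ei])
      if (any(touched[fs])) next
      a <- e[ei, 1]; b <- e[ei, 2]
      mid_id <- nrow(V) + length(newV) + 1L
      newV[[length(newV) + 1]] <- (V[a, ] + V[b, ]) / 2
      for (f in fs) {
        tri <- F[f, ]
        c3 <- setdiff(tri, c(a, b))
        if (length(c3) != 1) next
        # preserve winding: replace b by mid, then a by mid
        t1 <- tri; t1[t1 == b] <- mid_id
        t2 <- tri; t2[t2 == a] <- mid_id
        newF[[length(newF) + 1]] <- t1
        newF[[length(newF) + 1]] <- t2
        drop[f] <- TRUE
        touched[f] <- TRUE
      }
    }
    if (length(newV) == 0) break
    V <- rbind(V, do.call(rbind, newV))
    F <- rbind(F[!drop, , drop = FALSE], do.call(rbind, newF))
  }
  list(V = V, F = F)
}

collapse_short_edges <- function(V, F, lmin, lmax) {
  e <- unique_edge_table(F)
  len <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  short <- which(len < lmin)
  if (length(short) == 0) return(list(V = V, F = F))
  short <- short[order(len[short])]
  nb <- vertex_neighbors(F, nrow(V))
  touched <- logical(nrow(V))
  remap <- seq_len(nrow(V))
  for (ei in short) {
    a <- e[ei, 1]; b <- e[ei, 2]
    if (touched[a] || touched[b]) next
    # link condition (light): the one-rings may share exactly two vertices
    common <- intersect(nb[[a]], nb[[b]])
    if (length(common) != 2) next
    mid <- (V[a, ] + V[b, ]) / 2
    # reject collapses that would create overlong edges
    ring <- setdiff(union(nb[[a]], nb[[b]]), c(a, b))
    if (any(sqrt(colSums((t(V[ring, , drop = FALSE]) - mid)^2)) > lmax)) next
    V[a, ] <- mid
    remap[b] <- a
    touched[a] <- TRUE; touched[b] <- TRUE
  }
  F <- matrix(remap[F], ncol = 3)
  deg <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
  F <- F[!deg, , drop = FALSE]
  # drop duplicated faces (can arise from aggressive collapses)
  lo <- pmin(F[, 1], F[, 2], F[, 3])
  hi <- pmax(F[, 1], F[, 2], F[, 3])
  key <- paste(lo, F[, 1] + F[, 2] + F[, 3] - lo - hi, hi)
  F <- F[!(key %in% key[duplicated(key)]), , drop = FALSE]
  list(V = V, F = F)
}

vertex_neighbors <- function(F, nv) {
  e <- unique_edge_table(F)
  split(c(e[, 2], e[, 1]),
        factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
}

flip_edges <- function(V, F) {
  nv <- nrow(V)
  deg <- tabulate(as.vector(F), nv)
  emap <- edge_face_map(F)
  ue <- unique_edge_table(F)
  touched <- logical(nrow(F))
  for (r in seq_len(nrow(ue))) {
    a <- ue[r, 1]; b <- ue[r, 2]
    fs <- edge_faces(emap, ekey_num(a, b))
    if (length(fs) != 2 || any(touched[fs])) next
    t1v <- F[fs[1], ]; t2v <- F[fs[2], ]
    c1 <- t1v[t1v != a & t1v != b]
    c2 <- t2v[t2v != a & t2v != b]
    if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
    # flip if it moves the four valences toward 6
    dev_now <- abs(deg[a] - 6) + abs(deg[b] - 6) + abs(deg[c1] - 6) + abs(deg[c2] - 6)
    dev_new <- abs(deg[a] - 1 - 6) + abs(deg[b] - 1 - 6) +
      abs(deg[c1] + 1 - 6) + abs(deg[c2] + 1 - 6)
    if (dev_new >= dev_now) next
    # keep winding: in face fs[1] = (a, b, c1) order unknown; rebuild flipped pair
    t1 <- F[fs[1], ]
    pos_a <- which(t1 == a); pos_b <- which(t1 == b)
    a_before_b <- (pos_a %% 3) + 1 == pos_b
    if (a_before_b) {
      F[fs[1], ] <- c(a, c2, c1)
      F[fs[2], ] <- c(c2, b, c1)
    } else {
      F[fs[1], ] <- c(a, c1, c2)
      F[fs[2], ] <- c(c1, b, c2)
    }
    deg[a] <- deg[a] - 1; deg[b] <- deg[b] - 1
    deg[c1] <- deg[c1] + 1; deg[c2] <- deg[c2] + 1
    touched[fs] <- TRUE
  }
  F
}

tangential_smooth <- function(V, F, lambda = 0.25) {
  mesh <- surface_mesh(V, F)
  n <- mesh$normals
  e <- unique_edge_table(F)
  idx <- c(e[, 1], e[, 2])
  acc <- rowsum(V[c(e[, 2], e[, 1]), , drop = FALSE], idx)
  deg <- tabulate(idx, nrow(V))
  cent <- V
  touched <- as.integer(rownames(acc))
  cent[touched, ] <- acc / pmax(deg[touched], 1)
  d <- lambda * (cent - V)
  d <- d - n * rowSums(d * n) # tangential component only
  V + d
}

#' Assign every mesh vertex its nearest residue
#'
#' The nearest residue of a vertex is that of the heavy atom minimizing the
#' Euclidean distance to it; exact ties are broken by the lower atom serial,
#' so the assignment is deterministic and invariant to atom order.
#'
#' @param mesh a [surface_mesh()].
#' @param structure a `surfibs_structure`.
#' @return the mesh with `$nearest_residue` filled (row indices into
#'   `structure$residues`).
#' @export
assign_nearest_residue <- function(mesh, structure) {
  heavy <- structure$atoms[structure$atoms$is_heavy, ]
  if (nrow(heavy) == 0 || nrow(mesh$vertices) == 0)
    stop_surfibs("mesh and structure must be nonempty")
  ord <- order(heavy$serial)
  heavy <- heavy[ord, ]
  ax <- as.matrix(heavy[, c("x", "y", "z")])
  Vx <- mesh$vertices
  # blocked distance computation keeps memory bounded
  n <- nrow(Vx)
  nearest <- integer(n)
  block <- max(1L, as.integer(2e6 / nrow(ax)))
  for (s in seq(1, n, by = block)) {
    idx <- s:min(n, s + block - 1)
    d2 <- outer(rowSums(Vx[idx, , drop = FALSE]^2), rowSums(ax^2), "+") -
      2 * Vx[idx, , drop = FALSE] %*% t(ax)
    # max.col picks the FIRST maximum on ties => lowest serial (sorted above)
    nearest[idx] <- max.col(-d2, ties.method = "first")
  }
  mesh$nearest_residue <- heavy$residue[nearest]
  mesh
}
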