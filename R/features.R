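# Per-vertex surface features. All five features live in [-1, 1] and are
# assembled in fixed column order:
#   1 shape_index, 2 ddc, 3 hydropathy, 4 electrostatics, 5 hbond

#' @export
FEATURE_NAMES <- c("shape_index", "ddc", "hydropathy", "electrostatics", "hbond")

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
              ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9,
              TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5,
              ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)

# coarse formal charges on charged side-chain heavy atoms at pH 7
CHARGE_TABLE <- tibble::tribble(
  ~residue_name, ~name, ~charge,
  "LYS", "NZ",  1,
  "ARG", "CZ",  1,
  "ASP", "CG", -1,
  "GLU", "CD", -1)

# hydrogen-bond roles: +1 donor, -1 acceptor, per residue/atom name;
# backbone N is a donor and backbone O an acceptor for every residue ("*")
HBOND_ROLES <- tibble::tribble(
  ~residue_name, ~name, ~role,
  "*",   "N",    1,
  "*",   "O",   -1,
  "LYS", "NZ",   1,
  "ARG", "NE",   1,
  "ARG", "NH1",  1,
  "ARG", "NH2",  1,
  "ASP", "OD1", -1,
  "ASP", "OD2", -1,
  "GLU", "OE1", -1,
  "GLU", "OE2", -1,
  "SER", "OG",   1,
  "THR", "OG1",  1,
  "TYR", "OH",   1,
  "ASN", "ND2",  1,
  "ASN", "OD1", -1,
  "GLN", "NE2",  1,
  "GLN", "OE1", -1,
  "HIS", "ND1", -1,
  "HIS", "NE2",  1,
  "TRP", "NE1",  1)

#' Shape index per vertex
#'
#' Normalized curvature descriptor s = (2/pi) atan((k1 + k2) / (k1 - k2))
#' with principal curvatures k1 >= k2 estimated from a local quadric fit in
#' the outward-normal frame over the 2-ring neighborhood. Convention:
#' outward-convex protrusions give +1, concave cups -1, saddles 0; umbilic
#' points (k1 = k2) give sign(k1).
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of length V in [-1, 1]; isolated vertices get 0
#'   with a warning.
#' @export
shape_index <- function(mesh) {
  V <- mesh$vertices
  n <- mesh$normals
  nb1 <- vertex_neighbors(mesh$faces, nrow(V))
  s <- numeric(nrow(V))
  isolated <- FALSE
  for (v in seq_len(nrow(V))) {
    ring1 <- nb1[[v]]
    if (length(ring1) == 0) { isolated <- TRUE; next }
    ring2 <- unique(c(ring1, unlist(nb1[ring1], use.names = FALSE)))
    ring2 <- setdiff(ring2, v)
    nv <- n[v, ]
    # local tangent frame
    t1 <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - nv * sum(t1 * nv)
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nv[2] * t1[3] - nv[3] * t1[2],
            nv[3] * t1[1] - nv[1] * t1[3],
            nv[1] * t1[2] - nv[2] * t1[1])
    d <- sweep(V[ring2, , drop = FALSE], 2, V[v, ])
    u <- d %*% cbind(t1, t2, nv)
    if (nrow(u) < 5) { s[v] <- 0; next }
    X <- cbind(u[, 1]^2, u[, 1] * u[, 2], u[, 2]^2, u[, 1], u[, 2])
    fit <- tryCatch(qr.solve(crossprod(X) + diag(1e-10, 5), crossprod(X, u[, 3])),
                    error = function(e) NULL)
    if (is.null(fit)) { s[v] <- 0; next }
    a <- fit[1]; b <- fit[2]; cc <- fit[3]; dd <- fit[4]; ee <- fit[5]
    den <- sqrt(1 + dd^2 + ee^2)
    # first and second fundamental forms of z = h(u1, u2)
    E <- 1 + dd^2; Fc <- dd * ee; G <- 1 + ee^2
    L <- 2 * a / den; M <- b / den; N <- 2 * cc / den
    S <- solve(matrix(c(E, Fc, Fc, G), 2), matrix(c(L, M, M, N), 2))
    k <- sort(Re(eigen(S, only.values = TRUE)$values), decreasing = TRUE)
    # height was measured along the outward normal: flip so convex => k > 0
    k <- sort(-k, decreasing = TRUE)
    k1 <- k[1]; k2 <- k[2]
    if (abs(k1 - k2) < 1e-9) s[v] <- sign(k1)
    else s[v] <- (2 / pi) * atan((k1 + k2) / (k1 - k2))
  }
  if (isolated) rlang::warn("isolated vertices present; their shape index is 0")
  clip_unit(s)
}

#' Distance-dependent curvature of patch members
#'
#' For member i of a patch centered at c with outward unit normal n_c,
#' ddc_i = clip(2 <p_i - p_c, n_c> / ||p_i - p_c||^2 * r_patch, -1, 1) - the
#' signed curvature of the circle tangent at the center passing through the
#' member, scaled by the patch radius. The center itself gets 0; members of
#' a planar patch get 0; members curving away from the outward normal (a
#' convex cap seen from its apex) get negative values.
#'
#' @param patch a patch (see [extract_patch()]).
#' @param mesh the owning [surface_mesh()].
#' @param r_patch patch radius, Angstrom (default 9).
#' @return numeric vector over patch members (padding slots get 0).
#' @export
distance_dependent_curvature <- function(patch, mesh, r_patch = 9) {
  pc <- mesh$vertices[patch$center, ]
  nc <- mesh$normals[patch$center, ]
  p <- mesh$vertices[patch$members, , drop = FALSE]
  d <- sweep(p, 2, pc)
  d2 <- rowSums(d^2)
  val <- ifelse(d2 < 1e-12, 0, 2 * (d %*% nc) / d2 * r_patch)
  val[!patch$mask] <- 0
  clip_unit(as.numeric(val))
}

#' Hydropathy per vertex
#'
#' Kyte-Doolittle index of the vertex's nearest residue, scaled by 4.5 to
#' [-1, 1] (ILE +1, ARG -1); unknown residue names map to 0.
#'
#' @param mesh a [surface_mesh()] with nearest residues assigned.
#' @param structure the owning `surfibs_structure`.
#' @return numeric vector of length V.
#' @export
hydropathy <- function(mesh, structure) {
  stopifnot(!is.null(mesh$nearest_residue))
  resn <- structure$residues$residue_name[mesh$nearest_residue]
  kd <- unname(KD_SCALE[resn])
  kd[is.na(kd)] <- 0
  clip_unit(kd / 4.5)
}

#' Screened-Coulomb electrostatic potential per vertex
#'
#' Debye-screened Coulomb potential of coarse formal side-chain charges
#' (LYS/ARG +1, ASP/GLU -1), evaluated at each vertex, robust-scaled by the
#' 97.5th percentile of |phi| over the protein and clipped to [-1, 1]. The
#' Debye length follows water at room temperature:
#' lambda_D = 3.04 / sqrt(I) Angstrom with I in mol/L.
#'
#' @param mesh a [surface_mesh()].
#' @param structure the owning `surfibs_structure`.
#' @param ionic_strength mol/L (default 0.15).
#' @param precomputed optional externally computed per-vertex potential
#'   (e.g. from a Poisson-Boltzmann solver); when given it is robust-scaled
#'   and clipped in place of the internal surrogate.
#' @return numeric vector of length V.
#' @export
electrostatics <- function(mesh, structure, ionic_strength = 0.15,
                           precomputed = NULL) {
  if (!is.null(precomputed)) {
    stopifnot(length(precomputed) == nrow(mesh$vertices))
    return(robust_unit_scale(precomputed))
  }
  a <- dplyr::inner_join(structure$atoms, CHARGE_TABLE,
                         by = c("residue_name", "name"))
  if (nrow(a) == 0) return(numeric(nrow(mesh$vertices)))
  kappa <- sqrt(ionic_strength) / 3.04 # inverse Debye length, 1/Angstrom
  Vx <- mesh$vertices
  d <- sqrt(pmax(outer(rowSums(Vx^2), rowSums(as.matrix(a[, c("x", "y", "z")])^2), "+") -
                   2 * Vx %*% t(as.matrix(a[, c("x", "y", "z")])), 0))
  d[d < 0.1] <- 0.1
  phi <- as.numeric((exp(-kappa * d) / d) %*% a$charge)
  robust_unit_scale(phi)
}

robust_unit_scale <- function(x) {
  sc <- stats::quantile(abs(x), 0.975, names = FALSE)
  if (sc <= 0) return(numeric(length(x)))
  clip_unit(x / sc)
}

#' Hydrogen-bond potential per vertex
#'
#' The nearest polar heavy atom (N/O with a donor or acceptor role from the
#' bundled per-residue table) within 3.5 Angstrom sets the sign (+1 donor,
#' -1 acceptor) and a Gaussian of the vertex-atom distance sets the
#' magnitude: role * exp(-(d - d0)^2 / (2 sigma^2)) with d0 = 1.5 A (probe
#' contact) and sigma = 1 A. Vertices with no polar atom within 3.5 A get 0.
#'
#' @inheritParams hydropathy
#' @param cutoff search radius in Angstrom (default 3.5).
#' @param d0,sigma Gaussian peak position and width, Angstrom.
#' @return numeric vector of length V.
#' @export
hbond_potential <- function(mesh, structure, cutoff = 3.5, d0 = 1.5, sigma = 1.0) {
  atoms <- structure$atoms
  side <- dplyr::inner_join(atoms, HBOND_ROLES[HBOND_ROLES$residue_name != "*", ],
                            by = c("residue_name", "name"))
  bb_roles <- HBOND_ROLES[HBOND_ROLES$residue_name == "*", ]
  bb <- dplyr::inner_join(atoms, bb_roles[, c("name", "role")], by = "name")
  bb <- bb[bb$residue_name %in% names(KD_SCALE), ] # backbone of amino acids only
  polar <- dplyr::bind_rows(side, bb)
  if (nrow(polar) == 0) return(numeric(nrow(mesh$vertices)))
  Vx <- mesh$vertices
  px <- as.matrix(polar[, c("x", "y", "z")])
  d2 <- outer(rowSums(Vx^2), rowSums(px^2), "+") - 2 * Vx %*% t(px)
  nearest <- max.col(-d2, ties.method = "first")
  d <- sqrt(pmax(d2[cbind(seq_len(nrow(Vx)), nearest)], 0))
  val <- polar$role[nearest] * exp(-(d - d0)^2 / (2 * sigma^2))
  val[d > cutoff] <- 0
  clip_unit(val)
}

#' Assemble the per-vertex feature table
#'
#' Fixed column order: shape_index, ddc, hydropathy, electrostatics, hbond.
#' The stored ddc column is the center-free vertex value 0; patch assembly
#' ([extract_patch()]) overwrites it with the patch-relative value.
#'
#' @inheritParams hydropathy
#' @param ionic_strength passed to [electrostatics()].
#' @param precomputed_electrostatics optional per-vertex override.
#' @return a tibble with `vertex` plus the five feature columns, all values
#'   in [-1, 1].
#' @export
assemble_features <- function(mesh, structure, ionic_strength = 0.15,
                              precomputed_electrostatics = NULL) {
  tibble(vertex = seq_len(nrow(mesh$vertices)),
         shape_index = shape_index(mesh),
         ddc = 0,
         hydropathy = hydropathy(mesh, structure),
         electrostatics = electrostatics(mesh, structure, ionic_strength,
                                         precomputed_electrostatics),
         hbond = hbond_potential(mesh, structure))
}
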