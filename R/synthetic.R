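# Synthetic fixtures: analytic meshes, toy helical proteins, planted-IBS
# datasets carrying the statistical structure the network must learn, and
# toy membrane-approach trajectories. Every generator is a pure function of
# its seed.

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with all vertices projected
#' to the sphere; V = 10 * 4^s + 2.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius, Angstrom.
#' @param center optional 3-vector center.
#' @return a [surface_mesh()] with outward orientation.
#' @export
make_icosphere <- function(subdivisions = 2, radius = 1, center = c(0, 0, 0)) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (V[a, ] + V[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      V <<- rbind(V, m)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    newF <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    F <- newF
  }
  surface_mesh(sweep(V * radius, 2, center, "+"), F)
}

TOY_COMPOSITION <- list(
  hydrophobic = c("LEU", "ILE", "VAL", "PHE", "ALA"),
  polar = c("SER", "THR", "ASN", "GLN"),
  charged = c("LYS", "ARG", "ASP", "GLU"))

# representative side-chain tip atom per residue type (element, radial reach)
TOY_TIPS <- tibble::tribble(
  ~residue_name, ~name, ~reach,
  "LYS", "NZ",  3.5,
  "ARG", "CZ",  3.4,
  "ASP", "CG",  1.9,
  "GLU", "CD",  2.6,
  "SER", "OG",  1.4,
  "THR", "OG1", 1.4,
  "ASN", "ND2", 2.2,
  "GLN", "NE2", 2.9,
  "LEU", "CD1", 2.2,
  "ILE", "CD1", 2.6,
  "VAL", "CG1", 1.5,
  "PHE", "CZ",  3.4)

#' Toy helical protein
#'
#' Ideal-helix backbone (rise 1.5 Angstrom, twist 100 degrees, radius 2.3)
#' with N/CA/C/O backbone atoms, a CB and a representative side-chain tip
#' atom per residue. Residue identities are drawn 50% hydrophobic, 30%
#' polar, 20% charged.
#'
#' @param n_residues number of residues (>= 1).
#' @param seed RNG seed; a fixed seed gives byte-identical PDB text.
#' @param chain chain identifier.
#' @return list with `structure` (a `surfibs_structure`) and `pdb` (the
#'   PDB lines).
#' @export
make_toy_protein <- function(n_residues, seed = 1, chain = "A") {
  stopifnot(n_residues >= 1)
  resn <- with_seed(sub_seed(seed, "toyprot"), {
    cls <- sample(c("hydrophobic", "polar", "charged"), n_residues,
                  replace = TRUE, prob = c(0.5, 0.3, 0.2))
    vapply(cls, function(k) sample(TOY_COMPOSITION[[k]], 1), character(1))
  })
  rows <- list()
  serial <- 0
  for (i in seq_len(n_residues)) {
    th <- (i - 1) * 100 * pi / 180
    u <- c(cos(th), sin(th), 0) # radial direction
    tgt <- c(-sin(th), cos(th), 0)
    ca <- 2.3 * u + c(0, 0, 1.5 * (i - 1))
    add <- function(name, element, pos) {
      serial <<- serial + 1
      rows[[length(rows) + 1]] <<- tibble(
        serial = serial, name = name, element = element,
        residue_name = resn[i], residue_index = as.character(i),
        chain_id = chain, x = pos[1], y = pos[2], z = pos[3],
        is_heavy = element != "H")
    }
    add("N", "N", ca - 0.8 * tgt + c(0, 0, -0.9))
    add("CA", "C", ca)
    add("C", "C", ca + 0.8 * tgt + c(0, 0, 0.6))
    add("O", "O", ca + 1.2 * tgt + c(0, 0, 1.5))
    add("CB", "C", ca + 1.5 * u)
    tip <- TOY_TIPS[TOY_TIPS$residue_name == resn[i], ]
    if (nrow(tip) == 1)
      add(tip$name, substr(tip$name, 1, 1), ca + (1.5 + tip$reach) * u)
  }
  st <- as_structure(dplyr::bind_rows(rows))
  list(structure = st, pdb = c(write_pdb(st), "END"))
}

#' Planted-IBS dataset configuration
#'
#' @param n_proteins number of synthetic proteins (default 20).
#' @param vertices_per_protein approximate mesh size; realized as the
#'   closest icosphere subdivision (default 642).
#' @param cap_fraction fraction of the surface area labelled IBS (default
#'   0.15; IBS regions are small, non-binding surface dominates).
#' @param feature_shift additive offset applied to hydropathy and shape
#'   index inside the cap (default +0.6).
#' @param noise_sd Gaussian feature noise (default 0.3).
#' @param sphere_radius base sphere radius, Angstrom (default 12).
#' @param seed master seed.
#' @return list of class `surfibs_plant_config`.
#' @export
plant_config <- function(n_proteins = 20, vertices_per_protein = 642,
                         cap_fraction = 0.15, feature_shift = 0.6,
                         noise_sd = 0.3, sphere_radius = 12, seed = 1) {
  if (cap_fraction <= 0 || cap_fraction >= 0.5)
    stop_surfibs("cap_fraction must be in (0, 0.5)")
  structure(list(n_proteins = n_proteins,
                 vertices_per_protein = vertices_per_protein,
                 cap_fraction = cap_fraction, feature_shift = feature_shift,
                 noise_sd = noise_sd, sphere_radius = sphere_radius,
                 seed = as.integer(seed)),
            class = "surfibs_plant_config")
}

#' Planted-IBS synthetic dataset
#'
#' Each protein is a bumpy sphere whose geodesic cap (a fraction of the
#' surface area, in a random direction) is labelled IBS. All five features
#' are noise except that hydropathy and shape index are shifted upward
#' inside the cap - a hydrophobic, protrusion-like signal. The cap
#' direction octant tags eight pseudo-superfamilies for grouped splits.
#'
#' @param config a [plant_config()].
#' @param with_patches also compute the geodesic patch decomposition
#'   (default `TRUE`; needed for training).
#' @param radius,max_points patch parameters (defaults 9 Angstrom / 100).
#' @return list of proteins, each a list with id, group, mesh, features
#'   tibble, labels (binary per vertex) and (optionally) patches.
#' @export
make_planted_dataset <- function(config = plant_config(), with_patches = TRUE,
                                 radius = 9, max_points = 100) {
  subdiv <- which.min(abs(10 * 4^(0:5) + 2 - config$vertices_per_protein)) - 1
  lapply(seq_len(config$n_proteins), function(i) {
    seed_i <- sub_seed(config$seed, paste0("planted", i))
    with_seed(seed_i, {
      mesh0 <- make_icosphere(subdiv, radius = 1)
      nv <- nrow(mesh0$vertices)
      # smooth radial bumps: a few random spherical Gaussians
      ctr <- matrix(rnorm(6 * 3), 6)
      ctr <- ctr / sqrt(rowSums(ctr^2))
      amp <- runif(6, -0.06, 0.06)
      ang <- acos(pmin(pmax(mesh0$vertices %*% t(ctr), -1), 1))
      bump <- as.numeric(exp(-(ang / 0.5)^2) %*% amp)
      r <- config$sphere_radius * (1 + bump)
      mesh <- surface_mesh(mesh0$vertices * r, mesh0$faces)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cap_angle <- acos(1 - 2 * config$cap_fraction)
      vang <- acos(pmin(1, pmax(-1, as.numeric(mesh0$vertices %*% u))))
      labels <- as.integer(vang <= cap_angle)
      feat <- matrix(rnorm(nv * 5, sd = config$noise_sd), nv, 5,
                     dimnames = list(NULL, FEATURE_NAMES))
      feat[labels == 1, "hydropathy"] <- feat[labels == 1, "hydropathy"] + config$feature_shift
      feat[labels == 1, "shape_index"] <- feat[labels == 1, "shape_index"] + config$feature_shift
      feat <- clip_unit(feat)
      features <- tibble::as_tibble(cbind(vertex = seq_len(nv), feat))
      group <- paste0("octant_", paste(as.integer(u > 0), collapse = ""))
      out <- list(id = sprintf("planted_%03d", i), group = group, mesh = mesh,
                  features = features, labels = labels)
      if (with_patches)
        out$patches <- surface_patches(mesh, features, radius = radius,
                                       max_points = max_points,
                                       seed = sub_seed(seed_i, "axes"))
      out
    })
  })
}

#' Toy membrane-approach trajectory
#'
#' Builds a planar pseudo-membrane of truncated-lipid residues (P at z = 0,
#' C1 at z = -2, 0.5 Angstrom lateral grid) and translates the protein frame
#' by frame toward it so that in the final frame exactly the requested
#' residues have a heavy atom within 4.9 Angstrom of membrane heavy atoms
#' while all others stay at 6 Angstrom or more. The protein is laid on its
#' helix side; rotations about the axis are searched for a pose in which
#' the requested residues form one face - otherwise the request is
#' geometrically infeasible and an error is raised. An empty contact set
#' produces a trajectory that never binds.
#'
#' @param protein a `surfibs_structure` from [make_toy_protein()].
#' @param contact_residues character vector of residue indices (author
#'   numbering) that must be in contact; may be empty.
#' @param n_frames number of approach frames (default 5).
#' @param seed RNG seed (jitters nothing at present; kept for interface
#'   stability).
#' @param retreat_frames frames appended after the bound frame with the
#'   protein moved back out of contact (default 0), exercising the
#'   last-bound-frame rule.
#' @param lipid_resname residue name used for membrane residues.
#' @return list with `trajectory` (structure + frames, as
#'   [read_trajectory()] returns), `pdb` (multi-MODEL PDB lines) and
#'   `membrane_residues` (selector for [md_contact_labels()]).
#' @export
make_toy_trajectory <- function(protein, contact_residues, n_frames = 5,
                                seed = 1, retreat_frames = 0,
                                lipid_resname = "MLP") {
  a <- protein$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  contact_residues <- as.character(contact_residues)
  if (!all(contact_residues %in% protein$residues$residue_index))
    stop_surfibs("contact_residues not present in the protein")
  is_contact_res <- protein$residues$residue_index[a$residue] %in% contact_residues
  # lay the helix axis (z) along x, then search the roll angle
  lay <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))
  best <- NULL
  if (length(contact_residues) > 0) {
    for (phi in seq(0, 2 * pi, length.out = 181)[-181]) {
      rot <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)), c(0, sin(phi), cos(phi))) %*% lay
      p <- xyz %*% t(rot)
      zmin <- tapply(p[a$is_heavy, 3], a$residue[a$is_heavy], min)
      cset <- names(zmin) %in%
        protein$residues$residue[protein$residues$residue_index %in% contact_residues]
      gap <- min(zmin[!cset]) - max(zmin[cset])
      if (is.null(best) || gap > best$gap) best <- list(gap = gap, rot = rot)
    }
    if (best$gap < 1.16)
      stop_surfibs("requested contact residues do not lie on one face of the protein")
  } else {
    best <- list(rot = lay, gap = Inf)
  }
  p <- xyz %*% t(best$rot)
  zmin_all <- min(p[a$is_heavy, 3])
  bound_shift <- if (length(contact_residues) > 0) {
    zc <- tapply(p[a$is_heavy & is_contact_res, 3],
                 a$residue[a$is_heavy & is_contact_res], min)
    4.85 - max(zc) # deepest point of the shallowest contact residue at 4.85 A
  } else 8 - zmin_all # never closer than 8 A
  # membrane grid under the protein footprint
  gx <- seq(min(p[, 1]) - 6, max(p[, 1]) + 6, by = 0.5)
  gy <- seq(min(p[, 2]) - 6, max(p[, 2]) + 6, by = 0.5)
  grid <- expand.grid(x = gx, y = gy)
  nm <- nrow(grid)
  mem <- tibble(
    serial = max(a$serial) + seq_len(2 * nm),
    name = rep(c("P", "C1"), nm),
    element = rep(c("P", "C"), nm),
    residue_name = lipid_resname,
    residue_index = as.character(rep(seq_len(nm), each = 2)),
    chain_id = "M",
    x = rep(grid$x, each = 2), y = rep(grid$y, each = 2),
    z = rep(c(0, -2), nm), is_heavy = TRUE)
  frames <- list()
  total <- n_frames + retreat_frames
  for (f in seq_len(n_frames)) {
    dz <- bound_shift + (n_frames - f) * 5
    frames[[f]] <- rbind(cbind(p[, 1], p[, 2], p[, 3] + dz),
                         as.matrix(mem[, c("x", "y", "z")]))
  }
  for (f in seq_len(retreat_frames)) {
    dz <- bound_shift + f * 5
    frames[[n_frames + f]] <- rbind(cbind(p[, 1], p[, 2], p[, 3] + dz),
                                    as.matrix(mem[, c("x", "y", "z")]))
  }
  atoms0 <- dplyr::bind_rows(a, mem)
  lines <- character(0)
  for (f in seq_len(total)) {
    atoms_f <- atoms0
    atoms_f$x <- frames[[f]][, 1]; atoms_f$y <- frames[[f]][, 2]
    atoms_f$z <- frames[[f]][, 3]
    st_f <- as_structure(atoms_f)
    lines <- c(lines, write_pdb(st_f, model = f))
  }
  lines <- c(lines, "END")
  st <- as_structure(atoms0)
  # frames must follow the structure's atom ordering (as_structure keeps
  # input order), which matches atoms0 row order
  list(trajectory = list(structure = st, frames = frames), pdb = lines,
       membrane_residues = lipid_resname)
}
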