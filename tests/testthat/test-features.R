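# Per-vertex surface features

grid_mesh <- function(f, xs, ys) {
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, f(g$x, g$y))
  nx <- length(xs); ny <- length(ys)
  F <- NULL
  for (iy in 1:(ny - 1)) for (ix in 1:(nx - 1)) {
    a <- (iy - 1) * nx + ix
    F <- rbind(F, c(a, a + 1, a + nx + 1), c(a, a + nx + 1, a + nx))
  }
  surface_mesh(V, F)
}

test_that("shape index hits the closed forms: sphere +1, saddle 0, cylinder +0.5", {
  sph <- make_icosphere(2, radius = 5)
  expect_true(all(abs(shape_index(sph) - 1) < 0.05))

  sad <- grid_mesh(function(x, y) (x^2 - y^2) / 2,
                   seq(-1, 1, by = 0.1), seq(-1, 1, by = 0.1))
  ctr <- which(abs(sad$vertices[, 1]) < 0.3 & abs(sad$vertices[, 2]) < 0.3)
  expect_true(all(abs(shape_index(sad)[ctr]) < 0.1))

  th <- seq(0, 2 * pi, length.out = 41)[-41]
  z <- seq(0, 10, by = 0.5)
  g <- expand.grid(t = th, z = z)
  nt <- length(th)
  F <- NULL
  for (iz in 1:(length(z) - 1)) for (it in 1:nt) {
    a <- (iz - 1) * nt + it; b <- (iz - 1) * nt + (it %% nt) + 1
    cc <- iz * nt + it; d <- iz * nt + (it %% nt) + 1
    F <- rbind(F, c(a, b, d), c(a, d, cc))
  }
  cyl <- surface_mesh(cbind(3 * cos(g$t), 3 * sin(g$t), g$z), F)
  interior <- which(g$z > 2 & g$z < 8)
  expect_true(all(abs(shape_index(cyl)[interior] - 0.5) < 0.1))
})

test_that("shape index values stay in [-1, 1] and concentrate at +1 on a sphere", {
  s <- shape_index(make_icosphere(3, radius = 8))
  expect_true(all(s >= -1 & s <= 1))
  expect_gt(mean(s > 0.9), 0.99)
})

test_that("distance-dependent curvature: flat 0, sphere closed form, center 0", {
  # planar patch
  flat <- grid_mesh(function(x, y) 0 * x, seq(-4, 4), seq(-4, 4))
  fe <- tibble::tibble(vertex = seq_len(nrow(flat$vertices)), shape_index = 0,
                       ddc = 0, hydropathy = 0, electrostatics = 0, hbond = 0)
  ctr <- which(flat$vertices[, 1] == 0 & flat$vertices[, 2] == 0)
  p <- extract_patch(flat, fe, ctr, radius = 4)
  expect_true(all(abs(p$features[, "ddc"]) < 1e-9))

  # sphere of radius R: chord-normal ratio gives -r_patch / R for every member
  R <- 15
  sph <- make_icosphere(3, radius = R)
  fes <- tibble::tibble(vertex = seq_len(nrow(sph$vertices)), shape_index = 0,
                        ddc = 0, hydropathy = 0, electrostatics = 0, hbond = 0)
  ps <- extract_patch(sph, fes, 1, radius = 9)
  members <- ps$mask & ps$rho > 1 # exclude the center itself
  # brute force from analytic sphere coordinates: 2 <p - pc, n> / |p - pc|^2
  pc <- sph$vertices[1, ]; nc <- pc / sqrt(sum(pc^2))
  d <- sweep(sph$vertices[ps$members[members], , drop = FALSE], 2, pc)
  oracle <- 2 * (d %*% nc) / rowSums(d^2) * 9
  expect_equal(as.numeric(ps$features[members, "ddc"]), as.numeric(oracle),
               tolerance = 1e-9)
  expect_true(all(abs(oracle + 9 / R) < 0.02)) # analytic value -r_patch/R
  expect_equal(ps$features[1, "ddc"][[1]], 0) # center convention
})

test_that("hydropathy is the Kyte-Doolittle value of the nearest residue over 4.5", {
  mk <- function(resn) {
    st <- surfibs:::as_structure(tibble::tibble(
      serial = 1L, name = "CA", element = "C", residue_name = resn,
      residue_index = "1", chain_id = "A", x = 0, y = 0, z = 0, is_heavy = TRUE))
    mesh <- assign_nearest_residue(
      surface_mesh(diag(3) * 4, matrix(c(1, 2, 3), 1)), st)
    hydropathy(mesh, st)[1]
  }
  expect_equal(mk("ILE"), 1.0)
  expect_equal(mk("ARG"), -1.0)
  expect_equal(mk("GLY"), -0.4 / 4.5, tolerance = 1e-6)
  expect_equal(mk("XXX"), 0)
})

test_that("screened-Coulomb electrostatics: zeros, single-source monotone, antisymmetric pair", {
  sph <- make_icosphere(2, radius = 10)
  neutral <- surfibs:::as_structure(tibble::tibble(
    serial = 1L, name = "CA", element = "C", residue_name = "ALA",
    residue_index = "1", chain_id = "A", x = 0, y = 0, z = 0, is_heavy = TRUE))
  expect_true(all(electrostatics(sph, neutral) == 0))

  lys <- surfibs:::as_structure(tibble::tibble(
    serial = 1:2, name = c("CA", "NZ"), element = c("C", "N"),
    residue_name = "LYS", residue_index = "1", chain_id = "A",
    x = c(0, 3), y = 0, z = 0, is_heavy = TRUE))
  offset_sph <- make_icosphere(2, radius = 10, center = c(3, 0, 0))
  phi <- electrostatics(offset_sph, lys)
  expect_true(all(phi >= 0))
  d <- sqrt(rowSums(sweep(offset_sph$vertices, 2, c(3, 0, 0))^2))
  expect_true(all(diff(phi[order(d)]) < 1e-9)) # non-increasing with distance

  pair <- surfibs:::as_structure(tibble::tibble(
    serial = 1:2, name = c("NZ", "CG"), element = c("N", "C"),
    residue_name = c("LYS", "ASP"), residue_index = c("1", "2"),
    chain_id = "A", x = c(-2, 2), y = 0, z = 0, is_heavy = TRUE))
  # mirror-symmetric probe points across the x = 0 plane
  probe <- surface_mesh(rbind(c(5, 1, 0), c(-5, 1, 0), c(6, 0, 2), c(-6, 0, 2)),
                        rbind(c(1, 3, 2), c(2, 3, 4)))
  phi2 <- electrostatics(probe, pair)
  expect_equal(phi2[1], -phi2[2], tolerance = 1e-6)
  expect_equal(phi2[3], -phi2[4], tolerance = 1e-6)
})

test_that("hydrogen-bond potential peaks at the contact distance with role sign", {
  donor <- surfibs:::as_structure(tibble::tibble(
    serial = 1L, name = "NZ", element = "N", residue_name = "LYS",
    residue_index = "1", chain_id = "A", x = 0, y = 0, z = 0, is_heavy = TRUE))
  probe <- function(dist) surface_mesh(rbind(c(dist, 0, 0), c(dist, 1, 0),
                                             c(dist, 0, 1)),
                                       matrix(c(1, 2, 3), 1))
  expect_equal(hbond_potential(probe(1.5), donor)[1], 1.0)
  acceptor <- surfibs:::as_structure(tibble::tibble(
    serial = 1L, name = "OE1", element = "O", residue_name = "GLU",
    residue_index = "1", chain_id = "A", x = 0, y = 0, z = 0, is_heavy = TRUE))
  expect_equal(hbond_potential(probe(1.5), acceptor)[1], -1.0)
  expect_equal(hbond_potential(probe(5), donor)[1], 0) # beyond 3.5 A cutoff
})

test_that("assembled features are bounded and rigid-motion invariant", {
  tp <- toy_protein_fixture()
  mesh <- toy_surface_fixture()
  fe <- assemble_features(mesh, tp$structure)
  fm <- as.matrix(fe[, FEATURE_NAMES])
  expect_true(all(fm >= -1 & fm <= 1))

  # rotate + translate structure and mesh jointly
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  t0 <- c(5, -3, 2)
  st2 <- tp$structure
  xyz <- as.matrix(st2$atoms[, c("x", "y", "z")]) %*% t(R)
  st2$atoms$x <- xyz[, 1] + t0[1]
  st2$atoms$y <- xyz[, 2] + t0[2]
  st2$atoms$z <- xyz[, 3] + t0[3]
  mesh2 <- surface_mesh(sweep(mesh$vertices %*% t(R), 2, t0, "+"), mesh$faces,
                        nearest_residue = mesh$nearest_residue)
  fe2 <- assemble_features(mesh2, st2)
  expect_equal(as.matrix(fe2[, FEATURE_NAMES]), fm, tolerance = 1e-5)
})

test_that("hydropathy depends only on the nearest-residue assignment", {
  tp <- toy_protein_fixture()
  mesh <- toy_surface_fixture()
  h1 <- hydropathy(mesh, tp$structure)
  st2 <- tp$structure
  perm <- rev(seq_len(nrow(st2$atoms)))
  st2 <- surfibs:::as_structure(st2$atoms[perm, ])
  mesh2 <- assign_nearest_residue(mesh, st2)
  expect_equal(hydropathy(mesh2, st2), h1)
})
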