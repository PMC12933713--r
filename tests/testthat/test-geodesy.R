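# Geodesic distances, patch extraction and polar coordinates

null_features <- function(nv) {
  tibble::tibble(vertex = seq_len(nv), shape_index = 0, ddc = 0,
                 hydropathy = 0, electrostatics = 0, hbond = 0)
}

test_that("geodesic distances on a path graph are the cumulative edge lengths", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 0)),
                       rbind(c(1, 2, 4), c(2, 3, 4)))
  d <- geodesic_distances(mesh, 1, cap = 9)
  expect_equal(unname(d[c("1", "2", "3")]), c(0, 1, 2))
  expect_error(geodesic_distances(mesh, 9), "out of range")
})

test_that("Dijkstra distances equal the Floyd-Warshall oracle on random meshes", {
  for (seed in 1:3) {
    mesh <- random_test_mesh(30, seed = seed)
    nv <- nrow(mesh$vertices)
    e <- mesh_edges(mesh)
    D_oracle <- floyd_warshall(nv, geodesic_edges(mesh))
    g <- surfibs:::mesh_graph(mesh)
    for (src in c(1, 7, nv)) {
      d <- geodesic_distances(mesh, src, cap = Inf, graph = g)
      full <- rep(Inf, nv)
      full[as.integer(names(d))] <- d
      expect_equal(full, D_oracle[src, ], tolerance = 1e-12)
    }
  }
})

test_that("mesh geodesics track great-circle arcs within 5% on a dense icosphere", {
  mesh <- make_icosphere(5, radius = 1)
  g <- surfibs:::mesh_graph(mesh)
  d <- geodesic_distances(mesh, 1, cap = Inf, graph = g)
  full <- rep(NA_real_, nrow(mesh$vertices))
  full[as.integer(names(d))] <- d
  arc <- acos(pmin(pmax(mesh$vertices %*% mesh$vertices[1, ], -1), 1))
  sel <- which(arc > 0.05 & arc <= pi / 3)
  rel <- abs(full[sel] - arc[sel]) / arc[sel]
  expect_lt(mean(rel), 0.05)
})

test_that("sampled triples satisfy the triangle inequality", {
  mesh <- random_test_mesh(30, seed = 9)
  g <- surfibs:::mesh_graph(mesh)
  D <- igraph::distances(g, algorithm = "dijkstra")
  withr::with_seed(4, {
    for (rep in 1:200) {
      ijk <- sample(nrow(D), 3)
      expect_lte(D[ijk[1], ijk[3]], D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
    }
  })
})

test_that("patch membership, capping and padding follow the contract", {
  mesh <- make_icosphere(2, radius = 4) # compact: everything within 9 A
  nv <- nrow(mesh$vertices)
  fe <- null_features(nv)
  p <- extract_patch(mesh, fe, 5, radius = 9, max_points = 200)
  expect_equal(sum(p$mask), sum(!is.na(geodesic_distances(mesh, 5, 9))))
  expect_equal(length(p$members), 200)
  expect_true(all(p$rho[!p$mask] == 9))
  expect_true(all(p$features[!p$mask, ] == 0))
  expect_false(is.unsorted(p$rho[p$mask]))
  expect_equal(p$members[1], 5)

  # cap selects exactly the geodesically nearest max_points (sorted oracle)
  big <- make_icosphere(3, radius = 6)
  feb <- null_features(nrow(big$vertices))
  d <- as.numeric(igraph::distances(surfibs:::mesh_graph(big), v = 10))
  expect_gt(sum(d <= 9), 100) # more candidates than the cap
  pb <- extract_patch(big, feb, 10, radius = 9, max_points = 100)
  oracle <- order(d, seq_along(d))[1:100]
  expect_setequal(pb$members[pb$mask], oracle)

  p0 <- extract_patch(mesh, fe, 3, radius = 0)
  expect_equal(sum(p0$mask), 1)
  expect_equal(p0$members[1], 3)
})

test_that("patch extraction is deterministic", {
  mesh <- make_icosphere(2, radius = 6)
  fe <- null_features(nrow(mesh$vertices))
  p1 <- extract_patch(mesh, fe, 17)
  p2 <- extract_patch(mesh, fe, 17)
  expect_identical(p1, p2)
})

test_that("polar coordinates embed a planar disc with negligible stress", {
  flat <- surface_mesh(
    cbind(as.matrix(expand.grid(x = seq(-4, 4), y = seq(-4, 4))), 0),
    { nx <- 9; F <- NULL
      for (iy in 1:(nx - 1)) for (ix in 1:(nx - 1)) {
        a <- (iy - 1) * nx + ix
        F <- rbind(F, c(a, a + 1, a + nx + 1), c(a, a + nx + 1, a + nx))
      }; F })
  fe <- null_features(nrow(flat$vertices))
  ctr <- which(flat$vertices[, 1] == 0 & flat$vertices[, 2] == 0)
  p <- polar_coordinates(extract_patch(flat, fe, ctr, radius = 4), flat,
                         rng_seed = 1)
  m <- p$members[p$mask]
  D <- surfibs:::submesh_pairwise(flat, m)
  xy <- cbind(p$rho[p$mask] * cos(p$theta[p$mask]),
              p$rho[p$mask] * sin(p$theta[p$mask]))
  # the embedded pairwise distances reproduce the geodesic input
  E <- as.matrix(stats::dist(xy))
  stress <- sqrt(sum((E - D)^2) / sum(D^2))
  expect_lt(stress, 0.05)
})

test_that("changing the reference-axis seed rotates theta by a constant", {
  mesh <- make_icosphere(2, radius = 6)
  fe <- null_features(nrow(mesh$vertices))
  p0 <- extract_patch(mesh, fe, 11)
  pa <- polar_coordinates(p0, mesh, rng_seed = 1)
  pb <- polar_coordinates(p0, mesh, rng_seed = 2)
  m <- pa$mask & pa$rho > 1e-9
  delta <- (pa$theta[m] - pb$theta[m]) %% (2 * pi)
  expect_lt(max(delta) - min(delta), 1e-6)
})

test_that("degenerate patches fall back to theta = 0", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1))
  fe <- null_features(3)
  p <- extract_patch(mesh, fe, 1, radius = 1.1, max_points = 2)
  expect_equal(sum(p$mask), 2)
  p <- polar_coordinates(p, mesh, rng_seed = 5)
  expect_equal(p$theta, c(0, 0))
})

test_that("patch archives round trip through JSON with a version field", {
  mesh <- make_icosphere(1, radius = 6)
  fe <- null_features(nrow(mesh$vertices))
  ps <- surface_patches(mesh, fe, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_patches(ps, path)
  back <- read_patches(path)
  expect_equal(back$members, ps$members, ignore_attr = TRUE)
  expect_equal(back$rho, ps$rho, ignore_attr = TRUE)
  expect_equal(back$theta, ps$theta, ignore_attr = TRUE)
  expect_equal(back$feat, ps$feat, ignore_attr = TRUE)
  expect_equal(back$version, "1")
})
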