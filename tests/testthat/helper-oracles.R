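# Independent oracles and shared fixtures for the test suite.

# Floyd-Warshall all-pairs shortest paths (dense, O(V^3)); independent of
# the igraph-based implementation under test.
floyd_warshall <- function(nv, edges) {
  D <- matrix(Inf, nv, nv)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(nv)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# ray-casting point-in-mesh test (odd crossings along +x)
point_in_mesh <- function(mesh, p) {
  V <- mesh$vertices
  F <- mesh$faces
  dir <- c(1, 0.000123, 0.000457) # jittered to dodge edge hits
  hits <- 0
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c <- V[F[f, 3], ]
    e1 <- b - a; e2 <- c - a
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * h)
    if (abs(det) < 1e-12) next
    s <- p - a
    u <- sum(s * h) / det
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    v <- sum(dir * q) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) / det
    if (t > 1e-9) hits <- hits + 1
  }
  hits %% 2 == 1
}

# brute-force O(n^2) pairwise-comparison ROC AUC estimator
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# confusion-matrix MCC from explicit counts
mcc_from_counts <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# random closed-ish triangulated mesh for graph tests: jittered icosphere
random_test_mesh <- function(nv_target = 30, seed = 1) {
  withr::with_seed(seed, {
    m <- make_icosphere(1, radius = 5) # 42 vertices
    keep <- sort(sample(nrow(m$vertices), nv_target))
    # keep faces fully inside the sample, then largest component
    fk <- rowSums(matrix(m$faces %in% keep, ncol = 3)) == 3
    map <- integer(nrow(m$vertices)); map[keep] <- seq_along(keep)
    mesh <- surface_mesh(m$vertices[keep, ] + matrix(rnorm(3 * nv_target, sd = 0.2),
                                                     ncol = 3),
                         matrix(map[m$faces[fk, ]], ncol = 3))
    mesh
  })
}

# single shared fixture cache (expensive objects computed once per run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

toy_protein_fixture <- function() fixture("toy_protein", function() make_toy_protein(10, seed = 3))

toy_surface_fixture <- function() fixture("toy_surface", function() {
  tp <- toy_protein_fixture()
  assign_nearest_residue(build_surface(tp$structure), tp$structure)
})

# the planted study set used by the training-level acceptance checks
planted_fixture <- function() fixture("planted", function()
  make_planted_dataset(plant_config(n_proteins = 20, seed = 101)))

small_planted_fixture <- function() fixture("planted_small", function()
  make_planted_dataset(plant_config(n_proteins = 5, seed = 55)))
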