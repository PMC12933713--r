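# Label mapping between residue and surface level; MD contact labelling

test_that("residue labels propagate to exactly the owned vertices", {
  tp <- toy_protein_fixture()
  mesh <- toy_surface_fixture()
  st <- tp$structure
  all1 <- st$residues
  all1$label <- 1L
  sv <- residue_to_surface(mesh, all1, st)
  expect_true(all(sv$label == 1))

  one <- all1[4, ]
  sv1 <- residue_to_surface(mesh, one, st)
  expect_setequal(which(sv1$label == 1), which(mesh$nearest_residue == 4))

  ghost <- tibble::tibble(chain_id = "Z", residue_index = "99",
                          residue_name = "LYS", label = 1L)
  expect_warning(sv0 <- residue_to_surface(mesh, ghost, st), "not found")
  expect_true(all(sv0$label == 0))
})

test_that("surface-to-residue aggregation: max, mean, buried exclusion", {
  st <- surfibs:::as_structure(tibble::tibble(
    serial = 1:3, name = "CA", element = "C",
    residue_name = c("ALA", "GLY", "SER"), residue_index = c("1", "2", "3"),
    chain_id = "A", x = c(0, 10, 50), y = 0, z = 0, is_heavy = TRUE))
  mesh <- surface_mesh(rbind(c(0, 1, 0), c(0, -1, 0), c(10, 1, 0), c(10, 0, 1)),
                       rbind(c(1, 2, 3), c(2, 3, 4)))
  mesh <- assign_nearest_residue(mesh, st)
  sc <- c(0.2, 0.9, 0.55, 0.55)
  agg_max <- surface_to_residue(sc, mesh, st)
  expect_equal(agg_max$value[1], 0.9)
  agg_mean <- surface_to_residue(sc, mesh, st, aggregation = "mean")
  expect_equal(agg_mean$value[1], 0.55)
  expect_true(agg_max$excluded[3]) # residue 3 owns no vertex
  expect_true(is.na(agg_max$value[3]))

  const <- surface_to_residue(rep(0.7, 4), mesh, st)
  expect_true(all(const$value[!const$excluded] == 0.7))
})

test_that("residue -> surface -> residue (max) is the identity when every residue owns a vertex", {
  tp <- toy_protein_fixture()
  mesh <- toy_surface_fixture()
  st <- tp$structure
  expect_true(all(tabulate(mesh$nearest_residue, nrow(st$residues)) > 0))
  lab <- st$residues
  lab$label <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L)
  sv <- residue_to_surface(mesh, lab, st)
  back <- surface_to_residue(sv$label, mesh, st)
  expect_equal(back$value[!back$excluded], lab$label[!back$excluded])
})

test_that("contact labels recover the planted contact set at the 5 A cutoff", {
  toy <- make_toy_protein(12, seed = 4)
  tr <- make_toy_trajectory(toy$structure, contact_residues = "5")
  lab <- md_contact_labels(tr$trajectory, tr$membrane_residues)
  expect_equal(lab$residue_index[lab$label == 1], "5")
  # loop closure through PDB text
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tr$pdb, path)
  lab2 <- md_contact_labels(read_trajectory(path), "MLP")
  expect_equal(lab2$residue_index[lab2$label == 1], "5")
  # two-residue face
  tr2 <- make_toy_trajectory(toy$structure, contact_residues = c("3", "7"))
  lab3 <- md_contact_labels(tr2$trajectory, "MLP")
  expect_setequal(lab3$residue_index[lab3$label == 1], c("3", "7"))
  # infeasible request (opposite faces of the helix)
  expect_error(make_toy_trajectory(toy$structure, c("4", "8")), "one face")
})

test_that("a 5.1 A near-miss yields no bound frame; 4.9 A binds", {
  mk <- function(dist) {
    atoms <- tibble::tibble(
      serial = 1:2, name = c("NZ", "P"), element = c("N", "P"),
      residue_name = c("LYS", "MLP"), residue_index = c("1", "1"),
      chain_id = c("A", "M"), x = 0, y = 0, z = c(dist, 0), is_heavy = TRUE)
    st <- surfibs:::as_structure(atoms)
    list(structure = st, frames = list(as.matrix(atoms[, c("x", "y", "z")])))
  }
  ok <- md_contact_labels(mk(4.9), "MLP")
  expect_equal(ok$residue_index[ok$label == 1], "1")
  expect_error(md_contact_labels(mk(5.1), "MLP"), "no bound frame",
               class = "surfibs_no_bound_frame")
})

test_that("the last bound frame is used when the protein detaches again", {
  toy <- make_toy_protein(12, seed = 4)
  tr <- make_toy_trajectory(toy$structure, "5", n_frames = 3, retreat_frames = 2)
  lab <- md_contact_labels(tr$trajectory, "MLP")
  expect_equal(attr(lab, "frame"), 3)
  expect_equal(lab$residue_index[lab$label == 1], "5")
})

test_that("contact labelling is invariant to atom order and joint rigid motion", {
  toy <- make_toy_protein(12, seed = 4)
  tr <- make_toy_trajectory(toy$structure, "5")$trajectory
  base <- md_contact_labels(tr, "MLP")

  perm <- rev(seq_len(nrow(tr$structure$atoms)))
  tr_perm <- list(structure = surfibs:::as_structure(tr$structure$atoms[perm, ]),
                  frames = lapply(tr$frames, function(f) f[perm, ]))
  expect_equal(md_contact_labels(tr_perm, "MLP")$label, base$label)

  ang <- 1.1
  R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
  tr_rot <- list(structure = tr$structure,
                 frames = lapply(tr$frames, function(f)
                   sweep(f %*% t(R), 2, c(3, -2, 7), "+")))
  expect_equal(md_contact_labels(tr_rot, "MLP")$label, base$label)
})

test_that("replica union and consensus follow set arithmetic", {
  base <- tibble::tibble(chain_id = "A", residue_index = as.character(1:4),
                         residue_name = "ALA")
  mk <- function(set) dplyr::mutate(base, label = as.integer(residue_index %in% set))
  reps <- list(mk(c("1", "2")), mk(c("2", "3")))
  half <- combine_replicas(reps, contact_config(consensus_min_fraction = 0.5))
  expect_setequal(half$union$residue_index[half$union$label == 1], c("1", "2", "3"))
  # ceil(0.5 * 2) = 1 replica suffices
  expect_setequal(half$consensus$residue_index[half$consensus$label == 1],
                  c("1", "2", "3"))
  full <- combine_replicas(reps, contact_config(consensus_min_fraction = 1))
  expect_setequal(full$consensus$residue_index[full$consensus$label == 1], "2")

  single <- combine_replicas(reps[1])
  expect_equal(single$union$label, single$consensus$label)
  expect_equal(single$union$label, reps[[1]]$label)

  disjoint <- combine_replicas(list(mk("1"), mk("3")),
                               contact_config(consensus_min_fraction = 1))
  expect_equal(sum(disjoint$consensus$label), 0)
  # consensus is always a subset of the union
  for (cf in c(0.2, 0.5, 0.8, 1)) {
    cc <- combine_replicas(reps, contact_config(consensus_min_fraction = cf))
    expect_true(all(cc$consensus$label <= cc$union$label))
  }
})
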