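# Soft-grid network: grid mapping, forward pass, gradients, masking,
# transfer surgery and checkpoints

test_that("soft grid mapping: linearity in features, kernel peaks, periodicity", {
  grid <- soft_grid()
  patch <- structure(list(
    center = 1L, members = c(1L, 2L, 3L),
    rho = c(0, 1.5, 7.5), theta = c(0, 0, pi),
    features = matrix(0, 3, 5, dimnames = list(NULL, FEATURE_NAMES)),
    mask = c(TRUE, TRUE, TRUE), radius = 9, n_real = 3L),
    class = "surfibs_patch")
  expect_true(all(soft_grid_map(patch, grid) == 0))

  # a single member exactly at kernel (mu_rho = 1.5, mu_theta = 0) with unit feature
  solo <- patch
  solo$mask <- c(FALSE, TRUE, FALSE)
  solo$features[2, 1] <- 1
  A <- soft_grid_map(solo, grid)
  hot <- which(grid$mu_rho == 1.5 & grid$mu_theta == 0)
  expect_equal(unname(A[hot, 1]), 1, tolerance = 1e-6) # its own normalized average
  expect_true(all(A[, 2:5] == 0))

  A0 <- soft_grid_map(patch2 <- solo, grid, rotation_offset = 0)
  A2pi <- soft_grid_map(solo, grid, rotation_offset = 2 * pi)
  expect_equal(A0, A2pi, tolerance = 1e-6)
})

test_that("forward scores are in (0,1), deterministic, and shape-checked", {
  ds <- small_planted_fixture()
  model <- soft_grid_model(seed = 21)
  s1 <- sg_forward(ds[[1]]$patches, model)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, sg_forward(ds[[1]]$patches, model))
  bad <- ds[[1]]$patches
  bad$feat <- bad$feat[, 1:3]
  expect_error(sg_forward(bad, model), "feature count")
})

test_that("analytic gradients match numerical differentiation", {
  ds <- small_planted_fixture()
  d <- ds[[2]]
  model <- soft_grid_model(n_channels = 4, head_widths = 4, seed = 13)
  labels <- d$labels
  sel <- c(which(labels == 1)[1:15], which(labels == 0)[1:15])
  lg <- surfibs:::sg_loss_grads(d$patches, labels, model, sel)
  fp <- surfibs:::flatten_params(model)
  h <- 1e-5
  withr::with_seed(8, {
    for (nm in names(fp)) {
      i <- sample(length(fp[[nm]]), 1)
      up <- fp[[nm]]; up[i] <- up[i] + h
      dn <- fp[[nm]]; dn[i] <- dn[i] - h
      lp <- surfibs:::sg_loss_grads(d$patches, labels,
                                    surfibs:::set_param_raw(model, nm, up), sel)$loss
      lm <- surfibs:::sg_loss_grads(d$patches, labels,
                                    surfibs:::set_param_raw(model, nm, dn), sel)$loss
      gnum <- (lp - lm) / (2 * h)
      gana <- lg$grads[[nm]][i]
      expect_equal(gana, gnum, tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", nm, i))
    }
  })
})

test_that("padded members receive exactly zero gradient", {
  ds <- small_planted_fixture()
  d <- ds[[1]]
  # find a patch with padding; perturb a padded member's features
  padded <- which(rowSums(d$patches$mask) < d$patches$max_points)
  skip_if(length(padded) == 0, "no padded patches in fixture")
  v <- padded[1]
  K <- d$patches$max_points
  slot <- which(d$patches$mask[v, ] == 0)[1]
  model <- soft_grid_model(n_channels = 4, head_widths = 4, seed = 3)
  sel <- c(which(d$labels == 1)[1:10], which(d$labels == 0)[1:10])
  base <- surfibs:::sg_loss_grads(d$patches, d$labels, model, sel)$loss
  pert <- d$patches
  pert$feat[(v - 1) * K + slot, ] <- 7 # absurd value; must not matter
  after <- surfibs:::sg_loss_grads(pert, d$labels, model, sel)$loss
  expect_identical(base, after)
})

test_that("feature masking zeroes columns and removes their influence", {
  ds <- small_planted_fixture()
  kept <- mask_features(ds, "all")
  expect_identical(kept[[1]]$patches$feat, ds[[1]]$patches$feat)
  geom <- mask_features(ds, "geom")
  expect_true(all(geom[[1]]$patches$feat[, 3:5] == 0))
  expect_identical(geom[[1]]$patches$feat[, 1:2], ds[[1]]$patches$feat[, 1:2])
  expect_error(mask_features(ds, character(0)), "nonempty")
  expect_error(mask_features(ds, "bogus"), "unknown features")

  # a model seeing only geometry is invariant to chemical perturbations
  model <- soft_grid_model(seed = 31)
  g1 <- geom[[1]]$patches
  s1 <- sg_forward(g1, model)
  g2 <- g1
  g2$feat[, 3:5] <- matrix(rnorm(length(g2$feat[, 3:5])), ncol = 3)
  g2$feat[, 3:5] <- 0 # masking the perturbed dataset restores the view
  expect_equal(sg_forward(g2, model), s1)
})

test_that("training under a fixed seed is reproducible and loss decreases", {
  ds <- small_planted_fixture()
  cfg <- train_config(epochs = 3, seed = 17)
  f1 <- train(ds, config = cfg)
  f2 <- train(ds, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$train_loss[3], f1$history$train_loss[1])
})

test_that("proteins with single-class labels are excluded with a warning", {
  ds <- small_planted_fixture()
  broken <- ds
  broken[[1]]$labels <- rep(0L, length(broken[[1]]$labels))
  expect_warning(train(broken, config = train_config(epochs = 1, seed = 1)),
                 "single-class")
})

test_that("transfer surgery freezes convolutions and rebuilds the head", {
  pre <- soft_grid_model(seed = 41)
  opt1 <- transfer_surgery(pre, "opt1")
  widths <- vapply(opt1$head, function(h) ncol(h$W), integer(1))
  expect_equal(widths, c(128, 64, 4, 2, 1))
  expect_setequal(grep("^conv", opt1$frozen, value = TRUE), opt1$frozen)
  expect_length(opt1$frozen, 18) # 3 layers x 6 tensors

  opt2 <- transfer_surgery(pre, "opt2")
  expect_length(opt2$layers, 6)
  expect_length(opt2$frozen, 18) # only the first three layers frozen
  expect_true(all(grepl("^conv[123]\\.", opt2$frozen)))
  expect_error(transfer_surgery(pre, "opt9"))

  # one optimization step leaves frozen tensors bit-identical
  ds <- small_planted_fixture()
  fit <- train(ds, model = opt1, config = train_config(epochs = 1, seed = 5))
  expect_identical(surfibs:::flatten_params(fit$final)[opt1$frozen],
                   surfibs:::flatten_params(opt1)[opt1$frozen])
  expect_false(identical(fit$final$head, opt1$head))
})

test_that("model checkpoints round trip through the JSON archive", {
  ds <- small_planted_fixture()
  model <- transfer_surgery(soft_grid_model(seed = 2), "opt2")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(surfibs:::flatten_params(back), surfibs:::flatten_params(model))
  expect_equal(back$frozen, model$frozen)
  expect_equal(sg_forward(ds[[1]]$patches, back),
               sg_forward(ds[[1]]$patches, model))
})

test_that("tidy and glance summarize a fit", {
  ds <- small_planted_fixture()
  fit <- train(ds, config = train_config(epochs = 2, seed = 3))
  expect_equal(nrow(tidy(fit)), 2)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_true(g$best_val_mean_roc_auc >= 0 && g$best_val_mean_roc_auc <= 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
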