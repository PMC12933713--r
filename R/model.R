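# Geodesic convolutional network on a learned soft polar grid.
#
# Each of the three convolution layers owns 12 Gaussian kernels (3 radial x
# 4 angular bins) whose centers and widths are learnable, a linear filter
# over the 12 x C_in grid activations, and a ReLU; the filter response is
# max-pooled over evenly spaced rotations of the angular origin, which makes
# the fingerprints insensitive to the random polar reference axes. Layers 2
# and 3 consume the previous layer's center outputs gathered over the same
# patch geometry. A small fully connected head maps the final fingerprint of
# each patch center to an IBS score through a sigmoid.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) log(expm1(y))
sigmoid <- function(x) 1 / (1 + exp(-x))

new_soft_grid <- function(n_radial = 3, n_angular = 4, radius = 9) {
  ctr_r <- (seq_len(n_radial) - 0.5) * radius / n_radial
  ctr_t <- (seq_len(n_angular) - 1) * 2 * pi / n_angular
  grid <- expand.grid(r = ctr_r, t = ctr_t)
  list(mu_rho = grid$r,
       s_rho = rep(softplus_inv(radius / n_radial / 2), nrow(grid)),
       mu_the = grid$t,
       s_the = rep(softplus_inv(pi / n_angular), nrow(grid)))
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

new_conv_layer <- function(cin, cout, n_radial, n_angular, radius) {
  g <- new_soft_grid(n_radial, n_angular, radius)
  B <- n_radial * n_angular
  c(g, list(W = glorot(cout, B * cin), b = numeric(cout)))
}

new_head <- function(cin, widths) {
  dims <- c(cin, widths, 1)
  lapply(seq_len(length(dims) - 1), function(i)
    list(W = glorot(dims[i], dims[i + 1]), b = numeric(dims[i + 1])))
}

#' Soft polar grid of Gaussian kernels
#'
#' `soft_grid()` builds the (initial) kernel system: `n_radial * n_angular`
#' Gaussians on (rho, theta) with centers on a regular polar lattice over
#' `[0, radius] x [0, 2 pi)` and widths of half the bin spacing.
#' `soft_grid_map()` maps one patch onto the grid: bin (b, f) is the
#' mask-weighted Gaussian average of feature f over the patch members,
#' normalized by the total kernel weight (epsilon = 1e-8 guards empty
#' bins); `rotation_offset` rotates the angular origin.
#'
#' @param n_radial,n_angular bin counts (defaults 3 and 4).
#' @param radius patch radius, Angstrom.
#' @return a list with `mu_rho`, `sigma_rho`, `mu_theta`, `sigma_theta`
#'   (each of length `n_radial * n_angular`).
#' @export
soft_grid <- function(n_radial = 3, n_angular = 4, radius = 9) {
  g <- new_soft_grid(n_radial, n_angular, radius)
  list(mu_rho = g$mu_rho, sigma_rho = softplus(g$s_rho),
       mu_theta = g$mu_the, sigma_theta = softplus(g$s_the))
}

#' @rdname soft_grid
#' @param patch a `surfibs_patch` with polar coordinates filled.
#' @param grid a `soft_grid()` (or a list with the same fields).
#' @param rotation_offset angular offset in radians.
#' @export
soft_grid_map <- function(patch, grid, rotation_offset = 0) {
  B <- length(grid$mu_rho)
  w <- matrix(0, length(patch$members), B)
  th <- patch$theta + rotation_offset
  for (b in seq_len(B)) {
    dt <- (th - grid$mu_theta[b]) %% (2 * pi)
    dt[dt > pi] <- dt[dt > pi] - 2 * pi
    w[, b] <- patch$mask *
      exp(-(patch$rho - grid$mu_rho[b])^2 / (2 * grid$sigma_rho[b]^2)
          - dt^2 / (2 * grid$sigma_theta[b]^2))
  }
  A <- t(w) %*% patch$features / (colSums(w) + 1e-8)
  dimnames(A) <- list(NULL, FEATURE_NAMES[seq_len(ncol(patch$features))])
  A
}

#' Create a soft-polar-grid surface fingerprint model
#'
#' @param n_features input features per patch member (default 5).
#' @param n_channels channel width of the convolution layers (default 16).
#' @param n_layers convolution layers (default 3).
#' @param n_rotations rotation offsets for angular max pooling (default 4).
#' @param n_radial,n_angular radial and angular Gaussian bins (default 3
#'   and 4; 12 kernels per layer).
#' @param radius patch radius in Angstrom (default 9); kernel centers are
#'   initialized on a regular polar lattice over `[0, radius] x [0, 2 pi)`
#'   with widths equal to half the bin spacing.
#' @param head_widths hidden widths of the fully connected head (default 8).
#' @param seed initialization seed (Glorot-style filter weights).
#' @return an object of class `surfibs_model`.
#' @export
soft_grid_model <- function(n_features = 5, n_channels = 16, n_layers = 3,
                            n_rotations = 4, n_radial = 3, n_angular = 4,
                            radius = 9, head_widths = 8, seed = 1) {
  with_seed(seed, {
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      cin <- if (l == 1) n_features else n_channels
      layers[[l]] <- new_conv_layer(cin, n_channels, n_radial, n_angular, radius)
    }
    head <- new_head(n_channels, head_widths)
    structure(list(layers = layers, head = head,
                   frozen = character(0),
                   config = list(n_features = n_features, n_channels = n_channels,
                                 n_layers = n_layers, n_rotations = n_rotations,
                                 n_radial = n_radial, n_angular = n_angular,
                                 radius = radius, head_widths = head_widths,
                                 seed = seed)),
              class = "surfibs_model")
  })
}

#' @export
print.surfibs_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<surfibs_model> %d conv layers (%d channels, %dx%d soft grid,",
                     " %d rotations), head %s -> 1, %d parameters%s\n"),
              cfg$n_layers, cfg$n_channels, cfg$n_radial, cfg$n_angular,
              cfg$n_rotations, paste(cfg$head_widths, collapse = "/"),
              n_parameters(x),
              if (length(x$frozen)) sprintf(", %d frozen tensors", length(x$frozen)) else ""))
  invisible(x)
}

#' @rdname soft_grid_model
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model), length, integer(1)))
}

# named flat view of all parameter arrays
flatten_params <- function(model) {
  out <- list()
  for (l in seq_along(model$layers)) {
    for (nm in c("mu_rho", "s_rho", "mu_the", "s_the", "W", "b"))
      out[[sprintf("conv%d.%s", l, nm)]] <- model$layers[[l]][[nm]]
  }
  for (h in seq_along(model$head)) {
    out[[sprintf("head%d.W", h)]] <- model$head[[h]]$W
    out[[sprintf("head%d.b", h)]] <- model$head[[h]]$b
  }
  out
}

set_param <- function(model, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (startsWith(parts[1], "conv")) {
    l <- as.integer(sub("conv", "", parts[1]))
    dim(value) <- dim(model$layers[[l]][[parts[2]]])
    model$layers[[l]][[parts[2]]] <- value
  } else {
    h <- as.integer(sub("head", "", parts[1]))
    dim(value) <- dim(model$head[[h]][[parts[2]]])
    model$head[[h]][[parts[2]]] <- value
  }
  model
}

# gather per-center outputs over patch members; row order k fastest within v
gather_members <- function(H, members) {
  H[as.vector(t(members)), , drop = FALSE]
}

scatter_members <- function(grad_Hm, members, nv) {
  scatter_rows_cpp(grad_Hm, as.vector(t(members)), nv)
}

rotation_offsets <- function(n) 2 * pi * (seq_len(n) - 1) / n

#' Forward pass: IBS scores for every patch center of one protein
#'
#' @param patches a `surfibs_patch_set` (all patches of one protein).
#' @param model a [soft_grid_model()].
#' @param n_rotations override the model's rotation count.
#' @param keep_caches retain layer caches for backpropagation (internal).
#' @return numeric vector of scores in (0, 1), one per patch center;
#'   with `keep_caches` a list with scores, logits and caches.
#' @export
sg_forward <- function(patches, model, n_rotations = NULL, keep_caches = FALSE) {
  cfg <- model$config
  R <- n_rotations %||% cfg$n_rotations
  offsets <- rotation_offsets(R)
  nv <- nrow(patches$members)
  if (ncol(patches$feat) != cfg$n_features)
    stop_surfibs("patch feature count does not match the model configuration")
  Hm <- patches$feat
  caches <- vector("list", length(model$layers))
  H <- NULL
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    if (l > 1) Hm <- gather_members(H, patches$members)
    fw <- sg_forward_cpp(Hm, patches$mask, patches$rho, patches$theta,
                         ly$mu_rho, softplus(ly$s_rho),
                         ly$mu_the, softplus(ly$s_the),
                         ly$W, ly$b, offsets)
    if (keep_caches) caches[[l]] <- c(fw, list(Hm = Hm))
    H <- fw$out
  }
  hcache <- list(H)
  for (h in seq_along(model$head)) {
    Z <- sweep(hcache[[h]] %*% model$head[[h]]$W, 2, model$head[[h]]$b, "+")
    hcache[[h + 1]] <- if (h < length(model$head)) pmax(Z, 0) else Z
  }
  logits <- as.numeric(hcache[[length(hcache)]])
  scores <- sigmoid(logits)
  if (!keep_caches) return(scores)
  list(scores = scores, logits = logits, caches = caches, hcache = hcache,
       offsets = offsets)
}

#' @export
predict.surfibs_model <- function(object, patches, ...) {
  sg_forward(patches, object)
}

# loss + gradients for one protein on the selected centers
sg_loss_grads <- function(patches, labels, model, sel) {
  fw <- sg_forward(patches, model, keep_caches = TRUE)
  z <- fw$logits[sel]
  y <- labels[sel]
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  n <- length(sel)
  nv <- length(fw$logits)
  gz <- numeric(nv)
  gz[sel] <- (sigmoid(z) - y) / n
  grads <- list()
  # head backward
  gh <- matrix(gz, ncol = 1)
  for (h in rev(seq_along(model$head))) {
    hin <- fw$hcache[[h]]
    if (h < length(model$head)) {
      # gh is gradient w.r.t. post-ReLU output of layer h; see below
    }
    grads[[sprintf("head%d.W", h)]] <- crossprod(hin, gh)
    grads[[sprintf("head%d.b", h)]] <- colSums(gh)
    gh <- gh %*% t(model$head[[h]]$W)
    if (h > 1) gh <- gh * (fw$hcache[[h]] > 0)
  }
  grad_H <- gh # gradient w.r.t. final conv output
  offsets <- fw$offsets
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    cc <- fw$caches[[l]]
    sig_r <- softplus(ly$s_rho)
    sig_t <- softplus(ly$s_the)
    bw <- sg_backward_cpp(grad_H, cc$Hm, patches$mask, patches$rho, patches$theta,
                          ly$mu_rho, sig_r, ly$mu_the, sig_t, ly$W, offsets,
                          cc$Z, cc$amax, cc$A, cc$denom, l > 1)
    grads[[sprintf("conv%d.W", l)]] <- bw$grad_W
    grads[[sprintf("conv%d.b", l)]] <- as.numeric(bw$grad_b)
    grads[[sprintf("conv%d.mu_rho", l)]] <- as.numeric(bw$grad_mu_rho)
    grads[[sprintf("conv%d.s_rho", l)]] <- as.numeric(bw$grad_sig_rho) * sigmoid(ly$s_rho)
    grads[[sprintf("conv%d.mu_the", l)]] <- as.numeric(bw$grad_mu_the)
    grads[[sprintf("conv%d.s_the", l)]] <- as.numeric(bw$grad_sig_the) * sigmoid(ly$s_the)
    if (l > 1) grad_H <- scatter_members(bw$grad_Hm, patches$members, nrow(grad_H))
  }
  list(loss = loss, grads = grads)
}

#' Zero out feature columns of a dataset (ablation masking)
#'
#' @param dataset list of proteins, each with a `patches` patch set (see
#'   [make_planted_dataset()] for the layout).
#' @param keep features to keep: a character subset of
#'   `r paste(FEATURE_NAMES, collapse = ", ")`, or one of the presets
#'   `"all"`, `"geom"` (shape_index + ddc), `"chem"` (hydropathy +
#'   electrostatics + hbond).
#' @return the dataset with all other feature columns set to 0 in every
#'   patch; attribute `feature_keep` records the kept set.
#' @export
mask_features <- function(dataset, keep = "all") {
  keep <- resolve_feature_keep(keep)
  drop <- setdiff(FEATURE_NAMES, keep)
  if (length(drop) == 0) {
    attr(dataset, "feature_keep") <- keep
    return(dataset)
  }
  for (i in seq_along(dataset)) {
    dataset[[i]]$patches$feat[, match(drop, FEATURE_NAMES)] <- 0
    for (j in seq_along(dataset[[i]]$patches$patches))
      dataset[[i]]$patches$patches[[j]]$features[, drop] <- 0
  }
  attr(dataset, "feature_keep") <- keep
  dataset
}

resolve_feature_keep <- function(keep) {
  if (length(keep) == 1 && keep %in% c("all", "geom", "chem")) {
    keep <- switch(keep,
                   all = FEATURE_NAMES,
                   geom = c("shape_index", "ddc"),
                   chem = c("hydropathy", "electrostatics", "hbond"))
  }
  if (length(keep) == 0) stop_surfibs("keep set must be nonempty")
  bad <- setdiff(keep, FEATURE_NAMES)
  if (length(bad)) stop_surfibs(sprintf("unknown features: %s", paste(bad, collapse = ", ")))
  keep
}

#' Transfer-learning surgery on a pretrained model
#'
#' Two strategies mirroring common fingerprint-network transfer recipes:
#' `opt1` freezes all convolution layers and replaces the head with a
#' deeper fully connected stack (hidden widths 128, 64, 4, 2, then a single
#' sigmoid output unit); `opt2` freezes the pretrained convolution layers,
#' appends three new trainable convolution layers and a fresh head.
#' [train()] updates only unfrozen tensors.
#'
#' @param pretrained a [soft_grid_model()].
#' @param strategy `"opt1"` or `"opt2"`.
#' @param seed initialization seed for the new tensors.
#' @return the modified model; `$frozen` names the frozen tensors.
#' @export
transfer_surgery <- function(pretrained, strategy = c("opt1", "opt2"), seed = 1) {
  strategy <- match.arg(strategy)
  model <- pretrained
  cfg <- model$config
  n_old <- length(model$layers)
  model$frozen <- unlist(lapply(seq_len(n_old), function(l)
    sprintf("conv%d.%s", l, c("mu_rho", "s_rho", "mu_the", "s_the", "W", "b"))))
  with_seed(seed, {
    if (strategy == "opt1") {
      model$head <- new_head(cfg$n_channels, c(128, 64, 4, 2))
      model$config$head_widths <- c(128, 64, 4, 2)
    } else {
      for (l in n_old + 1:3) {
        model$layers[[l]] <- new_conv_layer(cfg$n_channels, cfg$n_channels,
                                            cfg$n_radial, cfg$n_angular, cfg$radius)
      }
      model$config$n_layers <- n_old + 3
      model$head <- new_head(cfg$n_channels, cfg$head_widths)
    }
  })
  model$config$transfer <- strategy
  model
}

#' Save / load a model checkpoint as a JSON archive
#'
#' The archive holds every parameter array, the configuration, the frozen
#' manifest and a format version.
#'
#' @param model a [soft_grid_model()].
#' @param path output path (`.json`).
#' @return `read_model()` returns the model.
#' @export
write_model <- function(model, path) {
  params <- flatten_params(model)
  x <- list(version = "1", config = model$config, frozen = model$frozen,
            params = lapply(params, function(p)
              list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version)) stop_surfibs("model archive missing version field")
  cfg <- x$config
  model <- soft_grid_model(n_features = cfg$n_features, n_channels = cfg$n_channels,
                           n_layers = min(cfg$n_layers, 3), n_rotations = cfg$n_rotations,
                           n_radial = cfg$n_radial, n_angular = cfg$n_angular,
                           radius = cfg$radius, head_widths = cfg$head_widths,
                           seed = cfg$seed)
  if (cfg$n_layers > 3) {
    for (l in 4:cfg$n_layers)
      model$layers[[l]] <- new_conv_layer(cfg$n_channels, cfg$n_channels,
                                          cfg$n_radial, cfg$n_angular, cfg$radius)
  }
  model$head <- new_head(cfg$n_channels, cfg$head_widths)
  model$config <- cfg
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    v <- as.numeric(p$data)
    if (length(p$dim) == 2) dim(v) <- p$dim
    model <- set_param_raw(model, nm, v)
  }
  model$frozen <- as.character(x$frozen %||% character(0))
  model
}

set_param_raw <- function(model, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (startsWith(parts[1], "conv")) {
    l <- as.integer(sub("conv", "", parts[1]))
    model$layers[[l]][[parts[2]]] <- value
  } else {
    h <- as.integer(sub("head", "", parts[1]))
    model$head[[h]][[parts[2]]] <- value
  }
  model
}
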