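# Training: Adam on per-protein batches with balanced negative subsampling,
# validation checkpointing on mean per-protein ROC AUC.

#' Training configuration
#'
#' @param epochs training epochs (default 50).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed seed governing the validation split, the per-epoch protein
#'   order and the negative subsamples.
#' @param validation_fraction fraction of proteins set aside for validation
#'   (default 0.10, at least one protein).
#' @param negative_subsample balance each protein's loss by sampling as
#'   many negatives as there are positives, fresh each epoch (default
#'   `TRUE`).
#' @return a list of class `surfibs_train_config`.
#' @export
train_config <- function(epochs = 50, learning_rate = 1e-3, seed = 1,
                         validation_fraction = 0.10, negative_subsample = TRUE) {
  if (epochs < 1) stop_surfibs("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 negative_subsample = negative_subsample),
            class = "surfibs_train_config")
}

#' Train a soft-grid model on labelled surface patches
#'
#' Each protein is one optimization step (a single batch). The loss is
#' sigmoid cross-entropy over all positive vertices plus an equal-size
#' random subsample of negatives (redrawn every epoch); the optimizer is
#' Adam. After every epoch the mean per-protein ROC AUC on the validation
#' proteins is computed and the model is checkpointed whenever it improves.
#' Proteins with single-class labels are excluded with a warning. Frozen
#' tensors (see [transfer_surgery()]) are never updated.
#'
#' @param dataset list of proteins; each element is a list with `patches`
#'   (a `surfibs_patch_set`), `labels` (binary vector over patch centers)
#'   and optionally `id` and `group`.
#' @param model a [soft_grid_model()]; created from the data dimensions
#'   when `NULL`.
#' @param config a [train_config()].
#' @param validation_ids optional protein ids to use as the validation set
#'   instead of the random fraction.
#' @return a `surfibs_fit`: list with `model` (checkpointed best), `final`
#'   (last epoch), `history` tibble (epoch, train_loss, val_mean_roc_auc),
#'   `best_epoch` and `validation_ids`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
train <- function(dataset, model = NULL, config = train_config(),
                  validation_ids = NULL) {
  ids <- vapply(seq_along(dataset), function(i)
    dataset[[i]]$id %||% sprintf("protein_%03d", i), character(1))
  ok <- vapply(dataset, function(d) length(unique(d$labels)) == 2, logical(1))
  if (any(!ok)) {
    rlang::warn(sprintf("excluding %d single-class proteins: %s",
                        sum(!ok), paste(ids[!ok], collapse = ", ")))
    dataset <- dataset[ok]
    ids <- ids[ok]
  }
  if (length(dataset) < 2) stop_surfibs("need at least 2 usable proteins")
  model <- model %||%
    soft_grid_model(n_features = ncol(dataset[[1]]$patches$feat), seed = config$seed)

  with_seed(sub_seed(config$seed, "train"), {
    if (is.null(validation_ids)) {
      n_val <- max(1L, ceiling(config$validation_fraction * length(dataset)))
      validation_ids <- sample(ids, n_val)
    }
    val <- which(ids %in% validation_ids)
    tr <- setdiff(seq_along(dataset), val)
    if (length(tr) == 0) stop_surfibs("validation split left no training proteins")

    params <- flatten_params(model)
    trainable <- setdiff(names(params), model$frozen)
    mstate <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
    vstate <- mstate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0

    history <- vector("list", config$epochs)
    best <- list(metric = -Inf, model = model, epoch = 0L)
    for (epoch in seq_len(config$epochs)) {
      losses <- numeric(length(tr))
      order_tr <- sample(tr)
      for (pi in seq_along(order_tr)) {
        d <- dataset[[order_tr[pi]]]
        pos <- which(d$labels == 1)
        neg <- which(d$labels == 0)
        sel <- if (config$negative_subsample)
          c(pos, sample(neg, min(length(neg), length(pos)))) else c(pos, neg)
        lg <- sg_loss_grads(d$patches, d$labels, model, sel)
        losses[pi] <- lg$loss
        step <- step + 1
        for (nm in trainable) {
          g <- lg$grads[[nm]]
          if (is.null(g)) next
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          mh <- mstate[[nm]] / (1 - b1^step)
          vh <- vstate[[nm]] / (1 - b2^step)
          p <- flatten_params(model)[[nm]] - config$learning_rate * mh / (sqrt(vh) + eps)
          model <- set_param_raw(model, nm, p)
        }
      }
      val_auc <- vapply(val, function(vi)
        roc_auc(sg_forward(dataset[[vi]]$patches, model), dataset[[vi]]$labels),
        numeric(1))
      metric <- mean(val_auc)
      if (metric > best$metric) best <- list(metric = metric, model = model,
                                             epoch = epoch)
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 val_mean_roc_auc = metric)
    }
  })
  structure(list(model = best$model, final = model,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_metric = best$metric,
                 validation_ids = validation_ids, config = config),
            class = "surfibs_fit")
}

#' @export
print.surfibs_fit <- function(x, ...) {
  cat(sprintf("<surfibs_fit> %d epochs; best mean validation ROC AUC %.3f at epoch %d\n",
              nrow(x$history), x$best_metric, x$best_epoch))
  invisible(x)
}

#' @export
predict.surfibs_fit <- function(object, patches, ...) {
  sg_forward(patches, object$model)
}

#' Tidy methods for fitted models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary.
#'
#' @param x a `surfibs_fit`.
#' @param ... unused.
#' @export
tidy.surfibs_fit <- function(x, ...) x$history

#' @rdname tidy.surfibs_fit
#' @export
glance.surfibs_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_mean_roc_auc = x$best_metric,
         final_train_loss = x$history$train_loss[nrow(x$history)],
         n_parameters = n_parameters(x$model))
}

#' Write the training history as CSV (epoch, train_loss, val_mean_roc_auc)
#'
#' @param fit a `surfibs_fit`.
#' @param path output path.
#' @export
write_history <- function(fit, path) {
  utils::write.table(fit$history, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
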