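# Threshold-free and thresholded per-protein metrics, reports, grouped
# cross-validation splits.

#' ROC AUC (Mann-Whitney formulation)
#'
#' Probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted one half. Computed from average
#' ranks, so exact for tied scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), same length.
#' @return value in [0, 1]; errors on single-class input.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop_surfibs("ROC AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); returns 0 when any
#' factor of the denominator is zero (degenerate confusion matrices stay in
#' summaries).
#'
#' @param pred binary predictions (0/1).
#' @param labels binary labels (0/1), same length.
#' @return value in [-1, 1].
#' @export
mcc <- function(pred, labels) {
  stopifnot(length(pred) == length(labels))
  pred <- as.integer(pred); labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Binarize scores at a threshold
#'
#' @param scores numeric scores in [0, 1].
#' @param threshold decision threshold in [0, 1]; `score >= threshold`
#'   predicts 1.
#' @return integer vector of 0/1 predictions.
#' @export
binarize <- function(scores, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  as.integer(scores >= threshold)
}

#' Per-protein evaluation report
#'
#' One row per protein with ROC AUC and MCC (at the given threshold), plus
#' summary medians and means. Proteins missing labels are skipped with a
#' warning; at residue level the caller is expected to pass only
#' surface-exposed residues (see [surface_to_residue()]).
#'
#' @param predictions named list: protein id -> numeric scores.
#' @param labels named list: protein id -> binary labels.
#' @param level `"surface"` or `"residue"` (recorded in the report).
#' @param threshold binarization threshold for MCC (default 0.5).
#' @return a `surfibs_report`: list with `per_protein` tibble and `summary`
#'   one-row tibble; supports [tidy()] and [glance()].
#' @export
per_protein_report <- function(predictions, labels, level = "surface",
                               threshold = 0.5) {
  common <- intersect(names(predictions), names(labels))
  if (length(common) == 0) stop_surfibs("no proteins shared between predictions and labels")
  missing <- setdiff(names(predictions), common)
  if (length(missing))
    rlang::warn(sprintf("skipping %d proteins without labels: %s",
                        length(missing), paste(missing, collapse = ", ")))
  rows <- lapply(common, function(id) {
    s <- predictions[[id]]
    y <- as.integer(labels[[id]])
    tibble(protein = id,
           roc_auc = roc_auc(s, y),
           mcc = mcc(binarize(s, threshold), y),
           n_pos = sum(y == 1), n_neg = sum(y == 0), level = level)
  })
  per <- dplyr::bind_rows(rows)
  structure(list(per_protein = per,
                 summary = tibble(level = level, threshold = threshold,
                                  n_proteins = nrow(per),
                                  median_roc_auc = median(per$roc_auc),
                                  mean_roc_auc = mean(per$roc_auc),
                                  median_mcc = median(per$mcc))),
            class = "surfibs_report")
}

#' @export
print.surfibs_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<surfibs_report> %d proteins (%s level): median ROC AUC %.3f, mean %.3f, median MCC %.3f\n",
              s$n_proteins, s$level, s$median_roc_auc, s$mean_roc_auc, s$median_mcc))
  invisible(x)
}

#' @export
tidy.surfibs_report <- function(x, ...) x$per_protein

#' @export
glance.surfibs_report <- function(x, ...) x$summary

#' Write a report as CSV (per-protein rows) or JSON (rows + summary)
#'
#' @param report a `surfibs_report`.
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(report$per_protein, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(per_protein = report$per_protein,
                              summary = report$summary),
                         path, digits = NA, dataframe = "rows")
  } else stop_surfibs(sprintf("unsupported report extension: .%s", ext))
  invisible(path)
}

#' Group-respecting k-fold assignments
#'
#' Whole groups (e.g. superfamilies) are assigned to folds so that no group
#' spans folds: groups are taken largest first (seeded shuffle breaks size
#' ties) and each goes to the currently smallest fold.
#'
#' @param proteins tibble (or data frame) with columns `id` and `group`.
#' @param k number of folds (default 5); must not exceed the number of
#'   groups.
#' @param seed tie-break seed.
#' @return the input tibble with a `fold` column.
#' @export
grouped_kfold <- function(proteins, k = 5, seed = 1) {
  proteins <- tibble::as_tibble(proteins)
  groups <- table(proteins$group)
  if (k > length(groups))
    stop_surfibs(sprintf("k = %d exceeds the %d groups", k, length(groups)))
  gn <- names(groups)
  ord <- with_seed(seed, sample(seq_along(groups)))
  gn <- gn[ord][order(as.integer(groups)[ord], decreasing = TRUE)]
  fold_sizes <- integer(k)
  fold_of <- setNames(integer(length(gn)), gn)
  for (g in gn) {
    f <- which.min(fold_sizes)
    fold_of[g] <- f
    fold_sizes[f] <- fold_sizes[f] + groups[[g]]
  }
  proteins$fold <- as.integer(fold_of[as.character(proteins$group)])
  proteins
}

#' Grouped cross-validation with feature masking
#'
#' The feature-ablation harness: for each fold, trains on the other folds
#' (with the requested features kept, all others zeroed) and evaluates
#' per-protein ROC AUC on the held-out fold.
#'
#' @param dataset list of proteins (see [train()]), each with `id` and
#'   `group`.
#' @param keep features to keep (see [mask_features()]).
#' @param k folds (default 5).
#' @param config a [train_config()].
#' @param folds optional precomputed fold assignment tibble.
#' @return list with `report` (a `surfibs_report` over all held-out
#'   proteins), `fits` (one `surfibs_fit` per fold) and `folds`.
#' @export
crossval <- function(dataset, keep = "all", k = 5, config = train_config(),
                     folds = NULL) {
  ids <- vapply(seq_along(dataset), function(i)
    dataset[[i]]$id %||% sprintf("protein_%03d", i), character(1))
  grp <- vapply(seq_along(dataset), function(i)
    as.character(dataset[[i]]$group %||% ids[i]), character(1))
  folds <- folds %||% grouped_kfold(tibble(id = ids, group = grp), k, config$seed)
  masked <- mask_features(dataset, keep)
  preds <- list(); labs <- list(); fits <- vector("list", k)
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$id[folds$fold == f]
    tr_idx <- which(!ids %in% test_ids)
    fit <- train(masked[tr_idx], config = config)
    fits[[f]] <- fit
    for (ti in which(ids %in% test_ids)) {
      preds[[ids[ti]]] <- sg_forward(masked[[ti]]$patches, fit$model)
      labs[[ids[ti]]] <- masked[[ti]]$labels
    }
  }
  list(report = per_protein_report(preds, labs, level = "surface"),
       fits = fits, folds = folds)
}
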