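# Ground-truth machinery: residue <-> surface label mapping and
# contact-based IBS labelling of membrane-approach trajectories.

#' Contact labelling configuration
#'
#' @param cutoff heavy-atom contact distance in Angstrom (default 5.0,
#'   i.e. 0.5 nm).
#' @param consensus_min_fraction fraction of replicas a residue must be
#'   labelled in to enter the consensus set (default 0.5).
#' @param sidechain_only restrict protein contact atoms to side chains
#'   (exclude backbone N, CA, C, O); default `FALSE` uses all heavy atoms.
#' @return a list of class `surfibs_contact_config`.
#' @export
contact_config <- function(cutoff = 5.0, consensus_min_fraction = 0.5,
                           sidechain_only = FALSE) {
  if (cutoff <= 0) stop_surfibs("cutoff must be positive")
  if (consensus_min_fraction <= 0 || consensus_min_fraction > 1)
    stop_surfibs("consensus_min_fraction must be in (0, 1]")
  structure(list(cutoff = cutoff,
                 consensus_min_fraction = consensus_min_fraction,
                 sidechain_only = sidechain_only),
            class = "surfibs_contact_config")
}

#' Map residue-level labels to surface vertices
#'
#' Every vertex inherits the label of its nearest residue; residues absent
#' from the table are treated as 0. Label rows whose residue triple does
#' not occur in the structure are skipped with a warning.
#'
#' @param mesh a [surface_mesh()] with nearest residues assigned.
#' @param residue_labels tibble with columns chain_id, residue_index,
#'   residue_name, label (0/1).
#' @param structure the owning `surfibs_structure`.
#' @return tibble with columns `vertex` and `label`.
#' @export
residue_to_surface <- function(mesh, residue_labels, structure) {
  stopifnot(!is.null(mesh$nearest_residue))
  res <- structure$residues
  key <- paste(res$chain_id, res$residue_index, res$residue_name)
  lkey <- paste(residue_labels$chain_id, residue_labels$residue_index,
                residue_labels$residue_name)
  hit <- match(lkey, key)
  if (anyNA(hit)) {
    rlang::warn(sprintf("%d label rows not found in structure; skipped",
                        sum(is.na(hit))))
  }
  lab <- integer(nrow(res))
  lab[hit[!is.na(hit)]] <- residue_labels$label[!is.na(hit)]
  tibble(vertex = seq_len(nrow(mesh$vertices)),
         label = lab[mesh$nearest_residue])
}

#' Aggregate per-vertex scores (or labels) to residue level
#'
#' Each surface-exposed residue (owning at least one vertex) receives the
#' max (default) or mean of the scores of its vertices. Buried residues
#' own no vertex; they are returned with `excluded = TRUE` and `value = NA`
#' so residue-level evaluation can drop them.
#'
#' @param scores numeric per-vertex values.
#' @param mesh a [surface_mesh()] with nearest residues assigned.
#' @param structure the owning `surfibs_structure`.
#' @param aggregation `"max"` or `"mean"`.
#' @return tibble with residue, chain_id, residue_index, residue_name,
#'   value, n_vertices, excluded.
#' @export
surface_to_residue <- function(scores, mesh, structure, aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(!is.null(mesh$nearest_residue),
            length(scores) == nrow(mesh$vertices))
  f <- if (aggregation == "max") max else mean
  agg <- tapply(scores, mesh$nearest_residue, f)
  res <- structure$residues
  value <- rep(NA_real_, nrow(res))
  value[as.integer(names(agg))] <- as.numeric(agg)
  nv <- tabulate(mesh$nearest_residue, nrow(res))
  tibble(residue = res$residue, chain_id = res$chain_id,
         residue_index = res$residue_index, residue_name = res$residue_name,
         value = value, n_vertices = nv, excluded = nv == 0)
}

#' IBS labels from a membrane-approach trajectory
#'
#' Uses the last frame in which any protein-membrane heavy-atom pair is
#' within the cutoff (the last bound configuration) and labels a residue 1
#' iff its minimal heavy-atom distance to the membrane is at most the
#' cutoff (0.5 nm by default).
#'
#' @param trajectory a list as returned by [read_trajectory()]
#'   (`structure` plus `frames` of coordinate matrices).
#' @param membrane_residues character vector of residue names marking
#'   membrane (truncated lipid) atoms.
#' @param config a [contact_config()].
#' @return residue-level label tibble (chain_id, residue_index,
#'   residue_name, label) over the protein residues, plus attribute
#'   `frame` = index of the bound frame used.
#' @export
md_contact_labels <- function(trajectory, membrane_residues, config = contact_config()) {
  st <- trajectory$structure
  a <- st$atoms
  is_mem <- a$residue_name %in% membrane_residues
  if (!any(is_mem)) stop_surfibs("no membrane atoms matched the selector")
  if (all(is_mem)) stop_surfibs("no protein atoms outside the membrane selector")
  prot <- !is_mem & a$is_heavy
  if (config$sidechain_only)
    prot <- prot & !(a$name %in% c("N", "CA", "C", "O", "OXT"))
  mem <- is_mem & a$is_heavy
  bound_frame <- NA_integer_
  for (f in rev(seq_along(trajectory$frames))) {
    dmin <- min_cross_dist(trajectory$frames[[f]], prot, mem)
    if (dmin <= config$cutoff) { bound_frame <- f; break }
  }
  if (is.na(bound_frame)) stop_surfibs("no bound frame", class = "surfibs_no_bound_frame")
  xyz <- trajectory$frames[[bound_frame]]
  pd <- cross_dist(xyz[prot, , drop = FALSE], xyz[mem, , drop = FALSE])
  res_min <- tapply(apply(pd, 1, min), a$residue[prot], min)
  res <- st$residues[!st$residues$residue %in% unique(a$residue[is_mem]), ]
  lab <- integer(nrow(res))
  hit <- match(as.integer(names(res_min)), res$residue)
  lab[hit[!is.na(hit)]] <- as.integer(res_min[!is.na(hit)] <= config$cutoff)
  out <- tibble(chain_id = res$chain_id, residue_index = res$residue_index,
                residue_name = res$residue_name, label = lab)
  attr(out, "frame") <- bound_frame
  out
}

cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

min_cross_dist <- function(xyz, sel_a, sel_b) {
  min(cross_dist(xyz[sel_a, , drop = FALSE], xyz[sel_b, , drop = FALSE]))
}

#' Combine replica contact labels into union and consensus sets
#'
#' The union IBS contains residues labelled in at least one replica; the
#' consensus IBS those labelled in at least
#' `ceiling(consensus_min_fraction * n_replicas)` replicas, so consensus is
#' always a subset of the union and the rule reduces to the union as the
#' fraction approaches zero.
#'
#' @param label_sets list of residue-level label tibbles over identical
#'   residues.
#' @param config a [contact_config()].
#' @return list with `union` and `consensus` label tibbles.
#' @export
combine_replicas <- function(label_sets, config = contact_config()) {
  if (length(label_sets) == 0) stop_surfibs("need at least one replica")
  base <- label_sets[[1]][, c("chain_id", "residue_index", "residue_name")]
  counts <- Reduce(`+`, lapply(label_sets, function(l) l$label))
  need <- ceiling(config$consensus_min_fraction * length(label_sets))
  list(union = dplyr::mutate(base, label = as.integer(counts >= 1)),
       consensus = dplyr::mutate(base, label = as.integer(counts >= need)))
}
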