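#' Final-energy ratio between FDL and a model layout
#'
#' `Delta E = E_FDL / E_model`; values above 1 mean the model found a deeper
#' energy minimum than the direct force-directed optimizer.
#'
#' @param e_fdl,e_model positive final energies.
#' @return scalar ratio.
#' @export
energy_ratio <- function(e_fdl, e_model) {
  if (!is.finite(e_fdl) || !is.finite(e_model) || e_fdl <= 0 || e_model <= 0) {
    stop("energies must be positive and finite")
  }
  e_fdl / e_model
}

#' Steps and seconds to reach an energy target
#'
#' The first recorded step at which a trajectory's energy drops to
#' `(1 + delta) * e_target` or below. The natural target is the final energy
#' of a paired FDL run.
#'
#' @param traj an `nl_trajectory`.
#' @param e_target target energy.
#' @param delta slack fraction above the target (default 5%).
#' @return list with `steps` and `seconds`; both `NA` (with
#'   `reached = FALSE`) when the trajectory never reaches the target.
#' @export
convergence_time <- function(traj, e_target, delta = 0.05) {
  stopifnot(length(traj$energies) > 0)
  thr <- (1 + delta) * e_target
  idx <- which(traj$energies <= thr)
  if (!length(idx)) {
    return(list(steps = NA_real_, seconds = NA_real_, reached = FALSE))
  }
  i <- idx[1]
  list(steps = traj$steps[i], seconds = traj$wall_times[i], reached = TRUE)
}

#' Speedup of a model trajectory over the FDL baseline
#'
#' Ratio of FDL's cost to the model's cost to reach a common energy target,
#' in recorded steps and in wall-clock seconds. Step ratios are
#' hardware-independent; wall-clock ratios are not comparable across
#' machines. The default target is the FDL trajectory's final energy.
#'
#' @param traj_fdl,traj_model `nl_trajectory` objects.
#' @param delta slack fraction for the target crossing.
#' @param e_target common energy target; default FDL's final energy.
#' @return list with `step_ratio`, `time_ratio`, and the two crossing
#'   records; ratios are `NA` if either side never reaches the target.
#' @export
speedup <- function(traj_fdl, traj_model, delta = 0.05, e_target = NULL) {
  if (is.null(e_target)) e_target <- tail(traj_fdl$energies, 1)
  a <- convergence_time(traj_fdl, e_target, delta)
  b <- convergence_time(traj_model, e_target, delta)
  step_ratio <- if (a$reached && b$reached) {
    if (b$steps == 0 && a$steps == 0) 1 else a$steps / max(b$steps, 1)
  } else NA_real_
  time_ratio <- if (a$reached && b$reached) {
    tiny <- .Machine$double.eps
    max(a$seconds, tiny) / max(b$seconds, tiny)
  } else NA_real_
  list(step_ratio = step_ratio, time_ratio = time_ratio,
       fdl = a, model = b)
}

#' Histogram of Euclidean link lengths in a layout
#'
#' @param g an `nl_graph`.
#' @param layout N x d coordinate matrix.
#' @param bins number of equal-width bins spanning `[0, max length]`.
#' @return an object of class `length_histogram`: `bin_edges`, `counts`
#'   (summing to the number of links measured), `lengths`, `mean`, `median`,
#'   `upper_quartile`.
#' @export
link_length_distribution <- function(g, layout, bins = 50) {
  check_layout(g, layout)
  len <- link_lengths(g, layout)
  make_length_histogram(len, bins)
}

link_lengths <- function(g, layout, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- Matrix::which(Matrix::triu(g$adjacency) != 0, arr.ind = TRUE)
  }
  if (nrow(pairs) == 0) return(numeric(0))
  sqrt(rowSums((layout[pairs[, 1], , drop = FALSE] -
                  layout[pairs[, 2], , drop = FALSE])^2))
}

make_length_histogram <- function(len, bins) {
  hi <- max(len, 0)
  if (hi == 0) hi <- 1  # degenerate all-zero lengths: one unit-wide span
  edges <- seq(0, hi, length.out = bins + 1)
  counts <- if (length(len)) {
    tabulate(pmin(findInterval(len, edges, rightmost.closed = TRUE), bins),
             nbins = bins)
  } else integer(bins)
  structure(list(bin_edges = edges, counts = counts, lengths = len,
                 mean = if (length(len)) mean(len) else NA_real_,
                 median = if (length(len)) median(len) else NA_real_,
                 upper_quartile = if (length(len))
                   unname(quantile(len, 0.75)) else NA_real_),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %d links, mean %.4g, median %.4g, Q3 %.4g\n",
              sum(x$counts), x$mean, x$median, x$upper_quartile))
  invisible(x)
}

#' Per-community internal link-length distributions
#'
#' Restricts the link-length histogram to links whose two endpoints share a
#' community label; cross-community links are excluded. Tight internal
#' distributions indicate spatially co-localized communities.
#'
#' @inheritParams link_length_distribution
#' @param partition named vector mapping every node id to a community label
#'   (see [read_partition()]), or an unnamed vector in node order.
#' @return named list of `length_histogram` objects, one per community.
#' @export
community_length_distributions <- function(g, layout, partition, bins = 50) {
  check_layout(g, layout)
  lab <- align_partition(g, partition)
  pairs <- Matrix::which(Matrix::triu(g$adjacency) != 0, arr.ind = TRUE)
  out <- list()
  for (comm in sort(unique(lab))) {
    keep <- lab[pairs[, 1]] == comm & lab[pairs[, 2]] == comm
    out[[comm]] <- make_length_histogram(
      link_lengths(g, layout, pairs[keep, , drop = FALSE]), bins)
  }
  out
}

#' Geometric randomization of a layout
#'
#' The null model for link-length statistics: the nodes are randomly
#' exchanged over the existing coordinates, keeping both the coordinate
#' multiset and the adjacency matrix unchanged. Link lengths under this null
#' reflect the spatial extent of the layout but none of its structure.
#'
#' @param layout N x d coordinate matrix.
#' @param seed integer RNG seed.
#' @return a permuted copy of the layout.
#' @export
geometric_randomization <- function(layout, seed = NULL) {
  stopifnot(is.matrix(layout))
  perm <- with_seed(seed, sample.int(nrow(layout)))
  layout[perm, , drop = FALSE]
}

#' Cluster separation score of a layout
#'
#' Mean silhouette coefficient of the nodes under Euclidean distance, using
#' the community partition as the cluster assignment: for node i,
#' `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance to its own
#' community and `b_i` the smallest mean distance to another community.
#' Scores near 1 mean well-separated, compact communities; near 0, no spatial
#' separation. (The silhouette is this package's transparent choice of
#' spatial-similarity metric; see the vignette.)
#'
#' @param layout N x d coordinate matrix.
#' @param partition named vector of community labels covering all nodes, or
#'   an unnamed vector in node order.
#' @return scalar in `[-1, 1]`.
#' @export
cluster_separation <- function(layout, partition) {
  stopifnot(is.matrix(layout))
  lab <- as.character(partition)
  if (!is.null(names(partition)) && !is.null(rownames(layout))) {
    lab <- as.character(partition[rownames(layout)])
  }
  if (length(lab) != nrow(layout) || anyNA(lab)) {
    stop("partition must label every layout row")
  }
  if (length(unique(lab)) < 2) stop("cluster separation needs at least 2 communities")
  sizes <- table(lab)
  if (any(sizes == 1)) {
    warning(sprintf("%d singleton communit(ies) skipped", sum(sizes == 1)))
    keep <- lab %in% names(sizes)[sizes > 1]
    layout <- layout[keep, , drop = FALSE]
    lab <- lab[keep]
    if (length(unique(lab)) < 2) stop("fewer than 2 non-singleton communities")
  }
  sil <- cluster::silhouette(as.integer(factor(lab)), stats::dist(layout))
  mean(sil[, "sil_width"])
}
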