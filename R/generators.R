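#' Seeded benchmark graph generators
#'
#' Generators for the standard random-graph families used to benchmark layout
#' algorithms: Erdos-Renyi (ER), Barabasi-Albert (BA), the stochastic block
#' model (SBM), random geometric graphs (RGG) and cubic lattices. All are
#' deterministic given `seed` and return simple undirected [nl_graph]s.
#'
#' @param n number of nodes.
#' @param p link probability in `[0, 1]`.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return an `nl_graph`.
#' @name generators
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @rdname generators
#' @export
er_graph <- function(n, p, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must be a probability in [0, 1]")
  with_seed(seed, graph_from_igraph(igraph::sample_gnp(n, p)))
}

#' @rdname generators
#' @param m links added per new node (BA); the growth starts from a complete
#'   graph on `m` nodes.
#' @export
ba_graph <- function(n, m, seed = NULL) {
  if (m < 1 || m >= n) stop("require 1 <= m < n")
  with_seed(seed, {
    ig <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                            start.graph = igraph::make_full_graph(m))
    graph_from_igraph(ig)
  })
}

#' @rdname generators
#' @param block_sizes integer vector of community sizes (SBM).
#' @param p_in within-block link probability.
#' @param p_out cross-block link probability. The speedup analysis assumes an
#'   assortative model, `p_in > p_out`; violating it only warns.
#' @return For `sbm_graph` the planted partition is attached as
#'   `attr(g, "partition")`, a named character vector of block labels.
#' @export
sbm_graph <- function(block_sizes, p_in, p_out, seed = NULL) {
  stopifnot(all(block_sizes >= 1))
  for (pp in c(p_in, p_out)) {
    if (!is.numeric(pp) || pp < 0 || pp > 1) stop("probabilities must lie in [0, 1]")
  }
  if (p_in <= p_out) {
    warning("p_in <= p_out: the model is not assortative and the spectral speedup analysis does not apply")
  }
  k <- length(block_sizes)
  pref <- matrix(p_out, k, k); diag(pref) <- p_in
  g <- with_seed(seed, {
    ig <- igraph::sample_sbm(sum(block_sizes), pref.matrix = pref,
                             block.sizes = block_sizes)
    graph_from_igraph(ig)
  })
  part <- rep(paste0("b", seq_len(k)), block_sizes)
  names(part) <- g$node_ids
  attr(g, "partition") <- part
  g
}

#' @rdname generators
#' @param radius linking radius (RGG): nodes at Euclidean distance `<= radius`
#'   in the unit hypercube are connected. Hard walls, no wrap-around.
#' @param spatial_dim 2 or 3, the dimension of the hypercube.
#' @return For `rgg_graph` the planted positions are attached as
#'   `attr(g, "positions")` (an `n x spatial_dim` matrix).
#' @export
rgg_graph <- function(n, radius, spatial_dim = 2, seed = NULL) {
  stopifnot(n >= 1, spatial_dim %in% c(2, 3))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  pts <- with_seed(seed, matrix(runif(n * spatial_dim), n, spatial_dim))
  # cell-binned neighbor search; O(n) for fixed density
  ij <- radius_pairs(pts, radius)
  adj <- Matrix::sparseMatrix(i = c(ij[, 1], ij[, 2]), j = c(ij[, 2], ij[, 1]),
                              x = 1, dims = c(n, n))
  g <- graph_from_adjacency(adj)
  rownames(pts) <- g$node_ids
  attr(g, "positions") <- pts
  g
}

# all unordered pairs of rows of pts closer than r (grid binning)
radius_pairs <- function(pts, r) {
  n <- nrow(pts); d <- ncol(pts)
  cell <- floor(sweep(pts, 2, rep(r, d), "/"))
  key <- apply(cell, 1, paste, collapse = ",")
  bins <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(rep(list(-1:1), d)))
  res_i <- integer(0); res_j <- integer(0)
  for (b in names(bins)) {
    ci <- as.numeric(strsplit(b, ",", fixed = TRUE)[[1]])
    here <- bins[[b]]
    for (o in seq_len(nrow(offsets))) {
      nb <- paste(ci + offsets[o, ], collapse = ",")
      there <- bins[[nb]]
      if (is.null(there)) next
      for (i in here) {
        js <- there[there > i]
        if (!length(js)) next
        dd <- sqrt(rowSums((pts[js, , drop = FALSE] -
                              matrix(pts[i, ], length(js), d, byrow = TRUE))^2))
        hit <- js[dd <= r]
        res_i <- c(res_i, rep(i, length(hit))); res_j <- c(res_j, hit)
      }
    }
  }
  cbind(res_i, res_j)
}

#' @rdname generators
#' @param side lattice sites per side; the lattice has `side^3` nodes at the
#'   integer grid points with links between unit-distance neighbors
#'   (`3 * side^2 * (side - 1)` links).
#' @export
cubic_lattice <- function(side) {
  stopifnot(side >= 1)
  if (side == 1) {
    return(graph_from_adjacency(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                     x = numeric(0), dims = c(1, 1))))
  }
  graph_from_igraph(igraph::make_lattice(c(side, side, side)))
}

#' Generate a graph from a family name and parameter list
#'
#' Dispatch wrapper used by the experiment harness and the CLI.
#'
#' @param family one of `"er"`, `"ba"`, `"sbm"`, `"rgg"`, `"lattice"`.
#' @param params named list of family-specific parameters (see [generators]).
#' @param seed integer seed.
#' @return an `nl_graph`.
#' @export
generate_graph <- function(family = c("er", "ba", "sbm", "rgg", "lattice"),
                           params = list(), seed = NULL) {
  family <- match.arg(family)
  switch(family,
    er = er_graph(params$n, params$p, seed = seed),
    ba = ba_graph(params$n, params$m, seed = seed),
    sbm = sbm_graph(params$block_sizes, params$p_in, params$p_out, seed = seed),
    rgg = rgg_graph(params$n, params$radius,
                    spatial_dim = params$spatial_dim %||% 2, seed = seed),
    lattice = cubic_lattice(params$side))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
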