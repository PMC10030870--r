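#' Normalized adjacency operator f(A)
#'
#' The graph-convolution propagation operator
#' `f(A) = D~^(-1/2) (A + I) D~^(-1/2)` where `D~` is the degree matrix of
#' `A + I`. It is symmetric with eigenvalues in `[-1, 1]`; for a k-regular
#' graph the uniform vector is an eigenvector with eigenvalue 1.
#'
#' @param g an `nl_graph`.
#' @return an object of class `normalized_operator` with elements `matrix`
#'   (sparse symmetric), `degrees` (of the original graph) and `graph`.
#' @export
normalized_operator <- function(g) {
  at <- g$adjacency + Matrix::Diagonal(g$n_nodes)
  dinv <- Matrix::Diagonal(g$n_nodes, 1 / sqrt(Matrix::rowSums(at)))
  structure(list(matrix = dinv %*% at %*% dinv,
                 degrees = Matrix::rowSums(g$adjacency),
                 graph = g),
            class = "normalized_operator")
}

#' @export
print.normalized_operator <- function(x, ...) {
  cat(sprintf("<normalized_operator> f(A) for %d nodes\n", nrow(x$matrix)))
  invisible(x)
}

#' Eigendecomposition of the normalized operator, with outlier detection
#'
#' Full mode computes all eigenpairs densely (intended for N up to a few
#' thousand); `top_k` mode computes the leading `k` eigenpairs by orthogonal
#' iteration with Rayleigh-Ritz refinement, for larger graphs. Eigenvalues are
#' returned in descending order with orthonormal eigenvectors, together with
#' the spectrum mean and standard deviation and the outlier index set
#' `Out = { j : lambda_j > mean + sd }` (strict inequality). Outlier
#' statistics require the full spectrum and are `NULL` in `top_k` mode.
#'
#' @param op a [normalized_operator()] (or an `nl_graph`, converted first).
#' @param mode `"full"` or `"top_k"`.
#' @param k number of leading eigenpairs in `top_k` mode.
#' @param with_adjacency also decompose the raw adjacency matrix (needed by
#'   [predicted_decay_rate()]; full mode only).
#' @param tol,max_iter iteration controls for `top_k` mode.
#' @return an object of class `spectral_decomposition` with `values`,
#'   `vectors`, `mean_eig`, `sd_eig`, `out_set`, `mean_degree`, `degrees`,
#'   `mode`, and (optionally) `adj_values`, `adj_vectors`.
#' @export
eigendecompose <- function(op, mode = c("full", "top_k"), k = 64,
                           with_adjacency = FALSE, tol = 1e-9,
                           max_iter = 1000) {
  mode <- match.arg(mode)
  if (inherits(op, "nl_graph")) op <- normalized_operator(op)
  m <- op$matrix
  n <- nrow(m)
  if (mode == "full") {
    eig <- eigen(as.matrix(Matrix::symmpart(m)), symmetric = TRUE)
    values <- eig$values; vectors <- eig$vectors
    mean_eig <- mean(values); sd_eig <- stats::sd(values)
    out_set <- refine_outliers(values, mean_eig, sd_eig)
  } else {
    if (k >= n) stop("top_k mode requires k < N; use mode = 'full'")
    oi <- orthogonal_iteration(m, k, tol = tol, max_iter = max_iter)
    values <- oi$values; vectors <- oi$vectors
    mean_eig <- sd_eig <- NULL; out_set <- NULL
  }
  dec <- structure(
    list(values = values, vectors = vectors, mean_eig = mean_eig,
         sd_eig = sd_eig, out_set = out_set,
         mean_degree = mean(op$degrees), degrees = op$degrees, mode = mode),
    class = "spectral_decomposition")
  if (with_adjacency) {
    if (mode != "full") stop("adjacency spectrum requires mode = 'full'")
    ae <- eigen(as.matrix(op$graph$adjacency), symmetric = TRUE)
    dec$adj_values <- ae$values
    dec$adj_vectors <- ae$vectors
  }
  dec
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("<spectral_decomposition> %s mode, %d eigenpairs", x$mode,
              length(x$values)))
  if (!is.null(x$out_set)) cat(sprintf(", %d outlier(s)", length(x$out_set)))
  cat("\n")
  invisible(x)
}

# leading-k eigenpairs of a symmetric (sparse) matrix by block power
# iteration with Rayleigh-Ritz; no external sparse eigensolver is assumed
orthogonal_iteration <- function(m, k, tol = 1e-9, max_iter = 1000,
                                 seed = 1L) {
  n <- nrow(m)
  q <- with_seed(seed, matrix(rnorm(n * k), n, k))
  q <- qr.Q(qr(q))
  vals_old <- rep(Inf, k)
  for (it in seq_len(max_iter)) {
    z <- as.matrix(m %*% q)
    q <- qr.Q(qr(z))
    # Rayleigh-Ritz on the current subspace
    h <- crossprod(q, as.matrix(m %*% q))
    e <- eigen((h + t(h)) / 2, symmetric = TRUE)
    # order Ritz values by magnitude descending: power iteration converges to
    # the dominant-magnitude subspace
    o <- order(abs(e$values), decreasing = TRUE)
    vals <- e$values[o]
    if (max(abs(vals - vals_old)) < tol) {
      q <- q %*% e$vectors[, o, drop = FALSE]
      oo <- order(vals, decreasing = TRUE)
      return(list(values = vals[oo], vectors = q[, oo, drop = FALSE]))
    }
    vals_old <- vals
    q <- q %*% e$vectors[, o, drop = FALSE]
  }
  stop("orthogonal iteration did not converge; increase max_iter or use mode = 'full'")
}

#' Outlier eigenvalue indices
#'
#' Eigenvalues that separate from the bulk (Wigner semicircle) of the
#' spectrum. Candidates are the eigenvalues strictly above the spectrum mean
#' plus one standard deviation; by default the candidate list is then cut at
#' its largest downward gap (the standard eigengap heuristic), which discards
#' the upper tail of the semicircle that the plain one-standard-deviation
#' threshold inevitably sweeps up. For an assortative SBM this yields one
#' outlier per block; ER and BA graphs have at most the leading
#' (Perron) mode. `refine = "none"` gives the bare threshold rule; see the
#' vignette for why the refinement is the default.
#'
#' @param dec a full-mode [eigendecompose()] result.
#' @param refine `"gap"` (default) or `"none"`.
#' @return integer vector of indices into the descending spectrum (possibly
#'   empty).
#' @export
outlier_set <- function(dec, refine = c("gap", "none")) {
  refine <- match.arg(refine)
  if (is.null(dec$values) || is.null(dec$mean_eig)) {
    stop("outlier detection requires a full-mode decomposition")
  }
  refine_outliers(dec$values, dec$mean_eig, dec$sd_eig, refine)
}

refine_outliers <- function(values, mean_eig, sd_eig, refine = "gap") {
  cand <- which(values > mean_eig + sd_eig)  # strict, as the rule states
  if (!length(cand) || refine == "none") return(cand)
  m <- length(cand)
  if (m == length(values)) return(cand)
  # gap below each candidate, down to the top of the non-candidate bulk
  ref <- c(values[cand][-1], values[m + 1])
  cut <- which.max(values[cand] - ref)
  cand[seq_len(cut)]
}

#' Split the operator into outlier (top) and bulk parts
#'
#' `A_top = sum_{i in Out} lambda_i psi_i psi_i'` and
#' `A_bulk = f(A) - A_top`, the substitution matrices for the spectral
#' ablation experiment.
#'
#' @param dec a full-mode [eigendecompose()] result.
#' @param op the [normalized_operator()] the decomposition came from.
#' @return list with dense matrices `top` and `bulk`; `top` has rank
#'   `length(outlier_set(dec))`.
#' @export
split_operator <- function(dec, op) {
  if (dec$mode != "full") stop("split requires a full-mode decomposition")
  m <- as.matrix(operator_matrix(op))
  out <- dec$out_set
  if (length(out) == 0) {
    top <- matrix(0, nrow(m), ncol(m))
  } else {
    v <- dec$vectors[, out, drop = FALSE]
    top <- v %*% (dec$values[out] * t(v))
  }
  list(top = top, bulk = m - top)
}

#' Operator variant for the GCN layers
#'
#' Convenience dispatcher used by [train_model()]: the full normalized
#' operator, its outlier-only projection, or the bulk complement. The top and
#' bulk variants are returned in structured form (rank-`|Out|` factorization,
#' and sparse-minus-low-rank, respectively) so that training with them costs
#' no more per step than with the full sparse operator; they represent
#' exactly the same matrices as [split_operator()].
#'
#' @param g an `nl_graph`.
#' @param which `"full"`, `"top"` or `"bulk"`.
#' @return the full sparse matrix, or a structured operator usable wherever
#'   the GCN propagation matrix is expected.
#' @export
operator_variant <- function(g, which = c("full", "top", "bulk")) {
  which <- match.arg(which)
  op <- normalized_operator(g)
  if (which == "full") return(op$matrix)
  dec <- eigendecompose(op, mode = "full")
  out <- dec$out_set
  v <- dec$vectors[, out, drop = FALSE]
  lam <- dec$values[out]
  if (which == "top") {
    structure(list(V = v, lambda = lam, n = nrow(v)),
              class = "nl_lowrank_operator")
  } else {
    structure(list(matrix = op$matrix, V = v, lambda = lam, n = nrow(v)),
              class = "nl_deflated_operator")
  }
}

# multiply a (possibly structured) symmetric graph operator into dense columns
apply_operator <- function(op, m) {
  if (inherits(op, "nl_lowrank_operator")) {
    if (length(op$lambda) == 0) return(matrix(0, op$n, ncol(m)))
    return(op$V %*% (op$lambda * crossprod(op$V, m)))
  }
  if (inherits(op, "nl_deflated_operator")) {
    full <- as.matrix(op$matrix %*% m)
    if (length(op$lambda) == 0) return(full)
    return(full - op$V %*% (op$lambda * crossprod(op$V, m)))
  }
  as.matrix(op %*% m)
}

#' @export
print.nl_lowrank_operator <- function(x, ...) {
  cat(sprintf("<operator: outlier projection> rank %d on %d nodes\n",
              length(x$lambda), x$n))
  invisible(x)
}

#' @export
print.nl_deflated_operator <- function(x, ...) {
  cat(sprintf("<operator: bulk (outliers removed)> %d mode(s) deflated on %d nodes\n",
              length(x$lambda), x$n))
  invisible(x)
}

#' Overlap of a layout with eigenvector modes
#'
#' The Euclidean norm across layout columns of `psi_i' X` for each requested
#' eigenvector: the magnitude of the layout's projection on each mode. Over a
#' full basis the squared overlaps sum to `||X||_F^2`.
#'
#' @param layout N x d coordinate matrix.
#' @param dec a [eigendecompose()] result (normalized-operator eigenvectors),
#'   or a matrix of eigenvector columns.
#' @param indices which modes; default all available.
#' @return numeric vector of overlap magnitudes.
#' @export
mode_overlap <- function(layout, dec, indices = NULL) {
  v <- if (is.matrix(dec)) dec else dec$vectors
  if (is.null(indices)) indices <- seq_len(ncol(v))
  v <- v[, indices, drop = FALSE]
  stopifnot(nrow(v) == nrow(layout))
  sqrt(rowSums((crossprod(v, layout))^2))
}

#' Predicted early decay rate of eigenmode overlaps under FDL
#'
#' In the early, elastic-dominated stage of plain gradient descent on a
#' near-regular graph, the overlap of the layout with adjacency eigenvector
#' `psi_i` decays exponentially at rate `epsilon * (<k> - lambda_i)` per step,
#' where `lambda_i` is the raw adjacency eigenvalue. Modes with the largest
#' eigenvalues (the outliers) are the slow modes. The approximation
#' `L ~ <k> I - A` needs near-regularity; a degree coefficient of variation
#' above 0.2 triggers a warning. Rates are clamped at zero.
#'
#' @param dec an [eigendecompose()] result created with
#'   `with_adjacency = TRUE`.
#' @param indices which adjacency modes (descending eigenvalue order).
#' @param epsilon the gradient-descent learning rate.
#' @return numeric vector of per-step decay rates.
#' @export
predicted_decay_rate <- function(dec, indices, epsilon) {
  if (is.null(dec$adj_values)) {
    stop("decomposition lacks the adjacency spectrum; rerun eigendecompose(with_adjacency = TRUE)")
  }
  cv <- stats::sd(dec$degrees) / mean(dec$degrees)
  if (is.finite(cv) && cv > 0.2) {
    warning(sprintf("degree coefficient of variation %.2f > 0.2: the near-regular approximation is unreliable", cv))
  }
  pmax(0, epsilon * (dec$mean_degree - dec$adj_values[indices]))
}
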