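#' Energy parameters for the force-directed loss
#'
#' Bundles the knobs of the layout energy: the short-range Gaussian repulsion
#' amplitude `a_n`, its range `r0`, the interaction cutoff, and the gradient
#' descent learning rate `epsilon`.
#'
#' The repulsion amplitude defaults to `1/N` (resolved against the layout at
#' evaluation time when left `NULL`) so that the total repulsive pressure
#' stays comparable to the elastic term as graphs grow. The cutoff defaults to
#' `4 * r0`, at which the per-pair truncation error is below `exp(-4)`.
#'
#' @param a_n repulsion amplitude (energy units); `NULL` means `1/N`.
#' @param r0 repulsion range (length units), `> 0`.
#' @param cutoff interaction cutoff radius, at least `2 * r0`.
#' @param epsilon learning rate per step, `> 0`.
#' @return an object of class `energy_params`.
#' @export
energy_params <- function(a_n = NULL, r0 = 0.1, cutoff = 4 * r0, epsilon = 0.01) {
  stopifnot(r0 > 0, epsilon > 0)
  if (!is.null(a_n) && a_n < 0) stop("a_n must be non-negative")
  if (cutoff < 2 * r0) stop("cutoff must be at least 2 * r0")
  structure(list(a_n = a_n, r0 = r0, cutoff = cutoff, epsilon = epsilon),
            class = "energy_params")
}

resolve_a_n <- function(params, n) {
  if (is.null(params$a_n)) 1 / n else params$a_n
}

#' Elastic (spring) energy of a layout
#'
#' The quadratic link energy `V_el = 1/2 Tr(X' L X)`, i.e. half of
#' `sum_{i<j} A_ij |x_i - x_j|^2`, whose gradient is `L X`.
#'
#' @param g an `nl_graph`.
#' @param layout N x d coordinate matrix.
#' @return scalar energy, `>= 0`.
#' @export
elastic_energy <- function(g, layout) {
  check_layout(g, layout)
  lx <- as.matrix(graph_laplacian(g) %*% layout)
  0.5 * sum(layout * lx)
}

#' Gradient of the elastic energy
#'
#' @inheritParams elastic_energy
#' @return the N x d matrix `L X`.
#' @export
elastic_gradient <- function(g, layout) {
  check_layout(g, layout)
  as.matrix(graph_laplacian(g) %*% layout)
}

#' Short-range Gaussian repulsive energy
#'
#' `V_rep = a_n * sum_{i<j} exp(-|x_i - x_j|^2 / (4 r0^2))` over unordered
#' pairs closer than the cutoff. The default `"cell_list"` method bins points
#' on a grid of spacing `cutoff` and is exact for the truncated potential;
#' `"brute"` enumerates all pairs and is kept as an oracle.
#'
#' @param layout N x d coordinate matrix.
#' @param params an [energy_params()] object.
#' @param method `"cell_list"` or `"brute"`.
#' @return scalar energy, `>= 0`.
#' @export
repulsive_energy <- function(layout, params = energy_params(),
                             method = c("cell_list", "brute")) {
  method <- match.arg(method)
  stopifnot(is.matrix(layout), all(is.finite(layout)))
  a_n <- resolve_a_n(params, nrow(layout))
  repulsion_terms_cpp(layout, a_n, params$r0, params$cutoff,
                      method == "cell_list", FALSE)$energy
}

#' Gradient of the repulsive energy
#'
#' @inheritParams repulsive_energy
#' @return N x d gradient matrix (equal-and-opposite pairwise terms, so its
#'   column sums vanish).
#' @export
repulsive_gradient <- function(layout, params = energy_params(),
                               method = c("cell_list", "brute")) {
  method <- match.arg(method)
  stopifnot(is.matrix(layout), all(is.finite(layout)))
  a_n <- resolve_a_n(params, nrow(layout))
  repulsion_terms_cpp(layout, a_n, params$r0, params$cutoff,
                      method == "cell_list", TRUE)$gradient
}

#' Total layout loss: elastic plus repulsive energy
#'
#' The single optimization objective used by both the direct force-directed
#' optimizer and the neural reparametrizations.
#'
#' @inheritParams elastic_energy
#' @param params an [energy_params()] object.
#' @param method repulsion evaluation method.
#' @return scalar loss.
#' @export
total_loss <- function(g, layout, params = energy_params(),
                       method = c("cell_list", "brute")) {
  elastic_energy(g, layout) + repulsive_energy(layout, params, method)
}

# energy and gradient of the full loss in one pass (shared by optimizers)
loss_and_gradient <- function(g, L, layout, params, method = "cell_list") {
  lx <- as.matrix(L %*% layout)
  a_n <- resolve_a_n(params, nrow(layout))
  rep <- repulsion_terms_cpp(layout, a_n, params$r0, params$cutoff,
                             method == "cell_list", TRUE)
  list(energy = 0.5 * sum(layout * lx) + rep$energy,
       gradient = lx + rep$gradient)
}
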