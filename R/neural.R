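#' Initialize trainable parameters for a neural layout model
#'
#' Three architectures share one parameter container:
#' * `nodemlp` — a trainable `N x h` embedding `Z` projected straight to the
#'   layout, `X = sigma_out(Z W + b)`;
#' * `neulay` — one graph-convolution layer `G1 = tanh(f(A) Z W1)`
#'   concatenated with `Z` before projection;
#' * `neulay2` — two stacked layers, `G2 = tanh(f(A) G1 W2)`, with
#'   `G = [Z | G1 | G2]` and `X = sigma_out(G W + b)`.
#'
#' `Z` is i.i.d. Gaussian with standard deviation `scale`; weight matrices are
#' Gaussian with variance `1/fan_in`; biases start at zero. Widths of zero
#' drop the corresponding layer, so `neulay2` with `h2 = 0` is `neulay`, and
#' with `h1 = h2 = 0` it degenerates to `nodemlp`.
#'
#' @param n number of nodes.
#' @param model `"nodemlp"`, `"neulay"` or `"neulay2"`.
#' @param d layout dimension (2 or 3).
#' @param h,h1,h2 embedding and layer widths; default `min(n, 100)`.
#' @param seed integer RNG seed.
#' @param scale standard deviation of the initial embedding `Z`.
#' @param sigma_out output nonlinearity, `"identity"` (default) or `"tanh"`.
#'   The saturating output confines coordinates to a box and is off by
#'   default; see the package vignette.
#' @return an object of class `neural_params`.
#' @export
neural_params <- function(n, model = c("neulay2", "neulay", "nodemlp"),
                          d = 3, h = min(n, 100), h1 = NULL, h2 = NULL,
                          seed = NULL, scale = 1,
                          sigma_out = c("identity", "tanh")) {
  model <- match.arg(model)
  sigma_out <- match.arg(sigma_out)
  stopifnot(n >= 1, d %in% c(2, 3), h >= 1, scale >= 0)
  h1 <- h1 %||% (if (model == "nodemlp") 0L else min(n, 100))
  h2 <- h2 %||% (if (model == "neulay2") min(n, 100) else 0L)
  if (model == "nodemlp" && (h1 > 0 || h2 > 0)) {
    stop("nodemlp has no graph-convolution layers; h1 and h2 must be 0")
  }
  if (model == "neulay" && h2 > 0) stop("one-layer neulay requires h2 = 0")
  if (model == "neulay2" && h1 == 0 && h2 > 0) stop("h2 > 0 requires h1 > 0")
  with_seed(seed, {
    p <- list(model = model, n = n, d = d, h = h, h1 = h1, h2 = h2,
              sigma_hidden = "tanh", sigma_out = sigma_out,
              Z = matrix(rnorm(n * h, sd = scale), n, h),
              W = matrix(rnorm((h + h1 + h2) * d, sd = 1 / sqrt(h + h1 + h2)),
                         h + h1 + h2, d),
              b = numeric(d))
    if (h1 > 0) p$W1 <- matrix(rnorm(h * h1, sd = 1 / sqrt(h)), h, h1)
    if (h2 > 0) p$W2 <- matrix(rnorm(h1 * h2, sd = 1 / sqrt(h1)), h1, h2)
    structure(p, class = "neural_params")
  })
}

#' @export
print.neural_params <- function(x, ...) {
  cat(sprintf("<neural_params> %s: N=%d, d=%d, widths h=%d h1=%d h2=%d, sigma_out=%s\n",
              x$model, x$n, x$d, x$h, x$h1, x$h2, x$sigma_out))
  invisible(x)
}

sigma_apply <- function(tag, x) if (tag == "tanh") tanh(x) else x
# derivative expressed through the activation value
sigma_deriv_from_value <- function(tag, y) if (tag == "tanh") 1 - y^2 else 1

# forward pass keeping every intermediate needed by the backward pass.
# The concatenated embedding G = [Z | G1 | G2] is never materialized: the
# final projection G W is computed block-wise against the row blocks of W.
model_forward_cache <- function(params, op = NULL) {
  Z <- params$Z
  h <- params$h; h1 <- params$h1; h2 <- params$h2
  cache <- list(Z = Z)
  pre <- Z %*% params$W[seq_len(h), , drop = FALSE]
  if (h1 > 0) {
    if (is.null(op)) stop("graph operator required for neulay models")
    cache$FZ <- apply_operator(op, Z)
    cache$G1 <- sigma_apply(params$sigma_hidden, cache$FZ %*% params$W1)
    pre <- pre + cache$G1 %*% params$W[h + seq_len(h1), , drop = FALSE]
    if (h2 > 0) {
      cache$FG1 <- apply_operator(op, cache$G1)
      cache$G2 <- sigma_apply(params$sigma_hidden, cache$FG1 %*% params$W2)
      pre <- pre + cache$G2 %*% params$W[h + h1 + seq_len(h2), , drop = FALSE]
    }
  }
  if (any(params$b != 0)) pre <- pre + rep(params$b, each = nrow(Z))
  cache$X <- sigma_apply(params$sigma_out, pre)
  cache
}

#' Forward pass of a neural layout model
#'
#' @param params a [neural_params()] object.
#' @param op the normalized graph operator `f(A)` (a matrix or
#'   [normalized_operator()] result); only needed for `neulay`/`neulay2`.
#' @return the `N x d` layout matrix.
#' @export
model_forward <- function(params, op = NULL) {
  model_forward_cache(params, operator_matrix(op))$X
}

#' @rdname model_forward
#' @export
nodemlp_forward <- function(params) model_forward(params)

#' @rdname model_forward
#' @export
neulay2_forward <- function(op, params) model_forward(params, op)

operator_matrix <- function(op) {
  if (is.null(op)) return(NULL)
  if (inherits(op, "normalized_operator")) op$matrix else op
}

# reverse-mode gradients of the loss w.r.t. every trainable tensor, given the
# gradient gX of the loss w.r.t. the layout; op must be symmetric
model_backward <- function(params, cache, gX, op = NULL) {
  dpre <- gX * sigma_deriv_from_value(params$sigma_out, cache$X)
  h <- params$h; h1 <- params$h1; h2 <- params$h2
  gW <- matrix(0, h + h1 + h2, ncol(dpre))
  gW[seq_len(h), ] <- crossprod(cache$Z, dpre)
  grads <- list(Z = NULL, W = NULL, b = colSums(dpre))
  gZ <- dpre %*% t(params$W[seq_len(h), , drop = FALSE])
  if (h1 > 0) {
    gW[h + seq_len(h1), ] <- crossprod(cache$G1, dpre)
    gG1 <- dpre %*% t(params$W[h + seq_len(h1), , drop = FALSE])
    if (h2 > 0) {
      gW[h + h1 + seq_len(h2), ] <- crossprod(cache$G2, dpre)
      gG2 <- dpre %*% t(params$W[h + h1 + seq_len(h2), , drop = FALSE])
      gH2 <- gG2 * sigma_deriv_from_value(params$sigma_hidden, cache$G2)
      grads$W2 <- crossprod(cache$FG1, gH2)
      gG1 <- gG1 + apply_operator(op, gH2 %*% t(params$W2))
    }
    gH1 <- gG1 * sigma_deriv_from_value(params$sigma_hidden, cache$G1)
    grads$W1 <- crossprod(cache$FZ, gH1)
    gZ <- gZ + apply_operator(op, gH1 %*% t(params$W1))
  }
  grads$Z <- gZ
  grads$W <- gW
  grads[intersect(names(params), names(grads))]
}

#' Train a neural layout model on a graph
#'
#' Gradient descent on the trainable tensors of the chosen architecture,
#' minimizing the same elastic-plus-repulsion loss as [run_fdl()] but through
#' the reparametrization `X = X(theta)`; gradients are exact (reverse-mode
#' chain rule). Trajectory, stopping and recording semantics match
#' [run_fdl()].
#'
#' @inheritParams run_fdl
#' @param model `"neulay2"`, `"neulay"` or `"nodemlp"`.
#' @param init a [neural_params()] object; defaults to fresh parameters drawn
#'   with `seed` and widths `hidden`.
#' @param hidden widths `c(h, h1, h2)` used when `init` is NULL; `NULL` for
#'   the per-model defaults.
#' @param operator which graph operator to place inside the GCN layers:
#'   `"full"` (the normalized adjacency `f(A)`), `"top"` (its projection onto
#'   outlier eigenpairs), `"bulk"` (the complement), or an explicit symmetric
#'   matrix.
#' @param seed seed for the default parameter initialization.
#' @return a list with `layout`, `trajectory`, `params` (trained), and
#'   `operator` (the matrix actually used).
#' @examples
#' g <- cubic_lattice(2)
#' res <- train_model(g, "neulay2", seed = 1, stop = stop_rule(max_steps = 200))
#' @export
train_model <- function(g, model = c("neulay2", "neulay", "nodemlp"),
                        init = NULL, params = energy_params(),
                        stop = stop_rule(), record_every = 10, dim = 3,
                        seed = NULL, hidden = NULL,
                        operator = "full", optimizer = c("gd", "adam"),
                        modes = NULL, snapshot_every = 0,
                        method = "cell_list") {
  model <- match.arg(model)
  optimizer <- match.arg(optimizer)
  Fop <- if (is.character(operator)) {
    if (model == "nodemlp") NULL else operator_variant(g, operator)
  } else operator_matrix(operator)
  if (is.null(init)) {
    h <- if (is.null(hidden)) min(g$n_nodes, 100) else hidden[1]
    h1 <- if (is.null(hidden)) NULL else as.integer(hidden[2])
    h2 <- if (is.null(hidden)) NULL else as.integer(hidden[3])
    init <- neural_params(g$n_nodes, model, d = dim, h = h, h1 = h1, h2 = h2,
                          seed = seed)
  }
  stopifnot(inherits(init, "neural_params"), init$n == g$n_nodes)
  L <- graph_laplacian(g)
  trainable <- intersect(names(init), c("Z", "W1", "W2", "W", "b"))
  cache_env <- new.env(parent = emptyenv())

  run_gd_loop(
    state = init,
    forward = function(state) {
      cache_env$cache <- model_forward_cache(state, Fop)
      cache_env$cache$X
    },
    backward = function(state, gX) {
      model_backward(state, cache_env$cache, gX, Fop)
    },
    trainable = trainable,
    optimizer = optimizer, epsilon = params$epsilon,
    g = g, L = L, params = params, stop = stop,
    record_every = record_every, modes = modes,
    snapshot_every = snapshot_every, method = method,
    result = function(state, traj, eps) {
      list(layout = cache_env$cache$X, trajectory = traj, params = state,
           operator = Fop, epsilon = eps)
    })
}

#' Numerical loss gradient with respect to the model parameters
#'
#' Central finite differences of the total loss through the forward map —
#' the independent check for the analytic chain-rule gradients. Intended for
#' small instances only.
#'
#' @param g an `nl_graph`.
#' @param nparams a [neural_params()].
#' @param eparams an [energy_params()].
#' @param op graph operator (or NULL for nodemlp).
#' @param tensor name of the tensor to differentiate (`"Z"`, `"W1"`, ...).
#' @param eps finite-difference step.
#' @return an array of the same shape as the tensor.
#' @keywords internal
numerical_param_gradient <- function(g, nparams, eparams, op = NULL,
                                     tensor = "Z", eps = 1e-5) {
  op <- operator_matrix(op)
  f <- function(p) total_loss(g, model_forward_cache(p, op)$X, eparams,
                              method = "brute")
  th <- nparams[[tensor]]
  out <- th
  for (i in seq_along(th)) {
    pp <- nparams; pm <- nparams
    pp[[tensor]][i] <- th[i] + eps
    pm[[tensor]][i] <- th[i] - eps
    out[i] <- (f(pp) - f(pm)) / (2 * eps)
  }
  out
}
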