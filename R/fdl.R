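#' Random initial layout
#'
#' I.i.d. Gaussian coordinates with mean 0 and standard deviation `scale`,
#' the standard "random configuration" start for force-directed layout.
#'
#' @param n number of nodes.
#' @param dim layout dimension, 2 or 3.
#' @param scale coordinate standard deviation.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return an `n x dim` coordinate matrix.
#' @export
init_layout <- function(n, dim = 3, scale = 1, seed = NULL) {
  stopifnot(n >= 1, dim %in% c(2, 3), scale >= 0)
  with_seed(seed, matrix(rnorm(n * dim, sd = scale), n, dim))
}

#' Stopping rule for gradient-descent layout
#'
#' Declares convergence when the relative energy change over a window of
#' `window` steps falls below `rel_tol`, with a hard cap of `max_steps`.
#'
#' @param rel_tol relative energy-change tolerance, `> 0`.
#' @param window step span of the change test, `>= 1`.
#' @param max_steps iteration cap.
#' @return an object of class `stop_rule`.
#' @export
stop_rule <- function(rel_tol = 1e-5, window = 50, max_steps = 1e5) {
  stopifnot(rel_tol > 0, window >= 1, max_steps >= 1)
  structure(list(rel_tol = rel_tol, window = as.integer(window),
                 max_steps = as.integer(max_steps)),
            class = "stop_rule")
}

new_trajectory <- function(steps, energies, wall_times, snapshots = NULL,
                           mode_overlaps = NULL, converged = NA) {
  structure(list(steps = steps, energies = energies, wall_times = wall_times,
                 snapshots = snapshots, mode_overlaps = mode_overlaps,
                 converged = converged),
            class = "nl_trajectory")
}

#' @export
print.nl_trajectory <- function(x, ...) {
  cat(sprintf("<nl_trajectory> %d recorded steps (0..%d), energy %.6g -> %.6g%s\n",
              length(x$steps), max(x$steps), x$energies[1],
              tail(x$energies, 1),
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Has a trajectory converged under a stopping rule?
#'
#' TRUE when the relative energy change across the rule's window — measured on
#' the recorded energies, at the closest recorded lag of at least `window`
#' steps — is below `rel_tol`.
#'
#' @param trajectory an `nl_trajectory`.
#' @param stop a [stop_rule()].
#' @return logical.
#' @export
converged <- function(trajectory, stop = stop_rule()) {
  s <- trajectory$steps; e <- trajectory$energies
  t <- length(e)
  if (t < 2) return(FALSE)
  j <- which(s <= s[t] - stop$window)
  if (!length(j)) return(FALSE)
  j <- max(j)
  abs(e[t] - e[j]) / max(abs(e[t]), .Machine$double.xmin) < stop$rel_tol
}

# first-order optimizer over a list of arrays; "gd" is plain gradient descent
# (the baseline dynamics, fixed step), "adam" the standard adaptive-moment
# variant. The adaptive step size can be lowered mid-run (plateau annealing);
# plain GD keeps Eq.-style fixed-step dynamics.
make_optimizer <- function(optimizer = c("gd", "adam"), epsilon,
                           beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  optimizer <- match.arg(optimizer)
  st <- new.env(parent = emptyenv())
  st$m <- NULL; st$v <- NULL; st$t <- 0; st$eps <- epsilon
  update <- function(params, grads) {
    if (optimizer == "gd") {
      return(mapply(function(p, g) p - st$eps * g, params, grads,
                    SIMPLIFY = FALSE))
    }
    # moments kept as one flat vector across all tensors (elementwise updates
    # are order-independent, so flattening changes nothing numerically)
    st$t <- st$t + 1
    gflat <- unlist(grads, use.names = FALSE)
    if (is.null(st$m)) {
      st$m <- numeric(length(gflat))
      st$v <- numeric(length(gflat))
    }
    bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
    st$m <- beta1 * st$m + (1 - beta1) * gflat
    st$v <- beta2 * st$v + (1 - beta2) * gflat^2
    step <- st$eps * (st$m / bc1) / (sqrt(st$v / bc2) + adam_eps)
    out <- params
    i0 <- 0L
    for (k in seq_along(params)) {
      len <- length(params[[k]])
      out[[k]] <- params[[k]] - step[i0 + seq_len(len)]
      i0 <- i0 + len
    }
    out
  }
  list(update = update, set_eps = function(e) st$eps <- e,
       get_eps = function() st$eps)
}

#' Force-directed layout by gradient descent on node coordinates
#'
#' The baseline layout dynamics: repeated steps
#' `X <- X - epsilon * (L X + dV_rep/dX)` until the stopping rule fires. If
#' the first step increases the energy, the learning rate is halved (with a
#' warning) until it does not.
#'
#' @param g an `nl_graph`.
#' @param init initial layout; defaults to [init_layout()] with `seed`.
#' @param params an [energy_params()].
#' @param stop a [stop_rule()].
#' @param record_every record the energy/wall-time every this many steps.
#' @param dim layout dimension used when `init` is NULL.
#' @param seed seed for the default initial layout.
#' @param optimizer `"gd"` (plain gradient descent, the baseline) or
#'   `"adam"`. Model comparisons should use the same optimizer on both sides.
#' @param modes optional N x m matrix of eigenvectors; the Euclidean norm of
#'   each mode's overlap with the layout is recorded per recorded step.
#' @param snapshot_every if `> 0`, store a copy of the layout every this many
#'   steps.
#' @param method repulsion evaluation method.
#' @return a list with elements `layout` (final N x d matrix), `trajectory`
#'   (an `nl_trajectory`) and `epsilon` (the possibly halved learning rate).
#' @examples
#' g <- cubic_lattice(2)
#' res <- run_fdl(g, seed = 1, stop = stop_rule(max_steps = 500))
#' tail(res$trajectory$energies, 1)
#' @export
run_fdl <- function(g, init = NULL, params = energy_params(),
                    stop = stop_rule(), record_every = 10, dim = 3,
                    seed = NULL, optimizer = c("gd", "adam"), modes = NULL,
                    snapshot_every = 0, method = "cell_list") {
  optimizer <- match.arg(optimizer)
  if (is.null(init)) init <- init_layout(g$n_nodes, dim = dim, seed = seed)
  check_layout(g, init)
  L <- graph_laplacian(g)
  run_gd_loop(
    state = list(X = init),
    forward = function(state) state$X,
    backward = function(state, gX) list(X = gX),
    trainable = "X",
    optimizer = optimizer, epsilon = params$epsilon,
    g = g, L = L, params = params, stop = stop,
    record_every = record_every, modes = modes,
    snapshot_every = snapshot_every, method = method,
    result = function(state, traj, eps) list(layout = state$X, trajectory = traj,
                                             epsilon = eps))
}

# shared gradient-descent loop: `forward` maps the optimized state to a
# layout, `backward` pulls the loss gradient on X back to the state tensors
# named in `trainable`. For plain GD the learning rate is halved (with one
# warning) until the first step does not increase the energy.
run_gd_loop <- function(state, forward, backward, trainable, optimizer,
                        epsilon, g, L, params, stop,
                        record_every, modes, snapshot_every, method, result) {
  X <- forward(state)
  lg0 <- loss_and_gradient(g, L, X, params, method)
  eps <- epsilon
  if (optimizer == "gd" && g$n_nodes > 1) {
    g0 <- backward(state, lg0$gradient)
    halved <- 0
    while (halved < 60) {
      trial <- state
      trial[trainable] <- mapply(function(p, gr) p - eps * gr,
                                 state[trainable], g0[trainable],
                                 SIMPLIFY = FALSE)
      e1 <- loss_and_gradient(g, L, forward(trial), params, method)$energy
      if (is.finite(e1) && e1 <= lg0$energy) break
      eps <- eps / 2
      halved <- halved + 1
    }
    if (halved > 0) {
      warning(sprintf("first step increased the energy; epsilon halved %d time(s) to %g",
                      halved, eps))
    }
  }
  opt <- make_optimizer(optimizer, eps)
  update <- function(state, grads) {
    state[trainable] <- opt$update(state[trainable], grads[trainable])
    state
  }
  # the adaptive optimizer jitters around its basin with amplitude set by the
  # step size, so a plateau is only trusted after the step has been annealed
  # to its floor; plain GD is monotone and stops at the first plateau
  max_decay <- if (optimizer == "adam") 4L else 0L
  n_decay <- 0L
  last_event <- 0L
  rec_steps <- integer(0); rec_energy <- numeric(0); rec_wall <- numeric(0)
  rec_overlap <- NULL; snapshots <- if (snapshot_every > 0) list() else NULL
  energies <- numeric(stop$max_steps + 1)
  t0 <- proc.time()[["elapsed"]]
  X <- forward(state)  # refresh any forward cache after the trial steps
  lg <- list(energy = lg0$energy, gradient = lg0$gradient)

  record <- function(step, X, energy) {
    rec_steps <<- c(rec_steps, step)
    rec_energy <<- c(rec_energy, energy)
    rec_wall <<- c(rec_wall, proc.time()[["elapsed"]] - t0)
    if (!is.null(modes)) {
      ov <- sqrt(rowSums((crossprod(modes, X))^2))
      rec_overlap <<- rbind(rec_overlap, ov)
    }
    if (!is.null(snapshots) && (step %% snapshot_every == 0)) {
      snapshots[[as.character(step)]] <<- X
    }
  }

  energies[1] <- lg$energy
  record(0L, X, lg$energy)
  stopped <- FALSE
  final_step <- 0L

  n_backtrack <- 0L
  for (step in seq_len(stop$max_steps)) {
    if (!is.finite(lg$energy)) {
      stop("energy diverged (non-finite); use a smaller epsilon")
    }
    grads <- backward(state, lg$gradient)
    prev_state <- state
    state <- update(state, grads)
    X <- forward(state)
    lg_new <- loss_and_gradient(g, L, X, params, method)
    # backtracking safeguard: a catastrophic jump (non-finite energy or more
    # than double) reverts the step and halves the step size
    if ((!is.finite(lg_new$energy) || lg_new$energy > 2 * abs(lg$energy) + 1e-12) &&
        n_backtrack < 40L) {
      n_backtrack <- n_backtrack + 1L
      opt$set_eps(opt$get_eps() / 2)
      state <- prev_state
      X <- forward(state)
      energies[step + 1] <- lg$energy
      final_step <- step
      next
    }
    lg <- lg_new
    energies[step + 1] <- lg$energy
    final_step <- step
    if (step %% record_every == 0) record(step, X, lg$energy)
    # plateau test on window means (robust to step-to-step jitter): compare
    # the mean energy over the last window with the window before it
    if (step - last_event >= 2L * stop$window) {
      w <- stop$window
      m_now <- mean(energies[(step + 2 - w):(step + 1)])
      m_prev <- mean(energies[(step + 2 - 2 * w):(step + 1 - w)])
      if (abs(m_now - m_prev) / max(abs(m_now), .Machine$double.xmin) < stop$rel_tol) {
        if (n_decay < max_decay) {
          n_decay <- n_decay + 1L
          opt$set_eps(opt$get_eps() / 2)
          last_event <- step
        } else {
          stopped <- TRUE
          break
        }
      }
    }
  }
  if (!is.finite(lg$energy)) {
    stop("energy diverged (non-finite); use a smaller epsilon")
  }
  if (tail(rec_steps, 1) != final_step) record(final_step, X, lg$energy)
  traj <- new_trajectory(rec_steps, rec_energy, rec_wall, snapshots,
                         rec_overlap, stopped)
  result(state, traj, eps)
}
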