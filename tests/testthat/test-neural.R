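test_that("nodemlp forward is the affine map it claims to be", {
  p <- neural_params(5, "nodemlp", d = 3, h = 4, seed = 1)
  # zero weights and bias give the all-zero layout
  p0 <- p; p0$W[] <- 0; p0$b[] <- 0
  expect_equal(nodemlp_forward(p0), matrix(0, 5, 3), ignore_attr = TRUE)
  # identity-like projection shifts rows by the bias
  p1 <- neural_params(4, "nodemlp", d = 3, h = 3, seed = 2)
  p1$W <- diag(3); p1$b <- c(1, -2, 0.5)
  expect_equal(nodemlp_forward(p1), sweep(p1$Z, 2, c(1, -2, 0.5), "+"),
               ignore_attr = TRUE)
  # independent matrix-multiply oracle
  p2 <- neural_params(6, "nodemlp", d = 2, h = 5, seed = 3)
  expect_equal(nodemlp_forward(p2),
               sweep(p2$Z %*% p2$W, 2, p2$b, "+"), tolerance = 1e-12)
})

test_that("neulay2 forward composes GCN layers as specified", {
  g <- er_graph(20, 0.3, seed = 4)
  fa <- normalized_operator(g)
  p <- neural_params(20, "neulay2", d = 3, h = 6, h1 = 5, h2 = 4, seed = 5)
  x <- neulay2_forward(fa, p)
  # oracle recomputation
  fm <- as.matrix(fa$matrix)
  g1 <- tanh(fm %*% p$Z %*% p$W1)
  g2 <- tanh(fm %*% g1 %*% p$W2)
  gg <- cbind(p$Z, g1, g2)
  expect_equal(x, sweep(gg %*% p$W, 2, p$b, "+"), tolerance = 1e-9)

  # pass-through: zero GCN weights, W selecting the Z block
  pz <- p
  pz$W1[] <- 0; pz$W2[] <- 0; pz$W[] <- 0; pz$b[] <- 0
  pz$W[1:3, 1:3] <- diag(3)
  expect_equal(neulay2_forward(fa, pz), pz$Z[, 1:3], ignore_attr = TRUE)

  # single isolated node: f(A) = [[1]]
  g1n <- graph_from_adjacency(matrix(0, 1, 1))
  fa1 <- normalized_operator(g1n)
  expect_equal(as.matrix(fa1$matrix), matrix(1))
  p1 <- neural_params(1, "neulay2", d = 2, h = 2, h1 = 2, h2 = 2, seed = 6)
  x1 <- neulay2_forward(fa1, p1)
  gg1 <- cbind(p1$Z, tanh(p1$Z %*% p1$W1),
               tanh(tanh(p1$Z %*% p1$W1) %*% p1$W2))
  expect_equal(x1, sweep(gg1 %*% p1$W, 2, p1$b, "+"), tolerance = 1e-12)
})

test_that("the forward map is permutation-equivariant", {
  g <- er_graph(20, 0.3, seed = 7)
  p <- neural_params(20, "neulay2", d = 3, h = 8, h1 = 8, h2 = 8, seed = 8)
  x <- neulay2_forward(normalized_operator(g), p)
  perm <- sample(20)
  a <- as.matrix(adjacency(g))[perm, perm]
  gp <- graph_from_adjacency(a)
  pp <- p; pp$Z <- p$Z[perm, , drop = FALSE]
  xp <- neulay2_forward(normalized_operator(gp), pp)
  expect_equal(xp, x[perm, , drop = FALSE], tolerance = 1e-9)
})

test_that("parameter initialization is seeded and well-scaled", {
  a <- neural_params(30, "neulay2", seed = 11)
  b <- neural_params(30, "neulay2", seed = 11)
  expect_identical(a$Z, b$Z); expect_identical(a$W1, b$W1)
  expect_false(identical(a$Z, neural_params(30, "neulay2", seed = 12)$Z))
  # zero scale degenerates to an all-equal layout
  z0 <- neural_params(10, "nodemlp", scale = 0, seed = 1)
  x0 <- nodemlp_forward(z0)
  expect_true(all(apply(x0, 2, function(col) max(col) - min(col)) == 0))
  # finite loss at initialization across seeds
  g <- er_graph(100, 0.05, seed = 1)
  fa <- normalized_operator(g)
  for (s in 1:20) {
    p <- neural_params(100, "neulay2", seed = s)
    expect_true(is.finite(total_loss(g, neulay2_forward(fa, p))))
  }
})

test_that("chain-rule gradients match finite differences for every tensor", {
  g <- random_test_graph(10, 0.5, seed = 13)
  fa <- normalized_operator(g)
  ep <- energy_params(a_n = 0.5, r0 = 0.3, cutoff = 2)
  for (model in c("nodemlp", "neulay", "neulay2")) {
    p <- neural_params(10, model, d = 2, h = 4, h1 = if (model == "nodemlp") 0 else 3,
                       h2 = if (model == "neulay2") 3 else 0, seed = 14)
    op <- if (model == "nodemlp") NULL else fa$matrix
    cache <- neulay:::model_forward_cache(p, op)
    gX <- elastic_gradient(g, cache$X) + repulsive_gradient(cache$X, ep, "brute")
    grads <- neulay:::model_backward(p, cache, gX, op)
    for (tensor in intersect(names(p), c("Z", "W1", "W2", "W", "b"))) {
      fd <- neulay:::numerical_param_gradient(g, p, ep, op, tensor)
      denom <- max(abs(fd), 1)
      expect_lt(max(abs(grads[[tensor]] - fd)) / denom, 1e-4,
                label = paste(model, tensor))
    }
  }
})

test_that("width-zero reductions collapse the architectures consistently", {
  g <- er_graph(15, 0.3, seed = 15)
  fa <- normalized_operator(g)
  # neulay2 with h2 = 0 equals one-layer neulay with shared tensors
  p1 <- neural_params(15, "neulay", d = 3, h = 5, h1 = 4, seed = 16)
  p2 <- p1; p2$model <- "neulay2"
  expect_equal(model_forward(p2, fa), model_forward(p1, fa), tolerance = 1e-12)
  # both GCN widths zero behaves as nodemlp on the Z block
  p3 <- neural_params(15, "nodemlp", d = 3, h = 5, seed = 17)
  p4 <- p3; p4$model <- "neulay2"
  expect_equal(model_forward(p4, fa), nodemlp_forward(p3), tolerance = 1e-12)
})

test_that("training a single node leaves loss at zero", {
  g <- graph_from_adjacency(matrix(0, 1, 1))
  res <- train_model(g, "nodemlp", seed = 1, stop = stop_rule(max_steps = 60))
  expect_true(all(abs(res$trajectory$energies) < 1e-12))
})

test_that("training loss is non-increasing under plain GD on a small graph", {
  g <- sbm_graph(rep(10, 2), 0.6, 0.05, seed = 18)
  res <- suppressWarnings(
    train_model(g, "neulay2", seed = 19, params = energy_params(epsilon = 5e-4),
                record_every = 1, stop = stop_rule(max_steps = 400)))
  e <- res$trajectory$energies
  # per-step transient increases from discretization stay below 0.1%
  expect_lt(max(diff(e) / head(e, -1)), 1e-3)
})

test_that("neulay2 reaches FDL's energy basin faster on a small SBM", {
  g <- sbm_graph(rep(25, 4), 0.5, 0.02, seed = 20)
  st <- stop_rule(max_steps = 4000)
  ratios <- c(); e_fdl <- c(); e_nl <- c()
  for (s in 1:5) {
    r1 <- suppressWarnings(run_fdl(g, seed = s, stop = st, optimizer = "adam"))
    r2 <- suppressWarnings(train_model(g, "neulay2", seed = s, stop = st,
                                       optimizer = "adam"))
    sp <- speedup(r1$trajectory, r2$trajectory, delta = 0.05)
    ratios <- c(ratios, sp$step_ratio)
    e_fdl <- c(e_fdl, tail(r1$trajectory$energies, 1))
    e_nl <- c(e_nl, tail(r2$trajectory$energies, 1))
  }
  expect_gt(median(ratios), 1)               # fewer steps to FDL's basin
  expect_lte(median(e_nl), median(e_fdl) * 1.05)  # comparable or deeper energy
})
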