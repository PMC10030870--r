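test_that("normalized operator matches hand computations and regular-graph identity", {
  # isolated node
  g1 <- graph_from_adjacency(matrix(0, 1, 1))
  expect_equal(as.matrix(normalized_operator(g1)$matrix), matrix(1))
  # single edge: (A + I)/2
  g2 <- read_graph_file("0 1", format = "edgelist", text = TRUE)
  f2 <- as.matrix(normalized_operator(g2)$matrix)
  expect_equal(f2, matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(eigen(f2, only.values = TRUE)$values, c(1, 0), tolerance = 1e-12)
  # k-regular graph: the uniform vector has eigenvalue 1
  ring_edges <- paste(sprintf("%d %d", 0:11, c(1:11, 0)), collapse = "\n")
  g3 <- read_graph_file(ring_edges, format = "edgelist", text = TRUE)
  f3 <- normalized_operator(g3)$matrix
  ones <- rep(1, 12)
  expect_equal(as.numeric(f3 %*% ones), ones, tolerance = 1e-12)
})

test_that("full eigendecomposition reconstructs the operator", {
  # K4 with the self-loop normalization: f(K4) = J/4, spectrum {1, 0, 0, 0}
  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  dec <- eigendecompose(normalized_operator(k4))
  expect_equal(dec$values, c(1, 0, 0, 0), tolerance = 1e-12)
  # random graph: eigenvector orthonormality and reconstruction
  g <- random_test_graph(50, 0.15, weighted = FALSE, seed = 30)
  op <- normalized_operator(g)
  dec <- eigendecompose(op)
  v <- dec$vectors
  expect_lt(max(abs(crossprod(v) - diag(50))), 1e-8)
  recon <- v %*% (dec$values * t(v))
  expect_lt(max(abs(recon - as.matrix(op$matrix))), 1e-6)
  expect_true(all(dec$values <= 1 + 1e-9 & dec$values >= -1 - 1e-9))
})

test_that("top_k mode agrees with the dense solver on leading eigenpairs", {
  g <- sbm_graph(rep(20, 3), 0.6, 0.05, seed = 31)
  op <- normalized_operator(g)
  full <- eigendecompose(op, mode = "full")
  tk <- eigendecompose(op, mode = "top_k", k = 5)
  expect_equal(tk$values, full$values[1:5], tolerance = 1e-7)
  # eigenvectors agree up to sign
  for (i in 1:3) {
    expect_equal(abs(sum(tk$vectors[, i] * full$vectors[, i])), 1,
                 tolerance = 1e-6)
  }
  expect_error(outlier_set(tk), "full-mode")
})

test_that("outlier rule: SBM blocks, degenerate spectra, ER null", {
  # four clear blocks give exactly four outliers
  g <- sbm_graph(rep(25, 4), 0.5, 0.02, seed = 32)
  dec <- eigendecompose(normalized_operator(g))
  expect_equal(length(outlier_set(dec)), 4L)
  # the bare threshold rule is a superset: it also sweeps up the upper tail
  # of the bulk, which is why the gap refinement is the default
  bare <- outlier_set(dec, refine = "none")
  expect_true(all(outlier_set(dec) %in% bare))
  expect_gt(length(bare), 4L)
  expect_equal(bare, which(dec$values > dec$mean_eig + dec$sd_eig))
  # all-equal eigenvalues: strict inequality gives the empty set
  empty <- graph_from_adjacency(matrix(0, 5, 5))
  dec0 <- eigendecompose(normalized_operator(empty))
  expect_length(outlier_set(dec0), 0)
  # ER graphs rarely have more than one outlier
  nout <- vapply(1:30, function(s) {
    d <- eigendecompose(normalized_operator(er_graph(500, 0.05, seed = s)))
    length(outlier_set(d))
  }, numeric(1))
  expect_gte(mean(nout <= 1), 0.9)
})

test_that("top/bulk split reconstructs exactly with the right rank", {
  g <- sbm_graph(rep(25, 4), 0.5, 0.02, seed = 33)
  op <- normalized_operator(g)
  dec <- eigendecompose(op)
  sp <- split_operator(dec, op)
  expect_lt(max(abs(sp$top + sp$bulk - as.matrix(op$matrix))), 1e-9)
  expect_equal(qr(sp$top)$rank, length(dec$out_set))
  # empty outlier set: top is zero
  e0 <- graph_from_adjacency(matrix(0, 4, 4))
  d0 <- eigendecompose(normalized_operator(e0))
  s0 <- split_operator(d0, normalized_operator(e0))
  expect_equal(s0$top, matrix(0, 4, 4))
  expect_equal(s0$bulk, diag(4), ignore_attr = TRUE)
})

test_that("mode overlaps satisfy projection identities", {
  g <- random_test_graph(20, 0.3, seed = 34)
  dec <- eigendecompose(normalized_operator(g))
  v <- dec$vectors
  # layout equal to one eigenvector has unit overlap there, zero elsewhere
  x <- cbind(v[, 3], 0, 0)
  ov <- mode_overlap(x, dec)
  expect_equal(ov[3], 1, tolerance = 1e-9)
  expect_lt(max(ov[-3]), 1e-9)
  # Parseval over the full basis
  set.seed(35)
  y <- matrix(rnorm(60), 20, 3)
  expect_equal(sum(mode_overlap(y, dec)^2), sum(y^2), tolerance = 1e-9)
})

test_that("predicted decay rates need the adjacency spectrum and warn on irregularity", {
  ring_edges <- paste(sprintf("%d %d", 0:9, c(1:9, 0)), collapse = "\n")
  g <- read_graph_file(ring_edges, format = "edgelist", text = TRUE)
  dec_no <- eigendecompose(normalized_operator(g))
  expect_error(predicted_decay_rate(dec_no, 1, 0.01), "adjacency")
  dec <- eigendecompose(normalized_operator(g), with_adjacency = TRUE)
  expect_equal(predicted_decay_rate(dec, 1, 0.01), 0, tolerance = 1e-9)
  # a star graph is far from regular
  star <- read_graph_file(paste(sprintf("0 %d", 1:9), collapse = "\n"),
                          format = "edgelist", text = TRUE)
  dstar <- eigendecompose(normalized_operator(star), with_adjacency = TRUE)
  expect_warning(predicted_decay_rate(dstar, 1, 0.01), "near-regular")
})

test_that("substituting the full operator reproduces the default pipeline", {
  g <- sbm_graph(rep(10, 2), 0.6, 0.05, seed = 36)
  st <- stop_rule(max_steps = 150)
  r1 <- suppressWarnings(train_model(g, "neulay2", seed = 4, stop = st,
                                     operator = "full", optimizer = "adam"))
  r2 <- suppressWarnings(train_model(g, "neulay2", seed = 4, stop = st,
                                     operator = normalized_operator(g)$matrix,
                                     optimizer = "adam"))
  expect_equal(r1$trajectory$energies, r2$trajectory$energies, tolerance = 1e-12)
  expect_equal(r1$layout, r2$layout, tolerance = 1e-12)
})
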