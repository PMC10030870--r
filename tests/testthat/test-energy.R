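test_that("elastic energy matches the half-trace Laplacian form and hand cases", {
  # one unit-length link: V_el = 1/2 Tr(X'LX) = 1/2
  g <- read_graph_file("0 1", format = "edgelist", text = TRUE)
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(elastic_energy(g, x), 0.5)
  # coincident nodes have zero elastic energy
  expect_equal(elastic_energy(g, matrix(1, 2, 3)), 0)
  # random graphs: pairwise definition equals the Laplacian quadratic form
  for (seed in 1:5) {
    gg <- random_test_graph(10, 0.5, seed = seed)
    xx <- random_layout(10, 3, seed = seed)
    L <- as.matrix(graph_laplacian(gg))
    expect_equal(elastic_energy(gg, xx), 0.5 * sum(diag(t(xx) %*% L %*% xx)),
                 tolerance = 1e-9)
  }
  expect_error(elastic_energy(g, rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
})

test_that("repulsive energy: coincident pair, far pair, cell list = brute", {
  p <- energy_params(a_n = 0.7, r0 = 0.1)
  two <- matrix(0, 2, 3)
  expect_equal(repulsive_energy(two, p), 0.7)          # exp(0) per unordered pair
  far <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(repulsive_energy(far, p), 0)            # beyond cutoff
  # 300 random points: truncation bound against the untruncated sum
  set.seed(31)
  x <- matrix(rnorm(900, sd = 0.2), 300, 3)
  p2 <- energy_params(r0 = 0.1)                        # a_n -> 1/300
  e_cell <- repulsive_energy(x, p2, "cell_list")
  e_brute <- repulsive_energy(x, p2, "brute")
  expect_equal(e_cell, e_brute, tolerance = 1e-12)     # same truncated sum
  # against an untruncated oracle, within a_N * N^2 * exp(-cutoff^2 / 4 r0^2)
  d2 <- as.matrix(dist(x))^2
  e_full <- (1 / 300) * sum(exp(-d2[upper.tri(d2)] / (4 * 0.1^2)))
  expect_lt(abs(e_cell - e_full), (1 / 300) * 300^2 * exp(-0.4^2 / (4 * 0.01)))
})

test_that("energy parameter validation", {
  expect_error(energy_params(r0 = 0), "r0")
  expect_error(energy_params(cutoff = 0.1), "cutoff")
  expect_error(energy_params(a_n = -1), "a_n")
  expect_error(energy_params(epsilon = 0), "epsilon")
})

test_that("elastic gradient is L X and matches finite differences", {
  g <- read_graph_file("0 1", format = "edgelist", text = TRUE)
  x <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0))
  gr <- elastic_gradient(g, x)
  expect_equal(gr, rbind(c(-1, 0, 0), c(1, 0, 0)), ignore_attr = TRUE)
  # pulls the endpoints together under x <- x - eps * grad
  expect_lt(sum((x - 0.1 * gr)[1, ] - (x - 0.1 * gr)[2, ])^2, sum((x[1, ] - x[2, ])^2))
  # coincident nodes and disconnected nodes
  expect_equal(elastic_gradient(g, matrix(2, 2, 3)), matrix(0, 2, 3),
               ignore_attr = TRUE)
  g3 <- read_graph_file("0 1\n# 2 isolated via node list trick", text = TRUE,
                        format = "edgelist")
  gg <- random_test_graph(8, 0.4, seed = 2)
  xx <- random_layout(8, 3, seed = 3)
  fd <- fd_gradient(function(z) elastic_energy(gg, z), xx)
  expect_equal(elastic_gradient(gg, xx), fd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("repulsive gradient: closed form and finite differences", {
  p <- energy_params(a_n = 2, r0 = 0.1)
  # coincident pair: symmetric cancellation
  expect_equal(repulsive_gradient(matrix(0, 2, 3), p), matrix(0, 2, 3),
               ignore_attr = TRUE)
  # pair at distance r0: force magnitude a_n * (r0 / 2 r0^2) * exp(-1/4), apart
  x <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  gr <- repulsive_gradient(x, p, "brute")
  mag <- 2 * (0.1 / (2 * 0.1^2)) * exp(-1 / 4)
  expect_equal(gr[1, 1], mag, tolerance = 1e-12)   # gradient points toward j
  expect_equal(gr[2, 1], -mag, tolerance = 1e-12)  # descending drives them apart
  # isolated far node has a zero row
  y <- rbind(matrix(rnorm(30, sd = 0.05), 10, 3), c(50, 50, 50))
  expect_equal(repulsive_gradient(y, p)[11, ], c(0, 0, 0))
  # finite differences on random configurations, both methods
  for (seed in 1:3) {
    set.seed(seed)
    z <- matrix(rnorm(24, sd = 0.15), 8, 3)
    fd <- fd_gradient(function(w) repulsive_energy(w, p, "brute"), z)
    expect_equal(repulsive_gradient(z, p, "brute"), fd, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(repulsive_gradient(z, p, "cell_list"), fd, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("total loss is the sum of parts and reduces correctly", {
  g <- random_test_graph(10, 0.4, seed = 8)
  x <- random_layout(10, 3, seed = 9, scale = 0.3)
  p <- energy_params(a_n = 0.5)
  expect_equal(total_loss(g, x, p),
               elastic_energy(g, x) + repulsive_energy(x, p))
  # a_n = 0 leaves the elastic term
  expect_equal(total_loss(g, x, energy_params(a_n = 0)), elastic_energy(g, x))
  # empty graph leaves the repulsive term
  g0 <- graph_from_adjacency(matrix(0, 10, 10))
  expect_equal(total_loss(g0, x, p), repulsive_energy(x, p))
})

test_that("both energy terms are invariant under translation and rotation", {
  g <- random_test_graph(15, 0.3, seed = 21)
  x <- random_layout(15, 3, seed = 22, scale = 0.4)
  p <- energy_params()
  shift <- sweep(x, 2, c(3.2, -1.5, 0.7), "+")
  rot <- x %*% random_rotation(3)
  for (y in list(shift, rot)) {
    expect_equal(total_loss(g, y, p), total_loss(g, x, p), tolerance = 1e-9)
  }
  expect_gte(elastic_energy(g, x), 0)
  expect_gte(repulsive_energy(x, p), 0)
})
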