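# shared fixtures and oracles, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small weighted random graph (dense enough to exercise everything)
random_test_graph <- function(n = 12, p = 0.4, weighted = TRUE, seed = 42) {
  set.seed(seed)
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  link <- runif(sum(up)) < p
  w <- ifelse(link, if (weighted) round(runif(sum(up), 0.5, 2), 3) else 1, 0)
  a[up] <- w
  a <- a + t(a)
  graph_from_adjacency(a)
}

random_layout <- function(n, d = 3, seed = 1, scale = 1) {
  set.seed(seed)
  matrix(rnorm(n * d, sd = scale), n, d)
}

# brute-force elastic energy straight from the pairwise definition,
# independent of the Laplacian path
elastic_energy_oracle <- function(g, x) {
  a <- as.matrix(adjacency(g))
  n <- nrow(a)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- tot + a[i, j] * sum((x[i, ] - x[j, ])^2)
  }
  tot / 4  # ordered sum / 2 gives Tr(X'LX); halve again for V_el
}

# central finite differences of a scalar function of a matrix
fd_gradient <- function(f, x, eps = 1e-6) {
  gmat <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    gmat[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  gmat
}

# random orthogonal matrix (QR of a Gaussian)
random_rotation <- function(d, seed = 7) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
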