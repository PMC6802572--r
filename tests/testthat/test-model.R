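test_that("HKY with kappa = 1 and GTR with equal exchangeabilities reduce to JC", {
  jc <- build_model("JC")
  hky <- build_model("HKY", kappa = 1, frequencies = rep(0.25, 4))
  gtr <- build_model("GTR", exchangeabilities = rep(2, 6),
                     frequencies = rep(0.25, 4))
  expect_equal(hky$Q, jc$Q, tolerance = 1e-12)
  expect_equal(gtr$Q, jc$Q, tolerance = 1e-12)
  expect_true(all(abs(jc$Q[row(jc$Q) != col(jc$Q)] - 1 / 3) < 1e-12))
  expect_true(all(abs(diag(jc$Q) + 1) < 1e-12))
})

test_that("HKY rate matrix matches an independent scalar construction", {
  kappa <- 2
  pi <- c(0.3, 0.2, 0.2, 0.3)
  # scalar construction: s = kappa for A<->G, C<->T, else 1
  s <- matrix(1, 4, 4)
  s[1, 3] <- s[3, 1] <- kappa
  s[2, 4] <- s[4, 2] <- kappa
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) Q[i, j] <- s[i, j] * pi[j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))

  m <- build_model("HKY", kappa = kappa, frequencies = pi)
  expect_equal(m$Q, Q, tolerance = 1e-14)
})

test_that("model invariants hold: simplex, zero row sums, detailed balance, unit flux", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_gtr()
    expect_lt(abs(sum(m$frequencies) - 1), 1e-12)
    expect_lt(max(abs(rowSums(m$Q))), 1e-12)
    F <- m$frequencies * m$Q
    expect_lt(max(abs(F - t(F))), 1e-12)
    expect_lt(abs(-sum(m$frequencies * diag(m$Q)) - 1), 1e-12)
  }
})

test_that("model construction rejects invalid parameters", {
  expect_error(build_model("HKY", kappa = 2, frequencies = c(0.5, 0.5, 0.2, -0.2)),
               "nonnegative")
  expect_error(build_model("HKY", kappa = 2, frequencies = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(build_model("GTR", exchangeabilities = c(-1, 1, 1, 1, 1, 1),
                           frequencies = rep(0.25, 4)), "nonnegative")
  bad <- matrix(1, 4, 4)  # nonzero row sums
  expect_error(build_model("ARBITRARY", rate_matrix = bad,
                           frequencies = rep(0.25, 4)), "row sums")
})

test_that("eigendecomposition reconstructs Q with one zero and negative eigenvalues", {
  jc <- build_model("JC")
  es <- eigendecompose(jc)
  expect_equal(sort(es$values), c(-4 / 3, -4 / 3, -4 / 3, 0),
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:10) {
    m <- random_gtr()
    es <- eigendecompose(m)
    recon <- es$vectors %*% diag(es$values) %*% es$inverse_vectors
    expect_lt(max(abs(recon - m$Q)), 1e-9)
    expect_equal(sum(abs(es$values) < 1e-9), 1)
    expect_true(all(es$values[abs(es$values) >= 1e-9] < 0))
  }
  m5 <- build_model("HKY", kappa = 5, frequencies = c(0.1, 0.4, 0.4, 0.1))
  expect_true(all(is.finite(eigendecompose(m5)$values)))
  expect_error(eigendecompose(build_model("ARBITRARY",
    rate_matrix = rbind(c(-1, 1, 0, 0), c(0, -1, 1, 0),
                        c(0, 0, -1, 1), c(1, 0, 0, -1)),
    frequencies = rep(0.25, 4))), NA) # non-reversible: flagged, no error
  nr <- eigendecompose(build_model("ARBITRARY",
    rate_matrix = rbind(c(-1, 1, 0, 0), c(0, -1, 1, 0),
                        c(0, 0, -1, 1), c(1, 0, 0, -1)),
    frequencies = rep(0.25, 4)))
  expect_true(nr$unavailable)
})

test_that("discrete gamma: equal weights, mean one, quadrature-verified rates", {
  g <- discretize_gamma(0.5, 4)
  expect_equal(g$weights, rep(0.25, 4))
  expect_lt(abs(sum(g$weights * g$rates) - 1), 1e-12)
  expect_true(all(diff(g$rates) >= 0))

  # adaptive-quadrature oracle: E[X | quartile] for X ~ Gamma(0.5, 0.5)
  cuts <- qgamma(seq(0, 1, 0.25), shape = 0.5, rate = 0.5)
  oracle <- vapply(1:4, function(c) {
    4 * integrate(function(x) x * dgamma(x, shape = 0.5, rate = 0.5),
                  cuts[c], cuts[c + 1], rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(g$rates, oracle, tolerance = 1e-8)

  # vanishing heterogeneity
  g2 <- discretize_gamma(1e6, 4)
  expect_true(all(abs(g2$rates - 1) < 1e-2))
  expect_error(discretize_gamma(-1, 4), "positive")
  expect_error(discretize_gamma(1, 0), ">= 1")
  # median mode also normalises to mean one
  gm <- discretize_gamma(0.5, 4, method = "median")
  expect_lt(abs(sum(gm$weights * gm$rates) - 1), 1e-12)
})

test_that("transition matrices: identity at t = 0, stationarity at large t, closed-form JC", {
  jc <- build_model("JC")
  es <- eigendecompose(jc)
  r1 <- rate_categories(1)
  tm <- compute_transition_matrices(es, r1, c(0, 1e4, 0.1))
  expect_equal(tm[[1]]$P[, , 1], diag(4), tolerance = 1e-12)
  expect_true(all(abs(tm[[2]]$P[, , 1] - 0.25) < 1e-6))
  e <- exp(-4 * 0.1 / 3)
  expected <- matrix(0.25 - 0.25 * e, 4, 4)
  diag(expected) <- 0.25 + 0.75 * e
  expect_equal(tm[[3]]$P[, , 1], expected, tolerance = 1e-12)
  expect_error(compute_transition_matrices(es, r1, -0.1), "nonnegative")
})

test_that("Chapman-Kolmogorov, detailed balance of P, and expm agreement hold", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_gtr()
    es <- eigendecompose(m)
    r1 <- rate_categories(1)
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    tm <- compute_transition_matrices(es, r1, c(t1, t2, t1 + t2))
    expect_lt(max(abs(tm[[1]]$P[, , 1] %*% tm[[2]]$P[, , 1] -
                        tm[[3]]$P[, , 1])), 1e-9)
    P <- tm[[1]]$P[, , 1]
    FP <- m$frequencies * P
    expect_lt(max(abs(FP - t(FP))), 1e-9)
    t3 <- runif(1, 0, 10)
    Pe <- as.matrix(Matrix::expm(m$Q * t3))
    Pt <- compute_transition_matrices(es, r1, t3)[[1]]$P[, , 1]
    expect_lt(max(abs(Pe - Pt)), 1e-8)
    expect_lt(max(abs(rowSums(Pt) - 1)), 1e-9)
    expect_true(all(Pt >= 0))
  }
})

test_that("derivative matrices agree with central finite differences of P", {
  set.seed(13)
  m <- random_gtr()
  es <- eigendecompose(m)
  g <- discretize_gamma(0.7, 3)
  h <- 1e-5
  for (t in c(0.05, 0.4, 1.3)) {
    tm <- compute_transition_matrices(es, g, c(t - h, t, t + h),
                                      want_derivatives = TRUE)
    for (c in 1:3) {
      fd1 <- (tm[[3]]$P[, , c] - tm[[1]]$P[, , c]) / (2 * h)
      fd2 <- (tm[[3]]$P[, , c] - 2 * tm[[2]]$P[, , c] + tm[[1]]$P[, , c]) / h^2
      expect_lt(max(abs(tm[[2]]$d1[, , c] - fd1)), 1e-5)
      expect_lt(max(abs(tm[[2]]$d2[, , c] - fd2)), 1e-3)
    }
  }
})

test_that("non-reversible arbitrary models go through the matrix exponential", {
  Q <- rbind(c(-1, 0.7, 0.2, 0.1), c(0.1, -0.9, 0.5, 0.3),
             c(0.4, 0.1, -0.8, 0.3), c(0.2, 0.3, 0.1, -0.6))
  pi <- rep(0.25, 4)
  m <- build_model("ARBITRARY", rate_matrix = Q, frequencies = pi)
  expect_false(m$reversible)
  es <- eigendecompose(m)
  tm <- compute_transition_matrices(es, rate_categories(1), 0.5,
                                    want_derivatives = TRUE)
  P <- tm[[1]]$P[, , 1]
  expect_lt(max(abs(P - as.matrix(Matrix::expm(m$Q * 0.5)))), 1e-10)
  h <- 1e-5
  tm2 <- compute_transition_matrices(es, rate_categories(1),
                                     c(0.5 - h, 0.5 + h))
  fd1 <- (tm2[[2]]$P[, , 1] - tm2[[1]]$P[, , 1]) / (2 * h)
  expect_lt(max(abs(tm[[1]]$d1[, , 1] - fd1)), 1e-5)
})
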