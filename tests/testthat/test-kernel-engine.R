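# Kernel constructions, combination, expansion, and eigendecomposition.

test_that("linear kernel is trace-normalized and matches the inner-product oracle", {
  X <- matrix(c(1, 2), 2, 1)
  K <- linear_kernel(X)
  expect_equal(unclass(K), matrix(c(0.4, 0.8, 0.8, 1.6), 2), ignore_attr = TRUE)
  set.seed(3)
  X2 <- matrix(stats::rnorm(15 * 6), 15)
  K2 <- linear_kernel(X2)
  expect_equal(sum(diag(K2)), 15, tolerance = 1e-10)
  # explicit double-loop inner products, normalized by the trace factor
  raw <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15) raw[i, j] <- sum(X2[i, ] * X2[j, ])
  expect_equal(unclass(K2), raw / (sum(diag(raw)) / 15), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(linear_kernel(matrix(0, 3, 2)), "degenerate")
})

test_that("gaussian kernel has unit diagonal, median scaling, and the h->0 limit", {
  set.seed(4)
  X <- matrix(stats::rnorm(12 * 4), 12)
  K <- gaussian_kernel(X, h = 1)
  expect_true(all(diag(K) == 1))
  # identical rows give similarity 1
  Xd <- rbind(X, X[1, ])
  Kd <- gaussian_kernel(Xd, h = 2)
  expect_equal(Kd[1, 13], 1)
  # a pair at exactly the median squared distance has similarity exp(-1)
  D2 <- as.matrix(stats::dist(X))^2
  q <- stats::median(D2[upper.tri(D2)])
  expect_equal(attr(K, "hyper")$q, q)
  expect_equal(unclass(K)[2, 5], exp(-D2[2, 5] / q), tolerance = 1e-12)
  # monotone decreasing in squared distance
  ord <- order(D2[upper.tri(D2)])
  kv <- unclass(K)[upper.tri(K)][ord]
  expect_true(all(diff(kv) <= 1e-12))
  # h -> 0: all entries tend to 1
  K0 <- gaussian_kernel(X, h = 1e-8)
  expect_lt(max(abs(unclass(K0) - 1)), 1e-6)
  expect_error(gaussian_kernel(X[c(1, 1), ], h = 1), "identical")
})

test_that("arc-cosine layer-1 values match the closed form and the ReLU Monte-Carlo oracle", {
  x <- c(1, 2, 2)
  y <- c(3, 0, 0)
  X <- rbind(a = x, b = c(0, 1, -2), d = y)
  K <- arc_cosine_kernel(X, 1L)
  expect_equal(unclass(K)[1, 1], sum(x^2), tolerance = 1e-12)  # theta = 0, J = pi
  # orthogonal rows: theta = pi/2, J = 1
  expect_equal(unclass(K)[2, 3], sqrt(sum(X[2, ]^2)) * 3 / pi, tolerance = 1e-12)
  # Monte-Carlo random-feature oracle: k1(x, x') = 2 E[relu(w.x) relu(w.x')]
  set.seed(10)
  Xr <- matrix(stats::rnorm(4 * 3), 4)
  K1 <- unclass(arc_cosine_kernel(Xr, 1L))
  ndraw <- 2e5
  W <- matrix(stats::rnorm(ndraw * 3), ndraw)
  P <- pmax(W %*% t(Xr), 0)
  for (i in 1:4) for (j in 1:4) {
    prod_ij <- P[, i] * P[, j]
    est <- 2 * mean(prod_ij)
    se <- 2 * stats::sd(prod_ij) / sqrt(ndraw)
    expect_lt(abs(K1[i, j] - est), 3 * se + 1e-10)
  }
  # deep recursion stays a valid kernel
  K5 <- arc_cosine_kernel(Xr, 5L)
  expect_silent(validate_kernel(K5))
  expect_error(arc_cosine_kernel(rbind(c(0, 0, 0), c(1, 1, 1))), "zero-norm")
})

test_that("composite kernels weight constituents by inverse hyperparameters", {
  set.seed(6)
  X <- matrix(stats::rnorm(10 * 3), 10)
  K1 <- gaussian_kernel(X, h = 1)
  K3 <- gaussian_kernel(X, h = 3)
  comp <- composite_weather_kernel(list(a = K1, b = K3), "gaussian")
  expect_equal(attr(comp, "hyper")$weights, c(0.75, 0.25), ignore_attr = TRUE)
  expect_equal(unclass(comp), 0.75 * unclass(K1) + 0.25 * unclass(K3),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(abs(diag(comp) - 1) < 1e-12))  # convex combination of diag-1
  # identical constituents reproduce the constituent under any weights
  same <- composite_weather_kernel(list(a = K1, b = K1), "gaussian",
                                   hyperparams = c(5, 1))
  expect_equal(unclass(same), unclass(K1), ignore_attr = TRUE, tolerance = 1e-12)
  # linear composites are summed then trace-normalized
  L1 <- linear_kernel(X)
  L2 <- linear_kernel(X^2)
  lcomp <- composite_weather_kernel(list(L1, L2), "linear")
  expect_equal(sum(diag(lcomp)), 10, tolerance = 1e-10)
})

test_that("kernel expansion matches the elementwise loop oracle and stays PSD", {
  set.seed(7)
  Kh <- unclass(linear_kernel(matrix(stats::rnorm(8), 2)))   # 2 hybrids
  Ke <- unclass(linear_kernel(matrix(stats::rnorm(10), 2)))  # 2 environments
  hyb <- c("h1", "h2", "h1", "h2")
  env <- c("e1", "e1", "e2", "e2")
  Za <- incidence_matrix(hyb)
  Zb <- incidence_matrix(env)
  KX <- expand_kernel(Kh, Za, Ke, Zb)
  # explicit elementwise loop over the 4 records
  for (i in 1:4) for (j in 1:4) {
    expect_equal(unclass(KX)[i, j],
                 Kh[match(hyb[i], c("h1", "h2")), match(hyb[j], c("h1", "h2"))] *
                   Ke[match(env[i], c("e1", "e2")), match(env[j], c("e1", "e2"))],
                 tolerance = 1e-12)
  }
  ev <- eigen(unclass(KX), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  # all-ones second kernel (one level) reduces to the main-effect expansion
  ones <- matrix(1, 2, 2)
  expect_equal(unclass(expand_kernel(Kh, Za, ones, Zb)),
               unclass(expand_kernel(Kh, Za)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identity substitution blocks similarity across environments
  KI <- expand_kernel(Kh, Za, "identity", Zb)
  expect_equal(unclass(KI)[1, 3], 0)
  expect_equal(unclass(KI)[1, 2], Kh[1, 2] * 1)
})

test_that("eigendecomposition truncates correctly and reconstructs the kernel", {
  eb <- eigendecompose(diag(5))
  expect_equal(eb$values, rep(1, 5))
  v <- c(1, 2, 3)
  r1 <- eigendecompose(outer(v, v))
  expect_length(r1$values, 1L)
  expect_equal(r1$values, sum(v^2), tolerance = 1e-10)
  set.seed(9)
  X <- matrix(stats::rnorm(50 * 10), 50)
  K <- unclass(linear_kernel(X))
  eb2 <- eigendecompose(K, tol = 1e-10, max_rank = 6L)
  expect_equal(eb2$truncation, "max_rank")
  full <- eigen(K, symmetric = TRUE)
  expect_equal(eb2$variance_captured,
               sum(full$values[1:6]) / sum(pmax(full$values, 0)),
               tolerance = 1e-10)
  # orthonormality of retained vectors
  expect_lt(max(abs(crossprod(eb2$vectors) - diag(6))), 1e-8)
  # full-rank reconstruction
  ebf <- eigendecompose(K)
  recon <- ebf$vectors %*% (ebf$values * t(ebf$vectors))
  expect_lt(max(abs(recon - K)), 1e-8)
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("every produced kernel passes the validity contract", {
  set.seed(12)
  for (i in 1:10) {
    X <- matrix(stats::rnorm(12 * 5), 12)
    expect_silent(validate_kernel(linear_kernel(X)))
    expect_silent(validate_kernel(gaussian_kernel(X, h = stats::runif(1, 0.1, 5))))
    expect_silent(validate_kernel(arc_cosine_kernel(X, sample(1:4, 1))))
  }
})
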