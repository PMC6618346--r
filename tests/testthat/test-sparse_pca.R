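test_that("soft_threshold matches its closed form", {
  expect_equal(soft_threshold(c(2, -1, 0.5), 1), c(1, 0, 0))
  a <- c(-3.2, 0, 0.4, 7)
  expect_equal(soft_threshold(a, 0), a)            # identity at mu = 0
  expect_equal(soft_threshold(a, 7), rep(0, 4))    # saturation at max|a|
  expect_equal(soft_threshold(a, 1.5), c(-1.7, 0, 0, 5.5))
  expect_error(soft_threshold(a, -0.1), "non-negative")
})

test_that("solve_v returns the constrained maximizer", {
  # single support at c = 1
  expect_equal(solve_v(c(0, 0, 5), 1), c(0, 0, 1), tolerance = 1e-7)
  # symmetric case at c = sqrt(m)
  expect_equal(solve_v(rep(2, 9), 3), rep(1 / 3, 9), tolerance = 1e-10)
  # interior constraint: compare against the dense grid-search oracle
  v <- solve_v(c(3, 1, 0), 1.2)
  expect_gt(v[1], v[2])
  expect_gt(v[2], 0)
  expect_equal(v[3], 0)
  expect_equal(sum(v^2), 1, tolerance = 1e-10)
  expect_equal(sum(abs(v)), 1.2, tolerance = 1e-7)
  expect_equal(v, oracle_solve_v(c(3, 1, 0), 1.2), tolerance = 1e-4)
  # random instances: feasibility and optimality vs the oracle
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(12)
    c_par <- runif(1, 1, sqrt(12))
    v <- solve_v(a, c_par)
    expect_lte(sum(abs(v)), c_par + 1e-7)
    expect_equal(sum(v^2), 1, tolerance = 1e-10)
    expect_gte(sum(a * v), sum(a * oracle_solve_v(a, c_par)) - 1e-4)
  }
  expect_error(solve_v(rep(0, 5), 1.5), "degenerate")
  expect_error(solve_v(rnorm(5), 0.5), "must lie")
  expect_error(solve_v(rnorm(5), 5), "must lie")
})

test_that("solve_u normalizes and is scale invariant", {
  expect_equal(solve_u(c(3, 4)), c(0.6, 0.8))
  u <- unit(rnorm(7))
  expect_equal(solve_u(u), u)
  b <- rnorm(9)
  expect_equal(solve_u(b), solve_u(10 * b))
  expect_error(solve_u(rep(0, 3)), "degenerate")
})

test_that("fit_component recovers an exact sparse rank-one matrix", {
  set.seed(21)
  u0 <- unit(rnorm(15))
  v0 <- unit(c(rnorm(6), rep(0, 18)))
  X <- 5 * tcrossprod(u0, v0)
  f <- fit_component(X, c = sum(abs(v0)))
  expect_equal(f$d, 5, tolerance = 1e-6)
  expect_lt(min(max(abs(f$u - u0)), max(abs(f$u + u0))), 1e-6)
  expect_lt(min(max(abs(f$v - v0)), max(abs(f$v + v0))), 1e-6)
  expect_true(f$converged)
  expect_error(fit_component(matrix(0, 4, 5), c = 1.5), "zero matrix")
})

test_that("fit_component with inactive constraint matches the leading
           singular triplet", {
  set.seed(22)
  X <- matrix(rnorm(60), 6, 10)
  f <- fit_component(X, c = sqrt(10), tol = 1e-10, max_iter = 2000)
  sv <- svd(X)
  expect_equal(f$d, sv$d[1], tolerance = 1e-8)
  expect_equal(abs(sum(f$v * sv$v[, 1])), 1, tolerance = 1e-8)
  expect_equal(abs(sum(f$u * sv$u[, 1])), 1, tolerance = 1e-8)
})

test_that("fit_component at an active constraint agrees with the alternating
           grid-search oracle and is bounded by the top singular value", {
  set.seed(23)
  X <- matrix(rnorm(60), 6, 10)
  f <- fit_component(X, c = 1.5, tol = 1e-9, max_iter = 1000)
  expect_lte(f$d, svd(X)$d[1] + 1e-10)
  o <- oracle_fit_component(X, 1.5)
  expect_equal(f$d, o$d, tolerance = 1e-3)
  expect_lt(min(max(abs(f$v - o$v)), max(abs(f$v + o$v))), 2e-3)
})

test_that("objective is non-decreasing across alternations", {
  # Exact-arithmetic monotonicity of the alternation; numerically, entries at
  # the support boundary flip with ~1e-15 perturbations of X'u near the
  # optimum, moving the objective by ~(entry)^2, so the assertion carries a
  # relative tolerance above that noise floor.
  set.seed(24)
  for (i in 1:5) {
    X <- matrix(rnorm(30 * 50), 30, 50)
    f <- fit_component(X, c = runif(1, 1.2, 6), trace = TRUE)
    expect_true(all(diff(f$objective) >= -1e-7 * max(f$objective)))
  }
})

test_that("deflate removes the fitted component", {
  set.seed(25)
  X <- matrix(rnorm(8 * 12), 8, 12)
  f <- fit_component(X, c = 2)
  Xd <- deflate(X, f)
  expect_lt(abs(drop(t(f$u) %*% Xd %*% f$v)), 1e-8)
  # exact rank-one input deflates to zero
  f1 <- list(d = 3, u = unit(rnorm(8)), v = unit(rnorm(12)))
  expect_equal(deflate(3 * tcrossprod(f1$u, f1$v), f1),
               matrix(0, 8, 12))
  # exact singular triplet: Frobenius identity
  sv <- svd(X)
  comp <- list(d = sv$d[1], u = sv$u[, 1], v = sv$v[, 1])
  expect_equal(sum(deflate(X, comp)^2), sum(X^2) - sv$d[1]^2,
               tolerance = 1e-6)
  expect_error(deflate(X, list(d = 1, u = rnorm(3), v = rnorm(12))),
               "dimensions")
})

test_that("spca with c = sqrt(m) reproduces the truncated SVD", {
  set.seed(26)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 40), 20, 40)
    fit <- spca(X, K = 3, c = sqrt(40), tol = 1e-10, max_iter = 5000)
    sv <- svd(X)
    expect_equal(fit$d, sv$d[1:3], tolerance = 1e-6)
    expect_equal(abs(colSums(fit$V * sv$v[, 1:3])), rep(1, 3),
                 tolerance = 1e-6)
  }
})

test_that("spca satisfies its norm and sparsity invariants", {
  set.seed(27)
  X <- matrix(rnorm(30 * 80), 30, 80)
  for (c_par in c(1.3, 3, 6, sqrt(80))) {
    fit <- suppressWarnings(spca(X, K = 4, c = c_par))
    expect_equal(colSums(fit$U^2), rep(1, fit$K), tolerance = 1e-8)
    expect_equal(colSums(fit$V^2), rep(1, fit$K), tolerance = 1e-8)
    expect_true(all(colSums(abs(fit$V)) <= c_par + 1e-8))
    expect_true(all(fit$d > 0))
    # sign canonicalization: largest |entry| of each loading is positive
    expect_true(all(apply(fit$V, 2, function(v) v[which.max(abs(v))]) > 0))
  }
})

test_that("achieved sparsity is non-increasing in c", {
  set.seed(28)
  X <- matrix(rnorm(25 * 60), 25, 60)
  c_grid <- seq(1.05, sqrt(60), length.out = 10)
  sp <- vapply(c_grid, function(cc)
    suppressWarnings(spca(X, K = 1, c = cc))$achieved_sparsity[1], numeric(1))
  expect_true(all(diff(sp) <= 1e-12))
})

test_that("spca recovers ground truth on noise-free generated data", {
  spec <- sim1_spec(dims = c(20, 20, 2), psnr_db = Inf, seed = 5,
                    n_blobs = 2L)
  gen <- generate_sim1(spec, keep_intermediate = FALSE)
  c_true <- max(colSums(abs(gen$V_true)))
  fit <- spca(gen$X, K = 3, c = c_true)
  expect_gt(similarity(gen$V_true, fit$V)$mean, 0.99)
  expect_gt(similarity(gen$Y_true, scores(fit))$mean, 0.99)
})

test_that("K exceeding the rank stops early with a warning", {
  set.seed(29)
  X <- tcrossprod(matrix(rnorm(12 * 2), 12, 2), matrix(rnorm(30 * 2), 30, 2))
  expect_warning(fit <- spca(X, K = 5, c = sqrt(30)), "rank exhausted")
  expect_lte(fit$K, 2L)
})

test_that("scores equal the explicit matrix product and orthonormal identity", {
  set.seed(30)
  X <- matrix(rnorm(20 * 100), 20, 100)
  fit <- suppressWarnings(spca(X, K = 3, c = 4))
  # direct-arithmetic oracle on the reconstruction
  Xhat <- fit$U %*% diag(fit$d) %*% t(fit$V)
  expect_equal(scores(fit), Xhat %*% fit$V, tolerance = 1e-10)
  expect_equal(scores(fit, X, raw = TRUE), X %*% fit$V, tolerance = 1e-12)
  # exact decomposition with orthonormal V: Y = U D
  pf <- pca_fit(X, 3)
  expect_equal(scores(pf), pf$U %*% diag(pf$d), tolerance = 1e-8)
  # rank-one model: score column is d * u
  f1 <- pca_fit(X, 1)
  expect_equal(drop(scores(f1)), f1$d[1] * f1$U[, 1], tolerance = 1e-8)
  expect_error(scores(fit, X[, 1:10], raw = TRUE), "feature count")
})

test_that("pca_fit matches the full decomposition and the c = sqrt(m) fit", {
  set.seed(31)
  X <- matrix(rnorm(15 * 40), 15, 40)
  pf <- pca_fit(X, 4)
  sv <- svd(X)
  expect_equal(pf$d, sv$d[1:4], tolerance = 1e-10)
  expect_true(all(diff(pf$d) <= 0))
  # reconstruction error at rank K equals the tail sum of squares
  expect_equal(sum((X - reconstruct(pf))^2), sum(sv$d[5:15]^2),
               tolerance = 1e-8)
  # diagonal-like input aligns with axes
  Xd <- cbind(diag(c(4, 2, 1)), matrix(0, 3, 5))
  pd <- pca_fit(Xd, 3)
  expect_equal(pd$d, c(4, 2, 1))
  expect_equal(abs(pd$V[1:3, ]), diag(3), tolerance = 1e-12)
  # internal cross-check against the iterative fit
  fit <- spca(X, K = 4, c = sqrt(40), tol = 1e-10, max_iter = 5000)
  expect_equal(fit$d, pf$d, tolerance = 1e-6)
  expect_equal(abs(colSums(fit$V * pf$V)), rep(1, 4), tolerance = 1e-6)
})

test_that("sparsity_to_c reaches a requested zero fraction", {
  spec <- sim1_spec(dims = c(15, 15, 2), psnr_db = 20, seed = 8,
                    n_blobs = 2L)
  gen <- generate_sim1(spec, keep_intermediate = FALSE)
  cc <- sparsity_to_c(gen$X, 0.6, tol_sparsity = 0.05)
  f <- suppressWarnings(spca(gen$X, K = 1, c = as.numeric(cc)))
  expect_lt(abs(f$achieved_sparsity[1] - 0.6), 0.1)
  g <- sparsity_grid(gen$X, levels = c(0.8, 0.5))
  expect_true(!is.unsorted(g, strictly = TRUE))
  expect_equal(max(g), sqrt(450))
})
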