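test_that("similarity is exact for perfect and sign-flipped recovery", {
  set.seed(61)
  A <- matrix(rnorm(50 * 3), 50, 3)
  expect_equal(similarity(A, A)$mean, 1)
  expect_equal(similarity(A, -A)$mean, 1)
  # invariant to a consistent permutation of the estimated set
  perm <- c(3, 1, 2)
  expect_equal(similarity(A, A[, perm])$mean, 1)
  sim <- similarity(A, -A[, perm])
  expect_equal(sim$per_component, rep(1, 3))
  expect_equal(sim$perm, order(perm))
  expect_error(similarity(A, cbind(A[, 1:2], 0)), "constant")
})

test_that("similarity of independent columns matches the null expectation", {
  # E|corr| for independent n=80 Gaussians, by Monte Carlo
  set.seed(62)
  null_mc <- mean(replicate(3000, abs(cor(rnorm(80), rnorm(80)))))
  vals <- replicate(300, similarity(matrix(rnorm(80 * 3), 80, 3),
                                    matrix(rnorm(80 * 3), 80, 3))$mean)
  # assignment matching picks the best permutation, so the mean sits a bit
  # above the unmatched null; check the right order of magnitude and bound
  expect_gt(mean(vals), null_mc)
  expect_lt(mean(vals), 3 * null_mc)
})

test_that("correlation_error follows the stated sign convention", {
  expect_equal(correlation_error(c(0.7, 0.45, 0.22),
                                 c(0.7, 0.45, 0.22))$delta_rho, 0)
  expect_equal(correlation_error(c(0.7, 0.45, 0.22),
                                 c(0.6, 0.4, 0.2))$delta_rho, 0.17)
  # overestimation everywhere gives a negative value
  expect_lt(correlation_error(c(0.5, 0.3), c(0.6, 0.5))$delta_rho, 0)
  # linearity in offsets
  a <- c(0.02, -0.01, 0.03); b <- c(-0.05, 0.02, 0.01)
  rho <- c(0.7, 0.45, 0.22)
  expect_equal(correlation_error(rho, rho - (a + b))$delta_rho,
               correlation_error(rho, rho - a)$delta_rho +
                 correlation_error(rho, rho - b)$delta_rho)
  expect_error(correlation_error(c(0.7, 0.4), 0.7), "length")
})

test_that("roc_auc equals the brute-force pairwise probability", {
  # perfectly separated
  expect_equal(as.numeric(roc_auc(c(1, 2, 3, 11, 12, 13),
                                  rep(c(0, 1), each = 3))), 1)
  # label inversion complements
  s <- c(0.3, 0.1, 0.9, 0.5, 0.2, 0.8, 0.4, 0.6)
  l <- c(0, 0, 1, 1, 0, 1, 0, 1)
  expect_equal(as.numeric(roc_auc(s, l)) + as.numeric(roc_auc(s, 1 - l)), 1)
  # 8-point toy set with ties vs the brute-force oracle
  s2 <- c(1, 2, 2, 3, 3, 3, 4, 5)
  l2 <- c(0, 0, 1, 0, 1, 1, 0, 1)
  expect_equal(as.numeric(roc_auc(s2, l2)), oracle_auc(s2, l2 == 1))
  # property over random instances with n <= 20
  set.seed(63)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    score <- sample(1:6, n, replace = TRUE)  # forces ties
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(as.numeric(roc_auc(score, lab)), oracle_auc(score, lab == 1))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "two classes")
})

test_that("welch_ttest matches the textbook formula and t.test", {
  x <- c(3.1, 4.2, 2.8, 5.0, 3.9)
  y <- c(6.2, 5.8, 7.1, 6.6, 5.9)
  w <- welch_ttest(x, y, n_comparisons = 3)
  o <- oracle_welch(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(w$p_corr, min(1, 3 * o$p))
  # identical groups
  same <- welch_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # affine invariance of the statistic
  w2 <- welch_ttest(2 * x + 5, 2 * y + 5)
  expect_equal(w2$t, w$t, tolerance = 1e-12)
})

test_that("psnr follows its definition and scaling law", {
  clean <- matrix(runif(100), 10, 10)
  noise <- matrix(rnorm(100), 10, 10)
  noisy1 <- clean + 0.1 * noise / sqrt(mean(noise^2))
  expect_equal(psnr(clean, noisy1, maxval = 1), 20, tolerance = 1e-12)
  # doubling the noise amplitude costs 20 log10(2) dB
  noisy2 <- clean + 0.2 * noise / sqrt(mean(noise^2))
  expect_equal(psnr(clean, noisy1, maxval = 1) -
                 psnr(clean, noisy2, maxval = 1),
               20 * log10(2), tolerance = 1e-10)
  expect_equal(psnr(clean, clean), Inf)
  # round trip with the calibrated generator
  noisy3 <- add_noise_to_psnr(clean, 10, seed = 4)
  expect_equal(psnr(clean, noisy3), 10, tolerance = 0.01)
  # printed-form variant (MSE rather than RMSE in the denominator)
  expect_equal(psnr(clean, noisy1, maxval = 1, mse_denom = TRUE),
               20 * log10(1 / 0.01), tolerance = 1e-10)
})

test_that("match_components finds the optimal assignment", {
  S <- rbind(c(0.9, 0.2, 0.1),
             c(0.8, 0.7, 0.1),  # greedy on rows would take (1,1) then (2,2)
             c(0.1, 0.9, 0.2))
  mm <- match_components(S)
  expect_equal(mm$perm, c(1, 3, 2))
  expect_equal(mm$score, max(S[1, 1] + S[2, 2] + S[3, 3],
                             S[1, 1] + S[2, 3] + S[3, 2],
                             S[1, 2] + S[2, 1] + S[3, 3],
                             S[1, 2] + S[2, 3] + S[3, 1],
                             S[1, 3] + S[2, 1] + S[3, 2],
                             S[1, 3] + S[2, 2] + S[3, 1]))
})

test_that("sim1 benchmark reports per-method similarity summaries", {
  spec <- sim1_spec(dims = c(16, 16, 2), psnr_db = 15, seed = 17,
                    n_blobs = 2L, n_replicates = 2L)
  b <- suppressWarnings(run_sim1_benchmark(spec))
  expect_equal(nrow(b$results), 4L)
  expect_setequal(b$summary$method, c("spca", "pca"))
  expect_true(all(b$results$S_Y >= 0 & b$results$S_Y <= 1))
  expect_true(all(b$results$S_V >= 0 & b$results$S_V <= 1))
})

test_that("sim2 benchmark runs both methods on a miniature world", {
  spec <- sim2_spec(dims = c(16, 16, 2), n_per_group = 20L, seed = 18,
                    n_blobs = 2L, n_replicates = 2L)
  b <- suppressWarnings(run_sim2_benchmark(spec, n_folds = 5))
  expect_equal(b$n_failed, 0L)
  expect_equal(nrow(b$results), 4L)
  expect_true(all(is.finite(b$results$delta_rho)))
  expect_true(all(b$results$AUC >= 0.5 & b$results$AUC <= 1))
  # noise-free limit: both methods near-perfect
  spec0 <- sim2_spec(dims = c(16, 16, 2), n_per_group = 20L, seed = 19,
                     psnr_db = Inf, n_blobs = 2L, n_replicates = 1L)
  b0 <- suppressWarnings(run_sim2_benchmark(spec0, spca_c = "cv",
                                            n_folds = 5))
  expect_true(all(abs(b0$results$delta_rho) < 0.01))
  expect_true(all(b0$results$S_A > 0.99))
  expect_true(all(b0$results$S_C > 0.99))
})
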