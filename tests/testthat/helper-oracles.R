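# Independent oracles used across the test files. All are brute-force or
# closed-form routes that never touch the package's own solvers.

# Grid-search oracle for the L1-constrained direction update: scans a dense
# grid of thresholds and returns the normalized soft-thresholded vector
# maximizing a'v subject to ||v||_1 <= c.
oracle_solve_v <- function(a, c, n_grid = 20001L) {
  soft <- function(a, mu) sign(a) * pmax(abs(a) - mu, 0)
  best_v <- NULL
  best_obj <- -Inf
  for (mu in seq(0, max(abs(a)), length.out = n_grid)) {
    s <- soft(a, mu)
    ns <- sqrt(sum(s^2))
    if (ns == 0) next
    v <- s / ns
    if (sum(abs(v)) <= c + 1e-9) {
      obj <- sum(a * v)
      if (obj > best_obj) {
        best_obj <- obj
        best_v <- v
      }
    }
  }
  best_v
}

# Alternating oracle built on the grid-search update.
oracle_fit_component <- function(X, c, n_iter = 300L) {
  u <- svd(X, nu = 1L, nv = 0L)$u[, 1L]
  v <- NULL
  for (i in seq_len(n_iter)) {
    v <- oracle_solve_v(drop(crossprod(X, u)), c)
    b <- drop(X %*% v)
    u <- b / sqrt(sum(b^2))
  }
  list(u = u, v = v, d = drop(crossprod(u, X %*% v)))
}

# Normal-equations least squares.
oracle_lstsq <- function(A, B) solve(crossprod(A), crossprod(A, B))

# Brute-force AUC over all positive-negative pairs (ties count 1/2).
oracle_auc <- function(score, pos) {
  sp <- score[pos]
  sn <- score[!pos]
  tot <- 0
  for (i in seq_along(sp)) for (j in seq_along(sn))
    tot <- tot + (sp[i] > sn[j]) + 0.5 * (sp[i] == sn[j])
  tot / (length(sp) * length(sn))
}

# Textbook Welch statistic / Satterthwaite df / two-sided p.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Closed-form CCA through the generalized eigenproblem on the joint
# covariance: rho^2 are eigenvalues of S11^-1 S12 S22^-1 S21.
oracle_cca_rho <- function(Y1, Y2) {
  Y1 <- scale(Y1, scale = FALSE)
  Y2 <- scale(Y2, scale = FALSE)
  S11 <- crossprod(Y1); S22 <- crossprod(Y2); S12 <- crossprod(Y1, Y2)
  M <- solve(S11, S12) %*% solve(S22, t(S12))
  sqrt(pmax(sort(Re(eigen(M)$values), decreasing = TRUE), 0))
}

# Small deterministic rank-one problem builders.
unit <- function(x) x / sqrt(sum(x^2))
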