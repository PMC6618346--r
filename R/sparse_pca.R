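# Validate the sparsity bound, tolerating one-ulp excursions from
# exp(log(sqrt(m)))-style grid construction.
check_c <- function(c, m) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) ||
      c < 1 - 1e-9 || c > sqrt(m) * (1 + 1e-9))
    stop("c must lie in [1, sqrt(m)]")
  min(max(c, 1), sqrt(m))
}

#' Soft-thresholding operator
#'
#' `S(a, mu) = sign(a) * max(0, |a| - mu)`, applied element-wise: the proximal
#' operator of the L1 norm and the workhorse of the sparse rank-one update.
#'
#' @param a numeric vector.
#' @param mu non-negative threshold.
#' @return Numeric vector of the same length as `a`.
#' @export
soft_threshold <- function(a, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("mu must be a single non-negative number")
  sign(a) * pmax(abs(a) - mu, 0)
}

#' L1-constrained direction update
#'
#' Solves `max a'v` subject to `||v||_2 = 1`, `||v||_1 <= c`: the solution is
#' `S(a, mu)/||S(a, mu)||_2` with `mu = 0` when that is already feasible,
#' otherwise `mu` found by bisection on `[0, max|a|]` so that `||v||_1 = c`
#' (the L1 norm of the normalized thresholded vector is non-increasing in
#' `mu`).
#'
#' @param a numeric m-vector, not all zero.
#' @param c sparsity bound in `[1, sqrt(m)]`.
#' @param bis_tol relative bracket-width tolerance of the bisection: the
#'   threshold `mu` is resolved to `bis_tol * max(abs(a))`.
#' @param bis_maxit maximum bisection steps.
#' @return Unit-L2 numeric vector.
#' @export
solve_v <- function(a, c, bis_tol = 1e-12, bis_maxit = 100L) {
  m <- length(a)
  c <- check_c(c, m)
  if (all(a == 0)) stop("degenerate direction: a is the zero vector")
  .solve_v_cpp(a, c, bis_tol, as.integer(bis_maxit))[, 1L]
}

#' Unit-norm score update
#'
#' The unconstrained half-step of the alternation: `u = b/||b||_2`.
#'
#' @param b numeric vector, not all zero.
#' @return Unit-L2 vector along `b`.
#' @export
solve_u <- function(b) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("degenerate direction: b is the zero vector")
  b / nb
}

#' Fit a single sparse rank-one component
#'
#' Alternates the L1-constrained loading update [solve_v()] on `X'u` and the
#' score update [solve_u()] on `Xv` from a deterministic start (leading left
#' singular vector of `X` by power iteration from the normalized all-ones
#' vector) until the relative L2 change in `v` falls below `tol`. The
#' objective `d = u'Xv` is non-decreasing across iterations.
#'
#' @param X numeric matrix or [feature_matrix()], not all zero.
#' @param c sparsity bound in `[1, sqrt(m)]`.
#' @param tol relative convergence tolerance on `v` (default `1e-6`).
#' @param max_iter maximum alternations (default 200; a warning is raised and
#'   `converged = FALSE` returned when reached).
#' @param trace logical; record the objective value at every alternation.
#' @return A list of class `sparse_component` with elements `u`, `v`, `d`
#'   (`= u'Xv > 0`), `n_iter`, `converged` and (if requested) `objective`.
#' @export
fit_component <- function(X, c, tol = 1e-6, max_iter = 200L, trace = FALSE) {
  M <- fm_data(X)
  c <- check_c(c, ncol(M))
  res <- .spca_core_cpp(M, 1L, c, tol, as.integer(max_iter),
                        trace = trace)
  comp <- structure(list(u = res$U[, 1L], v = res$V[, 1L], d = res$d[1L],
                         n_iter = res$n_iter[1L],
                         converged = res$converged[1L] == 1L),
                    class = "sparse_component")
  if (trace) comp$objective <- res$trace[[1L]]
  if (!comp$converged)
    warning("component did not converge in ", max_iter, " alternations")
  comp
}

#' Remove a fitted component from the data
#'
#' Rank-one deflation `X - d u v'`; after deflating with a fitted component,
#' `u' X' v = 0`.
#'
#' @param X numeric matrix or [feature_matrix()].
#' @param comp a `sparse_component` with dimensions matching `X`.
#' @return The deflated matrix (plain matrix).
#' @export
deflate <- function(X, comp) {
  M <- fm_data(X)
  if (length(comp$u) != nrow(M) || length(comp$v) != ncol(M))
    stop("component dimensions do not match X")
  M - comp$d * tcrossprod(comp$u, comp$v)
}

# Joint sign canonicalization: flip (u, v) so the largest-|entry| of v is
# positive (first such entry on ties). Removes the inherent sign ambiguity.
canonicalize_signs <- function(U, V) {
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  list(U = U, V = V)
}

#' Sparse principal component analysis
#'
#' Sequential rank-one sparse PCA: each component solves
#' `max u'Xv  s.t. ||u||_2 = ||v||_2 = 1, ||v||_1 <= c`
#' by alternating convex half-steps, then the fitted rank-one term is deflated
#' from `X` before the next component. With `c = sqrt(m)` the L1 constraint is
#' inactive and the fit reproduces the truncated singular value decomposition.
#'
#' @param X numeric matrix or [feature_matrix()] (subjects x features).
#' @param K number of components, `1 <= K <= min(n, m)`. If the residual rank
#'   is exhausted earlier, fewer components are returned with a warning.
#' @param c sparsity tuning parameter in `[1, sqrt(m)]`; upper bound on the L1
#'   norm of each unit-L2 loading vector. Smaller `c` gives sparser loadings.
#' @inheritParams fit_component
#' @return An object of class `spca_model`: list with `U` (n x K scores
#'   directions), `V` (m x K sparse loadings), `d` (component weights, all
#'   positive), `c`, `K`, `achieved_sparsity` (fraction of exact zeros per
#'   loading), `n_iter`, `converged` and `sparse` flag.
#' @seealso [pca_fit()] for the exact (non-sparse) baseline, [cv_select()] for
#'   choosing `c` and `K`, [scores()] for subject-level scores.
#' @export
spca <- function(X, K, c, tol = 1e-6, max_iter = 200L, trace = FALSE) {
  M <- fm_data(X)
  n <- nrow(M); m <- ncol(M)
  if (K < 1L || K > min(n, m)) stop("K must lie in [1, min(n, m)]")
  c <- check_c(c, m)
  res <- .spca_core_cpp(M, as.integer(K), c, tol, as.integer(max_iter),
                        trace = trace)
  if (res$k < K)
    warning("rank exhausted: returning ", res$k, " of ", K, " components")
  flip <- canonicalize_signs(res$U, res$V)
  out <- structure(
    list(U = flip$U, V = flip$V, d = as.vector(res$d),
         c = c, K = res$k,
         achieved_sparsity = colMeans(flip$V == 0),
         n_iter = as.vector(res$n_iter),
         converged = as.vector(res$converged) == 1L,
         sparse = c < sqrt(m)),
    class = "spca_model")
  if (trace) out$objective <- res$trace
  if (!all(out$converged))
    warning("components not converged: ",
            paste(which(!out$converged), collapse = ", "))
  out
}

#' @export
print.spca_model <- function(x, ...) {
  cat("spca_model: ", x$K, " component(s), c = ", signif(x$c, 5),
      if (!x$sparse) " (L1 constraint inactive: exact PCA)", "\n", sep = "")
  cat("  d: ", paste(signif(x$d, 5), collapse = ", "), "\n", sep = "")
  cat("  zero fraction per loading: ",
      paste(sprintf("%.3f", x$achieved_sparsity), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Exact truncated PCA (SVD) baseline
#'
#' The K leading singular triplets of `X`, computed through the n x n Gram
#' matrix (efficient when features far outnumber subjects). Serves as the
#' non-sparse baseline: it equals [spca()] with `c = sqrt(m)`.
#'
#' @inheritParams spca
#' @return An `spca_model` with `d1 >= d2 >= ... > 0`; truncated with a
#'   warning if `K` exceeds the numerical rank.
#' @export
pca_fit <- function(X, K) {
  M <- fm_data(X)
  n <- nrow(M); m <- ncol(M)
  if (K < 1L || K > min(n, m)) stop("K must lie in [1, min(n, m)]")
  eg <- eigen(tcrossprod(M), symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  keep <- which(sqrt(d2) > max(sqrt(d2[1L]), 1) * 1e-12)
  if (length(keep) < K)
    warning("rank exhausted: returning ", length(keep), " of ", K,
            " components")
  K_eff <- min(K, length(keep))
  d <- sqrt(d2[seq_len(K_eff)])
  U <- eg$vectors[, seq_len(K_eff), drop = FALSE]
  V <- crossprod(M, U) %*% diag(1 / d, K_eff)
  flip <- canonicalize_signs(U, V)
  structure(list(U = flip$U, V = flip$V, d = d, c = sqrt(m), K = K_eff,
                 achieved_sparsity = colMeans(flip$V == 0),
                 n_iter = rep(0L, K_eff), converged = rep(TRUE, K_eff),
                 sparse = FALSE),
            class = "spca_model")
}

#' Principal component scores
#'
#' Subject-level scores `Y = Xhat V` where `Xhat = sum_i d_i u_i v_i'` is the
#' model reconstruction (default), or `Y = X V` on the raw data when
#' `raw = TRUE`.
#'
#' @param model an `spca_model`.
#' @param X the data the model was fitted on (matrix or [feature_matrix()]);
#'   required only for `raw = TRUE` but used to validate feature count.
#' @param raw logical; project the raw data instead of the reconstruction.
#' @return n x K numeric matrix of scores.
#' @export
scores <- function(model, X = NULL, raw = FALSE) {
  stopifnot(inherits(model, "spca_model"))
  if (raw || !is.null(X)) {
    M <- fm_data(X)
    if (ncol(M) != nrow(model$V))
      stop("feature count of X does not match the model")
    if (raw) return(M %*% model$V)
  }
  # Xhat V = U diag(d) (V'V), cheap in the reduced space
  (model$U %*% diag(model$d, model$K)) %*% crossprod(model$V)
}

#' Model reconstruction
#'
#' `Xhat = sum_i d_i u_i v_i'`.
#'
#' @param model an `spca_model`.
#' @return n x m numeric matrix.
#' @export
reconstruct <- function(model) {
  (model$U %*% diag(model$d, model$K)) %*% t(model$V)
}

#' Solve for the sparsity parameter reaching a target zero fraction
#'
#' Convenience inversion of the `c -> sparsity` map: bisects `c` in
#' `[1, sqrt(m)]` until the zero fraction of the first fitted loading is
#' within `tol_sparsity` of `target`, useful because sparsity is commonly
#' reported as a percentage of zero voxels (e.g. 70%).
#'
#' @inheritParams spca
#' @param target desired fraction of exactly-zero loading entries in `(0, 1)`.
#' @param tol_sparsity acceptable deviation from `target` (default 0.01).
#' @param maxit maximum bisection steps on `c`.
#' @param tol convergence tolerance passed to the component fits.
#' @return The sparsity parameter `c` (numeric scalar) with the achieved
#'   sparsity as attribute `"sparsity"`.
#' @export
sparsity_to_c <- function(X, target, tol_sparsity = 0.01, maxit = 30L,
                          tol = 1e-5) {
  M <- fm_data(X)
  if (target <= 0 || target >= 1) stop("target sparsity must be in (0, 1)")
  lo <- 1; hi <- sqrt(ncol(M))
  sp_at <- function(cc) {
    f <- suppressWarnings(fit_component(M, cc, tol = tol))
    mean(f$v == 0)
  }
  # sparsity is (weakly) decreasing in c
  best <- NA_real_; best_sp <- NA_real_
  for (i in seq_len(maxit)) {
    mid <- 0.5 * (lo + hi)
    sp <- sp_at(mid)
    if (is.na(best) || abs(sp - target) < abs(best_sp - target)) {
      best <- mid; best_sp <- sp
    }
    if (abs(sp - target) <= tol_sparsity) break
    if (sp > target) lo <- mid else hi <- mid
  }
  structure(best, sparsity = best_sp)
}

#' Sparsity-anchored grid for cross-validation
#'
#' Builds a grid of sparsity parameters whose first-component zero fractions
#' approximate the requested sparsity levels on the given data (via
#' [sparsity_to_c()]), plus the dense endpoint `sqrt(m)`. Anchoring the grid
#' in sparsity units puts the cross-validation resolution where results are
#' reported (the literature quotes sparsity levels such as 70% or 80%, and
#' the map from `c` to sparsity is steeply nonlinear near the dense end).
#'
#' @inheritParams spca
#' @param levels target zero fractions (default `c(0.9, 0.8, 0.7, 0.5)`,
#'   bracketing the operationally typical 70-80% range).
#' @param include_dense append `sqrt(m)` (the unconstrained fit).
#' @param tol convergence tolerance for the probe fits.
#' @return Strictly increasing numeric vector of `c` values, with the achieved
#'   probe sparsities as attribute `"levels"`.
#' @export
sparsity_grid <- function(X, levels = c(0.9, 0.8, 0.7, 0.5),
                          include_dense = TRUE, tol = 1e-4) {
  M <- fm_data(X)
  cs <- vapply(levels, function(l)
    as.numeric(sparsity_to_c(M, l, tol = tol)), numeric(1))
  if (include_dense) cs <- c(cs, sqrt(ncol(M)))
  out <- sort(unique(cs))
  structure(out, levels = levels)
}
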