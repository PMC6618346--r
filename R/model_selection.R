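#' Random balanced fold assignment
#'
#' Partitions `n` subjects into `n_folds` folds whose sizes differ by at most
#' one, reproducibly for a given seed.
#'
#' @param n number of subjects (`n >= n_folds`).
#' @param n_folds number of folds (`>= 2`), default 10.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return Object of class `fold_assignment`: list with `fold_of_sample`
#'   (integer n-vector of labels in `1..n_folds`), `n_folds` and `seed`.
#' @export
assign_folds <- function(n, n_folds = 10L, seed = NULL) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need n >= n_folds")
  labels <- rep(seq_len(n_folds), length.out = n)
  fold_of_sample <- with_seed(seed, sample(labels, n))
  structure(list(fold_of_sample = fold_of_sample, n_folds = n_folds,
                 seed = seed),
            class = "fold_assignment")
}

#' Least-squares reconstruction of a held-out block
#'
#' Regresses each held-out subject's feature vector on the training loadings:
#' `beta = V_train^+ X_heldout'` (Moore-Penrose pseudoinverse) and
#' `Xhat = (V_train beta)'`, i.e. the projection of each held-out row onto
#' `span(V_train)`.
#'
#' @param V_train m x K loading matrix from the retained folds.
#' @param X_heldout n_f x m held-out data block.
#' @return List with `X_hat` (n_f x m) and `beta` (K x n_f).
#' @export
reconstruct_heldout <- function(V_train, X_heldout) {
  V_train <- as.matrix(V_train)
  X_heldout <- rbind(as.matrix(X_heldout))
  if (ncol(X_heldout) != nrow(V_train))
    stop("feature counts of V_train and X_heldout do not match")
  K <- ncol(V_train)
  if (K > nrow(V_train)) warning("K exceeds the number of features")
  G <- crossprod(V_train)
  rhs <- crossprod(V_train, t(X_heldout))
  beta <- tryCatch(solve(G, rhs), error = function(e) {
    sv <- svd(G)
    pos <- sv$d > max(sv$d[1L], 1) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], rhs) / sv$d[pos])
  })
  list(X_hat = t(V_train %*% beta), beta = beta)
}

#' AIC for a held-out reconstruction
#'
#' Gaussian profile form `AIC = N log(RSS/N) + 2p` with `N` the number of
#' held-out residuals (`n_f * m`), `RSS` the squared reconstruction error and
#' `p = K * n_f + n_loading_par` model parameters: one regression coefficient
#' per component per held-out subject, plus optionally the free (non-zero)
#' entries of the loading matrix. The default (`n_loading_par = 0`) scores the
#' training loadings as a fixed design, which is well-posed under white
#' observation noise (a sparse basis close to the true support genuinely
#' reconstructs held-out subjects better). Under strongly spatially correlated
#' noise a denser, smoother basis always captures more held-out variance, and
#' the loading count should then be included to keep the criterion from
#' drifting to the dense boundary (see the methods vignette). Lower is better.
#' The formula is isolated here so an alternative penalty can be swapped in.
#'
#' @param X_heldout held-out block (n_f x m).
#' @param X_hat its reconstruction from training loadings.
#' @param K number of components used.
#' @param n_loading_par number of free loading parameters (non-zero entries of
#'   the training `V`; 0 omits the loading term).
#' @return AIC value (scalar).
#' @export
heldout_aic <- function(X_heldout, X_hat, K, n_loading_par = 0) {
  X_heldout <- rbind(as.matrix(X_heldout))
  X_hat <- rbind(as.matrix(X_hat))
  if (!identical(dim(X_heldout), dim(X_hat))) stop("shapes do not agree")
  N <- length(X_heldout)
  rss <- sum((X_heldout - X_hat)^2)
  if (rss == 0) {
    warning("zero residual sum of squares; flooring at 1e-300")
    rss <- 1e-300
  }
  N * log(rss / N) + 2 * (K * nrow(X_heldout) + n_loading_par)
}

#' Split-sample cross-validation for the sparsity parameter and rank
#'
#' Ten-fold (by default) split-sample cross-validation: for each fold, sparse
#' PCA is fitted on the retained subjects at every grid value of `c` (for a
#' fixed `c` the components are nested in `K`, so one fit at `max(K_grid)`
#' serves the whole `K` grid), the held-out block is reconstructed by
#' least-squares on the training loadings and scored by [heldout_aic()]. Each
#' fold contributes its AIC-minimizing pair `(c_f, K_f)`; the selected
#' parameters are `c* = mean(c_f)` and `K* = ` round-half-up of `mean(K_f)`.
#'
#' @param X numeric matrix or [feature_matrix()] (subjects x features).
#' @param c_grid strictly increasing sparsity values in `[1, sqrt(m)]`;
#'   default: 10 geometrically spaced values spanning that interval.
#' @param K_grid strictly increasing positive integers; default `1:20`
#'   (capped at `min(n - ceiling(n/n_folds), m)`).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param tol,max_iter convergence controls for the inner sPCA fits. The
#'   default CV tolerance (`1e-4`) is looser than the fitting default because
#'   parameter selection does not require high-precision components.
#' @return Object of class `spca_cv`: list with `c_star`, `K_star`,
#'   `fold_results` (per fold: `fold`, `c_f`, `K_f`, `aic` matrix over the
#'   grid, `beta` at the fold optimum), `c_grid`, `K_grid`, `n_folds`, `seed`.
#' @export
cv_select <- function(X, c_grid = NULL, K_grid = NULL, n_folds = 10L,
                      seed = NULL, tol = 1e-4, max_iter = 200L) {
  M <- fm_data(X)
  n <- nrow(M); m <- ncol(M)
  if (is.null(c_grid))
    c_grid <- exp(seq(log(1), log(sqrt(m)), length.out = 10L))
  if (is.null(K_grid)) K_grid <- seq_len(20L)
  K_grid <- as.integer(K_grid)
  n_train_min <- n - ceiling(n / n_folds)
  K_grid <- K_grid[K_grid <= min(n_train_min, m)]
  if (length(c_grid) == 0L || length(K_grid) == 0L) stop("empty grid")
  if (is.unsorted(c_grid, strictly = TRUE) ||
      is.unsorted(K_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  if (any(c_grid < 1 - 1e-9) || any(c_grid > sqrt(m) * (1 + 1e-9)))
    stop("c_grid must lie in [1, sqrt(m)]")
  c_grid <- pmin(pmax(c_grid, 1), sqrt(m))
  K_max <- max(K_grid)

  folds <- assign_folds(n, n_folds, seed)
  fold_results <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- folds$fold_of_sample == f
    X_tr <- M[!held, , drop = FALSE]
    X_ho <- M[held, , drop = FALSE]
    aic <- matrix(NA_real_, length(c_grid), length(K_grid),
                  dimnames = list(signif(c_grid, 6), K_grid))
    best <- list(aic = Inf)
    ok <- tryCatch({
      for (ci in seq_along(c_grid)) {
        fit <- suppressWarnings(
          spca(X_tr, K = K_max, c = c_grid[ci], tol = tol,
               max_iter = max_iter))
        for (ki in seq_along(K_grid)) {
          Kk <- K_grid[ki]
          if (Kk > fit$K) next
          Vk <- fit$V[, seq_len(Kk), drop = FALSE]
          rec <- reconstruct_heldout(Vk, X_ho)
          aic[ci, ki] <- heldout_aic(X_ho, rec$X_hat, Kk)
          if (aic[ci, ki] < best$aic)
            best <- list(aic = aic[ci, ki], c_f = c_grid[ci], K_f = Kk,
                         beta = rec$beta)
        }
      }
      TRUE
    }, error = function(e) {
      warning("fold ", f, " excluded: ", conditionMessage(e))
      FALSE
    })
    if (!ok || !is.finite(best$aic)) next
    if (best$c_f %in% range(c_grid))
      warning("fold ", f, ": optimal c on the grid boundary (",
              signif(best$c_f, 4), "); consider extending c_grid")
    fold_results[[f]] <- list(fold = f, c_f = best$c_f, K_f = best$K_f,
                              aic = aic, beta = best$beta)
  }
  fold_results <- Filter(Negate(is.null), fold_results)
  if (length(fold_results) == 0L) stop("all folds degenerate")

  c_f <- vapply(fold_results, `[[`, numeric(1), "c_f")
  K_f <- vapply(fold_results, `[[`, numeric(1), "K_f")
  structure(list(c_star = mean(c_f),
                 K_star = as.integer(floor(mean(K_f) + 0.5)),  # round half up
                 fold_results = fold_results,
                 c_grid = c_grid, K_grid = K_grid,
                 n_folds = n_folds, seed = seed),
            class = "spca_cv")
}

#' @export
print.spca_cv <- function(x, ...) {
  cat("spca_cv: c* = ", signif(x$c_star, 5), ", K* = ", x$K_star,
      " (", length(x$fold_results), "/", x$n_folds, " folds)\n", sep = "")
  cat("  per-fold c: ",
      paste(signif(vapply(x$fold_results, `[[`, numeric(1), "c_f"), 4),
            collapse = ", "), "\n", sep = "")
  cat("  per-fold K: ",
      paste(vapply(x$fold_results, `[[`, numeric(1), "K_f"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
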