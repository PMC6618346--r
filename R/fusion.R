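#' Canonical correlation analysis on score matrices
#'
#' Finds canonical transformation matrices `Z1`, `Z2` maximizing
#' `corr(Y1 z1, Y2 z2)` successively under within-set uncorrelatedness,
#' implemented by whitening each set (inverse square root of the within-set
#' covariance) followed by an SVD of the whitened cross-covariance; this is
#' numerically safer than a direct generalized eigensolve at these sizes.
#'
#' @param Y1,Y2 numeric matrices with the same number of rows (subjects);
#'   `n` must exceed the larger column count. Columns are centered internally.
#' @param ridge ridge added to a within-set covariance when it is numerically
#'   rank deficient (with a warning); default `1e-10` relative to the largest
#'   eigenvalue.
#' @return Object of class `cca_model`: `Z1` (K1 x D), `Z2` (K2 x D), `rho`
#'   (D-vector, non-increasing, in `[0, 1]`), `center1`, `center2`,
#'   `D = min(K1, K2)`.
#' @export
fit_cca <- function(Y1, Y2, ridge = 1e-10) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  n <- nrow(Y1)
  if (nrow(Y2) != n) stop("Y1 and Y2 must have the same subjects")
  K1 <- ncol(Y1); K2 <- ncol(Y2)
  if (n <= max(K1, K2)) stop("need more subjects than components")
  c1 <- colMeans(Y1); c2 <- colMeans(Y2)
  Y1c <- sweep(Y1, 2L, c1); Y2c <- sweep(Y2, 2L, c2)
  S11 <- crossprod(Y1c) / (n - 1)
  S22 <- crossprod(Y2c) / (n - 1)
  S12 <- crossprod(Y1c, Y2c) / (n - 1)
  whiten <- function(S, label) {
    eg <- eigen(S, symmetric = TRUE)
    lam <- eg$values
    if (min(lam) < ridge * max(lam)) {
      warning("rank-deficient within-set covariance (", label,
              "); adding ridge")
      lam <- lam + ridge * max(lam)
    }
    eg$vectors %*% diag(1 / sqrt(lam), length(lam)) %*% t(eg$vectors)
  }
  W1 <- whiten(S11, "Y1"); W2 <- whiten(S22, "Y2")
  sv <- svd(W1 %*% S12 %*% W2)
  D <- min(K1, K2)
  structure(list(Z1 = W1 %*% sv$u[, seq_len(D), drop = FALSE],
                 Z2 = W2 %*% sv$v[, seq_len(D), drop = FALSE],
                 rho = pmin(pmax(sv$d[seq_len(D)], 0), 1),
                 center1 = c1, center2 = c2, D = D),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat("cca_model: D = ", x$D, ", rho = ",
      paste(sprintf("%.4f", x$rho), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Modulation profiles (canonical variates)
#'
#' `A = Y Z` after centering `Y`; each column is scaled to unit variance so
#' profile magnitudes are comparable across components and modalities. Sign
#' matching across modalities (so that `corr(A1_d, A2_d) >= 0`) is applied by
#' [fuse()], which sees both modalities.
#'
#' @param Y n x K score matrix.
#' @param Z K x D canonical transformation matrix.
#' @param center column means to remove (default: means of `Y`).
#' @return n x D matrix of unit-variance modulation profiles.
#' @export
modulation_profiles <- function(Y, Z, center = NULL) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (ncol(Y) != nrow(Z)) stop("shapes of Y and Z do not agree")
  if (is.null(center)) center <- colMeans(Y)
  A <- sweep(Y, 2L, center) %*% Z
  s <- apply(A, 2L, sd)
  if (any(s == 0)) stop("constant canonical variate")
  sweep(A, 2L, s, "/")
}

#' Spatial maps by least-squares back-projection
#'
#' `C = A^+ Xhat` (Moore-Penrose pseudoinverse): row `d` of `C` is the spatial
#' pattern whose subject-wise expression best reproduces the data given the
#' modulation profiles. The reconstruction `Xhat` is the default regressand;
#' pass the raw data matrix to use it instead.
#'
#' @param A n x D modulation profiles (`n >= D`).
#' @param X n x m data or reconstruction matrix.
#' @return D x m matrix of spatial maps.
#' @export
spatial_maps <- function(A, X) {
  A <- as.matrix(A); X <- fm_data(X)
  if (nrow(A) != nrow(X)) stop("A and X must have the same subjects")
  if (nrow(A) < ncol(A)) stop("need n >= D")
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    warning("rank-deficient profiles; using pseudoinverse")
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1L], 1) * 1e-12
    return(sv$v[, pos, drop = FALSE] %*%
             (crossprod(sv$u[, pos, drop = FALSE], X) / sv$d[pos]))
  }
  qr.coef(qa, X)
}

#' Z-score a spatial map
#'
#' Standardizes a map row to mean 0, sd 1 over the included features (the
#' usual convention before thresholding maps for display, e.g. at `z >= 1.5`).
#' Thresholding itself is left to the consumer.
#'
#' @param c_row numeric vector (one spatial map), non-constant.
#' @return Standardized vector.
#' @export
zscore_map <- function(c_row) {
  s <- sd(c_row)
  if (!is.finite(s) || s == 0) stop("zero-variance map cannot be z-scored")
  (c_row - mean(c_row)) / s
}

#' sPCA+CCA fusion of two modalities
#'
#' The full pipeline: sparse PCA per modality at the supplied `(c, K)`
#' (typically the cross-validated optimum from [cv_select()]), subject scores
#' `Y_r = Xhat_r V_r`, CCA linking the two score sets, unit-variance
#' modulation profiles `A_r = Y_r Z_r` (signs fixed so matched pairs correlate
#' positively), least-squares spatial maps `C_r = A_r^+ Xhat_r` and their
#' z-scored versions. With `method = "pca"` (or `c_r = sqrt(m_r)`) this is the
#' PCA+CCA baseline.
#'
#' @param X1,X2 the two modalities ([feature_matrix()] or matrices) with the
#'   same subjects in the same row order (checked via sample ids).
#' @param K1,K2 number of components per modality.
#' @param c1,c2 sparsity parameters; ignored for `method = "pca"`.
#' @param method `"spca"` (default) or `"pca"` for the exact-PCA baseline.
#' @param use_reconstructed logical; use `Xhat_r` (default, as in the score
#'   and map definitions) or the raw `X_r` in both places.
#' @param tol,max_iter convergence controls for the sPCA fits.
#' @return Object of class `fusion_result`: `A1`, `A2` (n x D modulation
#'   profiles), `C1`, `C2` (D x m spatial maps), `zmaps1`, `zmaps2`, `rho`
#'   (D-vector), `cca`, `model1`, `model2`, `D`, `method`.
#' @export
fuse <- function(X1, X2, K1, K2, c1 = NULL, c2 = NULL,
                 method = c("spca", "pca"), use_reconstructed = TRUE,
                 tol = 1e-6, max_iter = 200L) {
  method <- match.arg(method)
  ids1 <- fm_ids(X1); ids2 <- fm_ids(X2)
  if (length(ids1) != length(ids2) || !all(ids1 == ids2))
    stop("modalities must share the same subjects in the same order")
  M1 <- fm_data(X1); M2 <- fm_data(X2)

  fit_one <- function(M, K, c) {
    if (method == "pca" || (!is.null(c) && c >= sqrt(ncol(M))))
      pca_fit(M, K)
    else {
      if (is.null(c)) stop("c required for method = 'spca'")
      spca(M, K, c, tol = tol, max_iter = max_iter)
    }
  }
  model1 <- fit_one(M1, K1, c1)
  model2 <- fit_one(M2, K2, c2)
  Y1 <- if (use_reconstructed) scores(model1) else scores(model1, M1, raw = TRUE)
  Y2 <- if (use_reconstructed) scores(model2) else scores(model2, M2, raw = TRUE)

  cca <- fit_cca(Y1, Y2)
  A1 <- modulation_profiles(Y1, cca$Z1, cca$center1)
  A2 <- modulation_profiles(Y2, cca$Z2, cca$center2)
  for (d in seq_len(cca$D)) {       # matched pairs correlate positively
    if (cor(A1[, d], A2[, d]) < 0) {
      A2[, d] <- -A2[, d]
      cca$Z2[, d] <- -cca$Z2[, d]
    }
  }
  R1 <- if (use_reconstructed) reconstruct(model1) else M1
  R2 <- if (use_reconstructed) reconstruct(model2) else M2
  C1 <- spatial_maps(A1, R1)
  C2 <- spatial_maps(A2, R2)
  structure(list(A1 = A1, A2 = A2, C1 = C1, C2 = C2,
                 zmaps1 = t(apply(C1, 1L, zscore_map)),
                 zmaps2 = t(apply(C2, 1L, zscore_map)),
                 rho = cca$rho, cca = cca,
                 model1 = model1, model2 = model2,
                 D = cca$D, method = method),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("fusion_result (", if (x$method == "spca") "sPCA+CCA" else "PCA+CCA",
      "): D = ", x$D, "\n", sep = "")
  cat("  rho: ", paste(sprintf("%.4f", x$rho), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
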