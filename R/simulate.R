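#' Specification for the single-modality simulation
#'
#' States the simulated world for the sPCA-vs-PCA study: 80 subjects, 3
#' intrinsic components on a 91 x 109 x 3 grid (2-mm voxels), orthogonal
#' sparse spatial maps at a stated zero fraction, additive Gaussian noise
#' calibrated to a stated PSNR and 8-mm FWHM Gaussian smoothing.
#'
#' @param n number of subjects (default 80).
#' @param K number of intrinsic components (default 3).
#' @param dims 3-D grid dimensions (default `c(91, 109, 3)`).
#' @param sparsity fraction of exactly-zero voxels per map, in `(0, 1)`
#'   (default 0.7; the study grid is 0.3 / 0.5 / 0.7).
#' @param psnr_db target peak signal-to-noise ratio in dB (default 15; the
#'   study grid is 5 / 10 / 15). `Inf` disables noise.
#' @param fwhm_mm spatial-correlation scale of the world in mm (default 8):
#'   the smoothing FWHM applied to the noise field when
#'   `noise_type = "smoothed"`. The spatial maps themselves are smooth blobs
#'   by construction, so the default white-noise world already carries
#'   spatially correlated signal.
#' @param noise_type `"white"` (default) or `"smoothed"`: whether the Gaussian
#'   noise field is FWHM-smoothed before the exact PSNR calibration. See the
#'   methods vignette for why reconstruction-based cross-validation is only
#'   well-posed under white observation noise.
#' @param voxel_mm isotropic voxel size in mm (default 2, the MNI 2-mm grid).
#' @param weights component-strength ratios: the sd of score column `d` is
#'   `weights[d]` (default `c(1, 0.8, 0.6)`), giving well-separated singular
#'   values so component order is identifiable.
#' @param n_blobs contiguous blobs per spatial map (default 4).
#' @param n_replicates replicates sharing `(Y, V)` with fresh noise
#'   (default 100).
#' @param seed integer seed fixing the ground truth and, jointly with the
#'   replicate index, each noise field.
#' @return Object of class `sim1_spec`.
#' @export
sim1_spec <- function(n = 80L, K = 3L, dims = c(91L, 109L, 3L),
                      sparsity = 0.7, psnr_db = 15, fwhm_mm = 8,
                      noise_type = c("white", "smoothed"),
                      voxel_mm = 2, weights = c(1, 0.8, 0.6), n_blobs = 4L,
                      n_replicates = 100L, seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(n >= 4L, K >= 1L, length(dims) == 3L, all(dims >= 1L),
            sparsity > 0, sparsity < 1, is.finite(fwhm_mm),
            length(weights) == K, all(weights > 0), n_replicates >= 1L)
  if (!is.infinite(psnr_db)) stopifnot(is.finite(psnr_db))
  structure(list(n = as.integer(n), K = as.integer(K),
                 dims = as.integer(dims), sparsity = sparsity,
                 psnr_db = psnr_db, fwhm_mm = fwhm_mm,
                 noise_type = noise_type, voxel_mm = voxel_mm,
                 weights = weights, n_blobs = as.integer(n_blobs),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim1_spec")
}

#' Specification for the two-modality fusion simulation
#'
#' States the simulated world for the fusion study: two balanced groups of 40
#' subjects, three modulation-profile pairs with canonical correlations
#' `c(0.70, 0.45, 0.22)` satisfying the within- and cross-set orthogonality
#' structure exactly, independent sparse orthogonal map sets per modality at
#' 70% sparsity, 10 dB PSNR noise and 8-mm FWHM smoothing; the first profile
#' pair is group-distinct.
#'
#' @param n_per_group subjects per group (default 40, two groups).
#' @param rho true canonical correlations, strictly decreasing in `(0, 1]`
#'   (default `c(0.70, 0.45, 0.22)`).
#' @param group_effect standardized mean difference injected on the first
#'   profile pair (default 1.5).
#' @inheritParams sim1_spec
#' @return Object of class `sim2_spec`.
#' @export
sim2_spec <- function(n_per_group = 40L, rho = c(0.70, 0.45, 0.22),
                      sparsity = 0.7, psnr_db = 10, fwhm_mm = 8,
                      noise_type = c("white", "smoothed"),
                      dims = c(91L, 109L, 3L), voxel_mm = 2,
                      weights = c(1, 0.8, 0.6), n_blobs = 4L,
                      group_effect = 1.5, n_replicates = 50L, seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(n_per_group >= 2L, all(rho > 0), all(rho <= 1),
            !is.unsorted(rev(rho), strictly = TRUE),
            sparsity > 0, sparsity < 1, length(weights) == length(rho),
            all(weights > 0), n_replicates >= 1L)
  structure(list(n_per_group = as.integer(n_per_group), rho = rho,
                 K = length(rho), sparsity = sparsity, psnr_db = psnr_db,
                 fwhm_mm = fwhm_mm, noise_type = noise_type,
                 dims = as.integer(dims),
                 voxel_mm = voxel_mm, weights = weights,
                 n_blobs = as.integer(n_blobs), group_effect = group_effect,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim2_spec")
}

#' Orthogonal sparse spatial maps
#'
#' Builds `K` unit-norm spatial maps on a 3-D grid, each supported on
#' `n_blobs` contiguous blobs and carrying exactly `round(sparsity * m)` zero
#' entries, with pairwise inner products exactly zero. Orthogonality is
#' enforced by a support-restricted least-squares correction: the correction
#' applied to map `k` is a linear combination of the earlier maps restricted
#' to map `k`'s support, so it cannot create values outside the support and
#' the zero count is preserved exactly.
#'
#' @param dims integer 3-vector of grid dimensions.
#' @param K number of maps.
#' @param sparsity zero fraction per map in `(0, 1)`.
#' @param seed integer seed (blob centers are random).
#' @param n_blobs contiguous blobs per map (default 4).
#' @return m x K matrix of unit-norm, mutually orthogonal sparse maps.
#' @export
make_sparse_maps <- function(dims, K, sparsity, seed = NULL, n_blobs = 4L) {
  dims <- as.integer(dims)
  m <- prod(dims)
  n_zero <- round(sparsity * m)
  n_nz <- m - n_zero
  if (n_nz <= K + 1L)
    stop("infeasible sparsity/K combination: too few nonzero entries")
  coords <- arrayInd(seq_len(m), dims)
  # in-plane blob radius if blobs tile all slices; sets the value decay scale
  r_eff <- sqrt(n_nz / (n_blobs * pi * dims[3L]))
  V <- matrix(0, m, K)
  with_seed(seed, {
    for (k in seq_len(K)) {
      centers <- coords[sample.int(m, n_blobs), , drop = FALSE]
      dmin <- rep(Inf, m)
      for (b in seq_len(n_blobs)) {
        db <- sqrt((coords[, 1L] - centers[b, 1L])^2 +
                   (coords[, 2L] - centers[b, 2L])^2 +
                   (coords[, 3L] - centers[b, 3L])^2)
        dmin <- pmin(dmin, db)
      }
      support <- sort(order(dmin)[seq_len(n_nz)])
      v <- numeric(m)
      v[support] <- exp(-dmin[support]^2 / (2 * (r_eff / 2)^2)) + 1e-6
      if (k > 1L) {
        W <- V[support, seq_len(k - 1L), drop = FALSE]
        use <- colSums(W^2) > 0
        if (any(use)) {
          W <- W[, use, drop = FALSE]
          G <- crossprod(W)
          cvec <- crossprod(W, v[support])
          alpha <- tryCatch(solve(G, cvec), error = function(e) {
            sv <- svd(G)
            pos <- sv$d > max(sv$d[1L], 1) * 1e-12
            sv$v[, pos, drop = FALSE] %*%
              (crossprod(sv$u[, pos, drop = FALSE], cvec) / sv$d[pos])
          })
          v[support] <- v[support] - as.vector(W %*% alpha)
        }
      }
      if (sum(v != 0) != n_nz)
        stop("infeasible sparsity/K combination: ",
             "orthogonalization annihilated support entries")
      V[, k] <- v / sqrt(sum(v^2))
    }
  })
  gram <- crossprod(V) - diag(K)
  if (max(abs(gram)) > 1e-10)
    stop("map orthogonalization failed (max |inner| = ", max(abs(gram)), ")")
  V
}

#' Correlated orthogonal modulation-profile pairs
#'
#' Constructs two n x D profile sets with centered, mutually orthogonal
#' columns within each set, `corr(A1_d, A2_d) = rho_d` exactly and all
#' cross-index correlations exactly zero (Gram-Schmidt construction:
#' `A2_d = rho_d A1_d + sqrt(1 - rho_d^2) E_d` with the `E_d` orthonormal and
#' orthogonal to every `A1` column). Columns are scaled to unit variance.
#' When group labels are given, the first profile carries a standardized mean
#' difference of `group_effect` between the groups (attenuated by `rho_1` in
#' the second modality).
#'
#' @param n number of subjects; must exceed `2 * length(rho) + 1`.
#' @param rho vector of target correlations in `[0, 1]`.
#' @param group_labels optional factor/vector with two levels, length `n`.
#' @param group_effect standardized mean difference on the first profile pair
#'   (used only with `group_labels`; default 1.5).
#' @param seed integer seed.
#' @return List with `A1`, `A2` (n x D, unit-variance centered columns) and
#'   `group_labels`.
#' @export
make_profile_pair <- function(n, rho, group_labels = NULL, group_effect = 1.5,
                              seed = NULL) {
  D <- length(rho)
  if (n <= 2L * D + 1L) stop("need n > 2 * D + 1 for the orthogonalization")
  if (any(rho < 0) || any(rho > 1)) stop("rho must lie in [0, 1]")
  raw <- with_seed(seed, matrix(rnorm(n * 2L * D), n, 2L * D))
  if (!is.null(group_labels)) {
    group_labels <- as.factor(group_labels)
    if (nlevels(group_labels) != 2L || length(group_labels) != n)
      stop("group_labels must have two levels and length n")
    g <- ifelse(group_labels == levels(group_labels)[2L], 1, -1)
    raw[, 1L] <- raw[, 1L] + group_effect / 2 * g
  }
  raw <- sweep(raw, 2L, colMeans(raw))
  qrd <- qr(raw)
  if (qrd$rank < 2L * D) stop("degenerate draw: columns not independent")
  Q <- qr.Q(qrd)
  Q <- sweep(Q, 2L, sign(diag(qr.R(qrd))), "*")  # align with Gram-Schmidt
  A1 <- Q[, seq_len(D), drop = FALSE]
  E <- Q[, D + seq_len(D), drop = FALSE]
  A2 <- sweep(A1, 2L, rho, "*") + sweep(E, 2L, sqrt(1 - rho^2), "*")
  scale <- sqrt(n - 1)   # unit-norm centered columns -> unit variance
  list(A1 = A1 * scale, A2 = A2 * scale, group_labels = group_labels)
}

#' Add white Gaussian noise calibrated to an exact PSNR
#'
#' Draws a Gaussian noise field and rescales it after the draw so the realized
#' PSNR between clean and noisy data equals `psnr_db` exactly (to floating
#' point), under `PSNR = 10 log10(maxval^2 / MSE)` with `maxval` the maximum
#' of the clean data.
#'
#' @param X_clean numeric matrix/array, non-constant.
#' @param psnr_db target PSNR in dB; `Inf` returns a clean copy.
#' @param seed integer seed for the noise draw.
#' @param maxval peak value used in the PSNR definition (default
#'   `max(X_clean)`).
#' @return Noisy data with attribute `"realized_psnr"`.
#' @export
add_noise_to_psnr <- function(X_clean, psnr_db, seed = NULL,
                              maxval = max(X_clean)) {
  if (is.infinite(psnr_db)) {
    out <- X_clean
    attr(out, "realized_psnr") <- Inf
    return(out)
  }
  if (!is.finite(psnr_db)) stop("psnr_db must be finite or +Inf")
  if (max(X_clean) == min(X_clean)) stop("X_clean is constant")
  if (maxval <= 0) stop("maxval must be positive")
  target_mse <- maxval^2 * 10^(-psnr_db / 10)
  E <- with_seed(seed, array(rnorm(length(X_clean)), dim = dim(X_clean)))
  E <- E * sqrt(target_mse / mean(E^2))
  out <- X_clean + E
  attr(out, "realized_psnr") <- psnr(X_clean, out, maxval = maxval)
  out
}

# Banded 1-D smoothing matrix: truncated discrete Gaussian, normalized to unit
# sum (interior), zero-padding at the boundary.
smooth_kernel_matrix <- function(d, sigma_vox) {
  r <- min(max(1L, ceiling(4 * sigma_vox)), d - 1L)
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- max(1L, i - r):min(d, i + r)
    K[i, j] <- w[j - i + r + 1L]
  }
  K
}

#' Gaussian spatial smoothing of stacked images
#'
#' Per-subject separable 3-D Gaussian filtering with
#' `sigma = FWHM / (2 sqrt(2 ln 2))` converted to voxels, constant-zero
#' boundary handling. Rows of `X` are flattened volumes in column-major order
#' (first axis fastest).
#'
#' @param X n x m matrix of flattened images (or a single m-vector).
#' @param dims integer 3-vector with `prod(dims) == m`.
#' @param fwhm_mm kernel FWHM in mm; `<= 0` returns `X` with a warning.
#' @param voxel_mm voxel size in mm (scalar or 3-vector, default 2).
#' @return Smoothed data, same shape as `X`.
#' @export
smooth_images <- function(X, dims, fwhm_mm = 8, voxel_mm = 2) {
  vec_in <- is.null(dim(X))
  X <- rbind(as.matrix(X))
  if (vec_in) X <- matrix(X, nrow = 1L)
  dims <- as.integer(dims)
  m <- prod(dims)
  if (ncol(X) != m) stop("ncol(X) must equal prod(dims)")
  if (fwhm_mm <= 0) {
    warning("non-positive FWHM: returning input unchanged")
    return(if (vec_in) X[1L, ] else X)
  }
  voxel_mm <- rep(voxel_mm, length.out = 3L)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
  n <- nrow(X)
  A <- array(t(X), c(dims, n))
  # axis 1
  K1 <- smooth_kernel_matrix(dims[1L], sigma_vox[1L])
  A <- array(K1 %*% matrix(A, dims[1L]), c(dims, n))
  # axis 2
  K2 <- smooth_kernel_matrix(dims[2L], sigma_vox[2L])
  P <- aperm(A, c(2L, 1L, 3L, 4L))
  P <- array(K2 %*% matrix(P, dims[2L]), dim(P))
  A <- aperm(P, c(2L, 1L, 3L, 4L))
  # axis 3
  if (dims[3L] > 1L) {
    K3 <- smooth_kernel_matrix(dims[3L], sigma_vox[3L])
    P <- aperm(A, c(3L, 1L, 2L, 4L))
    P <- array(K3 %*% matrix(P, dims[3L]), dim(P))
    A <- aperm(P, c(2L, 3L, 1L, 4L))
  }
  out <- t(matrix(A, m, n))
  if (vec_in) out[1L, ] else out
}

# Orthonormal centered score columns scaled to the requested sds.
make_scores <- function(n, weights, seed = NULL) {
  K <- length(weights)
  raw <- with_seed(seed, matrix(rnorm(n * K), n, K))
  raw <- sweep(raw, 2L, colMeans(raw))
  qrd <- qr(raw)
  Q <- sweep(qr.Q(qrd), 2L, sign(diag(qr.R(qrd))), "*")
  sweep(Q, 2L, weights * sqrt(n - 1), "*")
}

# Gaussian noise at an exact PSNR: white by default, optionally FWHM-smoothed
# before the calibration (spatially correlated noise). Either way the field is
# rescaled after the draw so the realized PSNR of clean vs clean+noise hits
# the target exactly. The signal is never smoothed: that would destroy the
# sparse ground truth the study is about.
sim_noise_to_psnr <- function(X_clean, psnr_db, dims, fwhm_mm, voxel_mm,
                              noise_type = "white", seed = NULL) {
  if (is.infinite(psnr_db)) return(array(0, dim = dim(X_clean)))
  maxval <- max(X_clean)
  if (maxval <= 0) stop("clean data must have a positive peak")
  E <- with_seed(seed, matrix(rnorm(length(X_clean)), nrow(X_clean)))
  if (noise_type == "smoothed" && fwhm_mm > 0)
    E <- smooth_images(E, dims, fwhm_mm, voxel_mm)
  target_mse <- maxval^2 * 10^(-psnr_db / 10)
  E * sqrt(target_mse / mean(E^2))
}

#' Generate one replicate of the single-modality simulation
#'
#' `X = Y V' + noise`: intrinsic scores `Y` (orthogonal columns with sds given
#' by `spec$weights`) times orthogonal sparse maps `V` (smooth contiguous
#' blobs, i.e. spatially correlated signal), plus Gaussian noise rescaled
#' after the draw so the realized PSNR between clean and noisy data equals the
#' target exactly (white by default; FWHM-smoothed first when
#' `spec$noise_type = "smoothed"`). All replicates of a spec share the same
#' `(Y, V)` and differ only in the noise realization.
#'
#' @param spec a [sim1_spec()].
#' @param replicate replicate index (seeds the noise field).
#' @param keep_intermediate keep the clean matrix (default TRUE; disable
#'   inside replicate loops to save memory).
#' @return Object of class `sim_dataset`: `X` ([feature_matrix()] with mask
#'   geometry), `Y_true` (n x K), `V_true` (m x K), `rho_true = NULL`,
#'   `group_labels = NULL`, `realized_psnr`, `X_clean` (optional) and `meta`.
#' @export
generate_sim1 <- function(spec, replicate = 1L, keep_intermediate = TRUE) {
  stopifnot(inherits(spec, "sim1_spec"))
  Y <- make_scores(spec$n, spec$weights, seed = derive_seed(spec$seed, 0L))
  V <- make_sparse_maps(spec$dims, spec$K, spec$sparsity,
                        seed = derive_seed(spec$seed, 1L),
                        n_blobs = spec$n_blobs)
  X_clean <- tcrossprod(Y, V)
  noise_seed <- derive_seed(spec$seed, 1000L + as.integer(replicate))
  X <- X_clean + sim_noise_to_psnr(X_clean, spec$psnr_db, spec$dims,
                                   spec$fwhm_mm, spec$voxel_mm,
                                   noise_type = spec$noise_type,
                                   seed = noise_seed)
  realized <- if (is.infinite(spec$psnr_db)) Inf else psnr(X_clean, X)
  geom <- mask_geometry(spec$dims, rep(spec$voxel_mm, 3L))
  out <- list(X = feature_matrix(X, modality = "sim1", geometry = geom),
              Y_true = Y, V_true = V, rho_true = NULL, group_labels = NULL,
              realized_psnr = realized,
              meta = list(spec = spec, replicate = as.integer(replicate),
                          noise_seed = noise_seed))
  if (keep_intermediate) out$X_clean <- X_clean
  structure(out, class = "sim_dataset")
}

#' Generate one replicate of the two-modality fusion simulation
#'
#' Each modality is built as `X_r = A_r diag(w) V_r' + noise` with spatially
#' correlated PSNR-calibrated noise as in [generate_sim1()]: shared correlated
#' modulation profiles (exact canonical correlations `spec$rho`, exact
#' orthogonality structure, group-distinct first pair) times independent
#' sparse orthogonal map sets. Replicates share profiles and maps and differ
#' only in the noise realizations.
#'
#' @param spec a [sim2_spec()].
#' @inheritParams generate_sim1
#' @return List of class `sim2_dataset` with elements `mod1`, `mod2` (each a
#'   `sim_dataset` whose ground truth holds `A_true` in `Y_true`), `rho_true`,
#'   `group_labels` and `meta`.
#' @export
generate_sim2 <- function(spec, replicate = 1L, keep_intermediate = TRUE) {
  stopifnot(inherits(spec, "sim2_spec"))
  n <- 2L * spec$n_per_group
  group <- factor(rep(c("G1", "G2"), each = spec$n_per_group))
  prof <- make_profile_pair(n, spec$rho, group_labels = group,
                            group_effect = spec$group_effect,
                            seed = derive_seed(spec$seed, 2L))
  geom <- mask_geometry(spec$dims, rep(spec$voxel_mm, 3L))
  build <- function(A, map_seed_idx, noise_seed_idx, label) {
    V <- make_sparse_maps(spec$dims, spec$K, spec$sparsity,
                          seed = derive_seed(spec$seed, map_seed_idx),
                          n_blobs = spec$n_blobs)
    X_clean <- tcrossprod(sweep(A, 2L, spec$weights, "*"), V)
    noise_seed <- derive_seed(spec$seed,
                              noise_seed_idx + 2L * as.integer(replicate))
    X <- X_clean + sim_noise_to_psnr(X_clean, spec$psnr_db, spec$dims,
                                     spec$fwhm_mm, spec$voxel_mm,
                                     noise_type = spec$noise_type,
                                     seed = noise_seed)
    realized <- if (is.infinite(spec$psnr_db)) Inf else psnr(X_clean, X)
    out <- list(X = feature_matrix(X, modality = label, geometry = geom),
                Y_true = A, V_true = V, rho_true = spec$rho,
                group_labels = group, realized_psnr = realized,
                meta = list(spec = spec, replicate = as.integer(replicate),
                            noise_seed = noise_seed))
    if (keep_intermediate) out$X_clean <- X_clean
    structure(out, class = "sim_dataset")
  }
  structure(list(mod1 = build(prof$A1, 3L, 2000L, "mod1"),
                 mod2 = build(prof$A2, 4L, 2001L, "mod2"),
                 rho_true = spec$rho, group_labels = group,
                 meta = list(spec = spec, replicate = as.integer(replicate))),
            class = "sim2_dataset")
}
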