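perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Match estimated components to ground truth
#'
#' Optimal one-to-one assignment of estimated columns to true columns
#' maximizing the summed absolute Pearson correlation (estimated component
#' order and sign are arbitrary, so index-blind matching is required before
#' any similarity is computed). Several correlation tables can be summed when
#' components must be matched jointly (e.g. profile pairs across two
#' modalities).
#'
#' @param cor_tables list of D x D matrices of absolute correlations
#'   (true components in rows, estimated in columns), summed before matching.
#' @return List with `perm` (estimated column matched to each true column),
#'   and `score` (summed matched correlation).
#' @export
match_components <- function(cor_tables) {
  if (!is.list(cor_tables)) cor_tables <- list(cor_tables)
  S <- Reduce(`+`, lapply(cor_tables, as.matrix))
  D <- nrow(S)
  if (ncol(S) != D) stop("matching requires equal component counts")
  if (D > 7L) {  # enumeration infeasible; greedy fallback
    perm <- integer(D); avail <- seq_len(D)
    for (d in order(apply(S, 1L, max), decreasing = TRUE)) {
      j <- avail[which.max(S[d, avail])]
      perm[d] <- j
      avail <- setdiff(avail, j)
    }
    return(list(perm = perm, score = sum(S[cbind(seq_len(D), perm)])))
  }
  best <- NULL; best_score <- -Inf
  for (p in perm_list(seq_len(D))) {
    sc <- sum(S[cbind(seq_len(D), p)])
    if (sc > best_score) {
      best_score <- sc
      best <- p
    }
  }
  list(perm = best, score = best_score)
}

#' Similarity between true and estimated component sets
#'
#' Mean over components of the absolute Pearson correlation between matched
#' true and estimated columns; 1 means perfect recovery up to sign and order.
#' Matching uses the optimal assignment of [match_components()] unless a
#' permutation is supplied.
#'
#' @param true_set,est_set matrices with one component per column and equal
#'   column counts (scores: n x D; maps: m x D).
#' @param perm optional pre-computed matching (estimated column index for each
#'   true column).
#' @return Object of class `similarity_report`: `mean` (the similarity value
#'   in `[0, 1]`), `per_component` (matched absolute correlations), `perm`,
#'   `signs` (sign of each matched correlation).
#' @export
similarity <- function(true_set, est_set, perm = NULL) {
  true_set <- as.matrix(true_set); est_set <- as.matrix(est_set)
  if (ncol(true_set) != ncol(est_set))
    stop("equal component counts required")
  if (any(apply(true_set, 2L, sd) == 0) || any(apply(est_set, 2L, sd) == 0))
    stop("constant column: correlation undefined")
  ctab <- abs(cor(true_set, est_set))
  if (is.null(perm)) perm <- match_components(ctab)$perm
  idx <- cbind(seq_len(ncol(true_set)), perm)
  signs <- sign(cor(true_set, est_set)[idx])
  structure(list(mean = mean(ctab[idx]), per_component = ctab[idx],
                 perm = perm, signs = signs),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("similarity: ", sprintf("%.4f", x$mean), " (per component: ",
      paste(sprintf("%.4f", x$per_component), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Canonical-correlation error
#'
#' `delta_rho = sum_d (rho_true_d - rho_est_d)`: positive values mean the
#' canonical correlations are, overall, underestimated; negative values mean
#' overestimation.
#'
#' @param rho_true,rho_est equal-length vectors of canonical correlations.
#' @return Object of class `correlation_error` with `delta_rho`, `rho_true`,
#'   `rho_est`.
#' @export
correlation_error <- function(rho_true, rho_est) {
  if (length(rho_true) != length(rho_est)) stop("length mismatch")
  structure(list(delta_rho = sum(rho_true - rho_est),
                 rho_true = rho_true, rho_est = rho_est),
            class = "correlation_error")
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation with tied scores averaged: the
#' probability that a randomly chosen positive scores above a randomly chosen
#' negative. The raw (orientation-dependent) value is returned; the
#' orientation-free value `max(auc, 1 - auc)` is attached as attribute
#' `"oriented"`.
#'
#' @param score numeric vector.
#' @param labels two-level vector; the second factor level (or the larger of
#'   two unique values) is the positive class. Both classes must be present.
#' @return AUC in `[0, 1]` with attribute `"oriented"`.
#' @export
roc_auc <- function(score, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (length(score) != length(labels)) stop("length mismatch")
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, oriented = max(auc, 1 - auc))
}

#' Welch two-sample t-test with Bonferroni correction
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' two-sided p value (via [stats::t.test()]), plus a Bonferroni-adjusted p
#' for `n_comparisons` tests (e.g. the number of canonical pairs examined).
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param n_comparisons Bonferroni correction factor (default 1).
#' @return Object of class `group_stats`: `t`, `df`, `p`, `p_corr`.
#' @export
welch_ttest <- function(x, y, n_comparisons = 1L) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    t_stat <- if (eq) 0 else sign(mean(x) - mean(y)) * Inf
    p <- if (eq) 1 else 0
    df <- length(x) + length(y) - 2L
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(t = t_stat, df = df, p = p,
                 p_corr = min(1, p * n_comparisons)),
            class = "group_stats")
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(maxval^2 / MSE)` in dB, with `maxval` the maximum of the
#' clean data by default and `MSE` the mean squared difference. The variant
#' dividing `maxval` by the MSE itself (rather than the RMSE) is available via
#' `mse_denom = TRUE`.
#'
#' @param clean,noisy equal-shape numeric data; `clean` non-constant.
#' @param maxval peak value (default `max(clean)`).
#' @param mse_denom use `20 log10(maxval / MSE)` instead of the standard form.
#' @return PSNR in dB; `Inf` for identical inputs.
#' @export
psnr <- function(clean, noisy, maxval = max(clean), mse_denom = FALSE) {
  if (!identical(dim(clean), dim(noisy)) || length(clean) != length(noisy))
    stop("clean and noisy must have the same shape")
  if (max(clean) == min(clean)) stop("clean data are constant")
  mse <- mean((clean - noisy)^2)
  if (mse == 0) return(Inf)
  if (mse_denom) 20 * log10(maxval / mse) else 10 * log10(maxval^2 / mse)
}

#' Benchmark sPCA against PCA on the single-modality simulation
#'
#' Runs the requested methods on `n_replicates` fresh noise realizations of a
#' [sim1_spec()] world and scores each fit by the similarity of its scores and
#' loadings to the generating ground truth. The sparsity parameter for sPCA
#' defaults to the oracle value `max_d ||v_d^true||_1`, isolating the effect
#' of the sparsity constraint at matched (true) sparsity.
#'
#' @param spec a [sim1_spec()].
#' @param n_replicates number of replicates (default `spec$n_replicates`).
#' @param methods subset of `c("spca", "pca")`.
#' @param c sparsity parameter for sPCA; `NULL` for the oracle default.
#' @param tol,max_iter convergence controls for the sPCA fits.
#' @return List with `results` (one row per replicate x method: `S_Y`, `S_V`,
#'   achieved sparsity) and `summary` (means by method).
#' @export
run_sim1_benchmark <- function(spec, n_replicates = spec$n_replicates,
                               methods = c("spca", "pca"), c = NULL,
                               tol = 1e-6, max_iter = 200L) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    gen <- generate_sim1(spec, replicate = r, keep_intermediate = FALSE)
    if (is.null(c) && "spca" %in% methods)
      c <- max(colSums(abs(gen$V_true)))
    for (method in methods) {
      model <- if (method == "spca") {
        suppressWarnings(spca(gen$X, K = spec$K, c = c, tol = tol,
                              max_iter = max_iter))
      } else {
        pca_fit(gen$X, K = spec$K)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = method,
        S_Y = similarity(gen$Y_true, scores(model))$mean,
        S_V = similarity(gen$V_true, model$V)$mean,
        sparsity = mean(model$achieved_sparsity))
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate(cbind(S_Y, S_V, sparsity) ~ method, data = results,
                       FUN = mean)
  list(results = results, summary = summary)
}

# Metrics for one fitted fusion result against sim2 ground truth.
sim2_metrics <- function(fus, gen) {
  D <- fus$D
  perm <- match_components(list(abs(cor(gen$mod1$Y_true, fus$A1)),
                                abs(cor(gen$mod2$Y_true, fus$A2))))$perm
  s_a1 <- similarity(gen$mod1$Y_true, fus$A1, perm = perm)
  s_a2 <- similarity(gen$mod2$Y_true, fus$A2, perm = perm)
  s_c1 <- similarity(gen$mod1$V_true, t(fus$C1), perm = perm)
  s_c2 <- similarity(gen$mod2$V_true, t(fus$C2), perm = perm)
  grp <- gen$group_labels
  auc1 <- attr(roc_auc(fus$A1[, perm[1L]], grp), "oriented")
  auc2 <- attr(roc_auc(fus$A2[, perm[1L]], grp), "oriented")
  p1 <- welch_ttest(fus$A1[grp == levels(grp)[1L], perm[1L]],
                    fus$A1[grp == levels(grp)[2L], perm[1L]],
                    n_comparisons = D)$p_corr
  p2 <- welch_ttest(fus$A2[grp == levels(grp)[1L], perm[1L]],
                    fus$A2[grp == levels(grp)[2L], perm[1L]],
                    n_comparisons = D)$p_corr
  data.frame(delta_rho = correlation_error(gen$rho_true, fus$rho)$delta_rho,
             S_A = mean(c(s_a1$per_component, s_a2$per_component)),
             S_C = mean(c(s_c1$per_component, s_c2$per_component)),
             AUC = mean(c(auc1, auc2)),
             p_corr_1 = p1, p_corr_2 = p2,
             rho_1 = fus$rho[1L], rho_2 = fus$rho[min(2L, D)],
             rho_3 = fus$rho[min(3L, D)])
}

#' Benchmark fusion methods on the two-modality simulation
#'
#' Runs sPCA+CCA and/or the PCA+CCA baseline on `n_replicates` fresh noise
#' realizations of a [sim2_spec()] world and reports, per replicate and
#' averaged: the canonical-correlation error `delta_rho`, the profile and map
#' similarities `S_A`/`S_C` (matched jointly across modalities), the group
#' AUC of the profile matched to the group-distinct pair (mean of the two
#' modalities, orientation-free) and Bonferroni-corrected Welch p values.
#'
#' For sPCA the sparsity parameter is selected per replicate and per modality
#' by split-sample cross-validation with `K` fixed (the default), or can be
#' supplied as a number.
#'
#' @param spec a [sim2_spec()].
#' @param n_replicates number of replicates (default `spec$n_replicates`).
#' @param methods subset of `c("spca", "pca")`.
#' @param spca_c `"cv"` (default) or a numeric sparsity parameter used for
#'   both modalities.
#' @param c_grid CV grid for `spca_c = "cv"`; by default a [sparsity_grid()]
#'   (levels 0.9/0.8/0.7/0.5 plus dense) is computed once per modality on the
#'   first replicate and reused, since all replicates share the same spatial
#'   maps and the grid is kept small because the CV sits inside the replicate
#'   loop.
#' @param n_folds CV folds (default 10).
#' @param cv_tol convergence tolerance for the CV-internal fits (default
#'   `1e-4`).
#' @param tol,max_iter convergence controls for the final fits.
#' @param verbose print per-replicate progress.
#' @return List with `results` (one row per replicate x method), `summary`
#'   (means by method) and `n_failed` (replicates excluded by errors).
#' @export
run_sim2_benchmark <- function(spec, n_replicates = spec$n_replicates,
                               methods = c("spca", "pca"), spca_c = "cv",
                               c_grid = NULL, n_folds = 10L, cv_tol = 1e-4,
                               tol = 1e-6, max_iter = 200L, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  grids <- if (is.null(c_grid)) NULL else list(c_grid, c_grid)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    res_r <- tryCatch({
      gen <- generate_sim2(spec, replicate = r, keep_intermediate = FALSE)
      if (is.null(grids) && "spca" %in% methods && !is.numeric(spca_c))
        grids <- list(sparsity_grid(gen$mod1$X, tol = cv_tol),
                      sparsity_grid(gen$mod2$X, tol = cv_tol))
      out <- list()
      for (method in methods) {
        if (method == "spca") {
          cc <- if (is.numeric(spca_c)) rep(spca_c, 2L) else suppressWarnings(c(
            cv_select(gen$mod1$X, c_grid = grids[[1L]], K_grid = spec$K,
                      n_folds = n_folds, tol = cv_tol,
                      seed = derive_seed(spec$seed, 5000L + 2L * r))$c_star,
            cv_select(gen$mod2$X, c_grid = grids[[2L]], K_grid = spec$K,
                      n_folds = n_folds, tol = cv_tol,
                      seed = derive_seed(spec$seed, 5001L + 2L * r))$c_star))
          fus <- fuse(gen$mod1$X, gen$mod2$X, K1 = spec$K, K2 = spec$K,
                      c1 = cc[1L], c2 = cc[2L], method = "spca",
                      tol = tol, max_iter = max_iter)
        } else {
          fus <- fuse(gen$mod1$X, gen$mod2$X, K1 = spec$K, K2 = spec$K,
                      method = "pca")
        }
        out[[method]] <- cbind(data.frame(replicate = r, method = method),
                               sim2_metrics(fus, gen))
      }
      do.call(rbind, out)
    }, error = function(e) {
      warning("replicate ", r, " excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(res_r)) n_failed <- n_failed + 1L else
      rows[[length(rows) + 1L]] <- res_r
    if (verbose) message("replicate ", r, "/", n_replicates, " done")
  }
  if (length(rows) == 0L) stop("all replicates failed")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- aggregate(cbind(delta_rho, S_A, S_C, AUC) ~ method,
                       data = results, FUN = mean)
  list(results = results, summary = summary, n_failed = n_failed)
}
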