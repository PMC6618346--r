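#' Load a feature matrix from a delimited file
#'
#' Reads a TSV/CSV table whose first column holds sample identifiers and whose
#' remaining columns are numeric features (one row per subject). An optional
#' JSON sidecar (same path with extension `.json`) restores mask geometry
#' written by [write_feature_matrix()].
#'
#' @param path delimited file as written by [write_feature_matrix()].
#' @param modality optional modality label attached to the result.
#' @return A [feature_matrix()].
#' @export
load_feature_matrix <- function(path, modality = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 3L) stop("expected sample-id column plus >= 2 features")
  ids <- as.character(dt[[1L]])
  X <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    bad <- ids[rowSums(!is.finite(X)) > 0L]
    stop("non-finite values for subjects: ", paste(head(bad, 10L), collapse = ", "))
  }
  geometry <- NULL
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$dims))
      geometry <- mask_geometry(meta$dims, meta$voxel_mm, meta$included)
    if (is.null(modality) && !is.null(meta$modality)) modality <- meta$modality
  }
  feature_matrix(X, sample_ids = ids, modality = modality, geometry = geometry)
}

#' Write a feature matrix to a delimited file
#'
#' Writes a TSV with the sample identifiers in the first column; mask geometry
#' and the modality label, when present, go to a JSON sidecar so that
#' [load_feature_matrix()] round-trips the object.
#'
#' @param X a [feature_matrix()] or numeric matrix.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  ids <- fm_ids(X)
  M <- fm_data(X)
  dt <- data.table::data.table(sample_id = ids)
  dt <- cbind(dt, data.table::as.data.table(M))
  data.table::fwrite(dt, path, sep = "\t")
  if (inherits(X, "feature_matrix") &&
      (!is.null(X$geometry) || !is.null(X$modality))) {
    meta <- list(modality = X$modality)
    if (!is.null(X$geometry))
      meta <- c(meta, list(dims = X$geometry$dims,
                           voxel_mm = X$geometry$voxel_mm,
                           included = X$geometry$included))
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Regress covariates out of every feature
#'
#' Per-feature least-squares residualization on an intercept plus the supplied
#' covariates (numeric columns used as-is, character/factor columns
#' dummy-coded with first-level reference), the usual correction for nuisance
#' effects such as age, gender and handedness before fusion analysis.
#'
#' @param X a [feature_matrix()] or numeric matrix (subjects x features).
#' @param covariates data.frame with one row per subject, aligned to `X` by a
#'   `sample_id` column when present, otherwise by row order.
#' @return Residualized object of the same class as `X`.
#' @export
residualize <- function(X, covariates) {
  M <- fm_data(X)
  ids <- fm_ids(X)
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    idx <- match(ids, as.character(covariates$sample_id))
    if (anyNA(idx)) stop("covariates missing for subjects: ",
                         paste(head(ids[is.na(idx)], 10L), collapse = ", "))
    covariates <- covariates[idx, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  }
  if (nrow(covariates) != nrow(M))
    stop("covariate table must have one row per subject")
  Z <- stats::model.matrix(~ ., data = covariates)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):ncol(Z)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  R <- M - qr.fitted(qrz, M)
  if (inherits(X, "feature_matrix")) {
    feature_matrix(R, sample_ids = ids, modality = X$modality,
                   geometry = X$geometry)
  } else R
}

#' Write spatial maps as delimited volumes
#'
#' Each map (row of `C`) is un-flattened into the mask grid (zeros outside the
#' mask) and written as a long-format TSV with voxel coordinates; a JSON
#' manifest records dimensions and voxel size. [read_maps()] inverts the
#' operation.
#'
#' @param C numeric matrix, D maps x m in-mask features.
#' @param geometry a [mask_geometry()] matching `ncol(C)`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"map"`.
#' @return Character vector of files written, invisibly.
#' @export
write_maps <- function(C, geometry, dir, prefix = "map") {
  C <- rbind(as.matrix(C))
  stopifnot(inherits(geometry, "mask_geometry"),
            ncol(C) == length(geometry$included))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- arrayInd(geometry$included, geometry$dims)
  files <- character(nrow(C))
  for (d in seq_len(nrow(C))) {
    dt <- data.table::data.table(x = coords[, 1L], y = coords[, 2L],
                                 z = coords[, 3L], value = C[d, ])
    files[d] <- file.path(dir, sprintf("%s_%02d.tsv", prefix, d))
    data.table::fwrite(dt, files[d], sep = "\t")
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(dims = geometry$dims,
                            voxel_mm = geometry$voxel_mm,
                            included = geometry$included,
                            n_maps = nrow(C), prefix = prefix),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(files, manifest))
}

#' Read spatial maps written by [write_maps()]
#'
#' @param dir directory holding the map TSVs and manifest.
#' @param prefix file-name prefix used at write time.
#' @return List with `C` (D x m matrix of in-mask values) and `geometry`.
#' @export
read_maps <- function(dir, prefix = "map") {
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  geometry <- mask_geometry(meta$dims, meta$voxel_mm, meta$included)
  C <- matrix(0, meta$n_maps, length(geometry$included))
  for (d in seq_len(meta$n_maps)) {
    dt <- data.table::fread(file.path(dir, sprintf("%s_%02d.tsv", prefix, d)))
    flat <- (dt$z - 1L) * meta$dims[1L] * meta$dims[2L] +
      (dt$y - 1L) * meta$dims[1L] + dt$x
    if (!identical(as.integer(flat), geometry$included))
      stop("map voxel order does not match manifest mask")
    C[d, ] <- dt$value
  }
  list(C = C, geometry = geometry)
}
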