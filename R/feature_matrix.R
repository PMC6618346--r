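#' Subjects-by-features matrix with sample metadata
#'
#' A `feature_matrix` is a numeric matrix (rows = subjects, columns = voxels or
#' other features) carrying sample identifiers, an optional modality label and
#' an optional [mask_geometry()] describing how columns map back into a 3-D
#' volume. All model-fitting functions in the package accept either a plain
#' matrix or a `feature_matrix`.
#'
#' @param data numeric matrix, n subjects x m features; all entries finite.
#' @param sample_ids character vector of length n; defaults to rownames or
#'   `"S1".."Sn"`.
#' @param modality optional single string naming the modality.
#' @param geometry optional [mask_geometry()] with as many included voxels as
#'   `ncol(data)`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(data, sample_ids = NULL, modality = NULL,
                           geometry = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("feature_matrix requires at least 2 subjects and 2 features")
  if (!all(is.finite(data))) {
    bad <- which(rowSums(!is.finite(data)) > 0L)
    stop("non-finite values in rows: ", paste(head(bad, 10L), collapse = ", "))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(data)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(data)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(data))
    stop("sample_ids length must equal nrow(data)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "mask_geometry"))
    if (length(geometry$included) != ncol(data))
      stop("geometry voxel count (", length(geometry$included),
           ") does not match ncol(data) (", ncol(data), ")")
  }
  rownames(data) <- sample_ids
  structure(list(data = data, sample_ids = sample_ids,
                 modality = modality, geometry = geometry),
            class = "feature_matrix")
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$data

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$data), " subjects x ", ncol(x$data),
      " features", if (!is.null(x$modality)) paste0(" [", x$modality, "]"),
      "\n", sep = "")
  invisible(x)
}

# Internal: accept a feature_matrix or a plain numeric matrix.
fm_data <- function(X) {
  if (inherits(X, "feature_matrix")) return(X$data)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix or feature_matrix")
  X
}

fm_ids <- function(X) {
  if (inherits(X, "feature_matrix")) return(X$sample_ids)
  rn <- rownames(X)
  if (is.null(rn)) paste0("S", seq_len(nrow(X))) else rn
}

#' Mask geometry for mapping features to volume coordinates
#'
#' Describes a 3-D grid and the ordered set of in-mask voxels backing the
#' columns of a [feature_matrix()]. Voxels are flattened in column-major order
#' (first spatial axis fastest), the native array order of R.
#'
#' @param dims integer 3-vector of grid dimensions.
#' @param voxel_mm numeric 3-vector of voxel sizes in mm (default 2 mm
#'   isotropic, the MNI 2-mm grid convention).
#' @param mask logical/0-1 array of dimension `dims`, or a strictly increasing
#'   integer vector of included flat voxel indices. Default: all voxels.
#' @return An object of class `mask_geometry`.
#' @export
mask_geometry <- function(dims, voxel_mm = c(2, 2, 2), mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), length(voxel_mm) == 3L,
            all(voxel_mm > 0))
  m_total <- prod(dims)
  if (is.null(mask)) {
    included <- seq_len(m_total)
  } else if (is.array(mask) || is.logical(mask)) {
    if (length(mask) != m_total) stop("mask size does not match dims")
    included <- which(as.logical(mask) != FALSE)
  } else {
    included <- as.integer(mask)
    if (is.unsorted(included, strictly = TRUE))
      stop("included voxel indices must be strictly increasing")
    if (any(included < 1L) || any(included > m_total))
      stop("voxel indices out of range")
  }
  if (length(included) == 0L) stop("mask includes zero voxels")
  structure(list(dims = dims, voxel_mm = as.numeric(voxel_mm),
                 included = as.integer(included)),
            class = "mask_geometry")
}

#' Un-flatten one feature vector into its 3-D volume
#'
#' Inverse of the masking step of [load_feature_matrix()]: values are placed at
#' the in-mask voxel positions (column-major order, first axis fastest), zeros
#' elsewhere.
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param geometry a [mask_geometry()].
#' @return 3-D array of dimension `geometry$dims`.
#' @export
features_to_volume <- function(values, geometry) {
  stopifnot(inherits(geometry, "mask_geometry"),
            length(values) == length(geometry$included))
  vol <- array(0, dim = geometry$dims)
  vol[geometry$included] <- values
  vol
}

#' Flatten a 3-D volume to the in-mask feature vector
#'
#' @inheritParams features_to_volume
#' @param volume 3-D array of dimension `geometry$dims`.
#' @return numeric vector of in-mask values, in mask order.
#' @export
volume_to_features <- function(volume, geometry) {
  stopifnot(inherits(geometry, "mask_geometry"))
  if (!identical(as.integer(dim(volume)), geometry$dims))
    stop("volume dimensions do not match geometry")
  as.vector(volume)[geometry$included]
}
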