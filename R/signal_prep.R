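#' Drop initial volumes from a 4D image
#'
#' Scanner signal needs several TRs to reach steady state, so the first
#' volumes of a resting-state acquisition are discarded before analysis.
#'
#' @param image4d 4D numeric array (x, y, z, time), optionally carrying an
#'   `affine` attribute.
#' @param n_discard Number of leading volumes to drop.
#' @return The trailing `T - n_discard` volumes, order preserved, affine kept.
#' @export
discard_initial_volumes <- function(image4d, n_discard) {
  stopifnot(length(dim(image4d)) == 4)
  n_vol <- dim(image4d)[4]
  if (n_discard < 0 || n_discard >= n_vol)
    stop("`n_discard` must be in [0, ", n_vol - 1, "]", call. = FALSE)
  if (n_discard == 0) return(image4d)
  out <- image4d[, , , (n_discard + 1):n_vol, drop = FALSE]
  attr(out, "affine") <- attr(image4d, "affine")
  out
}

# world-coordinate centers of all voxels of a grid under a NIfTI affine
# (voxel indices are 0-based in world-coordinate computations)
voxel_world_coords <- function(affine, grid_shape) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1L,
                               j = seq_len(grid_shape[2]) - 1L,
                               k = seq_len(grid_shape[3]) - 1L))
  xyz <- ijk %*% t(affine[1:3, 1:3])
  sweep(xyz, 2, affine[1:3, 4], "+")
}

#' Spherical region-of-interest mask
#'
#' Marks every voxel whose world-coordinate center lies within
#' `radius_mm` of `center_mm` (Euclidean distance, inclusive).
#'
#' @param center_mm MNI coordinates (x, y, z) of the sphere center, in mm.
#' @param radius_mm Sphere radius in mm.
#' @param affine 4x4 voxel-to-world affine.
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @return Logical 3D array of `grid_shape`.
#' @export
sphere_mask <- function(center_mm, radius_mm, affine, grid_shape) {
  if (radius_mm <= 0) stop("`radius_mm` must be > 0", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is not invertible", call. = FALSE)
  xyz <- voxel_world_coords(affine, grid_shape)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  mask <- array(d2 <= radius_mm^2, dim = grid_shape)
  if (!any(mask))
    stop("sphere at (", paste(center_mm, collapse = ", "),
         ") mm contains no voxel of the grid", call. = FALSE)
  mask
}

#' Tissue mask from a probability image
#'
#' Thresholds a tissue-probability map with a strict inequality, so a voxel
#' exactly at the threshold is excluded. A high threshold (default 0.99)
#' keeps gray-matter voxels out of white-matter and CSF nuisance masks.
#'
#' @param probability_image 3D array of probabilities in \[0, 1\].
#' @param threshold Exclusive lower bound (mask is `p > threshold`).
#' @return Logical array of the same shape.
#' @export
tissue_mask <- function(probability_image, threshold = 0.99) {
  p <- probability_image
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mask <- array(p > threshold, dim = dim(p))
  if (!any(mask)) {
    warning("tissue mask is empty at threshold ", threshold, call. = FALSE)
    stop("empty tissue mask", call. = FALSE)
  }
  mask
}

#' Discrete-cosine high-pass drift basis
#'
#' Builds the drift regressors of an implicit high-pass filter with cutoff
#' period `cutoff_seconds`: the K = floor(2 n TR / cutoff + 1) lowest-order
#' discrete cosine functions, excluding the constant, each unit-norm. With
#' these columns in a GLM, ordinary least squares projects out fluctuations
#' slower than the cutoff.
#'
#' @param n_scans Number of scans.
#' @param tr_seconds Repetition time in seconds.
#' @param cutoff_seconds High-pass cutoff period in seconds (default 100,
#'   i.e. 1/100 Hz).
#' @return `n_scans` x (K-1) matrix with orthonormal columns (possibly 0
#'   columns).
#' @export
dct_highpass_basis <- function(n_scans, tr_seconds, cutoff_seconds = 100) {
  if (cutoff_seconds <= 2 * tr_seconds)
    stop("`cutoff_seconds` must exceed 2 * TR", call. = FALSE)
  K <- floor(2 * n_scans * tr_seconds / cutoff_seconds + 1)
  if (K <= 1) return(matrix(0, n_scans, 0))
  dct_basis(n_scans, K)[, -1, drop = FALSE]
}

#' Bundle nuisance regressors for a subject
#'
#' @param wm,csf [bold_series()] nuisance summaries (first eigenvariates of
#'   the white-matter and CSF compartments), or NULL.
#' @param motion `n_scans` x 6 matrix of rigid-body motion parameters
#'   (translations in mm, rotations in rad), or NULL.
#' @param dct_drift Drift matrix from [dct_highpass_basis()], or NULL.
#' @return Object of class `confound_set`.
#' @export
confound_set <- function(wm = NULL, csf = NULL, motion = NULL,
                         dct_drift = NULL) {
  n <- NULL
  take_n <- function(m) if (is.null(n)) nrow(m) else n
  blocks <- list()
  labels <- character()
  for (nm in c("wm", "csf")) {
    s <- get(nm)
    if (!is.null(s)) {
      stopifnot(inherits(s, "bold_series"))
      m <- matrix(s$values, ncol = 1)
      n <- take_n(m)
      blocks[[nm]] <- m
      labels <- c(labels, nm)
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6)
      stop("`motion` must have exactly 6 columns", call. = FALSE)
    n <- take_n(motion)
    blocks[["motion"]] <- motion
    labels <- c(labels, paste0("motion", 1:6))
  }
  if (!is.null(dct_drift)) {
    dct_drift <- as.matrix(dct_drift)
    if (ncol(dct_drift) > 1) {
      G <- crossprod(dct_drift)
      if (max(abs(G - diag(diag(G)))) > 1e-8)
        stop("`dct_drift` columns must be mutually orthogonal", call. = FALSE)
    }
    n <- take_n(dct_drift)
    blocks[["drift"]] <- dct_drift
    if (ncol(dct_drift) > 0)
      labels <- c(labels, paste0("drift", seq_len(ncol(dct_drift))))
  }
  if (length(blocks) > 0) {
    rows <- vapply(blocks, nrow, integer(1))
    if (length(unique(rows)) != 1)
      stop("confound blocks have differing numbers of rows", call. = FALSE)
  }
  structure(list(blocks = blocks, labels = labels, n_scans = n),
            class = "confound_set")
}

#' @export
as.matrix.confound_set <- function(x, ...) {
  if (length(x$blocks) == 0) return(NULL)
  m <- do.call(cbind, x$blocks)
  colnames(m) <- x$labels
  m
}

# residualize columns of Y against [intercept | confounds]
remove_confounds <- function(Y, confounds = NULL) {
  Y <- as.matrix(Y)
  X <- cbind(intercept = rep(1, nrow(Y)))
  if (inherits(confounds, "confound_set")) confounds <- as.matrix(confounds)
  if (!is.null(confounds)) X <- cbind(X, confounds)
  qr.resid(qr(X), Y)
}

#' First eigenvariate of a region's time series
#'
#' Residualises every in-mask voxel time series against an intercept plus the
#' supplied confounds, then summarises the region by the first left singular
#' vector of the time-by-voxel residual matrix. The sign is fixed by positive
#' correlation with the in-mask mean series (ties broken toward a positive
#' first element) and the output is scaled to unit variance.
#'
#' @param image4d 4D array (x, y, z, time).
#' @param mask Logical 3D mask with at least one voxel.
#' @param confounds A [confound_set()] or confound matrix, or NULL.
#' @param tr_seconds TR of the output series.
#' @param label Optional label for the output series.
#' @return A [bold_series()] of unit variance.
#' @export
extract_eigenvariate <- function(image4d, mask, confounds = NULL,
                                 tr_seconds, label = NULL) {
  stopifnot(length(dim(image4d)) == 4)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  n_vol <- dim(image4d)[4]
  Y <- matrix(image4d, ncol = n_vol)[as.vector(mask), , drop = FALSE]
  Y <- t(Y)                                   # time x voxels
  R <- remove_confounds(Y, confounds)
  if (max(abs(R)) < 1e-12)
    stop("degenerate signal: all in-mask residuals are zero", call. = FALSE)
  sv <- svd(R, nu = 1, nv = 0)
  u <- sv$u[, 1]
  m <- rowMeans(R)
  s <- sum(u * m)
  if (abs(s) < 1e-12) s <- if (u[1] >= 0) 1 else -1
  u <- u * sign(s)
  u <- u / stats::sd(u)
  bold_series(u, tr_seconds, label = label)
}
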