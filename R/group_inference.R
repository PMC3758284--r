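#' Group-level one-sample t map
#'
#' Treats each subject's contrast map as one observation per voxel and tests
#' the mean against zero: t = mean / (sd / sqrt(n)), dof = n - 1. Voxels with
#' zero between-subject variance are masked (NA).
#'
#' @param con_maps `n_subjects` x V matrix of subject contrast values.
#' @param grid_shape Integer 3-vector giving the spatial grid; `prod` must
#'   equal V.
#' @param affine 4x4 voxel-to-world affine (for peak coordinates).
#' @param mask Optional logical analysis mask (3D or length-V); defaults to
#'   all voxels.
#' @return Object of class `group_map` with `t_values`, `dof`, `n_subjects`,
#'   `grid_shape`, `affine`, `mask`.
#' @export
one_sample_t <- function(con_maps, grid_shape, affine = diag(4),
                         mask = NULL) {
  con_maps <- as.matrix(con_maps)
  n <- nrow(con_maps)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (prod(grid_shape) != ncol(con_maps))
    stop("`grid_shape` does not match the number of voxels", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, ncol(con_maps))
  mask <- as.vector(mask)
  m <- unname(colMeans(con_maps))
  s <- sqrt(unname(colSums(sweep(con_maps, 2, m)^2)) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- NA_real_
  t[!mask] <- NA_real_
  structure(list(t_values = t, dof = n - 1, n_subjects = n,
                 grid_shape = as.integer(grid_shape), affine = affine,
                 mask = mask),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat("<group_map> ", prod(x$grid_shape), " voxels (",
      paste(x$grid_shape, collapse = "x"), "), n = ", x$n_subjects,
      ", dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

# neighbor offsets for 6 (faces), 18 (faces+edges), 26 (full) connectivity
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  off[keep, , drop = FALSE]
}

# label connected components of a logical 3D array; returns an integer array
# (0 = background), labels ordered by first (smallest linear index) voxel.
# Vectorised min-label propagation: every in-mask voxel starts with its own
# linear index and repeatedly adopts the smallest label among its in-mask
# neighbours until a fixed point.
label_components <- function(mask, connectivity = 18) {
  dims <- dim(mask)
  off <- connectivity_offsets(connectivity)
  out <- array(0L, dims)
  if (!any(mask)) return(out)
  lab <- array(NA_integer_, dims)
  lab[mask] <- which(mask)
  src <- function(d, s) if (s >= 0) 1:(d - s) else (1 - s):d
  dst <- function(d, s) if (s >= 0) (1 + s):d else 1:(d + s)
  repeat {
    prev <- lab
    for (r in seq_len(nrow(off))) {
      s <- off[r, ]
      shifted <- lab[src(dims[1], s[1]), src(dims[2], s[2]),
                     src(dims[3], s[3]), drop = FALSE]
      i1 <- dst(dims[1], s[1]); i2 <- dst(dims[2], s[2])
      i3 <- dst(dims[3], s[3])
      cur <- lab[i1, i2, i3, drop = FALSE]
      upd <- !is.na(cur) & !is.na(shifted) & shifted < cur
      if (any(upd)) {
        cur[upd] <- shifted[upd]
        lab[i1, i2, i3] <- cur
      }
    }
    if (identical(lab, prev)) break
  }
  roots <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], roots)
  out
}

#' Form suprathreshold clusters on a group t map
#'
#' Voxels whose one-sided p-value for the requested sign falls below
#' `height_p` are labeled into connected components.
#'
#' @param group A [one_sample_t()] result.
#' @param height_p One-sided height threshold on p (default 0.001).
#' @param sign `"positive"` or `"negative"` contrast direction.
#' @param connectivity 6, 18 (default) or 26.
#' @return Tibble with one row per cluster: `label_id`, `voxel_count`,
#'   `peak_t` (signed), `peak_x`, `peak_y`, `peak_z` (MNI mm), `sign`, and a
#'   list-column `voxels` of linear indices. Attributes `t_threshold` and
#'   `label_array` are attached.
#' @export
form_clusters <- function(group, height_p = 0.001,
                          sign = c("positive", "negative"),
                          connectivity = 18) {
  stopifnot(inherits(group, "group_map"))
  sign <- match.arg(sign)
  if (height_p <= 0 || height_p >= 1)
    stop("`height_p` must be in (0, 1)", call. = FALSE)
  t_u <- stats::qt(1 - height_p, df = group$dof)
  t <- group$t_values
  supra <- if (sign == "positive") !is.na(t) & t > t_u else !is.na(t) & t < -t_u
  supra_arr <- array(supra, dim = group$grid_shape)
  labels <- label_components(supra_arr, connectivity)
  n_cl <- max(labels)
  if (n_cl == 0) {
    out <- tibble::tibble(label_id = integer(), voxel_count = integer(),
                          peak_t = numeric(), peak_x = numeric(),
                          peak_y = numeric(), peak_z = numeric(),
                          sign = character(), voxels = list())
  } else {
    vox_by_cl <- split(which(labels > 0), labels[labels > 0])
    peaks <- vapply(vox_by_cl, function(vox)
      vox[which.max(abs(t[vox]))], numeric(1))   # first tie = smallest index
    ijk <- arrayInd(as.integer(peaks), group$grid_shape) - 1L
    mm <- cbind(ijk, 1) %*% t(group$affine[1:3, ])
    out <- tibble::tibble(label_id = seq_len(n_cl),
                          voxel_count = unname(lengths(vox_by_cl)),
                          peak_t = unname(t[peaks]),
                          peak_x = mm[, 1], peak_y = mm[, 2],
                          peak_z = mm[, 3],
                          sign = sign, voxels = unname(vox_by_cl))
  }
  attr(out, "t_threshold") <- t_u
  attr(out, "label_array") <- labels
  attr(out, "height_p") <- height_p
  out
}

#' Estimate field smoothness from residual maps
#'
#' Standardises each residual map within the mask and estimates, per axis,
#' the variance of the spatial first difference; for a Gaussian-autocorrelated
#' field of unit variance that variance is 4 log 2 / FWHM^2. Resels are the
#' mask volume divided by the product of FWHMs (in voxels).
#'
#' @param residual_maps List of 3D arrays, or V x n_maps matrix with
#'   `grid_shape` supplied.
#' @param mask Logical 3D analysis mask (default: all voxels).
#' @param grid_shape Required when `residual_maps` is a matrix.
#' @return List with `fwhm_voxels` (length 3), `resels`, `n_voxels`.
#' @export
estimate_smoothness <- function(residual_maps, mask = NULL,
                                grid_shape = NULL) {
  if (is.matrix(residual_maps)) {
    stopifnot(!is.null(grid_shape))
    if (nrow(residual_maps) != prod(grid_shape))
      stop("residual matrix must be voxels x maps with prod(grid_shape) rows",
           call. = FALSE)
    residual_maps <- lapply(seq_len(ncol(residual_maps)), function(j)
      array(residual_maps[, j], dim = grid_shape))
  }
  if (length(residual_maps) < 2)
    stop("need at least 2 residual maps", call. = FALSE)
  dims <- dim(residual_maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, dims)
  grad_var <- matrix(NA_real_, length(residual_maps), 3)
  for (m in seq_along(residual_maps)) {
    r <- residual_maps[[m]]
    v <- r[mask]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12)
      stop("degenerate smoothness: a residual map is flat", call. = FALSE)
    r <- (r - mean(v)) / s
    d1 <- r[-1, , , drop = FALSE] - r[-dims[1], , , drop = FALSE]
    d2 <- r[, -1, , drop = FALSE] - r[, -dims[2], , drop = FALSE]
    d3 <- r[, , -1, drop = FALSE] - r[, , -dims[3], drop = FALSE]
    m1 <- mask[-1, , , drop = FALSE] & mask[-dims[1], , , drop = FALSE]
    m2 <- mask[, -1, , drop = FALSE] & mask[, -dims[2], , drop = FALSE]
    m3 <- mask[, , -1, drop = FALSE] & mask[, , -dims[3], drop = FALSE]
    grad_var[m, ] <- c(mean(d1[m1]^2), mean(d2[m2]^2), mean(d3[m3]^2))
  }
  gv <- colMeans(grad_var)
  if (any(gv < 1e-12))
    stop("degenerate smoothness: zero spatial gradient variance",
         call. = FALSE)
  fwhm <- sqrt(4 * log(2) / gv)
  n_vox <- sum(mask)
  list(fwhm_voxels = fwhm, resels = n_vox / prod(fwhm), n_voxels = n_vox)
}

#' Random-field-theory cluster p-values
#'
#' Under the Gaussian-field approximation at height threshold u (the standard
#' normal quantile matching the height p-value), the expected number of
#' clusters is E\[m\] = R (4 log 2)^(3/2) (2 pi)^(-2) (u^2 - 1) exp(-u^2 / 2)
#' with R the resel count, and cluster extent has the exponential-form tail
#' P(N >= k) = exp(-beta k^(2/3)). The uncorrected cluster p-value is that
#' tail probability (this is what topological FDR corrects); the set-level
#' family-wise combination 1 - exp(-E\[m\] P(N >= k)) is returned alongside.
#'
#' @param cluster_sizes Integer vector of cluster extents in voxels.
#' @param resels Resel count of the analysis mask.
#' @param height_p One-sided height threshold as a p-value.
#' @param n_voxels Number of voxels in the analysis mask.
#' @return Tibble with `voxel_count`, `p_uncorrected`, `p_fwe`,
#'   `expected_clusters`.
#' @export
rft_cluster_p <- function(cluster_sizes, resels, height_p, n_voxels) {
  if (!is.numeric(resels) || resels <= 0)
    stop("`resels` must be a positive number", call. = FALSE)
  if (any(cluster_sizes <= 0))
    stop("cluster sizes must be positive", call. = FALSE)
  u <- stats::qnorm(1 - height_p)
  if (u <= 1)
    stop("height threshold too lenient for the Gaussian-field cluster ",
         "approximation (need qnorm(1 - height_p) > 1)", call. = FALSE)
  e_m <- resels * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) *
    (u^2 - 1) * exp(-u^2 / 2)
  e_n <- n_voxels * stats::pnorm(u, lower.tail = FALSE)   # voxels above u
  beta <- (gamma(5 / 2) * e_m / e_n)^(2 / 3)
  p_unc <- exp(-beta * cluster_sizes^(2 / 3))
  tibble::tibble(voxel_count = cluster_sizes,
                 p_uncorrected = p_unc,
                 p_fwe = 1 - exp(-e_m * p_unc),
                 expected_clusters = e_m)
}

#' Sign-flip permutation cluster p-values
#'
#' Builds the null distribution of the maximum suprathreshold cluster extent
#' by randomly negating subjects' contrast maps (valid when the no-effect
#' distribution is symmetric about zero), and assigns each observed cluster
#' p = (1 + #\{perm max >= k\}) / (1 + n_permutations).
#'
#' @param con_maps `n_subjects` x V matrix of subject contrast values.
#' @param grid_shape Spatial grid dimensions.
#' @param height_p Height threshold (one-sided p).
#' @param n_permutations Number of sign-flip permutations (>= 100).
#' @param seed RNG seed for reproducibility.
#' @param sign Contrast direction for cluster forming.
#' @param connectivity 6, 18 or 26.
#' @param affine Voxel-to-world affine.
#' @return The observed cluster tibble from [form_clusters()] with an added
#'   `p_uncorrected` column (permutation p of each cluster's extent against
#'   the max-cluster null); attribute `null_max_sizes` holds the null draws.
#' @export
permutation_cluster_p <- function(con_maps, grid_shape, height_p = 0.001,
                                  n_permutations = 1000, seed = 1,
                                  sign = c("positive", "negative"),
                                  connectivity = 18, affine = diag(4)) {
  sign <- match.arg(sign)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is only 1/",
            n_permutations + 1, call. = FALSE)
  con_maps <- as.matrix(con_maps)
  n <- nrow(con_maps)
  group <- one_sample_t(con_maps, grid_shape, affine = affine)
  observed <- form_clusters(group, height_p, sign, connectivity)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  # fast sign-flip null: sums of squares are flip-invariant, so only the
  # mean changes per permutation
  ss <- colSums(con_maps^2)
  t_u <- stats::qt(1 - height_p, df = n - 1)
  null_max <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    m <- drop(crossprod(flips, con_maps)) / n
    s2 <- (ss - n * m^2) / (n - 1)
    tt <- m / sqrt(s2 / n)
    supra <- if (sign == "positive") !is.na(tt) & s2 > 0 & tt > t_u
      else !is.na(tt) & s2 > 0 & tt < -t_u
    lab <- label_components(array(supra, grid_shape), connectivity)
    null_max[b] <- if (max(lab) > 0) max(tabulate(lab[lab > 0L])) else 0
  }
  p <- vapply(observed$voxel_count, function(k)
    (1 + sum(null_max >= k)) / (1 + n_permutations), numeric(1))
  observed$p_uncorrected <- p
  attr(observed, "null_max_sizes") <- null_max
  observed
}

#' Topological (cluster-level) FDR correction
#'
#' Benjamini–Hochberg adjustment applied to the cluster-level uncorrected
#' p-values of the suprathreshold clusters, per contrast sign; a cluster
#' survives when its adjusted p is at most `q`.
#'
#' @param clusters Tibble with columns `p_uncorrected` and `sign`.
#' @param q FDR level (default 0.05).
#' @return The tibble with added `p_fdr` and logical `survives` columns.
#' @export
topological_fdr <- function(clusters, q = 0.05) {
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  if (nrow(clusters) == 0) {
    clusters$p_fdr <- numeric()
    clusters$survives <- logical()
    return(clusters)
  }
  clusters <- dplyr::group_by(clusters, .data$sign)
  clusters <- dplyr::mutate(clusters,
                            p_fdr = stats::p.adjust(.data$p_uncorrected,
                                                    method = "BH"))
  clusters <- dplyr::ungroup(clusters)
  clusters$survives <- clusters$p_fdr <= q
  clusters
}

#' Publication-style cluster table
#'
#' One row per cluster, sorted by descending absolute peak t within sign
#' (positive block first); clusters of negative modulation carry negative
#' peak t values.
#'
#' @param clusters Cluster tibble with `p_fdr` (from [topological_fdr()]).
#' @param group The [one_sample_t()] map the clusters came from (unused
#'   values, kept for provenance; may be NULL).
#' @return Tibble with columns `sign`, `p_fdr`, `voxels`, `peak_t`,
#'   `peak_x`, `peak_y`, `peak_z`.
#' @export
cluster_table <- function(clusters, group = NULL) {
  if (nrow(clusters) == 0)
    return(tibble::tibble(sign = character(), p_fdr = numeric(),
                          voxels = integer(), peak_t = numeric(),
                          peak_x = numeric(), peak_y = numeric(),
                          peak_z = numeric()))
  out <- tibble::tibble(sign = clusters$sign,
                        p_fdr = clusters$p_fdr,
                        voxels = clusters$voxel_count,
                        peak_t = clusters$peak_t,
                        peak_x = clusters$peak_x,
                        peak_y = clusters$peak_y,
                        peak_z = clusters$peak_z)
  dplyr::arrange(out, dplyr::desc(.data$sign == "positive"),
                 dplyr::desc(abs(.data$peak_t)))
}
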