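# shared fixtures built in code

default_kernel <- function() canonical_hrf(2, 16, 32)

# smooth band-limited series on the microtime grid of `kernel`
smooth_microtime_signal <- function(n_scans, kernel, bandwidth_hz = 0.06,
                                    seed = 1) {
  set.seed(seed)
  bins <- kernel$params$microtime_bins_per_tr
  restppi:::bandlimited_process(n_scans * bins, kernel$dt_seconds,
                                bandwidth_hz)
}

# white-noise ROI series with the standard scan count
noise_bold <- function(n = 228, tr = 2, seed = 1, label = NULL) {
  set.seed(seed)
  bold_series(rnorm(n), tr, label = label)
}

# full confound set with random motion and the default drift basis
random_confounds <- function(n = 228, tr = 2, seed = 2) {
  set.seed(seed)
  confound_set(
    wm = bold_series(rnorm(n), tr, "wm"),
    csf = bold_series(rnorm(n), tr, "csf"),
    motion = apply(matrix(rnorm(n * 6, sd = 0.02), n, 6), 2, cumsum),
    dct_drift = dct_highpass_basis(n, tr, 100))
}

# periodic Gaussian-smoothed standardized null field
smooth_null_field <- function(grid, fwhm) {
  f <- array(rnorm(prod(grid)), grid)
  f <- array(restppi:::smooth_noise(matrix(f, 1), grid, fwhm), grid)
  (f - mean(f)) / sd(f)
}

# fast small simulation for pipeline tests
small_sim_config <- function(n_subjects = 4, n_volumes_acquired = 110, ...) {
  simulation_config(n_subjects = n_subjects,
                    n_volumes_acquired = n_volumes_acquired,
                    grid_shape = c(16, 16, 16),
                    roi1_center_mm = c(-10.5, 10.5, 1.5),
                    roi2_center_mm = c(10.5, 10.5, 1.5),
                    target_center_mm = c(1.5, -10.5, 1.5),
                    roi_radius_mm = 6,
                    ...)
}

# does any surviving positive cluster overlap the target mask?
target_detected <- function(cohort, sign = "positive") {
  tgt <- which(as.vector(cohort$target_mask))
  cl <- cohort$group$clusters
  cl <- cl[cl$survives & cl$sign == sign, , drop = FALSE]
  any(vapply(cl$voxels, function(v) length(intersect(v, tgt)) > 0,
             logical(1)))
}

# voxel indices within `dilate` voxels (Chebyshev) of a mask
dilate_mask <- function(mask, dilate) {
  g <- dim(mask)
  idx <- which(mask)
  co <- arrayInd(idx, g)
  out <- array(FALSE, g)
  rng <- -dilate:dilate
  for (dx in rng) for (dy in rng) for (dz in rng) {
    sh <- cbind(pmin(pmax(co[, 1] + dx, 1), g[1]),
                pmin(pmax(co[, 2] + dy, 1), g[2]),
                pmin(pmax(co[, 3] + dz, 1), g[3]))
    out[sh] <- TRUE
  }
  out
}
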