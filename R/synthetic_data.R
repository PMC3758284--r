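#' Configuration of a synthetic resting-state cohort
#'
#' Describes a multi-subject synthetic dataset with a known modulatory
#' interaction: two seed regions carry band-limited neuronal signals x1 and
#' x2, and a target region carries beta1 x1 + beta2 x2 + beta3 x1 x2 at the
#' neuronal level, all passed through the canonical HRF. Every voxel receives
#' a slow cosine drift and AR(1) measurement noise; white-matter and CSF
#' slabs carry shared nuisance signals and probability maps above 0.99.
#'
#' Defaults mirror a typical 3 T resting-state acquisition: 230 volumes at
#' TR 2 s (two discarded by the pipeline), 3 mm isotropic voxels, 8 mm seed
#' spheres, target temporal SNR 1 (signal sd / noise sd at the target).
#'
#' @param n_subjects Number of subjects (default 20).
#' @param n_volumes_acquired Acquired volumes per subject (default 230).
#' @param n_discard Leading volumes the pipeline will discard (default 2).
#' @param tr_seconds Repetition time (default 2).
#' @param grid_shape Grid dimensions (default 24 x 24 x 24).
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param roi1_center_mm,roi2_center_mm,target_center_mm Sphere centers (MNI
#'   mm).
#' @param roi_radius_mm Sphere radius (default 8).
#' @param true_beta1,true_beta2,true_beta3 Neuronal-level coupling weights
#'   (defaults 1, 1, 0.5).
#' @param beta3_sd Between-subject SD of the interaction weight (default 0.1).
#' @param neuronal_bandwidth_hz Band limit of the neuronal processes
#'   (default 0.1 Hz).
#' @param noise_sigma Marginal SD of the AR(1) measurement noise (default 1,
#'   giving target tSNR 1).
#' @param ar1_coefficient AR(1) coefficient of the noise (default 0.3).
#' @param smooth_fwhm_voxels Spatial FWHM (in voxels) of the Gaussian
#'   correlation of the measurement noise (default 2), emulating the spatial
#'   smoothness that preprocessing smoothing induces in real data — the
#'   structure random-field cluster inference assumes. 0 gives spatially
#'   white noise.
#' @param drift_amplitude,drift_period_s Cosine drift parameters (defaults
#'   1 and 128 s, slow enough that a 1/100 Hz high-pass must remove it).
#' @param microtime_bins_per_tr Microtime bins per TR (default 16).
#' @param seed Master seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 20,
                              n_volumes_acquired = 230,
                              n_discard = 2,
                              tr_seconds = 2,
                              grid_shape = c(24, 24, 24),
                              voxel_mm = 3,
                              roi1_center_mm = c(-16.5, 16.5, 1.5),
                              roi2_center_mm = c(16.5, 16.5, 1.5),
                              target_center_mm = c(1.5, -16.5, 1.5),
                              roi_radius_mm = 8,
                              true_beta1 = 1, true_beta2 = 1,
                              true_beta3 = 0.5,
                              beta3_sd = 0.1,
                              neuronal_bandwidth_hz = 0.1,
                              noise_sigma = 1,
                              ar1_coefficient = 0.3,
                              smooth_fwhm_voxels = 2,
                              drift_amplitude = 1,
                              drift_period_s = 128,
                              microtime_bins_per_tr = 16,
                              seed = 1) {
  if (n_volumes_acquired <= n_discard)
    stop("`n_volumes_acquired` must exceed `n_discard`", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (abs(ar1_coefficient) >= 1)
    stop("|ar1_coefficient| must be < 1", call. = FALSE)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  centers <- rbind(roi1_center_mm, roi2_center_mm, target_center_mm)
  extent <- voxel_mm * (grid_shape - 1) / 2
  if (any(abs(centers) + roi_radius_mm > rep(extent, each = 3)))
    stop("a sphere extends beyond the grid", call. = FALSE)
  dists <- stats::dist(centers)
  if (any(dists < 2 * roi_radius_mm))
    stop("configuration error: ROI/target spheres overlap", call. = FALSE)
  nyquist <- microtime_bins_per_tr / (2 * tr_seconds)
  if (neuronal_bandwidth_hz >= nyquist)
    stop("`neuronal_bandwidth_hz` must be below the microtime Nyquist ",
         "frequency (", nyquist, " Hz)", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_volumes_acquired = n_volumes_acquired,
                 n_discard = n_discard, tr_seconds = tr_seconds,
                 grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 affine = affine,
                 roi1_center_mm = roi1_center_mm,
                 roi2_center_mm = roi2_center_mm,
                 target_center_mm = target_center_mm,
                 roi_radius_mm = roi_radius_mm,
                 true_beta1 = true_beta1, true_beta2 = true_beta2,
                 true_beta3 = true_beta3, beta3_sd = beta3_sd,
                 neuronal_bandwidth_hz = neuronal_bandwidth_hz,
                 noise_sigma = noise_sigma,
                 ar1_coefficient = ar1_coefficient,
                 smooth_fwhm_voxels = smooth_fwhm_voxels,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 microtime_bins_per_tr = microtime_bins_per_tr,
                 seed = seed),
            class = "simulation_config")
}

# band-limited unit-variance Gaussian process via Fourier truncation
bandlimited_process <- function(n, dt, bandwidth_hz) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freq <- c(0, seq_len(n - 1)) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq)          # fold to two-sided
  f[freq > bandwidth_hz] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  y <- y - mean(y)
  y / stats::sd(y)
}

#' Simulate a pair of independent neuronal time series
#'
#' Two independent band-limited Gaussian processes of unit variance on the
#' microtime grid.
#'
#' @param n_points Number of samples.
#' @param dt Sampling step in seconds.
#' @param bandwidth_hz Band limit (must be below Nyquist, 1 / (2 dt)).
#' @param seed RNG seed; NULL draws from the current stream.
#' @return List of two [neuronal_series()].
#' @export
simulate_neuronal_pair <- function(n_points, dt, bandwidth_hz, seed = NULL) {
  if (bandwidth_hz >= 1 / (2 * dt))
    stop("`bandwidth_hz` must be below the Nyquist frequency ", 1 / (2 * dt),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x1 <- bandlimited_process(n_points, dt, bandwidth_hz)
  x2 <- bandlimited_process(n_points, dt, bandwidth_hz)
  list(neuronal_series(x1, dt), neuronal_series(x2, dt))
}

# AR(1) noise matrix (n x V) with marginal SD sigma
ar1_noise <- function(n, V, sigma, phi) {
  if (sigma == 0) return(matrix(0, n, V))
  e <- matrix(stats::rnorm(n * V, sd = sigma * sqrt(1 - phi^2)), n, V)
  if (phi != 0)
    for (t in 2:n) e[t, ] <- e[t, ] + phi * e[t - 1, ]
  e
}

# smooth each volume of an n x V noise matrix with a periodic 3D Gaussian
# (FFT), then rescale to restore the original marginal SD
smooth_noise <- function(E, g, fwhm) {
  if (fwhm <= 0) return(E)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ax <- lapply(g, function(d) {
    x <- c(0:(d %/% 2), -((d - d %/% 2 - 1):1))
    exp(-x^2 / (2 * sigma^2))
  })
  kern <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  kern <- kern / sum(kern)
  G <- stats::fft(kern)
  V <- prod(g)
  sd0 <- stats::sd(E)
  for (t in seq_len(nrow(E))) {
    vol <- array(E[t, ], dim = g)
    E[t, ] <- Re(stats::fft(stats::fft(vol) * G, inverse = TRUE)) / V
  }
  if (sd0 > 0) E <- E * (sd0 / stats::sd(E))
  E
}

# x-axis slab masks for the WM and CSF compartments (clear of all spheres
# under the default geometry)
compartment_masks <- function(config) {
  g <- config$grid_shape
  wm <- array(FALSE, g); wm[1:2, , ] <- TRUE
  csf <- array(FALSE, g); csf[(g[1] - 1):g[1], , ] <- TRUE
  list(wm = wm, csf = csf)
}

#' Simulate one subject's dataset
#'
#' @param config A [simulation_config()].
#' @param subject_seed Seed for this subject's random draws.
#' @param beta3 Subject-specific interaction weight (default: the config's
#'   `true_beta3`).
#' @return Object of class `subject_dataset`: `image4d` (x, y, z, time array
#'   with an `affine` attribute, all acquired volumes included),
#'   `motion_params` (T x 6), `wm_prob`, `csf_prob`, `ground_truth` (3D array
#'   of the planted beta3), `tsnr_target`, `seed_used`.
#' @export
simulate_subject <- function(config, subject_seed, beta3 = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(beta3)) beta3 <- config$true_beta3
  set.seed(subject_seed)
  g <- config$grid_shape
  V <- prod(g)
  Tn <- config$n_volumes_acquired
  bins <- config$microtime_bins_per_tr
  dt <- config$tr_seconds / bins
  n_micro <- Tn * bins
  kernel <- canonical_hrf(config$tr_seconds, bins)

  pair <- simulate_neuronal_pair(n_micro, dt, config$neuronal_bandwidth_hz)
  x1 <- pair[[1]]$values
  x2 <- pair[[2]]$values
  inter <- x1 * x2
  inter <- inter - mean(inter)

  to_scan <- function(v) {
    s <- convolve_to_bold(neuronal_series(v, dt), kernel, Tn,
                          config$tr_seconds)$values
    s / stats::sd(s)
  }
  c1 <- to_scan(x1)
  c2 <- to_scan(x2)
  ci <- to_scan(inter)
  b <- c(config$true_beta1, config$true_beta2, beta3)
  target_sig <- (b[1] * c1 + b[2] * c2 + b[3] * ci) / sqrt(sum(b^2))

  roi1_mask <- sphere_mask(config$roi1_center_mm, config$roi_radius_mm,
                           config$affine, g)
  roi2_mask <- sphere_mask(config$roi2_center_mm, config$roi_radius_mm,
                           config$affine, g)
  target_mask <- sphere_mask(config$target_center_mm, config$roi_radius_mm,
                             config$affine, g)
  comp <- compartment_masks(config)

  Y <- ar1_noise(Tn, V, config$noise_sigma, config$ar1_coefficient)
  if (config$noise_sigma > 0)
    Y <- smooth_noise(Y, g, config$smooth_fwhm_voxels)
  t_sec <- (seq_len(Tn) - 1) * config$tr_seconds
  drift <- config$drift_amplitude *
    cos(2 * pi * t_sec / config$drift_period_s + stats::runif(1, 0, 2 * pi))
  Y <- Y + drift + 100
  add_signal <- function(Y, mask, sig) {
    idx <- which(as.vector(mask))
    Y[, idx] <- Y[, idx] + sig
    Y
  }
  Y <- add_signal(Y, roi1_mask, c1)
  Y <- add_signal(Y, roi2_mask, c2)
  Y <- add_signal(Y, target_mask, target_sig)
  nw <- bandlimited_process(Tn, config$tr_seconds, 0.05)
  nc <- bandlimited_process(Tn, config$tr_seconds, 0.05)
  Y <- add_signal(Y, comp$wm, nw)
  Y <- add_signal(Y, comp$csf, nc)

  image4d <- array(t(Y), dim = c(g, Tn))
  attr(image4d, "affine") <- config$affine

  motion <- cbind(
    apply(matrix(stats::rnorm(Tn * 3, sd = 0.02), Tn, 3), 2, cumsum),
    apply(matrix(stats::rnorm(Tn * 3, sd = 5e-4), Tn, 3), 2, cumsum))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  wm_prob <- array(0.3, g); wm_prob[comp$wm] <- 0.995
  csf_prob <- array(0.3, g); csf_prob[comp$csf] <- 0.995
  gt <- array(0, g); gt[target_mask] <- beta3

  structure(list(image4d = image4d, motion_params = motion,
                 wm_prob = wm_prob, csf_prob = csf_prob,
                 ground_truth = gt, seed_used = subject_seed,
                 beta = b,
                 tsnr_target = if (config$noise_sigma > 0)
                   1 / config$noise_sigma else Inf,
                 config = config),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  d <- dim(x$image4d)
  cat("<subject_dataset> ", paste(d[1:3], collapse = "x"), " grid, ",
      d[4], " volumes, seed ", x$seed_used, ", beta = (",
      paste(signif(x$beta, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-subject seeds and interaction weights for a cohort
#'
#' Seeds are drawn deterministically from the master seed; each subject's
#' interaction weight is the population value plus Gaussian between-subject
#' variation.
#'
#' @param config A [simulation_config()].
#' @return Tibble with `subject`, `seed`, `beta3`.
#' @export
group_manifest <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  seeds <- sample.int(2^31 - 2, n)
  beta3 <- config$true_beta3 + stats::rnorm(n, sd = config$beta3_sd)
  tibble::tibble(subject = sprintf("sub-%02d", seq_len(n)),
                 seed = seeds, beta3 = beta3)
}

#' Simulate a multi-subject cohort
#'
#' @param config A [simulation_config()] with `n_subjects >= 2`.
#' @param dir Optional output directory; when given, each subject's 4D image
#'   (`sub-XX/func.nii.gz`), motion parameters (`sub-XX/motion.txt`), the
#'   tissue probability maps and a JSON manifest are written there and file
#'   paths are returned instead of in-memory datasets.
#' @return List with `manifest` (tibble) and either `subjects` (list of
#'   [simulate_subject()] results) or `paths`.
#' @export
simulate_group <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_subjects < 2) stop("need n_subjects >= 2", call. = FALSE)
  manifest <- group_manifest(config)
  if (is.null(dir)) {
    subjects <- Map(function(s, b3) simulate_subject(config, s, beta3 = b3),
                    manifest$seed, manifest$beta3)
    names(subjects) <- manifest$subject
    return(list(manifest = manifest, subjects = subjects))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tissue"), showWarnings = FALSE)
  paths <- character(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    ds <- simulate_subject(config, manifest$seed[i],
                           beta3 = manifest$beta3[i])
    sdir <- file.path(dir, manifest$subject[i])
    dir.create(sdir, showWarnings = FALSE)
    write_volume(ds$image4d, file.path(sdir, "func.nii.gz"))
    utils::write.table(ds$motion_params, file.path(sdir, "motion.txt"),
                       row.names = FALSE, col.names = FALSE)
    if (i == 1) {
      write_volume(structure(ds$wm_prob, affine = config$affine),
                   file.path(dir, "tissue", "wm.nii.gz"))
      write_volume(structure(ds$csf_prob, affine = config$affine),
                   file.path(dir, "tissue", "csf.nii.gz"))
    }
    paths[i] <- sdir
  }
  cfg <- unclass(config)
  cfg$affine <- NULL
  jsonlite::write_json(
    list(config = cfg,
         subjects = manifest,
         tsnr_target = if (config$noise_sigma > 0)
           1 / config$noise_sigma else Inf),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, paths = paths)
}
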