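test_that("neuronal pair generation is reproducible, unit-variance, independent",
{
  n <- 230 * 16; dt <- 2 / 16
  p1 <- simulate_neuronal_pair(n, dt, 0.1, seed = 99)
  p2 <- simulate_neuronal_pair(n, dt, 0.1, seed = 99)
  expect_identical(p1[[1]]$values, p2[[1]]$values)
  expect_identical(p1[[2]]$values, p2[[2]]$values)
  for (s in p1) {
    expect_gt(var(s$values), 0.8)
    expect_lt(var(s$values), 1.2)
  }
  expect_lt(abs(cor(p1[[1]]$values, p1[[2]]$values)), 0.15)
  expect_error(simulate_neuronal_pair(n, dt, 10, seed = 1), "Nyquist")
})

test_that("simulation config validates its geometry and noise model", {
  expect_error(simulation_config(n_volumes_acquired = 2, n_discard = 2),
               "exceed")
  expect_error(simulation_config(ar1_coefficient = 1), "ar1")
  expect_error(simulation_config(roi1_center_mm = c(0, 0, 0),
                                 roi2_center_mm = c(5, 0, 0)),
               "overlap")
  expect_error(simulation_config(roi1_center_mm = c(200, 0, 0)), "grid")
  expect_error(simulation_config(neuronal_bandwidth_hz = 5), "Nyquist")
})

test_that("subject simulation embeds the planted structure", {
  cfg <- small_sim_config(noise_sigma = 0.5)
  ds <- simulate_subject(cfg, 7)
  expect_equal(dim(ds$image4d), c(cfg$grid_shape, cfg$n_volumes_acquired))
  expect_true(all(is.finite(ds$image4d)))
  expect_equal(dim(ds$motion_params), c(cfg$n_volumes_acquired, 6L))
  expect_true(all(ds$wm_prob >= 0 & ds$wm_prob <= 1))
  # tissue compartments exceed the 0.99 threshold inside only
  expect_gt(sum(tissue_mask(ds$wm_prob, 0.99)), 0)
  expect_equal(sum(ds$ground_truth != 0),
               sum(sphere_mask(cfg$target_center_mm, cfg$roi_radius_mm,
                               cfg$affine, cfg$grid_shape)))
  expect_equal(unique(ds$ground_truth[ds$ground_truth != 0]),
               cfg$true_beta3)
  # ROI sphere voxels carry the seed signal
  m1 <- sphere_mask(cfg$roi1_center_mm, cfg$roi_radius_mm, cfg$affine,
                    cfg$grid_shape)
  center_series <- apply(ds$image4d, 4, function(v) mean(v[m1]))
  expect_gt(sd(center_series), 0.5)
})

test_that("noiseless null subject yields sub-threshold PPI t at the target", {
  hits <- sapply(1:4, function(s) {
    cfg <- small_sim_config(noise_sigma = 0, drift_amplitude = 0,
                            true_beta3 = 0)
    ds <- simulate_subject(cfg, s)
    sub <- suppressWarnings(run_subject(ds, pipeline_config()))
    tgt <- which(as.vector(sphere_mask(cfg$target_center_mm, 1, cfg$affine,
                                       cfg$grid_shape)))
    tvals <- sub$variants$deconv$t[tgt]
    crit <- qt(1 - 0.001, sub$variants$deconv$dof)
    all(is.nan(tvals) | abs(tvals) < crit)
  })
  expect_true(all(hits))
})

test_that("planted interaction sign is recovered and flips with beta3", {
  signs <- sapply(1:5, function(s) {
    cfg <- small_sim_config(noise_sigma = 0, true_beta3 = 0.5)
    ds <- simulate_subject(cfg, s)
    sub <- suppressWarnings(run_subject(ds, pipeline_config()))
    tgt <- which(as.vector(sphere_mask(cfg$target_center_mm, 1, cfg$affine,
                                       cfg$grid_shape)))
    beta_idx <- match("ppi", rownames(sub$variants$deconv$fit$betas))
    sub$variants$deconv$fit$betas[beta_idx, tgt]
  })
  expect_true(all(signs > 0))
  # beta3 -> -beta3 with the same seed flips the planted component exactly
  cfg <- small_sim_config(noise_sigma = 0.8)
  ds_pos <- simulate_subject(cfg, 11, beta3 = 0.5)
  ds_neg <- simulate_subject(cfg, 11, beta3 = -0.5)
  diff_img <- ds_pos$image4d - ds_neg$image4d
  tgt_mask <- sphere_mask(cfg$target_center_mm, cfg$roi_radius_mm,
                          cfg$affine, cfg$grid_shape)
  outside <- array(TRUE, cfg$grid_shape); outside[tgt_mask] <- FALSE
  flat <- matrix(diff_img, ncol = dim(diff_img)[4])
  expect_equal(max(abs(flat[as.vector(outside), ])), 0)
  expect_gt(max(abs(flat[as.vector(tgt_mask), ])), 0)
})

test_that("group manifests are deterministic with distinct seeds", {
  cfg <- small_sim_config(n_subjects = 6)
  m1 <- group_manifest(cfg)
  m2 <- group_manifest(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 6)
  expect_equal(anyDuplicated(m1$seed), 0)
  expect_true(all(m1$seed < 2^31))
  # per-subject interaction weights center on the population value
  cfg64 <- simulation_config(n_subjects = 64)
  m64 <- group_manifest(cfg64)
  sem <- cfg64$beta3_sd / sqrt(64)
  expect_lt(abs(mean(m64$beta3) - cfg64$true_beta3), 2 * sem + 1e-12)
})

test_that("cohort generation writes a standard on-disk layout", {
  cfg <- small_sim_config(n_subjects = 2, n_volumes_acquired = 40)
  dir <- withr::local_tempdir()
  out <- simulate_group(cfg, dir = dir)
  expect_equal(nrow(out$manifest), 2)
  expect_true(all(file.exists(file.path(out$paths, "func.nii.gz"))))
  expect_true(all(file.exists(file.path(out$paths, "motion.txt"))))
  expect_true(file.exists(file.path(dir, "tissue", "wm.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(man$subjects), 2)
  expect_equal(man$config$tr_seconds, 2)
  # image round trip preserves data and affine
  img <- read_volume(file.path(out$paths[1], "func.nii.gz"))
  ds1 <- simulate_subject(cfg, out$manifest$seed[1],
                          beta3 = out$manifest$beta3[1])
  expect_equal(as.vector(img), as.vector(ds1$image4d), tolerance = 1e-12)
  expect_equal(attr(img, "affine"), cfg$affine, tolerance = 1e-6,
               ignore_attr = TRUE)
  # in-memory generation is reproducible
  g1 <- simulate_group(cfg)
  g2 <- simulate_group(cfg)
  expect_identical(g1$subjects[[1]]$image4d, g2$subjects[[1]]$image4d)
})

test_that("null cohorts with main effects but no interaction stay clean", {
  surviving <- sapply(1:4, function(s) {
    cfg <- small_sim_config(n_subjects = 8, true_beta3 = 0, beta3_sd = 0,
                            seed = s)
    res <- run_simulated_cohort(cfg, pipeline_config())
    sum(res$group$clusters$survives)
  })
  expect_lte(sum(surviving > 0), 1)
})

test_that("noiseless subjects recover the interaction sign with bounded attenuation",
{
  # high-pass filtering and deconvolution do not commute with the product,
  # so the PPI coefficient is systematically attenuated; the estimate must
  # keep the right sign and stay within a factor ~2 of the planted value
  errs <- sapply(1:6, function(s) {
    cfg <- simulation_config(noise_sigma = 0)
    ds <- simulate_subject(cfg, 700 + s)
    sub <- suppressWarnings(run_subject(ds, pipeline_config()))
    tgt <- which(as.vector(sphere_mask(cfg$target_center_mm, 1, cfg$affine,
                                       cfg$grid_shape)))
    v <- sub$variants$deconv
    bhat <- v$fit$betas[match("ppi", rownames(v$fit$betas)), tgt]
    a3 <- cfg$true_beta3 /
      sqrt(cfg$true_beta1^2 + cfg$true_beta2^2 + cfg$true_beta3^2)
    expect_gt(bhat, 0)
    (bhat * sd(v$ppi$values) - a3) / a3
  })
  expect_lt(median(abs(errs)), 0.5)
  expect_lt(median(errs), 0)   # attenuation, not inflation
})
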