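#' Pipeline configuration
#'
#' Collects every tunable analysis setting. The defaults are the standard
#' resting-state PPI settings: 8 mm seed spheres, tissue-probability
#' threshold 0.99, 1/100 Hz implicit high-pass, cluster forming at one-sided
#' p < 0.001 and cluster-level FDR at q = 0.05.
#'
#' @param n_discard Leading volumes to discard (default 2).
#' @param roi_radius_mm Seed sphere radius (default 8).
#' @param tissue_threshold Exclusive tissue-probability threshold
#'   (default 0.99).
#' @param highpass_cutoff_s High-pass cutoff period in seconds (default 100).
#' @param detrend `"linear"` or `"mean"` detrending of neuronal series.
#' @param variant `"deconv"`, `"raw"` or `"both"` interaction regressors.
#' @param microtime_bins_per_tr Microtime bins per TR (default 16).
#' @param hrf Named list of overrides for [canonical_hrf()] parameters.
#' @param deconv_regularization `"evidence"` or a fixed ridge weight.
#' @param height_p Cluster-forming height threshold (one-sided p, default
#'   0.001).
#' @param q Cluster-level FDR level (default 0.05).
#' @param connectivity Cluster connectivity, 6/18/26 (default 18).
#' @param inference `"rft"` or `"permutation"` cluster p-values.
#' @param n_permutations Permutations when `inference = "permutation"`.
#' @param seed Seed for permutation inference.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_discard = 2,
                            roi_radius_mm = 8,
                            tissue_threshold = 0.99,
                            highpass_cutoff_s = 100,
                            detrend = c("linear", "mean"),
                            variant = c("deconv", "raw", "both"),
                            microtime_bins_per_tr = 16,
                            hrf = list(),
                            deconv_regularization = "evidence",
                            height_p = 0.001,
                            q = 0.05,
                            connectivity = 18,
                            inference = c("rft", "permutation"),
                            n_permutations = 1000,
                            seed = 1) {
  detrend <- match.arg(detrend)
  variant <- match.arg(variant)
  inference <- match.arg(inference)
  stopifnot(roi_radius_mm > 0, tissue_threshold > 0, tissue_threshold < 1,
            highpass_cutoff_s > 0, height_p > 0, height_p < 1,
            q > 0, q < 1, connectivity %in% c(6, 18, 26))
  structure(list(n_discard = n_discard, roi_radius_mm = roi_radius_mm,
                 tissue_threshold = tissue_threshold,
                 highpass_cutoff_s = highpass_cutoff_s,
                 detrend = detrend, variant = variant,
                 microtime_bins_per_tr = microtime_bins_per_tr,
                 hrf = hrf,
                 deconv_regularization = deconv_regularization,
                 height_p = height_p, q = q, connectivity = connectivity,
                 inference = inference, n_permutations = n_permutations,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected, so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

subject_kernel <- function(config, tr_seconds) {
  do.call(canonical_hrf,
          c(list(tr_seconds = tr_seconds,
                 microtime_bins_per_tr = config$microtime_bins_per_tr),
            config$hrf))
}

load_subject_inputs <- function(dataset) {
  if (inherits(dataset, "subject_dataset")) return(dataset)
  if (is.character(dataset)) {
    sdir <- dataset
    tdir <- file.path(dirname(sdir), "tissue")
    return(list(image4d = read_volume(file.path(sdir, "func.nii.gz")),
                motion_params = read_motion_params(file.path(sdir,
                                                             "motion.txt")),
                wm_prob = read_volume(file.path(tdir, "wm.nii.gz")),
                csf_prob = read_volume(file.path(tdir, "csf.nii.gz"))))
  }
  stopifnot(is.list(dataset),
            all(c("image4d", "motion_params", "wm_prob", "csf_prob") %in%
                  names(dataset)))
  dataset
}

#' Run the subject-level PPI analysis
#'
#' Discards initial volumes, derives WM/CSF masks and their first
#' eigenvariates, builds the motion + drift confounds, extracts the two seed
#' eigenvariates with confounds removed, constructs the interaction
#' regressor(s), fits the voxel-wise GLM and computes the interaction t map.
#'
#' @param dataset A [simulate_subject()] result, a subject directory written
#'   by [simulate_group()], or a list with `image4d` (with affine attribute),
#'   `motion_params`, `wm_prob`, `csf_prob`.
#' @param config A [pipeline_config()].
#' @param roi1_center_mm,roi2_center_mm Seed centers in MNI mm; default to
#'   the simulation's own centers when `dataset` is a `subject_dataset`.
#' @param tr_seconds TR; defaults to the simulation's TR when available.
#' @param out_dir Optional directory: writes con/t maps (NIfTI), the design
#'   matrix (TSV) and a JSON sidecar with dof, condition number and
#'   settings.
#' @return Object of class `ppi_subject`: per-variant `design`, `fit`, `con`
#'   (vector), `t` (vector), plus the seed series, interaction regressors,
#'   grid shape and affine.
#' @export
run_subject <- function(dataset, config = pipeline_config(),
                        roi1_center_mm = NULL, roi2_center_mm = NULL,
                        tr_seconds = NULL, out_dir = NULL) {
  inp <- load_subject_inputs(dataset)
  if (inherits(dataset, "subject_dataset")) {
    sim <- dataset$config
    if (is.null(roi1_center_mm)) roi1_center_mm <- sim$roi1_center_mm
    if (is.null(roi2_center_mm)) roi2_center_mm <- sim$roi2_center_mm
    if (is.null(tr_seconds)) tr_seconds <- sim$tr_seconds
  }
  if (is.null(roi1_center_mm) || is.null(roi2_center_mm) ||
      is.null(tr_seconds))
    stop("ROI centers and TR must be supplied for non-simulated inputs",
         call. = FALSE)
  affine <- attr(inp$image4d, "affine")
  if (is.null(affine)) stop("image has no affine", call. = FALSE)

  img <- discard_initial_volumes(inp$image4d, config$n_discard)
  motion <- inp$motion_params[(config$n_discard + 1):nrow(inp$motion_params),
                              , drop = FALSE]
  n_scans <- dim(img)[4]
  g <- dim(img)[1:3]
  kernel <- subject_kernel(config, tr_seconds)

  drift <- dct_highpass_basis(n_scans, tr_seconds, config$highpass_cutoff_s)
  wm_mask <- tissue_mask(inp$wm_prob, config$tissue_threshold)
  csf_mask <- tissue_mask(inp$csf_prob, config$tissue_threshold)
  drift_conf <- confound_set(dct_drift = drift)
  wm <- extract_eigenvariate(img, wm_mask, drift_conf, tr_seconds, "wm")
  csf <- extract_eigenvariate(img, csf_mask, drift_conf, tr_seconds, "csf")
  confounds <- confound_set(wm = wm, csf = csf, motion = motion,
                            dct_drift = drift)

  roi1 <- extract_eigenvariate(
    img, sphere_mask(roi1_center_mm, config$roi_radius_mm, affine, g),
    confounds, tr_seconds, "roi1")
  roi2 <- extract_eigenvariate(
    img, sphere_mask(roi2_center_mm, config$roi_radius_mm, affine, g),
    confounds, tr_seconds, "roi2")

  Y <- t(matrix(img, ncol = n_scans))          # scans x voxels
  variants <- if (config$variant == "both") c("deconv", "raw") else
    config$variant
  results <- list()
  for (v in variants) {
    ppi <- if (v == "deconv")
      build_ppi_deconv(roi1, roi2, kernel, detrend = config$detrend,
                       regularization = config$deconv_regularization)
    else build_ppi_raw(roi1, roi2, detrend = config$detrend)
    design <- assemble_design(roi1, roi2, ppi, confounds)
    fit <- fit_glm(Y, design)
    ct <- contrast_t(fit, "ppi")
    results[[v]] <- list(ppi = ppi, design = design, fit = fit,
                         con = ct$effect, t = ct$t, dof = ct$dof)
  }
  out <- structure(list(variants = results, roi1 = roi1, roi2 = roi2,
                        grid_shape = g, affine = affine,
                        n_scans = n_scans, tr_seconds = tr_seconds),
                   class = "ppi_subject")
  if (!is.null(out_dir)) write_subject_outputs(out, out_dir, config)
  out
}

write_subject_outputs <- function(subject, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(subject$variants)) {
    res <- subject$variants[[v]]
    tag <- paste0("ppi-", v)
    write_volume(structure(array(res$con, subject$grid_shape),
                           affine = subject$affine),
                 file.path(out_dir, paste0("con_", tag, ".nii.gz")))
    write_volume(structure(array(res$t, subject$grid_shape),
                           affine = subject$affine),
                 file.path(out_dir, paste0("t_", tag, ".nii.gz")))
    dm <- as.data.frame(res$design$matrix)
    utils::write.table(dm, file.path(out_dir, paste0("design_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(variant = v, dof = res$dof,
           condition_number = res$design$condition_number,
           detrend = config$detrend,
           highpass_cutoff_s = config$highpass_cutoff_s,
           deconv_regularization = config$deconv_regularization),
      file.path(out_dir, paste0("sidecar_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Run the group-level inference
#'
#' One-sample t-test across subjects' interaction contrast maps, cluster
#' forming for the positive and negative contrasts, cluster p-values by
#' random-field theory (with smoothness estimated from the standardized
#' between-subject residual maps) or by sign-flip permutation, and
#' topological FDR per sign.
#'
#' @param con_maps `n_subjects` x V matrix, or a list of `ppi_subject`
#'   results (the requested `variant`'s con map is pulled from each).
#' @param config A [pipeline_config()].
#' @param grid_shape,affine Spatial metadata (taken from the first subject
#'   result when a list is given).
#' @param variant Which variant's con maps to use from subject results.
#' @return Object of class `ppi_group`: `group_map`, `clusters` (tibble,
#'   both signs, with p-values and FDR), `table` ([cluster_table()] of the
#'   surviving clusters and all clusters separately), `smoothness`.
#' @export
run_group <- function(con_maps, config = pipeline_config(),
                      grid_shape = NULL, affine = NULL, variant = NULL) {
  if (is.list(con_maps) && !is.matrix(con_maps)) {
    subs <- con_maps
    stopifnot(all(vapply(subs, inherits, logical(1), "ppi_subject")))
    if (is.null(variant)) variant <- names(subs[[1]]$variants)[1]
    grid_shape <- subs[[1]]$grid_shape
    affine <- subs[[1]]$affine
    con_maps <- do.call(rbind, lapply(subs, function(s)
      s$variants[[variant]]$con))
  }
  if (is.null(grid_shape)) stop("`grid_shape` required", call. = FALSE)
  if (is.null(affine)) affine <- diag(4)
  n <- nrow(con_maps)
  if (n < 2) stop("need at least 2 subjects' con maps", call. = FALSE)
  if (n < 5) warning("only ", n, " subjects: group dof = ", n - 1,
                     "; power is very low", call. = FALSE)
  group <- one_sample_t(con_maps, grid_shape, affine = affine)

  clusters <- dplyr::bind_rows(
    form_clusters(group, config$height_p, "positive", config$connectivity),
    form_clusters(group, config$height_p, "negative", config$connectivity))
  smoothness <- NULL
  if (nrow(clusters) > 0) {
    if (config$inference == "rft") {
      res <- t(sweep(con_maps, 2, colMeans(con_maps)))   # V x subjects
      smoothness <- estimate_smoothness(res, grid_shape = grid_shape)
      p <- rft_cluster_p(clusters$voxel_count, smoothness$resels,
                         config$height_p, prod(grid_shape))
      clusters$p_uncorrected <- p$p_uncorrected
    } else {
      parts <- lapply(c("positive", "negative"), function(sg) {
        cl <- permutation_cluster_p(con_maps, grid_shape,
                                    height_p = config$height_p,
                                    n_permutations = config$n_permutations,
                                    seed = config$seed, sign = sg,
                                    connectivity = config$connectivity,
                                    affine = affine)
        cl
      })
      clusters <- dplyr::bind_rows(parts)
    }
    clusters <- topological_fdr(clusters, config$q)
  } else {
    clusters$p_uncorrected <- numeric()
    clusters <- topological_fdr(clusters, config$q)
  }
  tbl <- cluster_table(clusters, group)
  structure(list(group_map = group, clusters = clusters, table = tbl,
                 surviving = cluster_table(
                   clusters[clusters$survives, , drop = FALSE], group),
                 smoothness = smoothness, config = config),
            class = "ppi_group")
}

#' @export
print.ppi_group <- function(x, ...) {
  cat("<ppi_group> n = ", x$group_map$n_subjects, " subjects, ",
      nrow(x$clusters), " cluster(s), ", sum(x$clusters$survives),
      " surviving FDR q = ", x$config$q, "\n", sep = "")
  if (nrow(x$surviving) > 0) print(x$surviving)
  invisible(x)
}

#' Compare deconvolved and raw interaction regressors
#'
#' For each subject run with `variant = "both"`, the Pearson correlation
#' between the interaction regressor built from deconvolved neuronal series
#' and the one built from raw BOLD series.
#'
#' @param subject_results List of `ppi_subject` objects carrying both
#'   variants, or a tibble with columns `subject`, `r` (and optionally
#'   `pair`, `group`) from prior runs.
#' @param pair Optional label of the ROI pair analysed.
#' @param group Optional sample label (e.g. "discovery"/"replication") per
#'   subject.
#' @return List with `per_subject` (tibble `subject`, `pair`, `group`, `r`)
#'   and `summary` (mean and SD of r per pair/group; SD omitted with a
#'   warning below 3 subjects).
#' @export
run_deconv_comparison <- function(subject_results, pair = "pair1",
                                  group = NULL) {
  if (is.data.frame(subject_results)) {
    per <- tibble::as_tibble(subject_results)
    if (!"pair" %in% names(per)) per$pair <- pair
    if (!"group" %in% names(per)) per$group <- group %||% "all"
  } else {
    rs <- vapply(subject_results, function(s) {
      if (!all(c("deconv", "raw") %in% names(s$variants)))
        stop("subject result lacks both variants; run with variant = ",
             "\"both\"", call. = FALSE)
      ppi_term_correlation(s$variants$deconv$ppi, s$variants$raw$ppi)
    }, numeric(1))
    per <- tibble::tibble(subject = sprintf("sub-%02d",
                                            seq_along(subject_results)),
                          pair = pair,
                          group = (group %||% "all"),
                          r = rs)
  }
  if (any(table(interaction(per$pair, per$group)) < 3))
    warning("fewer than 3 subjects in a cell: dispersion omitted",
            call. = FALSE)
  summary <- dplyr::summarise(
    dplyr::group_by(per, .data$pair, .data$group),
    n = dplyr::n(),
    mean_r = mean(.data$r),
    sd_r = ifelse(dplyr::n() >= 3, stats::sd(.data$r), NA_real_),
    .groups = "drop")
  list(per_subject = per, summary = summary)
}

#' Association of mean regressor correlations between two samples
#'
#' Given per-subject deconvolved-vs-raw correlations for several ROI pairs
#' in two disjoint subsamples, correlates the per-pair mean correlations of
#' one sample with those of the other — the split-half reproducibility of
#' the network-wise correlation profile.
#'
#' @param per_subject Tibble with columns `pair`, `group`, `r` and exactly
#'   two groups.
#' @return Pearson correlation between the two groups' per-pair mean-r
#'   vectors.
#' @export
deconv_comparison_association <- function(per_subject) {
  gs <- unique(per_subject$group)
  if (length(gs) != 2)
    stop("need exactly 2 groups", call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$pair, .data$group),
    mean_r = mean(.data$r), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "group",
                             values_from = "mean_r")
  if (nrow(wide) < 2)
    stop("need at least 2 ROI pairs to correlate mean profiles",
         call. = FALSE)
  stats::cor(wide[[gs[1]]], wide[[gs[2]]])
}

#' Simulate a cohort and run the full pipeline on it
#'
#' Generates each subject in turn (keeping at most one subject's 4D data in
#' memory), runs the subject-level analysis, then the group inference on the
#' deconvolved-variant contrast maps.
#'
#' @param sim_config A [simulation_config()].
#' @param pipe_config A [pipeline_config()]; `variant = "both"` also yields
#'   the regressor comparison.
#' @return List with `group` (a `ppi_group`), `con_maps` (per variant),
#'   `comparison` (tibble of per-subject r, when both variants were run),
#'   `manifest`, `target_mask`, `sim_config`.
#' @export
run_simulated_cohort <- function(sim_config, pipe_config = pipeline_config()) {
  manifest <- group_manifest(sim_config)
  variants <- if (pipe_config$variant == "both") c("deconv", "raw") else
    pipe_config$variant
  V <- prod(sim_config$grid_shape)
  con <- lapply(variants, function(v)
    matrix(NA_real_, sim_config$n_subjects, V))
  names(con) <- variants
  rs <- rep(NA_real_, sim_config$n_subjects)
  for (i in seq_len(sim_config$n_subjects)) {
    ds <- simulate_subject(sim_config, manifest$seed[i],
                           beta3 = manifest$beta3[i])
    sub <- run_subject(ds, pipe_config)
    for (v in variants) con[[v]][i, ] <- sub$variants[[v]]$con
    if (length(variants) == 2)
      rs[i] <- ppi_term_correlation(sub$variants$deconv$ppi,
                                    sub$variants$raw$ppi)
    rm(ds, sub)
  }
  group <- run_group(con[[variants[1]]], pipe_config,
                     grid_shape = sim_config$grid_shape,
                     affine = sim_config$affine)
  target_mask <- sphere_mask(sim_config$target_center_mm,
                             sim_config$roi_radius_mm, sim_config$affine,
                             sim_config$grid_shape)
  list(group = group, con_maps = con,
       comparison = if (length(variants) == 2)
         tibble::tibble(subject = manifest$subject, r = rs) else NULL,
       manifest = manifest, target_mask = target_mask,
       sim_config = sim_config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
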