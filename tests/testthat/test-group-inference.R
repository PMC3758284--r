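test_that("one-sample t matches the closed form and masks zero variance", {
  vals <- c(1, 2, 3, 4)
  con <- cbind(vals, c(2, 2, 2, 2), -cbind(vals))
  g <- one_sample_t(con, c(3, 1, 1))
  expect_equal(g$t_values[1], 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-12)
  expect_true(is.na(g$t_values[2]))            # all-equal: zero variance
  expect_equal(g$t_values[3], -g$t_values[1])  # odd symmetry
  expect_equal(g$dof, 3)
  expect_error(one_sample_t(con[1, , drop = FALSE], c(3, 1, 1)), "2 subjects")
})

test_that("cluster labeling matches an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  igraph_labels <- function(mask, connectivity) {
    idx <- which(mask)
    if (length(idx) == 0) return(list())
    co <- arrayInd(idx, dim(mask))
    off <- restppi:::connectivity_offsets(connectivity)
    edges <- NULL
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    lut <- setNames(seq_along(idx), key(co))
    for (r in seq_len(nrow(off))) {
      nb <- sweep(co, 2, off[r, ], "+")
      hit <- lut[key(nb)]
      ok <- !is.na(hit)
      if (any(ok)) edges <- rbind(edges, cbind(which(ok), hit[ok]))
    }
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
    split(idx, comp)
  }
  set.seed(50)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      mask <- array(runif(16^3) < 0.12, dim = c(16, 16, 16))
      lab <- restppi:::label_components(mask, conn)
      expect_equal(sum(lab > 0), sum(mask))
      mine <- split(which(lab > 0), lab[lab > 0])
      oracle <- igraph_labels(mask, conn)
      canon <- function(l) unname(l[order(vapply(l, min, numeric(1)))])
      expect_equal(canon(mine), canon(oracle))
    }
  }
})

test_that("cluster forming respects connectivity and reports peaks in mm", {
  g <- c(8, 8, 8)
  t_map <- array(0, g)
  # a 3x3x3 block plus a diagonal-corner neighbour voxel
  t_map[2:4, 2:4, 2:4] <- 5
  t_map[5, 5, 5] <- 6
  con <- rbind(as.vector(t_map) * 0.9, as.vector(t_map) * 1.1,
               as.vector(t_map) * 1.05, as.vector(t_map) * 0.95)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- -10.5
  gm <- one_sample_t(con, g, affine = aff)
  cl18 <- form_clusters(gm, 0.001, "positive", connectivity = 18)
  expect_equal(sort(cl18$voxel_count), c(1, 27))
  cl26 <- form_clusters(gm, 0.001, "positive", connectivity = 26)
  expect_equal(cl26$voxel_count, 28)           # corner touches diagonally
  # two face-touching voxels form one cluster under 18-connectivity
  t2 <- array(0, g); t2[2, 2, 2] <- 5; t2[3, 2, 2] <- 5
  con2 <- rbind(as.vector(t2) * 0.9, as.vector(t2) * 1.1,
                as.vector(t2), as.vector(t2))
  cl2 <- form_clusters(one_sample_t(con2, g), 0.001, "positive", 18)
  expect_equal(cl2$voxel_count, 2)
  # all-zero map: no clusters
  z <- one_sample_t(matrix(rnorm(4 * 8, sd = 1e-6), 4, 8) * 0, c(2, 2, 2))
  expect_equal(nrow(form_clusters(z, 0.001, "positive")), 0)
  # peak coordinates are world mm of the peak voxel
  peak_cl <- cl18[cl18$voxel_count == 1, ]
  expect_equal(c(peak_cl$peak_x, peak_cl$peak_y, peak_cl$peak_z),
               drop(aff %*% c(4, 4, 4, 1))[1:3])
})

test_that("smoothness estimation tracks the true field smoothness", {
  set.seed(52)
  g <- c(20, 20, 20)
  # white noise: sampling-limited FWHM well below 1.5 voxels
  white <- lapply(1:4, function(i) array(rnorm(prod(g)), g))
  sm_w <- estimate_smoothness(white)
  expect_true(all(sm_w$fwhm_voxels < 1.5))
  # smoothed FWHM 4: estimate close to 4 (median over replicates)
  est <- replicate(10, {
    maps <- lapply(1:3, function(i) smooth_null_field(g, 4))
    median(estimate_smoothness(maps)$fwhm_voxels)
  })
  expect_gt(median(est), 3)
  expect_lt(median(est), 5)
  flat <- lapply(1:3, function(i) array(1, g))
  expect_error(estimate_smoothness(flat), "degenerate")
})

test_that("RFT cluster p-values have the correct limits and monotonicity", {
  p <- rft_cluster_p(c(1, 5, 20, 100), resels = 500, height_p = 0.001,
                     n_voxels = 13824)
  expect_true(all(diff(p$p_uncorrected) < 0))
  expect_true(all(diff(p$p_fwe) <= 0))
  expect_true(all(p$p_uncorrected >= 0 & p$p_uncorrected <= 1))
  # k -> 0 limit: extent tail -> 1, set-level -> 1 - exp(-E[m])
  tiny <- rft_cluster_p(1e-9, 500, 0.001, 13824)
  expect_equal(tiny$p_uncorrected, 1, tolerance = 1e-4)
  expect_equal(tiny$p_fwe, 1 - exp(-tiny$expected_clusters),
               tolerance = 1e-4)
  expect_lte(tiny$p_fwe, 1)
  expect_error(rft_cluster_p(5, -1, 0.001, 1000), "resels")
  expect_error(rft_cluster_p(0, 10, 0.001, 1000), "positive")
})

test_that("RFT uncorrected cluster p is calibrated on smooth null fields", {
  set.seed(53)
  g <- c(32, 32, 32); V <- prod(g); fwhm <- 3
  u <- qnorm(0.999)
  n_sim <- 120
  tot <- 0; sig <- 0
  for (s in seq_len(n_sim)) {
    f <- smooth_null_field(g, fwhm)
    lab <- restppi:::label_components(f > u, 18)
    if (max(lab) > 0) {
      ks <- tabulate(lab[lab > 0])
      p <- rft_cluster_p(ks, V / fwhm^3, 0.001, V)$p_uncorrected
      tot <- tot + length(ks)
      sig <- sig + sum(p < 0.05)
    }
  }
  expect_gt(tot, 100)
  ratio <- sig / (0.05 * tot)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("permutation p-values are deterministic and rank extremes right", {
  set.seed(54)
  g <- c(10, 10, 10); V <- prod(g)
  effect <- array(0, g); effect[4:6, 4:6, 4:6] <- 2
  con <- matrix(rnorm(12 * V, sd = 0.3), 12, V) +
    rep(as.vector(effect), each = 12)
  p1 <- permutation_cluster_p(con, g, height_p = 0.001,
                              n_permutations = 100, seed = 9)
  p2 <- permutation_cluster_p(con, g, height_p = 0.001,
                              n_permutations = 100, seed = 9)
  expect_identical(p1$p_uncorrected, p2$p_uncorrected)
  big <- p1[which.max(p1$voxel_count), ]
  null_max <- attr(p1, "null_max_sizes")
  if (all(null_max < big$voxel_count))
    expect_equal(big$p_uncorrected, 1 / 101)
  expect_warning(
    permutation_cluster_p(con, g, n_permutations = 50, seed = 1),
    "resolution")
})

test_that("Benjamini-Hochberg over clusters matches hand computation", {
  cl <- tibble::tibble(p_uncorrected = c(0.001, 0.02, 0.04, 0.5),
                       sign = "positive",
                       voxel_count = c(50, 30, 20, 5))
  out <- topological_fdr(cl, q = 0.05)
  # BH thresholds i*q/m = 0.0125, 0.025, 0.0375, 0.05: first two survive
  expect_equal(out$survives, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$p_fdr, p.adjust(cl$p_uncorrected, "BH"))
  expect_true(all(out$p_fdr >= out$p_uncorrected))
  # single cluster: identity
  one <- topological_fdr(tibble::tibble(p_uncorrected = 0.01,
                                        sign = "positive"), 0.05)
  expect_equal(one$p_fdr, 0.01)
  expect_true(one$survives)
  # empty list passes through
  empty <- topological_fdr(tibble::tibble(p_uncorrected = numeric(),
                                          sign = character()), 0.05)
  expect_equal(nrow(empty), 0)
})

test_that("BH controls the false discovery proportion on uniform nulls", {
  set.seed(55)
  m <- 20
  fdp <- replicate(1000, {
    p <- runif(m)
    adj <- p.adjust(p, "BH")
    rej <- sum(adj <= 0.05)
    if (rej == 0) 0 else 1   # all nulls: any rejection is false
  })
  expect_lte(mean(fdp), 0.05 + 0.02)
})

test_that("cluster tables are sorted and sign-dual", {
  set.seed(56)
  g <- c(12, 12, 12); V <- prod(g)
  effect <- array(0, g)
  effect[3:5, 3:5, 3:5] <- 1.5
  effect[8:10, 8:10, 8:10] <- -2
  con <- matrix(rnorm(10 * V, sd = 0.4), 10, V) +
    rep(as.vector(effect), each = 10)
  cfg <- pipeline_config(height_p = 0.01)
  grp <- run_group(con, cfg, grid_shape = g)
  tbl <- grp$table
  expect_true(all(c("sign", "p_fdr", "voxels", "peak_t") %in% names(tbl)))
  pos <- tbl[tbl$sign == "positive", ]; neg <- tbl[tbl$sign == "negative", ]
  expect_true(all(diff(abs(pos$peak_t)) <= 0))
  expect_true(all(neg$peak_t < 0))   # negative modulation: negative peak t
  # sign duality: negated maps swap the sign blocks exactly
  grp2 <- run_group(-con, cfg, grid_shape = g)
  tbl2 <- grp2$table
  expect_equal(tbl2[tbl2$sign == "positive", ]$peak_t, -neg$peak_t)
  expect_equal(tbl2[tbl2$sign == "negative", ]$voxels, pos$voxels)
  # empty input: header-only table
  expect_equal(nrow(cluster_table(tibble::tibble(
    sign = character(), p_fdr = numeric(), voxel_count = integer(),
    peak_t = numeric(), peak_x = numeric(), peak_y = numeric(),
    peak_z = numeric()))), 0)
})
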