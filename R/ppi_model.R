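# remove mean and (optionally) linear trend from a vector
detrend_vector <- function(x, mode = c("linear", "mean")) {
  mode <- match.arg(mode)
  if (mode == "mean") return(x - mean(x))
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * sum(t * x) / sum(t * t)
}

#' Physiophysiological interaction regressor via deconvolution
#'
#' Builds the interaction regressor at the neuronal level: both seed BOLD
#' series are deconvolved with the canonical HRF, detrended, multiplied
#' elementwise on the microtime grid, reconvolved with the HRF and resampled
#' to the scan grid. The product of neuronal signals, not of BOLD signals, is
#' what a multiplicative neuronal coupling predicts at the hemodynamic level.
#'
#' @param roi1,roi2 [bold_series()] seed summaries of equal length and TR.
#' @param kernel An [canonical_hrf()] kernel.
#' @param detrend `"linear"` (mean + linear trend, default) or `"mean"`.
#' @param regularization Passed to [deconvolve_bold()].
#' @return A [bold_series()] interaction regressor of length `n_scans`.
#' @export
build_ppi_deconv <- function(roi1, roi2, kernel, detrend = "linear",
                             regularization = "evidence") {
  stopifnot(inherits(roi1, "bold_series"), inherits(roi2, "bold_series"))
  if (roi1$n_scans != roi2$n_scans)
    stop("ROI series must have equal length", call. = FALSE)
  if (abs(roi1$tr_seconds - roi2$tr_seconds) > 1e-9)
    stop("ROI series must share the same TR", call. = FALSE)
  n1 <- deconvolve_bold(roi1, kernel, regularization = regularization)
  n2 <- deconvolve_bold(roi2, kernel, regularization = regularization)
  d1 <- detrend_vector(n1$values, detrend)
  d2 <- detrend_vector(n2$values, detrend)
  if (stats::sd(d1) < 1e-12 || stats::sd(d2) < 1e-12)
    stop("degenerate signal: a deconvolved series has zero variance after ",
         "detrending", call. = FALSE)
  prod_series <- neuronal_series(d1 * d2, kernel$dt_seconds)
  out <- convolve_to_bold(prod_series, kernel, roi1$n_scans, roi1$tr_seconds)
  out$label <- "ppi_deconv"
  out
}

#' Physiophysiological interaction regressor from raw BOLD series
#'
#' The no-deconvolution variant: each BOLD series is detrended and the
#' product is taken directly on the scan grid.
#'
#' @inheritParams build_ppi_deconv
#' @return A [bold_series()] of length `n_scans`.
#' @export
build_ppi_raw <- function(roi1, roi2, detrend = "linear") {
  stopifnot(inherits(roi1, "bold_series"), inherits(roi2, "bold_series"))
  if (roi1$n_scans != roi2$n_scans)
    stop("ROI series must have equal length", call. = FALSE)
  d1 <- detrend_vector(roi1$values, detrend)
  d2 <- detrend_vector(roi2$values, detrend)
  out <- bold_series(d1 * d2, roi1$tr_seconds, label = "ppi_raw")
  out
}

#' Pearson correlation between two interaction regressors
#'
#' @param ppi_deconv,ppi_raw [bold_series()] of equal length.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
ppi_term_correlation <- function(ppi_deconv, ppi_raw) {
  a <- if (inherits(ppi_deconv, "bold_series")) ppi_deconv$values else ppi_deconv
  b <- if (inherits(ppi_raw, "bold_series")) ppi_raw$values else ppi_raw
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  stats::cor(a, b)
}

#' Assemble the subject-level PPI design matrix
#'
#' Column order: the two ROI main effects, the interaction regressor, the
#' WM and CSF nuisance summaries, six motion parameters, the high-pass drift
#' columns and an intercept. The design's rank and condition number are
#' computed and attached.
#'
#' @param roi1,roi2 [bold_series()] ROI main-effect regressors.
#' @param ppi [bold_series()] interaction regressor.
#' @param confounds A [confound_set()].
#' @return Object of class `ppi_design` with elements `matrix`,
#'   `column_labels`, `tr_seconds`, `condition_number`.
#' @export
assemble_design <- function(roi1, roi2, ppi, confounds) {
  stopifnot(inherits(roi1, "bold_series"), inherits(roi2, "bold_series"),
            inherits(ppi, "bold_series"), inherits(confounds, "confound_set"))
  n <- roi1$n_scans
  C <- as.matrix(confounds)
  cols <- cbind(roi1 = roi1$values, roi2 = roi2$values, ppi = ppi$values)
  if (!is.null(C)) cols <- cbind(cols, C)
  cols <- cbind(cols, intercept = rep(1, n))
  if (any(vapply(list(roi2$values, ppi$values), length, integer(1)) != n) ||
      nrow(cols) != n)
    stop("all design columns must have length ", n, call. = FALSE)
  nonconst <- colnames(cols) != "intercept"
  degenerate <- nonconst & apply(cols, 2, function(x) stats::sd(x) < 1e-12)
  if (any(degenerate))
    stop("degenerate (constant or all-zero) design column(s): ",
         paste(colnames(cols)[degenerate], collapse = ", "), call. = FALSE)
  d <- svd(cols, nu = 0, nv = 0)$d
  rank <- sum(d > 1e-10 * d[1])
  if (rank < ncol(cols)) {
    # name the columns involved in the collinearity via QR pivoting
    qrx <- qr(cols)
    bad <- colnames(cols)[qrx$pivot[(qrx$rank + 1):ncol(cols)]]
    stop("rank-deficient design (rank ", rank, " < ", ncol(cols),
         "); collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(matrix = cols, column_labels = colnames(cols),
                 tr_seconds = roi1$tr_seconds,
                 condition_number = d[1] / d[length(d)]),
            class = "ppi_design")
}

#' @export
print.ppi_design <- function(x, ...) {
  cat("<ppi_design> ", nrow(x$matrix), " scans x ", ncol(x$matrix),
      " regressors, condition number ",
      format(x$condition_number, digits = 4), "\n  columns: ",
      paste(x$column_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit the voxel-wise general linear model
#'
#' Ordinary least squares per voxel (no prewhitening), shared design across
#' voxels.
#'
#' @param data `n_scans` x V matrix, one column per voxel.
#' @param design A [assemble_design()] result, or a plain full-rank design
#'   matrix.
#' @return Object of class `ppi_glm` with `betas` (p x V), `sigma2`, `dof`
#'   and the design.
#' @export
fit_glm <- function(data, design) {
  if (is.matrix(design)) {
    d <- svd(design, nu = 0, nv = 0)$d
    if (sum(d > 1e-10 * d[1]) < ncol(design))
      stop("rank-deficient design matrix", call. = FALSE)
    labels <- colnames(design) %||% paste0("x", seq_len(ncol(design)))
    design <- structure(list(matrix = design, column_labels = labels,
                             tr_seconds = NA_real_,
                             condition_number = d[1] / d[length(d)]),
                        class = "ppi_design")
    colnames(design$matrix) <- labels
  }
  stopifnot(inherits(design, "ppi_design"))
  data <- as.matrix(data)
  if (!all(is.finite(data))) {
    bad <- which(!apply(is.finite(data), 2, all))
    stop("non-finite data at voxel(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ...", call. = FALSE)
  }
  X <- design$matrix
  if (nrow(data) != nrow(X))
    stop("data rows must equal design rows", call. = FALSE)
  qrx <- qr(X)
  betas <- qr.coef(qrx, data)
  res <- data - X %*% betas
  dof <- nrow(X) - qrx$rank
  sigma2 <- colSums(res^2) / dof
  rownames(betas) <- design$column_labels
  data_var <- colSums(sweep(data, 2, colMeans(data))^2) / (nrow(data) - 1)
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 design = design, xtx_inv = chol2inv(qr.R(qrx)),
                 data_var = data_var),
            class = "ppi_glm")
}

#' @export
print.ppi_glm <- function(x, ...) {
  cat("<ppi_glm> ", ncol(x$betas), " voxel(s), ", nrow(x$betas),
      " regressors, dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

#' Tidy a voxel-wise GLM fit
#'
#' @param x A `ppi_glm` object.
#' @param voxels Voxel indices to report (default: all).
#' @param ... Unused.
#' @return Tibble with columns `voxel`, `term`, `estimate`.
#' @export
tidy.ppi_glm <- function(x, voxels = NULL, ...) {
  if (is.null(voxels)) voxels <- seq_len(ncol(x$betas))
  tibble::tibble(
    voxel = rep(voxels, each = nrow(x$betas)),
    term = rep(rownames(x$betas), times = length(voxels)),
    estimate = as.vector(x$betas[, voxels, drop = FALSE]))
}

#' One-row summary of a voxel-wise GLM fit
#'
#' @param x A `ppi_glm` object.
#' @param ... Unused.
#' @return Tibble with `n_scans`, `n_regressors`, `n_voxels`, `dof`,
#'   `condition_number`.
#' @export
glance.ppi_glm <- function(x, ...) {
  tibble::tibble(n_scans = nrow(x$design$matrix),
                 n_regressors = nrow(x$betas),
                 n_voxels = ncol(x$betas),
                 dof = x$dof,
                 condition_number = x$design$condition_number)
}

#' Contrast t statistics for a fitted GLM
#'
#' @param fit A [fit_glm()] result.
#' @param contrast_vector Numeric contrast of length p, or the name of a
#'   single design column (contrast weight 1 on it).
#' @return Object of class `ppi_contrast` with `effect`, `t`, `dof`. Voxels
#'   with zero residual variance are reported as NaN with a warning.
#' @export
contrast_t <- function(fit, contrast_vector) {
  stopifnot(inherits(fit, "ppi_glm"))
  p <- nrow(fit$betas)
  if (is.character(contrast_vector)) {
    idx <- match(contrast_vector, rownames(fit$betas))
    if (is.na(idx)) stop("unknown design column: ", contrast_vector,
                         call. = FALSE)
    cv <- numeric(p)
    cv[idx] <- 1
  } else {
    cv <- as.numeric(contrast_vector)
    if (length(cv) != p)
      stop("contrast length must equal the number of regressors",
           call. = FALSE)
  }
  effect <- drop(crossprod(cv, fit$betas))
  cvar <- drop(crossprod(cv, fit$xtx_inv %*% cv))
  se <- sqrt(fit$sigma2 * cvar)
  t <- effect / se
  # residual variance at (relative) machine level means an exact linear fit:
  # t is 0/0 noise there and is masked
  degenerate <- fit$sigma2 <= 1e-16 * pmax(fit$data_var, .Machine$double.eps)
  if (any(degenerate)) {
    warning("zero residual variance at ", sum(degenerate),
            " voxel(s); t set to NaN there", call. = FALSE)
    t[degenerate] <- NaN
  }
  structure(list(contrast_vector = cv, effect = effect, t = t,
                 dof = fit$dof), class = "ppi_contrast")
}

#' @export
print.ppi_contrast <- function(x, ...) {
  cat("<ppi_contrast> ", length(x$t), " voxel(s), dof = ", x$dof,
      ", max |t| = ", format(max(abs(x$t), na.rm = TRUE), digits = 4),
      "\n", sep = "")
  invisible(x)
}
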