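#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — the difference of two gamma densities, one for
#' the positive response and one for the late undershoot — on a microtime grid
#' of `microtime_bins_per_tr` bins per repetition time. The kernel is
#' peak-normalised to 1; the absolute scale of the HRF cancels in every t
#' statistic the package computes.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param microtime_bins_per_tr Number of microtime bins per TR (default 16).
#' @param duration_seconds Support of the kernel in seconds (default 32).
#' @param peak_delay_s Delay of the response peak (gamma shape, seconds).
#' @param undershoot_delay_s Delay of the undershoot (seconds).
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters.
#' @param undershoot_ratio Ratio of undershoot to peak amplitude.
#'
#' @return An object of class `hrf_kernel`: a list with `samples`,
#'   `dt_seconds`, `duration_seconds` and `params`.
#' @examples
#' k <- canonical_hrf(tr_seconds = 2)
#' k$samples[1]  # 0 at the origin
#' @export
canonical_hrf <- function(tr_seconds, microtime_bins_per_tr = 16,
                          duration_seconds = 32,
                          peak_delay_s = 6, undershoot_delay_s = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive number", call. = FALSE)
  if (microtime_bins_per_tr < 1)
    stop("`microtime_bins_per_tr` must be >= 1", call. = FALSE)
  if (duration_seconds < tr_seconds)
    stop("`duration_seconds` must be >= `tr_seconds`", call. = FALSE)
  dt <- tr_seconds / microtime_bins_per_tr
  n <- round(duration_seconds / dt)
  t <- seq(0, by = dt, length.out = n)
  h <- stats::dgamma(t, shape = peak_delay_s / peak_dispersion,
                     scale = peak_dispersion) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay_s / undershoot_dispersion,
                    scale = undershoot_dispersion)
  h <- h / max(h)
  structure(
    list(samples = h, dt_seconds = dt, duration_seconds = duration_seconds,
         params = list(peak_delay_s = peak_delay_s,
                       undershoot_delay_s = undershoot_delay_s,
                       peak_dispersion = peak_dispersion,
                       undershoot_dispersion = undershoot_dispersion,
                       undershoot_ratio = undershoot_ratio,
                       microtime_bins_per_tr = microtime_bins_per_tr,
                       tr_seconds = tr_seconds)),
    class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("<hrf_kernel> ", length(x$samples), " samples, dt = ", x$dt_seconds,
      " s, duration = ", x$duration_seconds, " s\n", sep = "")
  cat("  peak at t = ",
      (which.max(x$samples) - 1) * x$dt_seconds, " s\n", sep = "")
  invisible(x)
}

#' Construct a neuronal-level time series
#'
#' @param values Numeric vector of (arbitrary-unit) neuronal activity.
#' @param dt_seconds Sampling step in seconds (microtime or scan grid).
#' @return Object of class `neuronal_series`.
#' @export
neuronal_series <- function(values, dt_seconds) {
  if (!all(is.finite(values)))
    stop("neuronal series contains non-finite values", call. = FALSE)
  if (dt_seconds <= 0) stop("`dt_seconds` must be > 0", call. = FALSE)
  structure(list(values = as.numeric(values), dt_seconds = dt_seconds,
                 n_points = length(values)),
            class = "neuronal_series")
}

#' Construct a BOLD time series on the scan grid
#'
#' @param values Numeric vector, one value per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param label Optional label (e.g. ROI abbreviation).
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(values, tr_seconds, label = NULL) {
  if (!all(is.finite(values)))
    stop("BOLD series contains non-finite values", call. = FALSE)
  if (length(values) < 8)
    stop("BOLD series must have at least 8 scans", call. = FALSE)
  structure(list(values = as.numeric(values), tr_seconds = tr_seconds,
                 n_scans = length(values), label = label),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> ", x$n_scans, " scans, TR = ", x$tr_seconds, " s",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
print.neuronal_series <- function(x, ...) {
  cat("<neuronal_series> ", x$n_points, " points, dt = ", x$dt_seconds,
      " s\n", sep = "")
  invisible(x)
}

# causal discrete convolution of a vector with the kernel samples,
# truncated to the input length
convolve_causal <- function(x, k) {
  n <- length(x)
  L <- stats::nextn(n + length(k) - 1L, 2L)
  fx <- stats::fft(c(x, rep(0, L - n)))
  fk <- stats::fft(c(k, rep(0, L - length(k))))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n)] / L
}

scan_grid_index <- function(n_scans, bins, reference_bin = 1L) {
  seq.int(reference_bin, by = bins, length.out = n_scans)
}

#' Convolve a neuronal series with the HRF and resample to the scan grid
#'
#' Applies causal discrete convolution (zero signal assumed before scan
#' start) on the microtime grid, then picks the first microtime bin of each
#' TR as the within-TR reference.
#'
#' @param neuronal A [neuronal_series()] on the kernel's microtime grid.
#' @param kernel An [canonical_hrf()] kernel.
#' @param n_scans Number of output scans.
#' @param tr_seconds Repetition time of the output grid.
#' @return A [bold_series()] of length `n_scans`.
#' @export
convolve_to_bold <- function(neuronal, kernel, n_scans, tr_seconds) {
  stopifnot(inherits(neuronal, "neuronal_series"),
            inherits(kernel, "hrf_kernel"))
  if (abs(neuronal$dt_seconds - kernel$dt_seconds) > 1e-9)
    stop("neuronal series and kernel are on different microtime grids",
         call. = FALSE)
  bins <- round(tr_seconds / kernel$dt_seconds)
  if (abs(bins * kernel$dt_seconds - tr_seconds) > 1e-9)
    stop("`tr_seconds` is not a whole number of microtime bins",
         call. = FALSE)
  idx <- scan_grid_index(n_scans, bins)
  if (max(idx) > neuronal$n_points)
    stop("neuronal series too short for ", n_scans, " scans", call. = FALSE)
  y <- convolve_causal(neuronal$values, kernel$samples)
  bold_series(y[idx], tr_seconds)
}

# orthonormal DCT-II basis, n rows, k columns (first column constant)
dct_basis <- function(n, k) {
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(matrix(0, n, 0))
  i <- seq_len(n)
  B <- vapply(seq_len(k) - 1L, function(f) {
    if (f == 0) rep(1 / sqrt(n), n)
    else sqrt(2 / n) * cos(pi * (2 * i - 1) * f / (2 * n))
  }, numeric(n))
  B
}

# cache of deconvolution operators keyed by kernel/grid parameters
.deconv_cache <- new.env(parent = emptyenv())

deconv_operator <- function(kernel, n_scans, basis_size) {
  bins <- kernel$params$microtime_bins_per_tr
  key <- paste(n_scans, basis_size, bins,
               paste(signif(kernel$samples[c(1:5, length(kernel$samples))], 8),
                     collapse = ","),
               length(kernel$samples), sep = "|")
  if (!is.null(.deconv_cache[[key]])) return(.deconv_cache[[key]])
  n_micro <- n_scans * bins
  B <- dct_basis(n_micro, basis_size)
  L <- stats::nextn(n_micro + length(kernel$samples) - 1L, 2L)
  FB <- stats::mvfft(rbind(B, matrix(0, L - n_micro, basis_size)))
  fk <- stats::fft(c(kernel$samples, rep(0, L - length(kernel$samples))))
  CB <- Re(stats::mvfft(FB * fk, inverse = TRUE))[seq_len(n_micro), ,
                                                  drop = FALSE] / L
  A <- CB[scan_grid_index(n_scans, bins), , drop = FALSE]
  sv <- svd(A)
  op <- list(B = B, A = A, u = sv$u, d = sv$d, v = sv$v, n_micro = n_micro)
  .deconv_cache[[key]] <- op
  op
}

# two-hyperparameter Gaussian evidence maximisation for the ridge weight:
# y = A theta + e, e ~ N(0, sigma2), theta ~ N(0, tau2); lambda = sigma2/tau2
evidence_lambda <- function(d, z, y2, n, max_iter = 32, tol = 1e-6) {
  r0 <- max(y2 - sum(z^2), 0)
  lambda <- mean(d^2)
  for (iter in seq_len(max_iter)) {
    w <- d^2 / (d^2 + lambda)
    gamma_eff <- sum(w)
    theta2 <- sum((d * z / (d^2 + lambda))^2)
    rss <- r0 + sum((lambda * z / (d^2 + lambda))^2)
    if (gamma_eff < 1e-8 || theta2 < 1e-300) break
    sigma2 <- rss / max(n - gamma_eff, 1)
    tau2 <- theta2 / gamma_eff
    lambda_new <- sigma2 / tau2
    if (!is.finite(lambda_new) || lambda_new <= 0) break
    if (abs(lambda_new - lambda) <= tol * lambda) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
  }
  lambda
}

#' Deconvolve a BOLD series to an approximate neuronal time course
#'
#' Represents the unknown neuronal signal in a discrete-cosine basis and
#' solves the ridge-regularised least-squares inversion of convolution with
#' the canonical HRF — an empirical-Bayes formulation in which the ridge
#' weight is the ratio of noise to prior precision. By default that weight is
#' chosen by maximising the Gaussian evidence with a fixed-point iteration;
#' pass a numeric `regularization` for a fixed, fully deterministic weight.
#'
#' @param bold A [bold_series()].
#' @param kernel An [canonical_hrf()] kernel whose microtime grid defines the
#'   output resolution.
#' @param basis_size Number of DCT basis functions (default: one per scan).
#' @param regularization Either `"evidence"` (default) or a fixed
#'   non-negative ridge weight.
#' @param max_iter,tol Fixed-point iteration controls for the evidence rule.
#' @return A [neuronal_series()] of length `n_scans * microtime_bins_per_tr`.
#' @export
deconvolve_bold <- function(bold, kernel, basis_size = NULL,
                            regularization = "evidence",
                            max_iter = 32, tol = 1e-6) {
  stopifnot(inherits(bold, "bold_series"), inherits(kernel, "hrf_kernel"))
  if (bold$n_scans < 8)
    stop("BOLD series must have at least 8 scans", call. = FALSE)
  n <- bold$n_scans
  if (is.null(basis_size)) basis_size <- n
  op <- deconv_operator(kernel, n, basis_size)
  y <- bold$values
  if (all(y == 0))
    return(neuronal_series(rep(0, op$n_micro), kernel$dt_seconds))
  cond <- op$d[1] / op$d[length(op$d)]
  if (!is.finite(cond))
    stop("deconvolution system is singular (condition number not finite)",
         call. = FALSE)
  z <- drop(crossprod(op$u, y))
  lambda <- if (identical(regularization, "evidence")) {
    evidence_lambda(op$d, z, sum(y^2), n, max_iter = max_iter, tol = tol)
  } else {
    if (!is.numeric(regularization) || regularization < 0)
      stop("`regularization` must be \"evidence\" or a non-negative number",
           call. = FALSE)
    regularization
  }
  theta <- op$v %*% (op$d * z / (op$d^2 + lambda))
  est <- drop(op$B %*% theta)
  if (!all(is.finite(est)))
    stop("deconvolution failed: non-finite estimate (condition number ",
         format(cond, digits = 3), ")", call. = FALSE)
  out <- neuronal_series(est, kernel$dt_seconds)
  attr(out, "lambda") <- lambda
  attr(out, "condition_number") <- cond
  out
}

#' Export an HRF kernel as a two-column TSV
#'
#' @param kernel An [canonical_hrf()] kernel.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_hrf_tsv <- function(kernel, path) {
  stopifnot(inherits(kernel, "hrf_kernel"))
  df <- data.frame(
    time_s = seq(0, by = kernel$dt_seconds,
                 length.out = length(kernel$samples)),
    amplitude = kernel$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
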