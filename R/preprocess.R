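#' Remove the linear trend from BOLD time series
#'
#' Returns the residual of an ordinary least-squares fit of each series on
#' an intercept and a linear ramp, removing the slow linear drift (e.g.
#' scanner heat absorption) together with the mean. The output is zero-mean
#' and orthogonal to the ramp.
#'
#' @param ts Numeric vector (one series) or matrix (timepoints x voxels).
#' @return Residual series of the same shape.
#' @export
detrend_linear <- function(ts) {
  x <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  n <- nrow(x)
  if (n < 3L) stop("series must have length >= 3")
  X <- cbind(1, seq_len(n))
  out <- qr.resid(qr(X), x)
  if (is.matrix(ts)) out else drop(out)
}

#' Regress nuisance signals out of BOLD time series
#'
#' OLS residual of each series on an intercept plus the nuisance regressors
#' (head motion, white-matter signal, cerebrospinal-fluid signal, global
#' signal, ...).
#'
#' @param ts Numeric vector or matrix (timepoints x voxels).
#' @param nuisance Numeric matrix (timepoints x k); row count must match
#'   the series length, no regressor may be constant zero, and the design
#'   (with intercept) must have full column rank.
#' @return Residual series of the same shape.
#' @export
regress_nuisance <- function(ts, nuisance) {
  x <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(x))
    stop("nuisance rows (", nrow(nuisance), ") must match series length (",
         nrow(x), ")")
  if (any(apply(nuisance, 2, function(r) all(r == 0))))
    stop("nuisance regressors must not be constant zero")
  X <- cbind(`(intercept)` = 1, nuisance)
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(X)))
    bad <- nm[dec$pivot[(dec$rank + 1):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  out <- qr.resid(dec, x)
  if (is.matrix(ts)) out else drop(out)
}

#' Ideal band-pass filter for BOLD time series
#'
#' Retains the discrete-Fourier components with frequency
#' `f_lo <= f <= f_hi` (inclusive band edges) and zeroes everything else,
#' including the DC component. This is an ideal (rectangular) filter in the
#' DFT domain: real-valued output, idempotent, and exactly reproducible.
#'
#' @param ts Numeric vector or matrix (timepoints x voxels).
#' @param tr_s Repetition time in seconds (sampling interval).
#' @param f_lo,f_hi Pass-band edges in Hz; defaults 0.01-0.08 Hz, the
#'   conventional resting-state band. Requires `f_lo < f_hi < 1/(2 tr_s)`.
#' @return Filtered series of the same shape.
#' @export
bandpass <- function(ts, tr_s, f_lo = 0.01, f_hi = 0.08) {
  if (tr_s <= 0) stop("tr_s must be positive")
  nyquist <- 1 / (2 * tr_s)
  if (!(f_lo < f_hi)) stop("f_lo must be below f_hi")
  if (f_hi >= nyquist)
    stop(sprintf("f_hi (%.4g Hz) must be below the Nyquist frequency (%.4g Hz)",
                 f_hi, nyquist))
  if (f_lo < 0) stop("f_lo must be non-negative")
  x <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  n <- nrow(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr_s)  # two-sided spectrum, Hz
  keep <- freq >= f_lo & freq <= f_hi
  X <- mvfft(x)
  X[!keep, ] <- 0
  out <- Re(mvfft(X, inverse = TRUE)) / n
  if (is.matrix(ts)) out else drop(out)
}

# reflective-padding 1D Gaussian convolution along the first margin of a
# matrix (series in rows); kernel normalized to unit sum
.conv_reflect <- function(m, kern) {
  r <- (length(kern) - 1L) / 2L
  n <- nrow(m)
  if (r == 0L) return(m * kern)
  idx <- seq_len(n + 2L * r) - r - 1L          # 0-based, -r .. n-1+r
  idx <- ifelse(idx < 0L, -idx - 1L, idx)      # reflect about the edges
  idx <- ifelse(idx > n - 1L, 2L * n - 1L - idx, idx)
  padded <- m[idx + 1L, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (d in seq_along(kern))
    out <- out + kern[d] * padded[seq_len(n) + d - 1L, , drop = FALSE]
  out
}

.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Per-timepoint separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, converted from mm to voxels
#' via the affine's column scales. Boundaries are handled by reflective
#' padding; the kernel is normalized, so a constant volume is unchanged and
#' the voxel sum is preserved. `fwhm_mm = 0` is the identity.
#'
#' @param vol A [ts_volume()].
#' @param fwhm_mm Full width at half maximum of the kernel in mm.
#' @return A smoothed [ts_volume()].
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 8) {
  stopifnot(inherits(vol, "ts_volume"))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  scales <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / scales
  d <- dim(vol$data)
  out <- vol$data
  for (ax in 1:3) {
    kern <- .gauss_kernel(sigma_vox[ax])
    if (length(kern) == 1L) next
    perm <- c(ax, setdiff(1:4, ax))
    m <- aperm(out, perm)
    dm <- dim(m)
    m <- .conv_reflect(matrix(m, dm[1]), kern)
    out <- aperm(array(m, dm), order(perm))
  }
  ts_volume(out, vol$tr_s, vol$affine)
}

#' Temporal preprocessing of one subject
#'
#' Applies the standard resting-state temporal cleaning to every voxel
#' inside the mask, in fixed order: linear detrending, nuisance regression,
#' band-pass filtering. Spatial smoothing, when enabled, is applied to the
#' whole volume before the temporal stages (mirroring pipelines that smooth
#' during spatial preprocessing). Voxels outside the mask are passed
#' through the temporal stages untouched.
#'
#' @param vol A [ts_volume()].
#' @param nuisance Timepoints x k matrix, or `NULL` when
#'   `options$nuisance = FALSE`.
#' @param mask 3D logical array on the volume's grid.
#' @param options List of switches: `detrend`, `nuisance`, `bandpass`
#'   (logicals, all `TRUE` by default), `band` (c(f_lo, f_hi), default
#'   c(0.01, 0.08) Hz), and `fwhm_mm` (default 0 = no smoothing).
#' @return A preprocessed [ts_volume()].
#' @export
preprocess_subject <- function(vol, nuisance = NULL, mask,
                               options = list()) {
  stopifnot(inherits(vol, "ts_volume"))
  opts <- modifyList(list(detrend = TRUE, nuisance = TRUE, bandpass = TRUE,
                          band = c(0.01, 0.08), fwhm_mm = 0), options)
  d <- dim(vol$data)
  if (!identical(dim(mask), d[1:3]))
    stop("mask dimensions must match the volume grid")
  if (opts$fwhm_mm > 0)
    vol <- smooth_gaussian(vol, opts$fwhm_mm)
  if (!opts$detrend && !opts$nuisance && !opts$bandpass) return(vol)
  flat <- matrix(vol$data, prod(d[1:3]), d[4])
  sel <- which(as.logical(mask))
  x <- t(flat[sel, , drop = FALSE])  # timepoints x masked voxels
  if (opts$detrend) x <- detrend_linear(x)
  if (opts$nuisance) {
    if (is.null(nuisance))
      stop("nuisance regression enabled but no nuisance table given")
    x <- regress_nuisance(x, nuisance)
  }
  if (opts$bandpass)
    x <- bandpass(x, vol$tr_s, opts$band[1], opts$band[2])
  flat[sel, ] <- t(x)
  ts_volume(array(flat, d), vol$tr_s, vol$affine)
}
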