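#' Thresholded-correlation degree of masked voxel time series
#'
#' For every masked voxel i, counts the voxels j whose Pearson correlation
#' with i exceeds the threshold (strictly, positive correlations only):
#' the raw global FCD `g_raw(i) = #{ j != i : r_ij > threshold }`, and the
#' raw contralateral FCD `c_raw(i)`, the subset in the opposite hemisphere
#' (strictly opposite L/R labels; midline voxels neither give nor receive
#' contralateral connections).
#'
#' The computation is blockwise: correlations are evaluated panel by panel
#' so the full N x N matrix is never materialized, but every correlation is
#' the same standardized dot product, so the counts are independent of the
#' block size and identical to an exhaustive pairwise loop.
#'
#' @param x Numeric matrix, timepoints x N masked series. Every column must
#'   have nonzero variance (drop constant voxels from the mask first).
#' @param hemi Integer vector of N hemisphere codes (-1 left, 0 midline,
#'   +1 right), as stored in a [voxel_grid()].
#' @param threshold Correlation threshold; connections require a Pearson
#'   correlation strictly greater than it. Default 0.6, the conventional
#'   FCD cutoff.
#' @param block_size Number of voxels per computation panel.
#' @return List with integer vectors `g_raw` and `c_raw` of length N.
#' @export
correlation_degree <- function(x, hemi, threshold = 0.6, block_size = 512L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 voxels")
  if (length(hemi) != ncol(x))
    stop("hemi must have one label per column of x")
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)")
  ctr <- x - rep(colMeans(x), each = nrow(x))
  nrm <- sqrt(colSums(ctr^2))
  if (any(nrm == 0))
    stop("zero-variance series at voxel(s) ",
         paste(utils::head(which(nrm == 0), 5), collapse = ", "),
         "; remove constant voxels from the mask")
  z <- ctr / rep(nrm, each = nrow(x))
  .fcd_degree_blockwise(z, as.integer(hemi), threshold,
                        as.integer(block_size))
}

#' Ipsilateral FCD by decomposition
#'
#' The ipsilateral (same-hemisphere) degree is the total degree minus the
#' contralateral degree: `i_raw = g_raw - c_raw`, elementwise.
#'
#' @param g_raw,c_raw Non-negative integer vectors or arrays of equal
#'   shape, with `c_raw <= g_raw` everywhere.
#' @return `i_raw`, same shape as the inputs.
#' @export
fcd_decompose <- function(g_raw, c_raw) {
  if (!identical(dim(g_raw), dim(c_raw)) || length(g_raw) != length(c_raw))
    stop("g_raw and c_raw must have the same shape")
  if (any(c_raw > g_raw))
    stop("internal inconsistency: c_raw exceeds g_raw at ",
         sum(c_raw > g_raw), " voxel(s)")
  g_raw - c_raw
}

#' Normalize FCD maps by the subject's mean global FCD
#'
#' Divides each raw degree map by the subject's mean raw global FCD over
#' the gray-matter mask, so the mask average of the normalized global map
#' is exactly 1. This removes individual differences in overall
#' connectivity strength before group comparison.
#'
#' @param g_raw,c_raw,i_raw Raw degree vectors over the mask.
#' @return List with `g_norm`, `c_norm`, `i_norm`, and `mean_g` (the
#'   normalizer).
#' @export
normalize_fcd <- function(g_raw, c_raw, i_raw) {
  mean_g <- mean(g_raw)
  if (mean_g == 0)
    stop("mean global FCD is zero (no connections above threshold); ",
         "check the data or lower the threshold")
  list(g_norm = g_raw / mean_g, c_norm = c_raw / mean_g,
       i_norm = i_raw / mean_g, mean_g = mean_g)
}

#' Global, contralateral and ipsilateral FCD maps for one subject
#'
#' The central per-subject computation: extracts the masked time series
#' from a (preprocessed) 4D volume, drops zero-variance voxels from the
#' working mask with a warning, computes the thresholded-correlation
#' degree blockwise, decomposes it into contralateral and ipsilateral
#' parts, and normalizes all three maps by the subject's mean global FCD.
#' Voxels outside the working mask are 0 in every map.
#'
#' @param vol A (preprocessed) [ts_volume()] on the grid.
#' @param grid A [voxel_grid()].
#' @param threshold Correlation threshold (see [correlation_degree()]).
#' @param block_size Panel size for the blockwise computation.
#' @return Object of class `fcd_maps`: 3D arrays `g_raw`, `c_raw`, `i_raw`
#'   (integer counts), `g_norm`, `c_norm`, `i_norm`, plus `mean_g`, the
#'   working `mask`, and `n_dropped` (zero-variance voxels removed).
#' @export
fcd_maps <- function(vol, grid, threshold = 0.6, block_size = 512L) {
  stopifnot(inherits(vol, "ts_volume"), inherits(grid, "voxel_grid"))
  d <- dim(vol$data)
  if (!identical(d[1:3], grid$dim))
    stop("volume and grid dimensions differ")
  flat <- matrix(vol$data, prod(d[1:3]), d[4])
  sel <- which(grid$mask)
  x <- t(flat[sel, , drop = FALSE])
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance voxel(s) dropped from the working mask")
    keep <- v > 0
    sel <- sel[keep]
    x <- x[, keep, drop = FALSE]
  }
  deg <- correlation_degree(x, grid$hemi[sel], threshold, block_size)
  i_raw <- fcd_decompose(deg$g_raw, deg$c_raw)
  nrm <- normalize_fcd(deg$g_raw, deg$c_raw, i_raw)

  embed <- function(v, int = FALSE) {
    a <- array(if (int) 0L else 0, grid$dim)
    a[sel] <- v
    a
  }
  structure(
    list(g_raw = embed(deg$g_raw, TRUE), c_raw = embed(deg$c_raw, TRUE),
         i_raw = embed(i_raw, TRUE), g_norm = embed(nrm$g_norm),
         c_norm = embed(nrm$c_norm), i_norm = embed(nrm$i_norm),
         mean_g = nrm$mean_g,
         mask = embed(rep(TRUE, length(sel))) > 0,
         n_dropped = sum(v == 0)),
    class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat(sprintf("fcd_maps: %s grid, %d working voxels, mean gFCD %.2f\n",
              paste(dim(x$g_raw), collapse = " x "), sum(x$mask), x$mean_g))
  invisible(x)
}

#' Write the six FCD maps of a subject as NIfTI
#'
#' @param maps An [fcd_maps()] object.
#' @param grid The [voxel_grid()] of the analysis.
#' @param prefix Output path prefix; files are named
#'   `<prefix><measure>_<raw|norm>.nii.gz`.
#' @return Named vector of file paths, invisibly.
#' @export
write_fcd_maps <- function(maps, grid, prefix) {
  stopifnot(inherits(maps, "fcd_maps"))
  out <- character(0)
  for (m in c("g", "c", "i"))
    for (kind in c("raw", "norm")) {
      key <- paste0(m, "_", kind)
      f <- paste0(prefix, key, ".nii.gz")
      write_map_nifti(maps[[key]], grid, f)
      out[key] <- f
    }
  invisible(out)
}
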