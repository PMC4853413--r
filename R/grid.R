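#' Voxel grid: mask, hemisphere labels and world coordinates
#'
#' A `voxel_grid` is the shared spatial frame of all maps in an analysis: a
#' 3D gray-matter mask, the voxel-to-world affine, the world x-coordinate of
#' every voxel, and a hemisphere label derived from it. World coordinates
#' follow the RAS convention of MNI space: x < 0 is the left hemisphere,
#' x > 0 the right, and voxels with x exactly 0 are labelled midline.
#'
#' Hemisphere labels are stored as integers (-1 = left, 0 = midline,
#' +1 = right); `hemisphere_label()` converts them to `"L"`/`"M"`/`"R"`.
#'
#' @param mask 3D logical (or 0/1 numeric) array marking gray-matter voxels.
#' @param affine 4x4 voxel-index-to-world-mm matrix (0-based voxel indices,
#'   NIfTI convention). Must be invertible.
#' @return An object of class `voxel_grid`: a list with elements `mask`
#'   (3D logical), `dim`, `affine`, `world_x` (3D numeric, mm), `hemi`
#'   (3D integer, -1/0/+1), and `n_mask` (number of mask voxels).
#' @examples
#' g <- voxel_grid(array(TRUE, c(9, 8, 8)), affine_for_grid(c(9, 8, 8), 2))
#' table(hemisphere_label(g)[g$mask])
#' @export
voxel_grid <- function(mask, affine) {
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4, 4)
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  d <- dim(mask)
  # world x of voxel (i,j,k), 0-based indices per the NIfTI affine convention
  i0 <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j0 <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k0 <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  wx <- affine[1, 1] * i0 + affine[1, 2] * j0 + affine[1, 3] * k0 + affine[1, 4]
  world_x <- array(wx, d)
  hemi <- array(as.integer(sign(world_x)), d)
  structure(
    list(mask = mask, dim = d, affine = affine, world_x = world_x,
         hemi = hemi, n_mask = sum(mask)),
    class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
hemisphere_label <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  array(c("L", "M", "R")[grid$hemi + 2L], grid$dim)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dim, collapse = " x "),
      sprintf("(%d mask voxels: %d L / %d M / %d R)\n", x$n_mask,
              sum(x$hemi[x$mask] == -1L), sum(x$hemi[x$mask] == 0L),
              sum(x$hemi[x$mask] == 1L)))
  invisible(x)
}

#' Centered scaling affine for a synthetic grid
#'
#' Builds the voxel-to-world affine of an axis-aligned grid with isotropic
#' voxels, centered so the midline (world x = 0) falls on the central
#' sagittal plane: for an odd x-dimension that plane is a voxel plane, for an
#' even one it lies between the two central planes and no voxel has x = 0.
#'
#' @param dim Integer vector of 3 grid dimensions.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return A 4x4 affine matrix.
#' @export
affine_for_grid <- function(dim, voxel_size_mm) {
  stopifnot(length(dim) == 3L, all(dim >= 1), voxel_size_mm > 0)
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -voxel_size_mm * (dim - 1) / 2
  aff
}

#' Read a voxel grid from a NIfTI mask
#'
#' @param mask_file Path to a 3D NIfTI mask volume (non-zero = gray matter).
#' @return A [voxel_grid()].
#' @export
read_voxel_grid <- function(mask_file) {
  img <- RNifti::readNifti(mask_file)
  voxel_grid(array(as.array(img) != 0, dim(img)[1:3]),
             matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

# linear (1-based) array indices of an n x 3 matrix of 1-based voxel indices
.vox_linear <- function(vox, dim) {
  vox <- matrix(as.integer(vox), ncol = 3)
  if (any(vox < 1L) || any(vox[, 1] > dim[1]) || any(vox[, 2] > dim[2]) ||
      any(vox[, 3] > dim[3]))
    stop("voxel index outside the grid")
  as.integer(vox[, 1] + dim[1] * (vox[, 2] - 1L) + dim[1] * dim[2] * (vox[, 3] - 1L))
}

# mirror 1-based voxel indices across the central sagittal plane
.mirror_vox <- function(vox, dim) {
  vox <- matrix(as.integer(vox), ncol = 3)
  vox[, 1] <- dim[1] + 1L - vox[, 1]
  vox
}
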