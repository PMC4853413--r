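#' 4D BOLD time-series volume
#'
#' Container for one subject's 4D resting-state data: the intensity array,
#' the repetition time, and the voxel-to-world affine shared with the
#' analysis grid.
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 2.
#' @param tr_s Repetition time in seconds (> 0).
#' @param affine Invertible 4x4 voxel-index-to-world-mm matrix.
#' @return An object of class `ts_volume`.
#' @export
ts_volume <- function(data, tr_s, affine) {
  if (length(dim(data)) != 4L || dim(data)[4] < 2L)
    stop("data must be a 4D array with at least 2 timepoints")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a single positive number (seconds)")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(data = data, tr_s = tr_s, affine = affine),
            class = "ts_volume")
}

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ts_volume: %d x %d x %d voxels, %d timepoints, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

.as_nifti_with_affine <- function(data, affine, tr_s = NULL) {
  img <- RNifti::asNifti(data)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (!is.null(tr_s)) pd <- c(pd, tr_s)
  RNifti::pixdim(img) <- pd
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Read and write 4D BOLD volumes as NIfTI
#'
#' `write_ts_volume()` stores the array as float32 with the affine in the
#' qform/sform and the repetition time in `pixdim[4]`; `read_ts_volume()`
#' reconstructs the [ts_volume()] from those fields (an explicit `tr_s`
#' overrides the header).
#'
#' @param vol A [ts_volume()].
#' @param file Path to a `.nii` or `.nii.gz` file.
#' @param tr_s Optional repetition time override in seconds.
#' @return `read_ts_volume()` returns a [ts_volume()]; `write_ts_volume()`
#'   returns `file` invisibly.
#' @export
write_ts_volume <- function(vol, file) {
  stopifnot(inherits(vol, "ts_volume"))
  img <- .as_nifti_with_affine(vol$data, vol$affine, vol$tr_s)
  RNifti::writeNifti(img, file, datatype = "float")
  invisible(file)
}

#' @rdname write_ts_volume
#' @export
read_ts_volume <- function(file, tr_s = NULL) {
  img <- RNifti::readNifti(file)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI volume: ", file)
  if (is.null(tr_s)) {
    tr_s <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr_s) || tr_s <= 0)
      stop("no repetition time in the NIfTI header; pass tr_s explicitly")
  }
  ts_volume(array(as.numeric(img), d),
            tr_s = tr_s,
            affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write a 3D map (or mask) as NIfTI on a grid
#'
#' @param map 3D numeric or logical array.
#' @param grid A [voxel_grid()] supplying the affine.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_map_nifti <- function(map, grid, file) {
  stopifnot(inherits(grid, "voxel_grid"), length(dim(map)) == 3L)
  img <- .as_nifti_with_affine(array(as.numeric(map), dim(map)), grid$affine)
  RNifti::writeNifti(img, file, datatype = "float")
  invisible(file)
}

#' Read and write nuisance regressor tables
#'
#' TSV with one named column per regressor and one row per timepoint.
#'
#' @param nuisance Numeric matrix (timepoints x k).
#' @param file Path to a `.tsv` file.
#' @return `read_nuisance()` returns a numeric matrix with column names.
#' @export
write_nuisance <- function(nuisance, file) {
  write.table(as.data.frame(nuisance), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_nuisance
#' @export
read_nuisance <- function(file) {
  as.matrix(read.delim(file, check.names = FALSE))
}

#' Read and write cohort tables
#'
#' CSV with header `subject_id,group,age,sex,score` (additional columns are
#' preserved). `group` must contain only `"case"` and `"control"`.
#'
#' @param cohort Data frame with at least the columns above.
#' @param file Path to a `.csv` file.
#' @return `read_cohort()` returns a data frame.
#' @export
write_cohort <- function(cohort, file) {
  req <- c("subject_id", "group", "age", "sex", "score")
  if (!all(req %in% names(cohort)))
    stop("cohort table must have columns ", paste(req, collapse = ", "))
  write.csv(cohort[, c(req, setdiff(names(cohort), req))], file,
            row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  cohort <- read.csv(file, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex", "score")
  if (!all(req %in% names(cohort)))
    stop("cohort table must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(cohort$subject_id))
    stop("subject_id values must be unique")
  if (!all(cohort$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  cohort
}

#' Serialize a phantom specification to YAML
#'
#' @param spec A [phantom_spec()].
#' @param file Path to a `.yaml` file.
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, file) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$networks <- lapply(spec$networks, function(nw) {
    list(voxels = apply(nw$voxels, 1, function(v) as.list(as.integer(v)),
                        simplify = FALSE),
         coupling = nw$coupling, laterality = nw$laterality,
         group_effect = nw$group_effect, name = nw$name)
  })
  yaml::write_yaml(lst, file)
  invisible(file)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(file) {
  lst <- yaml::read_yaml(file)
  networks <- lapply(lst$networks, function(nw)
    network_spec(do.call(rbind, lapply(nw$voxels, unlist)),
                 coupling = nw$coupling, laterality = nw$laterality,
                 group_effect = nw$group_effect, name = nw$name))
  phantom_spec(grid_shape = unlist(lst$grid_shape),
               voxel_size_mm = lst$voxel_size_mm,
               networks = networks,
               n_timepoints = lst$n_timepoints,
               tr_s = lst$tr_s,
               noise_sd = lst$noise_sd,
               nuisance_k = lst$nuisance_k,
               nuisance_amplitude = lst$nuisance_amplitude,
               seed = lst$seed)
}

#' Write a simulated subject (volume + nuisance table) to disk
#'
#' @param subject Output of [simulate_subject()].
#' @param dir Output directory (created if needed).
#' @param id Subject identifier used as the file stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_phantom_subject <- function(subject, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bold <- file.path(dir, paste0(id, "_bold.nii.gz"))
  tsv <- file.path(dir, paste0(id, "_nuisance.tsv"))
  write_ts_volume(subject$volume, bold)
  write_nuisance(subject$nuisance, tsv)
  invisible(c(bold = bold, nuisance = tsv))
}
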