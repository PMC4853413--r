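#' Stream a cohort's FCD maps into matrices
#'
#' Simulates (or retrieves) each subject of a [simulate_cohort()] result,
#' optionally preprocesses it, computes its FCD maps, and collects the
#' masked values of the requested measures into subjects x voxels
#' matrices. Only the maps are kept, so large cohorts can be processed
#' without holding every 4D volume in memory (use
#' `keep_volumes = FALSE` in [simulate_cohort()]).
#'
#' @param cohort_obj A `phantom_cohort` from [simulate_cohort()].
#' @param measures Character vector among `g_raw`, `c_raw`, `i_raw`,
#'   `g_norm`, `c_norm`, `i_norm`.
#' @param threshold,block_size Passed to [fcd_maps()].
#' @param preprocess If `TRUE`, run [preprocess_subject()] (with
#'   `preprocess_options`) before the FCD computation.
#' @param preprocess_options Options list for [preprocess_subject()].
#' @return Named list of subjects x mask-voxels matrices, one per measure,
#'   with an attribute `mask_index` giving the linear voxel indices of the
#'   columns.
#' @export
cohort_fcd_matrix <- function(cohort_obj,
                              measures = c("g_norm", "c_norm", "i_norm"),
                              threshold = 0.6, block_size = 512L,
                              preprocess = FALSE,
                              preprocess_options = list()) {
  stopifnot(inherits(cohort_obj, "phantom_cohort"))
  grid <- cohort_obj$grid
  sel <- which(grid$mask)
  n <- nrow(cohort_obj$cohort)
  out <- lapply(measures, function(m) matrix(0, n, length(sel)))
  names(out) <- measures
  for (i in seq_len(n)) {
    sub <- cohort_subject(cohort_obj, i)
    vol <- sub$volume
    if (preprocess)
      vol <- preprocess_subject(vol, sub$nuisance, grid$mask,
                                preprocess_options)
    maps <- fcd_maps(vol, grid, threshold, block_size)
    for (m in measures) out[[m]][i, ] <- as.numeric(maps[[m]])[sel]
  }
  for (m in measures) attr(out[[m]], "mask_index") <- sel
  out
}

#' Group comparison of one FCD measure: GLM, FDR, clusters
#'
#' Convenience wrapper chaining [voxelwise_glm()], [fdr_correct()] and
#' [extract_clusters()] for one measure's per-subject maps.
#'
#' @param Y Subjects x mask-voxels matrix (e.g. one element of
#'   [cohort_fcd_matrix()]) or list of 3D maps.
#' @param cohort Cohort data frame (see [voxelwise_glm()]).
#' @param grid The analysis [voxel_grid()].
#' @param covariates Covariate columns, default age and sex.
#' @param q FDR level (default 0.05).
#' @param min_cluster_size Cluster extent threshold (default 20 voxels).
#' @param connectivity Cluster connectivity (default 18).
#' @return List with `stats` (a `stat_maps`), `sig_mask`, `p_corrected`
#'   (3D arrays) and `clusters` (a `cluster_table`).
#' @export
fcd_group_analysis <- function(Y, cohort, grid,
                               covariates = c("age", "sex"), q = 0.05,
                               min_cluster_size = 20, connectivity = 18) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(Y)) {
    sel <- attr(Y, "mask_index")
    if (is.null(sel)) sel <- which(grid$mask)
    stats <- voxelwise_glm(Y, cohort, covariates = covariates)
    t_map <- array(0, grid$dim); t_map[sel] <- stats$t_map
    p_map <- array(1, grid$dim); p_map[sel] <- stats$p_map
    stats$t_map <- t_map; stats$p_map <- p_map; stats$mask <- grid$mask
  } else {
    stats <- voxelwise_glm(Y, cohort, mask = grid$mask,
                           covariates = covariates)
  }
  fdr <- fdr_correct(stats$p_map, grid$mask, q)
  clusters <- extract_clusters(fdr$sig_mask, stats$t_map, grid,
                               min_cluster_size, connectivity)
  list(stats = stats, sig_mask = fdr$sig_mask,
       p_corrected = fdr$p_corrected, clusters = clusters)
}

.default_config <- function() {
  list(threshold = 0.6, band = c(0.01, 0.08), fwhm_mm = 0, q = 0.05,
       min_cluster_size = 20, connectivity = 18, seed = 1,
       measures = c("g_norm", "c_norm", "i_norm"),
       covariates = c("age", "sex"), score_col = "score",
       preprocess = TRUE, block_size = 512)
}

#' Run the full FCD workflow from a configuration
#'
#' Executes simulate (optional) -> preprocess -> FCD -> group comparison
#' -> clinical correlation, writing all artifacts (NIfTI maps, TSV/CSV
#' tables) plus a machine-readable JSON manifest with the effective
#' configuration, package version, seed and per-file MD5 checksums.
#' Re-running with the same configuration and seed reproduces identical
#' outputs.
#'
#' The configuration is a list (or path to a YAML file) with either a
#' `simulate` block (`spec`: a [phantom_spec()] or path to its YAML;
#' `n_case`, `n_control`, plus optional [simulate_cohort()] arguments), or
#' an `inputs` block (`data_dir` with `<subject_id>_bold.nii.gz` and
#' `<subject_id>_nuisance.tsv` files, `mask`: mask NIfTI path, `cohort`:
#' cohort CSV path). Analysis parameters (`threshold` 0.6, `band`
#' 0.01-0.08 Hz, `fwhm_mm` 0, `q` 0.05, `min_cluster_size` 20,
#' `connectivity` 18) default to the conventional values.
#'
#' @param config List or YAML path as described above.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  note <- function(f) files[basename(f)] <<- f

  # --- resolve inputs (validate everything before computing) -------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    spec <- sim$spec
    if (is.character(spec)) spec <- read_phantom_spec(spec)
    if (!inherits(spec, "phantom_spec"))
      stop("config$simulate$spec must be a phantom_spec or a YAML path")
    grid <- make_phantom_grid(spec)
    co <- simulate_cohort(grid, spec, n_case = sim$n_case,
                          n_control = sim$n_control,
                          score_model = if (is.null(sim$score_model))
                            list(alpha = 10, beta = -2, noise_sd = 1) else
                              sim$score_model,
                          subject_jitter = if (is.null(sim$subject_jitter))
                            0.2 else sim$subject_jitter,
                          seed = cfg$seed, keep_volumes = FALSE)
    sim_dir <- file.path(out_dir, "sim")
    dir.create(sim_dir, showWarnings = FALSE)
    note(write_cohort(co$cohort, file.path(sim_dir, "cohort.csv")))
    note(write_map_nifti(grid$mask, grid, file.path(sim_dir, "mask.nii.gz")))
    cohort <- co$cohort
    get_subject <- function(i) cohort_subject(co, i)
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    for (f in c(inp$mask, inp$cohort))
      if (!file.exists(f)) stop("input file does not exist: ", f)
    grid <- read_voxel_grid(inp$mask)
    cohort <- read_cohort(inp$cohort)
    bold <- file.path(inp$data_dir, paste0(cohort$subject_id, "_bold.nii.gz"))
    nuis <- file.path(inp$data_dir,
                      paste0(cohort$subject_id, "_nuisance.tsv"))
    missing <- c(bold, nuis)[!file.exists(c(bold, nuis))]
    if (length(missing))
      stop("missing subject files: ", paste(missing, collapse = ", "))
    get_subject <- function(i)
      list(volume = read_ts_volume(bold[i], tr_s = cfg$tr_s),
           nuisance = read_nuisance(nuis[i]))
  } else stop("config must contain a 'simulate' or an 'inputs' block")

  # --- per-subject: preprocess + FCD -------------------------------------
  sel <- which(grid$mask)
  n <- nrow(cohort)
  fcd_dir <- file.path(out_dir, "fcd")
  dir.create(fcd_dir, showWarnings = FALSE)
  Y <- lapply(cfg$measures, function(m) matrix(0, n, length(sel)))
  names(Y) <- cfg$measures
  popts <- list(band = cfg$band, fwhm_mm = cfg$fwhm_mm)
  for (i in seq_len(n)) {
    message("[fcdmap] subject ", cohort$subject_id[i], " (", i, "/", n, ")")
    sub <- get_subject(i)
    vol <- sub$volume
    if (isTRUE(cfg$preprocess))
      vol <- preprocess_subject(vol, sub$nuisance, grid$mask, popts)
    maps <- tryCatch(
      fcd_maps(vol, grid, cfg$threshold, cfg$block_size),
      error = function(e) stop("stage fcd failed for subject ",
                               cohort$subject_id[i], ": ",
                               conditionMessage(e)))
    for (m in cfg$measures) Y[[m]][i, ] <- as.numeric(maps[[m]])[sel]
    for (f in write_fcd_maps(maps, grid,
                             file.path(fcd_dir,
                                       paste0(cohort$subject_id[i], "_"))))
      note(f)
  }

  # --- group comparison per measure --------------------------------------
  grp_dir <- file.path(out_dir, "group")
  dir.create(grp_dir, showWarnings = FALSE)
  analyses <- list()
  for (m in cfg$measures) {
    Ym <- Y[[m]]; attr(Ym, "mask_index") <- sel
    an <- fcd_group_analysis(Ym, cohort, grid, cfg$covariates, cfg$q,
                             cfg$min_cluster_size, cfg$connectivity)
    analyses[[m]] <- an
    pre <- file.path(grp_dir, m)
    note(write_map_nifti(an$stats$t_map, grid, paste0(pre, "_t.nii.gz")))
    note(write_map_nifti(an$stats$p_map, grid, paste0(pre, "_p.nii.gz")))
    note(write_map_nifti(an$p_corrected, grid, paste0(pre, "_padj.nii.gz")))
    note(write_map_nifti(an$sig_mask, grid, paste0(pre, "_sig.nii.gz")))
    ctab <- as.data.frame(an$clusters)
    f <- paste0(pre, "_clusters.tsv")
    write.table(ctab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
  }
  if (all(c("g_norm", "c_norm", "i_norm") %in% names(analyses))) {
    ov <- overlap_map(analyses$g_norm$sig_mask, analyses$c_norm$sig_mask,
                      analyses$i_norm$sig_mask)
    note(write_map_nifti(ov$count, grid,
                         file.path(grp_dir, "overlap.nii.gz")))
  }

  # --- clinical correlations over surviving clusters ----------------------
  report <- NULL
  if (cfg$score_col %in% names(cohort) &&
      any(!is.na(cohort[[cfg$score_col]]))) {
    summaries <- list()
    for (m in names(analyses)) {
      members <- attr(analyses[[m]]$clusters, "members")
      for (r in seq_along(members)) {
        vals <- Y[[m]][, match(members[[r]], sel), drop = FALSE]
        summaries[[sprintf("%s_cluster%d", m, r)]] <- rowMeans(vals)
      }
    }
    if (length(summaries)) {
      report <- correlate_clinical(summaries, cohort, cfg$score_col,
                                   cfg$covariates)
      f <- file.path(out_dir, "clinical_correlations.tsv")
      write.table(report, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note(f)
    }
  }

  manifest <- list(
    package = "fcdmap",
    version = as.character(utils::packageVersion("fcdmap")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("simulate", "inputs"))],
    checksums = {
      cs <- tools::md5sum(unname(files))
      names(cs) <- sub(paste0("^", normalizePath(out_dir), "/"), "",
                       normalizePath(names(cs)))
      as.list(cs)
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
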