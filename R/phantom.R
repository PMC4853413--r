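#' Specify a latent network for a phantom brain
#'
#' Networks are the planted ground truth of a phantom: every voxel of a
#' network shares one latent unit-variance white-noise signal, so the
#' expected Pearson correlation between two member voxels equals the
#' coupling weight `w` (time series `x_v = sqrt(w) z + sqrt(1-w) e_v` with
#' independent unit-variance `z` and `e_v`).
#'
#' For a `"homotopic"` network, `voxels` gives the member set of one
#' hemisphere; the mirrored set across the midline is added automatically
#' and shares the same latent signal, emulating bilateral resting-state
#' networks. Unilateral networks must lie entirely in the named hemisphere.
#'
#' @param voxels n x 3 matrix of 1-based voxel indices.
#' @param coupling Coupling weight in `[0, 1)`: the fraction of each member
#'   voxel's variance carried by the shared latent signal.
#' @param laterality One of `"unilateral-left"`, `"unilateral-right"`,
#'   `"homotopic"`.
#' @param group_effect Multiplier applied to `coupling` for subjects in
#'   group `"case"`; values below 1 plant group-level under-connectivity.
#' @param name Optional network name.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(voxels,
                         coupling,
                         laterality = c("unilateral-left", "unilateral-right",
                                        "homotopic"),
                         group_effect = 1,
                         name = NULL) {
  laterality <- match.arg(laterality)
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) < 1L) stop("network has no voxels")
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      coupling < 0 || coupling >= 1)
    stop("coupling must be a single value in [0, 1)")
  if (!is.numeric(group_effect) || group_effect < 0)
    stop("group_effect must be a non-negative multiplier")
  structure(
    list(voxels = voxels, coupling = coupling, laterality = laterality,
         group_effect = group_effect, name = name),
    class = "network_spec")
}

#' Specify a phantom brain
#'
#' A `phantom_spec` bundles everything needed to generate synthetic
#' resting-state subjects with known connectivity structure: grid geometry,
#' planted networks, sampling parameters and noise levels.
#'
#' Nuisance regressors (head-motion-like signals plus tissue/global
#' signals) are always simulated and returned with every subject so the
#' nuisance-regression stage can be exercised; `nuisance_amplitude`
#' controls how strongly they contaminate the voxel time series and
#' defaults to 0 so that the closed-form within-network correlation of the
#' latent model holds exactly.
#'
#' @param grid_shape Integer vector of 3 grid dimensions (all >= 4).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param networks List of [network_spec()] objects.
#' @param n_timepoints Number of volumes (>= 50 for simulation).
#' @param tr_s Repetition time in seconds.
#' @param noise_sd Overall amplitude scale of the simulated BOLD series
#'   (applied to signal and noise alike, so correlations are unaffected).
#' @param nuisance_k Number of simulated nuisance regressors.
#' @param nuisance_amplitude Amplitude with which each nuisance regressor is
#'   added to every voxel's series.
#' @param seed Default random seed used when none is given explicitly.
#' @return An object of class `phantom_spec`.
#' @examples
#' net <- network_spec(cbind(2:4, 3, 3), coupling = 0.8,
#'                     laterality = "homotopic")
#' spec <- phantom_spec(c(9, 6, 6), networks = list(net))
#' grid <- make_phantom_grid(spec)
#' sub <- simulate_subject(grid, spec, group = "control", seed = 1)
#' dim(sub$volume$data)
#' @export
phantom_spec <- function(grid_shape,
                         voxel_size_mm = 2,
                         networks = list(),
                         n_timepoints = 200,
                         tr_s = 2,
                         noise_sd = 1,
                         nuisance_k = 4,
                         nuisance_amplitude = 0,
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be 3 integers, all >= 4")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (tr_s <= 0) stop("tr_s must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (nuisance_k < 0) stop("nuisance_k must be non-negative")
  if (nuisance_amplitude < 0) stop("nuisance_amplitude must be non-negative")
  if (!all(vapply(networks, inherits, logical(1), "network_spec")))
    stop("networks must be a list of network_spec objects")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         networks = networks, n_timepoints = as.integer(n_timepoints),
         tr_s = tr_s, noise_sd = noise_sd, nuisance_k = as.integer(nuisance_k),
         nuisance_amplitude = nuisance_amplitude, seed = as.integer(seed)),
    class = "phantom_spec")
}

# resolve each network to linear voxel indices on the grid, expanding
# homotopic networks with their mirrored set, and validate the invariants
# (inside the mask, pairwise disjoint, laterality consistent with hemisphere)
.resolve_networks <- function(spec, grid) {
  d <- grid$dim
  out <- vector("list", length(spec$networks))
  for (k in seq_along(spec$networks)) {
    nw <- spec$networks[[k]]
    vox <- nw$voxels
    lin <- .vox_linear(vox, d)
    hemi <- grid$hemi[lin]
    if (nw$laterality == "homotopic") {
      if (any(hemi == 0L))
        stop("homotopic network ", k, " contains midline voxels")
      mlin <- .vox_linear(.mirror_vox(vox, d), d)
      if (any(mlin %in% lin))
        stop("homotopic network ", k, " overlaps its own mirror image")
      members <- c(lin, mlin)
    } else {
      want <- if (nw$laterality == "unilateral-left") -1L else 1L
      if (any(hemi != want))
        stop("network ", k, " has voxels outside the ",
             if (want == -1L) "left" else "right", " hemisphere")
      members <- lin
    }
    if (!all(grid$mask[members]))
      stop("network ", k, " has voxels outside the gray-matter mask")
    out[[k]] <- list(members = members, coupling = nw$coupling,
                     group_effect = nw$group_effect,
                     name = if (is.null(nw$name)) paste0("net", k) else nw$name)
  }
  all_members <- unlist(lapply(out, `[[`, "members"))
  if (anyDuplicated(all_members))
    stop("networks are not pairwise disjoint voxel sets")
  out
}

#' Build the voxel grid of a phantom
#'
#' Constructs the grid implied by a [phantom_spec()]: an all-gray-matter
#' mask on the requested shape, with the world x origin centered so the
#' midline falls on the central sagittal plane (a voxel plane when the
#' x-dimension is odd). Validates that all planted networks fit the grid.
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_grid()].
#' @export
make_phantom_grid <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- voxel_grid(array(TRUE, spec$grid_shape),
                     affine_for_grid(spec$grid_shape, spec$voxel_size_mm))
  .resolve_networks(spec, grid)  # errors if the grid cannot host the networks
  grid
}

#' Linear voxel indices of a planted network
#'
#' Resolves one network of a [phantom_spec()] to linear array indices on
#' the grid, including the mirrored half of a homotopic network — the
#' ground-truth region for recovery checks and regional summaries.
#'
#' @param grid A [voxel_grid()].
#' @param spec A [phantom_spec()].
#' @param k Network index.
#' @return Integer vector of linear voxel indices.
#' @export
network_members <- function(grid, spec, k = 1L) {
  nets <- .resolve_networks(spec, grid)
  if (k < 1L || k > length(nets)) stop("no network with index ", k)
  nets[[k]]$members
}

#' Simulate one phantom subject
#'
#' Generates a 4D BOLD volume under the additive latent-signal model: a
#' voxel in network `k` with effective coupling `w` has series
#' `noise_sd * (sqrt(w) z_k(t) + sqrt(1-w) e_v(t))` with independent
#' unit-variance Gaussian white `z_k`, `e_v`; voxels in no network are pure
#' noise. For group `"case"` each network's coupling is multiplied by its
#' `group_effect`; `multiplier` adds subject-level coupling individuality
#' on top (used by [simulate_cohort()]). Effective couplings are clamped to
#' `[0, 0.97]`. Nuisance regressors are white Gaussian series added to
#' every voxel with amplitude `spec$nuisance_amplitude`.
#'
#' @param grid A [voxel_grid()] from [make_phantom_grid()].
#' @param spec A [phantom_spec()].
#' @param group `"control"` or `"case"`.
#' @param seed Integer seed; the output is deterministic given
#'   (spec, group, seed, multiplier).
#' @param multiplier Subject-level multiplier applied to every network's
#'   coupling (scalar, or one value per network).
#' @return A list with elements `volume` (a [ts_volume()]), `nuisance`
#'   (timepoints x k matrix with named columns), and `coupling` (named
#'   vector of effective per-network couplings used).
#' @export
simulate_subject <- function(grid, spec, group = c("control", "case"),
                             seed = spec$seed, multiplier = 1) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(spec, "phantom_spec"))
  group <- match.arg(group)
  if (spec$n_timepoints < 50L)
    stop("n_timepoints must be >= 50 for simulation")
  networks <- .resolve_networks(spec, grid)
  if (length(multiplier) == 1L)
    multiplier <- rep(multiplier, length(networks))
  if (length(multiplier) != length(networks))
    stop("multiplier must be scalar or one value per network")

  set.seed(seed)
  T <- spec$n_timepoints
  P <- prod(grid$dim)
  # voxel noise for the whole grid, then network voxels get the shared
  # latent signal mixed in; draw order is fixed so output is reproducible
  X <- matrix(rnorm(as.double(T) * P), T, P)
  w_eff <- numeric(length(networks))
  for (k in seq_along(networks)) {
    nw <- networks[[k]]
    w <- nw$coupling * multiplier[k]
    if (group == "case") w <- w * nw$group_effect
    w <- min(max(w, 0), 0.97)
    w_eff[k] <- w
    z <- rnorm(T)
    X[, nw$members] <- sqrt(w) * z +
      sqrt(1 - w) * X[, nw$members, drop = FALSE]
  }
  nuis <- matrix(rnorm(T * spec$nuisance_k), T, spec$nuisance_k)
  colnames(nuis) <- if (spec$nuisance_k == 4L)
    c("motion", "wm", "csf", "global")
  else if (spec$nuisance_k > 0L) paste0("nuis_", seq_len(spec$nuisance_k))
  if (spec$nuisance_k > 0L && spec$nuisance_amplitude > 0)
    X <- X + spec$nuisance_amplitude * rowSums(nuis)
  X <- spec$noise_sd * X

  vol <- ts_volume(array(t(X), c(grid$dim, T)), tr_s = spec$tr_s,
                   affine = grid$affine)
  names(w_eff) <- vapply(networks, `[[`, character(1), "name")
  list(volume = vol, nuisance = nuis, coupling = w_eff)
}

#' Simulate a phantom cohort with clinical scores
#'
#' Draws a cohort of case and control subjects over one [phantom_spec()].
#' Each subject `s` receives an individual coupling multiplier
#' `u_s ~ Uniform(1 - subject_jitter, 1 + subject_jitter)` applied to the
#' designated `score_network` (other networks keep multiplier 1, acting as
#' a stable connectivity background), and a clinical severity score
#' `score_s = alpha + beta * z(u_s) + Normal(0, noise_sd)`, where `z()`
#' standardizes the multipliers within the cohort; a negative `beta` plants
#' a negative association between that region's connectivity strength and
#' severity. Because per-subject normalization divides by the mean global
#' FCD, a score tied to whole-brain coupling would be cancelled by design;
#' tying it to one network against a fixed background is what makes the
#' association detectable in normalized maps, as regional effects are in
#' real data. Ages are Uniform(8, 30) years and sex is Bernoulli(0.85
#' male), so covariate adjustment is exercised downstream.
#'
#' @param grid,spec See [simulate_subject()].
#' @param n_case,n_control Group sizes (each >= 3).
#' @param score_model List with `alpha`, `beta`, `noise_sd`.
#' @param score_network Index of the network whose coupling the score
#'   tracks (default 1).
#' @param subject_jitter Half-width of the uniform subject-level coupling
#'   multiplier.
#' @param seed Integer seed; all cohort-level draws and per-subject volumes
#'   are deterministic given it.
#' @param keep_volumes If `FALSE`, subject volumes are not materialized;
#'   regenerate any subject with [cohort_subject()]. Useful when streaming
#'   large cohorts through [fcd_maps()].
#' @return A list of class `phantom_cohort`: `cohort` (data.frame with
#'   columns subject_id, group, age, sex, score, plus seed and multiplier),
#'   `subjects` (list of [simulate_subject()] outputs, or `NULL`), and the
#'   `grid`/`spec` used.
#' @export
simulate_cohort <- function(grid, spec, n_case, n_control,
                            score_model = list(alpha = 10, beta = -2,
                                               noise_sd = 1),
                            score_network = 1L,
                            subject_jitter = 0.2,
                            seed = spec$seed,
                            keep_volumes = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(spec, "phantom_spec"))
  if (n_case < 3L || n_control < 3L)
    stop("need at least 3 subjects per group")
  if (subject_jitter < 0 || subject_jitter >= 1)
    stop("subject_jitter must be in [0, 1)")
  if (length(spec$networks) && (score_network < 1L ||
                                score_network > length(spec$networks)))
    stop("score_network must index one of the spec's networks")
  n <- n_case + n_control

  set.seed(seed)
  sub_seed <- sample.int(.Machine$integer.max - 1L, n)
  age <- runif(n, 8, 30)
  sex <- ifelse(rbinom(n, 1, 0.85) == 1L, "M", "F")
  u <- runif(n, 1 - subject_jitter, 1 + subject_jitter)
  zu <- if (sd(u) > 0) (u - mean(u)) / sd(u) else rep(0, n)
  score <- score_model$alpha + score_model$beta * zu +
    rnorm(n, 0, score_model$noise_sd)
  cohort <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    age = age, sex = sex, score = score,
    seed = sub_seed, multiplier = u,
    stringsAsFactors = FALSE)

  obj <- structure(list(cohort = cohort, subjects = NULL, grid = grid,
                        spec = spec,
                        score_network = as.integer(score_network)),
                   class = "phantom_cohort")
  if (keep_volumes)
    obj$subjects <- lapply(seq_len(n), function(i) cohort_subject(obj, i))
  obj
}

#' @rdname simulate_cohort
#' @param x A `phantom_cohort`.
#' @param i Subject row index.
#' @export
cohort_subject <- function(x, i) {
  stopifnot(inherits(x, "phantom_cohort"))
  if (!is.null(x$subjects)) return(x$subjects[[i]])
  mult <- rep(1, length(x$spec$networks))
  if (length(mult)) mult[x$score_network] <- x$cohort$multiplier[i]
  simulate_subject(x$grid, x$spec, group = x$cohort$group[i],
                   seed = x$cohort$seed[i],
                   multiplier = if (length(mult)) mult else 1)
}
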