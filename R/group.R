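#' Voxel-wise group comparison with covariates
#'
#' Fits, at every masked voxel, the linear model
#' `FCD ~ intercept + group + age + sex` by OLS and reports the two-tailed
#' t-statistic for the group coefficient. Group is coded control = 0,
#' case = 1, so a negative t means lower FCD in cases. Covariates that are
#' constant over the cohort are dropped with a warning. Voxels with zero
#' residual variance (e.g. a map identically zero in both groups) get
#' t = 0, p = 1 rather than NaN.
#'
#' @param maps List of per-subject 3D maps (same order as `cohort` rows),
#'   or a subjects x voxels matrix of masked values.
#' @param cohort Data frame with columns `group` (`"case"`/`"control"`)
#'   and any covariates used.
#' @param mask 3D logical array selecting analysis voxels (required when
#'   `maps` is a list of arrays).
#' @param covariates Character vector of cohort columns to adjust for;
#'   default `c("age", "sex")`. Use `character(0)` for the unadjusted
#'   two-sample comparison.
#' @return Object of class `stat_maps`: `t_map` and `p_map` (3D arrays
#'   when a mask was given, else vectors), `df` (residual degrees of
#'   freedom), and the `mask`.
#' @export
voxelwise_glm <- function(maps, cohort, mask = NULL,
                          covariates = c("age", "sex")) {
  if (is.list(maps) && !is.data.frame(maps)) {
    if (is.null(mask)) stop("mask is required when maps is a list of arrays")
    sel <- which(as.logical(mask))
    Y <- do.call(rbind, lapply(maps, function(m) as.numeric(m)[sel]))
  } else {
    Y <- as.matrix(maps)
    sel <- NULL
  }
  n <- nrow(Y)
  if (n != nrow(cohort))
    stop("number of maps (", n, ") must match cohort rows (", nrow(cohort), ")")
  if (!all(cohort$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (length(unique(cohort$group)) < 2L)
    stop("both groups must be non-empty")

  X <- cbind(`(intercept)` = rep(1, n),
             group = as.numeric(cohort$group == "case"))
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort table: ", cv)
    v <- cohort[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    if (var(v) == 0) {
      warning("covariate '", cv, "' is constant; dropped from the design")
      next
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  df <- n - p
  if (df < 1L) stop("not enough subjects for the design (df < 1)")

  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)          # p x V coefficients
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXinv["group", "group"] * sigma2)
  tv <- ifelse(se > 0, B["group", ] / se, 0)
  pv <- ifelse(se > 0, 2 * pt(-abs(tv), df), 1)

  if (!is.null(sel)) {
    t_map <- array(0, dim(mask)); t_map[sel] <- tv
    p_map <- array(1, dim(mask)); p_map[sel] <- pv
  } else {
    t_map <- tv; p_map <- pv
  }
  structure(list(t_map = t_map, p_map = p_map, df = df, mask = mask,
                 design = colnames(X)),
            class = "stat_maps")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving with the
#' input indexing and never smaller than the raw values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_correct <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Voxel-wise FDR thresholding of a p-map
#'
#' Applies the Benjamini-Hochberg step-up procedure over the masked voxels
#' and marks voxels with adjusted p below `q` as significant.
#'
#' @param p_map 3D array of two-tailed p-values (or a vector).
#' @param mask 3D logical analysis mask (ignored for vector input).
#' @param q FDR level, default 0.05.
#' @return List with `sig_mask` (same shape as input, logical) and
#'   `p_corrected` (adjusted p, 1 outside the mask).
#' @export
fdr_correct <- function(p_map, mask = NULL, q = 0.05) {
  if (is.null(mask)) {
    padj <- bh_correct(as.numeric(p_map))
    return(list(sig_mask = padj < q, p_corrected = padj))
  }
  sel <- which(as.logical(mask))
  padj <- bh_correct(as.numeric(p_map)[sel])
  pc <- array(1, dim(mask)); pc[sel] <- padj
  list(sig_mask = pc < q, p_corrected = pc)
}

# neighbor offsets for 6 / 18 / 26 connectivity in 3D
.neighbor_offsets <- function(connectivity) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(o))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  o[keep, , drop = FALSE]
}

#' Extract significant clusters with an extent threshold
#'
#' Labels connected components of the significance mask (18-neighbor
#' connectivity by default, the convention of SPM-style cluster reporting),
#' discards components below the minimum extent, and reports each
#' surviving cluster's size, peak |t| voxel and its world coordinates.
#'
#' @param sig_mask 3D logical array of significant voxels.
#' @param t_map 3D t-statistic array on the same grid.
#' @param grid [voxel_grid()] supplying the affine for world coordinates.
#' @param min_cluster_size Minimum voxels per cluster; default 20.
#' @param connectivity 6, 18 or 26; default 18.
#' @return Object of class `cluster_table`: a data frame with columns
#'   `label`, `size`, `peak_x`, `peak_y`, `peak_z` (mm), `peak_t`,
#'   `mean_t`; attributes `labels` (3D label array, 0 = background) and
#'   `members` (list of linear voxel indices per cluster). Zero rows when
#'   nothing survives.
#' @export
extract_clusters <- function(sig_mask, t_map, grid, min_cluster_size = 20,
                             connectivity = 18) {
  stopifnot(identical(dim(sig_mask), dim(t_map)),
            inherits(grid, "voxel_grid"),
            identical(dim(sig_mask), grid$dim))
  d <- dim(sig_mask)
  offs <- .neighbor_offsets(connectivity)
  labels <- array(0L, d)
  sig <- which(sig_mask)
  comp <- list()
  cur <- 0L
  for (v in sig) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    labels[v] <- cur
    members <- integer(0)
    while (length(queue)) {
      node <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, node)
      k0 <- (node - 1L) %/% (d[1] * d[2])
      j0 <- ((node - 1L) %/% d[1]) %% d[2]
      i0 <- (node - 1L) %% d[1]
      ni <- i0 + offs[, 1]; nj <- j0 + offs[, 2]; nk <- k0 + offs[, 3]
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      nb <- 1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok])
      nb <- nb[sig_mask[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
    comp[[cur]] <- sort(members)
  }

  keep <- which(lengths(comp) >= min_cluster_size)
  rows <- lapply(seq_along(keep), function(r) {
    members <- comp[[keep[r]]]
    peak <- members[which.max(abs(t_map[members]))]
    i <- (peak - 1L) %% d[1]
    j <- ((peak - 1L) %/% d[1]) %% d[2]
    k <- (peak - 1L) %/% (d[1] * d[2])
    w <- grid$affine %*% c(i, j, k, 1)
    data.frame(label = r, size = length(members),
               peak_x = w[1], peak_y = w[2], peak_z = w[3],
               peak_t = t_map[peak], mean_t = mean(t_map[members]))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), size = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0), peak_t = numeric(0),
               mean_t = numeric(0))
  relab <- array(0L, d)
  members <- comp[keep]
  for (r in seq_along(members)) relab[members[[r]]] <- r
  structure(tab, labels = relab, members = members,
            class = c("cluster_table", "data.frame"))
}

#' Overlap categories of three significance masks
#'
#' Counts, per voxel, in how many of the three FCD comparisons (global,
#' contralateral, ipsilateral) the voxel is significant, binned into
#' 3-way / 2-way / 1-way overlap categories.
#'
#' @param g_mask,c_mask,i_mask 3D logical significance masks on one grid.
#' @return List with `count` (3D integer array 0-3) and `category` (3D
#'   factor-coded integer: 0 none, 1 one measure, 2 any pair, 3 all three).
#' @export
overlap_map <- function(g_mask, c_mask, i_mask) {
  stopifnot(identical(dim(g_mask), dim(c_mask)),
            identical(dim(g_mask), dim(i_mask)))
  cnt <- array(as.integer(g_mask) + as.integer(c_mask) + as.integer(i_mask),
               dim(g_mask))
  list(count = cnt, category = cnt)
}

#' Regional FCD summaries per subject
#'
#' Mean or maximum of each subject's FCD map over a region's voxels, the
#' per-subject quantities entered into clinical correlations.
#'
#' @param maps List of per-subject 3D maps.
#' @param voxels Integer vector of linear voxel indices defining the
#'   region (e.g. a cluster's `members` attribute entry).
#' @param mode `"mean"` or `"max"`.
#' @param ids Optional subject identifiers.
#' @return Data frame with columns `subject_id` and `value`.
#' @export
regional_summary <- function(maps, voxels, mode = c("mean", "max"),
                             ids = NULL) {
  mode <- match.arg(mode)
  if (length(voxels) < 1L) stop("region is empty")
  f <- if (mode == "mean") mean else max
  vals <- vapply(maps, function(m) f(as.numeric(m)[voxels]), numeric(1))
  data.frame(subject_id = if (is.null(ids)) seq_along(maps) else ids,
             value = vals, stringsAsFactors = FALSE)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' regressing each on an intercept plus the covariates. With covariates
#' age and sex, `df = n - 4` (n complete cases minus two covariates minus
#' two), and the two-tailed p-value comes from
#' `t = rho * sqrt(df / (1 - rho^2))`. Incomplete cases are dropped
#' pairwise.
#'
#' @param x,y Numeric vectors of per-subject values.
#' @param covariates Data frame (or matrix) of covariates; character
#'   columns are coded as factors. May have zero columns, reducing to the
#'   plain Pearson correlation with `df = n - 2`.
#' @return List with `rho`, `p`, `df`, and `n` (complete cases used).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n0 <- length(x)
  if (length(y) != n0) stop("x and y must have equal length")
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_len(n0))
  covariates <- as.data.frame(covariates)
  C <- if (ncol(covariates))
    do.call(cbind, lapply(covariates, function(v)
      if (is.numeric(v)) v else as.numeric(factor(v)) - 1))
  else matrix(numeric(0), n0, 0)
  cc <- if (ncol(C)) complete.cases(x, y, C) else complete.cases(x, y)
  n <- sum(cc)
  k <- ncol(C)
  if (n < k + 3L) stop("not enough complete cases (", n, ")")
  X <- cbind(1, C[cc, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  dec <- qr(X)
  rx <- qr.resid(dec, x[cc])
  ry <- qr.resid(dec, y[cc])
  if (sd(rx) <= 1e-10 * max(1, sd(x[cc])) ||
      sd(ry) <= 1e-10 * max(1, sd(y[cc])))
    stop("residuals are constant; correlation undefined")
  rho <- cor(rx, ry)
  df <- n - 2L - k
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tt), df), df = df, n = n)
}

#' Clinical correlation report over regions
#'
#' Runs [partial_correlation()] between each region's per-subject FCD
#' summaries and a clinical score, controlling for covariates, then
#' applies the Benjamini-Hochberg correction across the tests.
#'
#' @param summaries Named list of per-subject value vectors (one per
#'   region/measure combination), all aligned with `cohort` rows.
#' @param cohort Cohort data frame containing `score_col` and the
#'   covariate columns.
#' @param score_col Name of the clinical score column.
#' @param covariates Covariate column names; default age and sex.
#' @return Data frame with columns `region`, `rho`, `df`, `n`, `p_raw`,
#'   `p_bh`.
#' @export
correlate_clinical <- function(summaries, cohort, score_col = "score",
                               covariates = c("age", "sex")) {
  if (!score_col %in% names(cohort))
    stop("score column not in cohort table: ", score_col)
  res <- lapply(names(summaries), function(nm) {
    pc <- partial_correlation(summaries[[nm]], cohort[[score_col]],
                              cohort[, covariates, drop = FALSE])
    data.frame(region = nm, rho = pc$rho, df = pc$df, n = pc$n,
               p_raw = pc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_correct(out$p_raw)
  out
}
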