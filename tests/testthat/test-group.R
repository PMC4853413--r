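test_that("GLM with no covariates reproduces the two-sample t-statistic", {
  set.seed(401)
  n1 <- 14; n2 <- 17
  cohort <- data.frame(group = rep(c("case", "control"), c(n1, n2)))
  Y <- matrix(rnorm((n1 + n2) * 50), n1 + n2, 50)
  res <- voxelwise_glm(Y, cohort, covariates = character(0))
  expect_equal(res$df, n1 + n2 - 2)
  for (v in c(1, 17, 50)) {
    tt <- t.test(Y[cohort$group == "case", v],
                 Y[cohort$group == "control", v], var.equal = TRUE)
    expect_equal(res$t_map[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_map[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0 and p = 1 everywhere", {
  maps <- matrix(rnorm(5 * 30), 5, 30)
  Y <- rbind(maps, maps)
  cohort <- data.frame(group = rep(c("case", "control"), each = 5),
                       age = rep(runif(5, 10, 20), 2),
                       sex = rep(c("M", "M", "F", "M", "M"), 2))
  res <- voxelwise_glm(Y, cohort)
  expect_equal(unname(res$t_map), rep(0, 30), tolerance = 1e-8)
  expect_equal(unname(res$p_map), rep(1, 30), tolerance = 1e-8)
  expect_equal(res$df, 10 - 4)
})

test_that("GLM adjusts for age and sex and drops constant covariates", {
  set.seed(402)
  n <- 40
  cohort <- data.frame(group = rep(c("case", "control"), each = n / 2),
                       age = runif(n, 8, 30),
                       sex = ifelse(rbinom(n, 1, 0.85) == 1, "M", "F"))
  # map driven purely by age: adjusting must remove the group effect that
  # an unadjusted comparison would see through an age imbalance
  cohort$age[cohort$group == "case"] <- cohort$age[cohort$group == "case"] + 10
  Y <- matrix(2 * cohort$age + rnorm(n, 0, 0.1), n, 1)
  adj <- voxelwise_glm(Y, cohort)
  unadj <- voxelwise_glm(Y, cohort, covariates = character(0))
  expect_lt(abs(adj$t_map[1]), 2.5)
  expect_gt(abs(unadj$t_map[1]), 5)
  expect_equal(adj$df, n - 4)
  cohort$sex <- "M"
  expect_warning(res <- voxelwise_glm(Y, cohort), "constant")
  expect_equal(res$df, n - 3)
})

test_that("zero-residual-variance voxels get t = 0, p = 1", {
  cohort <- data.frame(group = rep(c("case", "control"), each = 4))
  Y <- cbind(rep(0, 8), rnorm(8))
  res <- voxelwise_glm(Y, cohort, covariates = character(0))
  expect_equal(res$t_map[1], 0)
  expect_equal(res$p_map[1], 1)
})

test_that("Benjamini-Hochberg adjustment matches hand-worked examples", {
  expect_equal(bh_correct(0.037), 0.037)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  padj <- bh_correct(p)
  expect_true(all(padj >= p))
  expect_true(all(diff(padj[order(p)]) >= -1e-15))
  # step-up by hand at the two ends
  expect_equal(padj[1], min(p * 25 / seq_len(25)))
  expect_equal(padj[25], 0.986)
  expect_error(bh_correct(c(0.2, 1.4)), "0, 1")
})

test_that("voxel-level FDR thresholds the masked p-map", {
  mask <- array(TRUE, c(4, 1, 1))
  p <- array(c(0.01, 0.02, 0.03, 0.04), c(4, 1, 1))
  fdr <- fdr_correct(p, mask, q = 0.05)
  expect_equal(as.numeric(fdr$p_corrected), rep(0.04, 4))
  expect_true(all(fdr$sig_mask))
  # single masked voxel: corrected equals raw
  mask1 <- array(c(TRUE, FALSE, FALSE, FALSE), c(4, 1, 1))
  fdr1 <- fdr_correct(p, mask1, q = 0.05)
  expect_equal(fdr1$p_corrected[1, 1, 1], 0.01)
  expect_equal(sum(fdr1$sig_mask), 1)
  # all p = 1: nothing survives
  fdr0 <- fdr_correct(array(1, c(4, 1, 1)), mask, q = 0.05)
  expect_false(any(fdr0$sig_mask))
})

test_that("cluster extraction honors extent and 18-connectivity", {
  d <- c(10, 10, 10)
  grid <- voxel_grid(array(TRUE, d), affine_for_grid(d, 2))
  tmap <- array(0, d)
  # a full 3x3x3 cube survives the 20-voxel minimum
  cube <- array(FALSE, d); cube[2:4, 2:4, 2:4] <- TRUE
  tmap[cube] <- -5; tmap[3, 3, 3] <- -9
  ct <- extract_clusters(cube, tmap, grid)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$size, 27)
  expect_equal(ct$peak_t, -9)
  # peak world coordinate: voxel index 3 -> 0-based 2 -> world -9 + 2*2
  expect_equal(c(ct$peak_x, ct$peak_y, ct$peak_z), rep(-5, 3))
  # a 19-voxel blob is discarded by the printed minimum of 20
  blob <- array(FALSE, d); blob[2:4, 2:4, 2:3] <- TRUE
  blob[2, 2, 2] <- FALSE
  blob[5, 2:3, 2] <- TRUE
  expect_equal(sum(blob), 19)
  expect_equal(nrow(extract_clusters(blob, tmap, grid)), 0)
  # two voxels sharing only an edge: one cluster at 18-connectivity,
  # two at 6-connectivity
  pair <- array(FALSE, d); pair[5, 5, 5] <- TRUE; pair[6, 6, 5] <- TRUE
  t2 <- array(1, d)
  expect_equal(nrow(extract_clusters(pair, t2, grid, min_cluster_size = 1,
                                     connectivity = 18)), 1)
  expect_equal(nrow(extract_clusters(pair, t2, grid, min_cluster_size = 1,
                                     connectivity = 6)), 2)
  # corner-sharing voxels connect only at 26
  pair2 <- array(FALSE, d); pair2[5, 5, 5] <- TRUE; pair2[6, 6, 6] <- TRUE
  expect_equal(nrow(extract_clusters(pair2, t2, grid, min_cluster_size = 1,
                                     connectivity = 18)), 2)
  expect_equal(nrow(extract_clusters(pair2, t2, grid, min_cluster_size = 1,
                                     connectivity = 26)), 1)
  # sizes sum to the surviving voxel count; members partition the mask
  multi <- cube; multi[7:9, 7:9, 7:9] <- TRUE
  ctm <- extract_clusters(multi, tmap, grid, min_cluster_size = 1)
  expect_equal(sum(ctm$size), sum(multi))
  members <- attr(ctm, "members")
  expect_equal(sort(unlist(members)), which(multi))
})

test_that("overlap map bins voxels by how many measures flag them", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[1:3, , ] <- TRUE
  ov_same <- overlap_map(a, a, a)
  expect_true(all(ov_same$count[a] == 3))
  expect_true(all(ov_same$count[!a] == 0))
  b <- array(FALSE, d); b[4, , ] <- TRUE
  cc <- array(FALSE, d); cc[5, , ] <- TRUE
  ov_disj <- overlap_map(a, b, cc)
  expect_true(all(ov_disj$count[a | b | cc] == 1))
  expect_equal(sum(ov_disj$count > 0), sum(a) + sum(b) + sum(cc))
})

test_that("regional summaries behave for constant, singleton and max mode", {
  maps <- list(array(2, c(3, 3, 3)), array(5, c(3, 3, 3)))
  vox <- c(1, 5, 9)
  expect_equal(regional_summary(maps, vox, "mean")$value, c(2, 5))
  expect_equal(regional_summary(maps, vox, "max")$value, c(2, 5))
  set.seed(403)
  rnd <- list(array(rnorm(27), c(3, 3, 3)))
  expect_gte(regional_summary(rnd, vox, "max")$value,
             regional_summary(rnd, vox, "mean")$value)
  expect_equal(regional_summary(rnd, 13, "max")$value,
               regional_summary(rnd, 13, "mean")$value)
})

test_that("partial correlation residualizes, reduces, and counts df", {
  set.seed(404)
  n <- 30
  cov <- data.frame(age = runif(n, 8, 30), sex = rbinom(n, 1, 0.85))
  x <- rnorm(n)
  pc <- partial_correlation(x, x, cov)
  expect_equal(pc$rho, 1, tolerance = 1e-10)
  expect_equal(pc$df, n - 4)
  # no covariates: plain Pearson with df = n - 2
  y <- rnorm(n)
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$rho, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$df, n - 2)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  # a confound driving both variables is removed
  z <- rnorm(n)
  pc_conf <- partial_correlation(2 * cov$age + 0.2 * z,
                                 -3 * cov$age + 0.2 * rnorm(n), cov)
  expect_lt(abs(pc_conf$rho), 0.5)
  # pairwise-complete deletion: 221 complete cases give df = 217
  xx <- rnorm(240); yy <- rnorm(240)
  xx[1:10] <- NA; yy[232:240] <- NA
  cov2 <- data.frame(age = runif(240, 8, 30), sex = rbinom(240, 1, 0.85))
  pc2 <- partial_correlation(xx, yy, cov2)
  expect_equal(pc2$n, 221)
  expect_equal(pc2$df, 217)
  expect_error(partial_correlation(rep(1, n), y, cov), "constant")
})

test_that("clinical correlation report recovers a planted association", {
  set.seed(405)
  n <- 60
  cohort <- data.frame(age = runif(n, 8, 30),
                       sex = ifelse(rbinom(n, 1, 0.85) == 1, "M", "F"),
                       score = NA_real_)
  u <- runif(n, 0.8, 1.2)
  cohort$score <- 10 - 2 * scale(u)[, 1] + rnorm(n)
  summaries <- list(planted = 15 * u + rnorm(n, 0, 0.5),
                    null = rnorm(n))
  rep <- correlate_clinical(summaries, cohort)
  expect_lt(rep$rho[rep$region == "planted"], 0)
  expect_lt(rep$p_bh[rep$region == "planted"], 0.05)
  expect_gt(rep$p_raw[rep$region == "null"], 0.001)
  expect_true(all(rep$p_bh >= rep$p_raw))
  expect_true(all(rep$df == n - 4))
})
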