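test_that("odd-width grids put the midline on the central sagittal plane", {
  g <- voxel_grid(array(TRUE, c(9, 8, 8)), affine_for_grid(c(9, 8, 8), 2))
  expect_equal(unique(as.numeric(g$world_x[5, , ])), 0)
  lab <- hemisphere_label(g)
  expect_equal(sum(lab == "L"), 4 * 8 * 8)
  expect_equal(sum(lab == "R"), 4 * 8 * 8)
  expect_equal(sum(lab == "M"), 8 * 8)
})

test_that("even-width grids have no midline voxels and balanced hemispheres", {
  g <- voxel_grid(array(TRUE, c(8, 8, 8)), affine_for_grid(c(8, 8, 8), 2))
  expect_true(all(g$world_x != 0))
  expect_equal(sum(g$hemi == -1L), 4 * 8 * 8)
  expect_equal(sum(g$hemi == 1L), 4 * 8 * 8)
})

test_that("hemisphere labels partition the mask", {
  for (shape in list(c(9, 6, 6), c(8, 6, 6), c(11, 4, 7))) {
    g <- voxel_grid(array(TRUE, shape), affine_for_grid(shape, 3))
    counts <- table(factor(hemisphere_label(g)[g$mask],
                           levels = c("L", "M", "R")))
    expect_equal(sum(counts), g$n_mask)
    expect_equal(unname(counts["L"]), unname(counts["R"]))
  }
})

test_that("network validation enforces the grid invariants", {
  # voxels outside the grid
  expect_error(
    make_phantom_grid(phantom_spec(c(8, 8, 8), networks = list(
      network_spec(cbind(9, 1, 1), 0.5, "unilateral-right")))),
    "outside the grid")
  # unilateral network in the wrong hemisphere (x index 6 of 8 is right)
  expect_error(
    make_phantom_grid(phantom_spec(c(8, 8, 8), networks = list(
      network_spec(cbind(6, 2, 2), 0.5, "unilateral-left")))),
    "left hemisphere")
  # homotopic network touching the midline plane of an odd grid
  expect_error(
    make_phantom_grid(phantom_spec(c(9, 8, 8), networks = list(
      network_spec(cbind(5, 2, 2), 0.5, "homotopic")))),
    "midline")
  # overlapping networks are rejected
  expect_error(
    make_phantom_grid(phantom_spec(c(8, 8, 8), networks = list(
      network_spec(cbind(2, 2, 2), 0.5, "unilateral-left"),
      network_spec(cbind(2:3, 2, 2), 0.5, "unilateral-left")))),
    "disjoint")
  # voxels outside the gray-matter mask
  spec <- phantom_spec(c(8, 8, 8), networks = list(
    network_spec(cbind(2, 2, 2), 0.5, "unilateral-left")))
  mask <- array(TRUE, c(8, 8, 8)); mask[2, 2, 2] <- FALSE
  grid <- voxel_grid(mask, affine_for_grid(c(8, 8, 8), 2))
  expect_error(simulate_subject(grid, spec, "control", seed = 1),
               "outside the gray-matter mask")
})

test_that("simulation is bit-identical under a fixed seed", {
  h <- homotopic_spec(m = 5, n_timepoints = 60)
  a <- simulate_subject(h$grid, h$spec, "case", seed = 42)
  b <- simulate_subject(h$grid, h$spec, "case", seed = 42)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$nuisance, b$nuisance)
  d <- simulate_subject(h$grid, h$spec, "case", seed = 43)
  expect_false(identical(a$volume$data, d$volume$data))
})

test_that("within-network correlation converges to the coupling weight", {
  h <- homotopic_spec(m = 8, w = 0.8, n_timepoints = 2000)
  sub <- simulate_subject(h$grid, h$spec, "control", seed = 3)
  flat <- matrix(sub$volume$data, prod(h$grid$dim), 2000)
  x <- t(flat[h$members, ])
  cm <- cor(x)
  rbar <- mean(cm[upper.tri(cm)])
  expect_lt(abs(rbar - 0.8), 0.05)
})

test_that("zero coupling yields an independent-noise null with no degree", {
  h <- homotopic_spec(m = 10, w = 0, n_timepoints = 200)
  sub <- simulate_subject(h$grid, h$spec, "control", seed = 11)
  flat <- matrix(sub$volume$data, prod(h$grid$dim), 200)
  deg <- correlation_degree(t(flat[h$grid$mask, ]),
                            h$grid$hemi[h$grid$mask])
  expect_lt(mean(deg$g_raw), 0.5)
  # a fully disconnected brain cannot be normalized: explicit error
  if (all(deg$g_raw == 0L))
    expect_error(fcd_maps(sub$volume, h$grid), "threshold")
})

test_that("group_effect scales the case coupling and jitter individualizes it", {
  h <- homotopic_spec(m = 5, w = 0.8, group_effect = 0.5, n_timepoints = 60)
  ctrl <- simulate_subject(h$grid, h$spec, "control", seed = 1)
  case <- simulate_subject(h$grid, h$spec, "case", seed = 1)
  expect_equal(unname(ctrl$coupling), 0.8)
  expect_equal(unname(case$coupling), 0.4)
  jit <- simulate_subject(h$grid, h$spec, "case", seed = 1, multiplier = 0.9)
  expect_equal(unname(jit$coupling), 0.8 * 0.9 * 0.5)
})

test_that("cohort tables carry planted scores of the right sign", {
  h <- homotopic_spec(m = 5, n_timepoints = 60)
  # |beta| / noise_sd = 2: the score-multiplier correlation has the planted
  # (negative) sign in every one of 10 replicate cohorts
  signs <- vapply(1:10, function(s) {
    co <- simulate_cohort(h$grid, h$spec, n_case = 10, n_control = 10,
                          score_model = list(alpha = 10, beta = -2,
                                             noise_sd = 1),
                          seed = s, keep_volumes = FALSE)
    cor(co$cohort$score, co$cohort$multiplier)
  }, numeric(1))
  expect_true(all(signs < 0))
  # beta = 0 leaves scores unrelated to coupling on average
  co0 <- simulate_cohort(h$grid, h$spec, 50, 50,
                         score_model = list(alpha = 10, beta = 0,
                                            noise_sd = 1),
                         seed = 5, keep_volumes = FALSE)
  expect_lt(abs(cor(co0$cohort$score, co0$cohort$multiplier)), 0.3)
  expect_identical(colnames(co0$cohort)[1:5],
                   c("subject_id", "group", "age", "sex", "score"))
  expect_true(all(co0$cohort$age >= 8 & co0$cohort$age <= 30))
})

test_that("cohort volumes round-trip through disk formats", {
  h <- homotopic_spec(m = 4, n_timepoints = 60)
  co <- simulate_cohort(h$grid, h$spec, 3, 3, seed = 2, keep_volumes = FALSE)
  sub <- cohort_subject(co, 2)
  dir <- withr::local_tempdir()
  files <- write_phantom_subject(sub, dir, "sub002")
  vol <- read_ts_volume(files["bold"])
  expect_equal(dim(vol$data), dim(sub$volume$data))
  expect_equal(vol$tr_s, sub$volume$tr_s)
  expect_equal(vol$data, sub$volume$data, tolerance = 1e-6) # float32 storage
  expect_equal(vol$affine, sub$volume$affine, tolerance = 1e-6)
  nuis <- read_nuisance(files["nuisance"])
  expect_equal(dim(nuis), dim(sub$nuisance))
  cf <- file.path(dir, "cohort.csv")
  write_cohort(co$cohort, cf)
  expect_equal(read_cohort(cf)$score, co$cohort$score, tolerance = 1e-12)
  sf <- file.path(dir, "spec.yaml")
  write_phantom_spec(h$spec, sf)
  spec2 <- read_phantom_spec(sf)
  s1 <- simulate_subject(h$grid, h$spec, "control", seed = 9)
  s2 <- simulate_subject(make_phantom_grid(spec2), spec2, "control", seed = 9)
  expect_identical(s1$volume$data, s2$volume$data)
})
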