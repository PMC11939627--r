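test_that("phantom generation is deterministic under a fixed seed", {
  a <- small_phantom(0, seed = 5)
  b <- small_phantom(0, seed = 5)
  for (k in c(1, 5, 9))
    expect_identical(a$series$volumes[[k]]$voxels, b$series$volumes[[k]]$voxels)
  expect_identical(a$peri_mask$voxels, b$peri_mask$voxels)
  expect_identical(a$centerline$points, b$centerline$points)
  c2 <- small_phantom(0, seed = 6)
  expect_false(identical(a$series$volumes[[1]]$voxels,
                         c2$series$volumes[[1]]$voxels))
})

test_that("coupling limits behave as specified", {
  ph1 <- small_phantom(1)
  ep <- eatmotion:::mask_points(ph1$eat_mask)
  # kappa = 1: EAT outside the thin shear layer is locked to the (static)
  # pericardium, so true disparity magnitudes vanish there
  spec <- ph1$spec
  abar <- mean(spec$semi_axes)
  rho <- sqrt((ep[, 1] / spec$semi_axes[1])^2 + (ep[, 2] / spec$semi_axes[2])^2 +
                (ep[, 3] / spec$semi_axes[3])^2)
  beyond_slip <- rho > 1 + spec$slip_width / abar
  expect_gt(sum(beyond_slip), 0)
  for (k in c(1, 3, 8)) {
    u <- ph1$true_displacement(ep, k)
    expect_lt(max(abs(u[beyond_slip, ])), 1e-12)
  }
  # kappa = 0: EAT carries the planted cardiac motion (nonzero where the
  # contraction level differs from the reference)
  ph0 <- small_phantom(0)
  u0 <- ph0$true_displacement(eatmotion:::mask_points(ph0$eat_mask), 1)
  expect_gt(mean(sqrt(rowSums(u0^2))), 0.1)
})

test_that("ground-truth motion is cyclic and zero at the reference phase", {
  ph <- small_phantom(0)
  ep <- eatmotion:::mask_points(ph$eat_mask)[1:50, ]
  expect_equal(max(abs(ph$true_displacement(ep, 5))), 0)
  # positions over the cycle close exactly (displacements are w.r.t. reference)
  pos <- lapply(1:9, function(k) ep + ph$true_displacement(ep, k))
  deltas <- lapply(1:9, function(k) pos[[k]] - pos[[if (k == 1) 9 else k - 1]])
  expect_equal(max(abs(Reduce(`+`, deltas))), 0)
})

test_that("largest inter-phase contraction step is at the 90%->10% transition", {
  spec <- phantom_spec()
  prof <- spec$phase_profile
  steps <- abs(prof - prof[c(9, 1:8)])
  expect_equal(which.max(steps), 1L)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(coupling = 1.5), "coupling")
  expect_error(phantom_spec(semi_axes = c(60, 60, 60)), "boundary")
})

test_that("adhesion-pattern samples match exponential moments", {
  x <- generate_disparity_samples(5000, "adhesion", rate = 40, rng_seed = 1)
  expect_true(all(x >= 0 & x <= 1))
  # mean of Exp(40) is 1/40, sd 1/40: sample mean within 3 sd of the mean
  expect_lt(abs(mean(x) - 1 / 40), 3 * (1 / 40) / sqrt(5000))
})

test_that("non-adhesion samples peak between 0.45 and 0.65", {
  x <- generate_disparity_samples(5000, "non-adhesion", rng_seed = 2)
  expect_true(all(x >= 0 & x <= 1))
  h <- disparity_histogram(x, 100)
  mode_bin <- which.max(h$counts)
  expect_gte(mode_bin / 100, 0.45)
  expect_lte(mode_bin / 100, 0.65)
})

test_that("sample generation is seeded and warns when underpowered", {
  expect_identical(generate_disparity_samples(500, "adhesion", rng_seed = 3),
                   generate_disparity_samples(500, "adhesion", rng_seed = 3))
  expect_warning(generate_disparity_samples(50, "adhesion"), "insufficient")
})

test_that("cohort generation mirrors the 7 + 13 study design", {
  co <- generate_cohort(7, 13, n_samples = 500, base_seed = 0)
  expect_length(co, 20)
  expect_equal(sum(vapply(co, `[[`, character(1), "label") == "adhesion"), 7)
  co2 <- generate_cohort(7, 13, n_samples = 500, base_seed = 0)
  expect_identical(co, co2)
  small <- generate_cohort(1, 1, n_samples = 500)
  expect_length(small, 2)
})

test_that("phantom studies can be written to and read from disk", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(dim = c(20, 20, 20), spacing = 4.5,
                                      semi_axes = c(18, 16, 22),
                                      eat_thickness = 7, rng_seed = 2))
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  ser <- read_phase_series(list.files(dir, "^phase_", full.names = TRUE))
  expect_equal(ser$volumes[[5]]$voxels, ref_volume(ph$series)$voxels,
               tolerance = 1e-6)
  m <- read_mask(file.path(dir, "pericardium_mask.nii.gz"))
  expect_identical(m$voxels, ph$peri_mask$voxels)
  cl <- read_centerline(file.path(dir, "centerline.json"))
  expect_equal(cl$points, ph$centerline$points, tolerance = 1e-9)
})
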