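test_that("phase series ordering, reference index and normalized times", {
  d <- c(6, 6, 6)
  aff <- rbind(cbind(diag(2, 3), c(-5, -5, -5)), c(0, 0, 0, 1))
  vols <- lapply(sample(seq(10, 90, 10)), function(p)
    ct_volume(array(p, d), aff, p))
  ser <- phase_series(vols, ref_phase = 50)
  expect_equal(vapply(ser$volumes, `[[`, integer(1), "phase_percent"),
               seq(10L, 90L, 10L))
  expect_equal(ser$ref_index, 5L)
  expect_equal(ser$normalized_times, (0:8) / 9)
  expect_equal(ser$normalized_times[1], 0)
  expect_true(all(diff(ser$normalized_times) > 0))
})

test_that("incomplete or incompatible series are rejected", {
  d <- c(4, 4, 4)
  vols <- lapply(seq(10, 80, 10), function(p) ct_volume(array(0, d), diag(4), p))
  expect_error(phase_series(vols), "incomplete")
  vols9 <- lapply(seq(10, 90, 10), function(p) ct_volume(array(0, d), diag(4), p))
  vols9[[3]] <- ct_volume(array(0, c(5, 4, 4)), diag(4), 30)
  expect_error(phase_series(vols9), "grid")
})

test_that("NIfTI round-trip preserves voxels exactly and affine to 1e-6 mm", {
  dir <- withr::local_tempdir()
  d <- c(8, 7, 6)
  aff <- rbind(cbind(diag(c(1.5, 2, 2.5)), c(-6, -7, -8)), c(0, 0, 0, 1))
  set.seed(1)
  paths <- character(9)
  arrs <- list()
  for (i in 1:9) {
    p <- i * 10
    arrs[[i]] <- array(rnorm(prod(d), -50, 100), d)
    paths[i] <- file.path(dir, sprintf("phase_%02d.nii.gz", p))
    write_nifti_volume(ct_volume(arrs[[i]], aff, p), paths[i])
  }
  ser <- read_phase_series(paths, ref_phase = 50)
  for (i in 1:9) {
    expect_equal(ser$volumes[[i]]$voxels, arrs[[i]], tolerance = 1e-6)
    expect_lt(max(abs(ser$volumes[[i]]$affine - aff)), 1e-6)
  }
  expect_equal(ser$ref_index, 5L)
  # masks round-trip too
  mp <- file.path(dir, "mask.nii.gz")
  m <- binary_mask(array(runif(prod(d)) > 0.5, d), aff, "pericardium")
  write_nifti_volume(m, mp)
  expect_identical(read_mask(mp)$voxels, m$voxels)
})

test_that("phase labels are parsed from file names", {
  dir <- withr::local_tempdir()
  d <- c(4, 4, 4)
  paths <- vapply(seq(10, 90, 10), function(p) {
    f <- file.path(dir, sprintf("study_phase%d.nii", p))
    write_nifti_volume(ct_volume(array(p, d), diag(4), p), f)
    f
  }, character(1))
  ser <- read_phase_series(sample(paths))
  expect_equal(ser$volumes[[1]]$voxels[1], 10)
  expect_equal(ser$volumes[[9]]$voxels[1], 90)
})

test_that("centerline arc lengths follow the cumulative-sum oracle", {
  cl <- centerline(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(cl$arclengths, c(0, 10))
  expect_equal(cl$length, 10)
  cl2 <- centerline(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(cl2$length, 5)
  # random polyline vs independent cumulative sum
  set.seed(42)
  pts <- matrix(rnorm(30, sd = 10), ncol = 3)
  cl3 <- centerline(pts)
  expected <- c(0, cumsum(vapply(2:10, function(i)
    sqrt(sum((pts[i, ] - pts[i - 1, ])^2)), numeric(1))))
  expect_equal(cl3$arclengths, expected)
  expect_equal(cl3$s_mid, cl3$length / 3)
  expect_equal(cl3$s_dist, 2 * cl3$length / 3)
})

test_that("degenerate centerlines error; duplicate points warn", {
  expect_error(centerline(matrix(c(1, 2, 3), ncol = 3)), "degenerate")
  pts <- rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 5), c(0, 0, 9))
  expect_warning(cl <- centerline(pts), "duplicated")
  expect_equal(cl$arclengths, c(0, 5, 5, 9))
})

test_that("centerline JSON and CSV readers agree", {
  dir <- withr::local_tempdir()
  pts <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(5, 5, 7))
  jp <- file.path(dir, "cl.json")
  write_centerline(centerline(pts, radius_r = 6), jp)
  clj <- read_centerline(jp)
  expect_equal(clj$points, pts)
  expect_equal(clj$radius_r, 6)
  cp <- file.path(dir, "cl.csv")
  write.csv(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]), cp,
            row.names = FALSE)
  clc <- read_centerline(cp)
  expect_equal(clc$arclengths, clj$arclengths)
})

test_that("report round-trips through JSON and CSV deterministically", {
  dir <- withr::local_tempdir()
  m <- adhesion_metrics(generate_disparity_samples(2000, "adhesion", rng_seed = 5))
  p1 <- file.path(dir, "rep1.json")
  p2 <- file.path(dir, "rep2.json")
  write_report(m, p1)
  write_report(m, p2)
  back <- read_report(p1)
  expect_equal(back$pr, m$pr)
  expect_equal(back$dwi, m$dwi)
  expect_identical(back$classification, m$classification)
  expect_identical(back$config$n_bins, m$config$n_bins)
  # same analysis -> byte-identical outputs
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(sub("json$", "csv", p1)),
                   readLines(sub("json$", "csv", p2)))
})

test_that("indeterminate classification is reported as such", {
  cfg <- adhesion_config()
  expect_identical(classify_adhesion(70, 0.35, cfg), "indeterminate")
  m <- adhesion_metrics(c(rep(0.005, 60), seq(0, 1, length.out = 40)))
  rep_path <- file.path(withr::local_tempdir(), "r.json")
  write_report(m, rep_path)
  expect_identical(read_report(rep_path)$classification, m$classification)
})

test_that("configuration validation and config file round-trip", {
  expect_error(adhesion_config(hu_low = -30, hu_high = -190))
  expect_error(adhesion_config(n_bins = 5))
  expect_error(adhesion_config(alpha_percent = 0))
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(hu_low = -150, n_bins = 50, alpha_percent = 20),
                       cfgp, auto_unbox = TRUE)
  cfg <- read_config(cfgp)
  expect_equal(cfg$hu_low, -150)
  expect_equal(cfg$n_bins, 50L)
  expect_equal(cfg$hu_high, -30)  # default retained
})
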