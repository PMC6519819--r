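# Dose-map container, I/O, rebinning, and the D_Rx / A_y% metrics.

test_that("dose map validation rejects bad input", {
  expect_error(dose_map(matrix(-1, 4, 4), 1), "non-negative")
  expect_error(dose_map(matrix(NaN, 4, 4), 1), "finite")
  expect_error(dose_map(matrix(1, 1, 4), 1), "2 x 2")
  expect_error(dose_map(matrix(1, 4, 4), 0), "pixel_size")
})

test_that("text-grid round trip is bit-identical", {
  set.seed(42)
  m <- dose_map(matrix(runif(48, 0, 200), 6, 8), pixel_size = 1.36,
                origin = c(-1.5, 2.25))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_map(m, path)
  m2 <- read_dose_map(path)
  expect_identical(m2$values, m$values)
  expect_identical(m2$pixel_size, m$pixel_size)
  expect_identical(m2$origin, m$origin)
})

test_that("malformed text grids are rejected with named fields", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("pixel_size_mm=1", "origin_cm=0,0", "units=cGy",
               "1 2", "3 -4"), path)
  expect_error(read_dose_map(path), "negative")
  writeLines(c("origin_cm=0,0", "units=cGy", "1 2", "3 4"), path)
  expect_error(read_dose_map(path), "pixel_size_mm")
})

test_that("image import converts dpi and gray levels via the sidecar", {
  skip_if_not_installed("png")
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  yaml::write_yaml(list(dpi = 75, cgy_per_value = 300), paste0(path, ".yml"))
  m <- read_dose_map(path, format = "image")
  expect_equal(m$pixel_size, 25.4 / 75, tolerance = 1e-3)
  expect_equal(m$pixel_size, 0.3387, tolerance = 1e-3)
  expect_equal(max(m$values), 300, tolerance = 1)
  # no sidecar -> explicit error
  file.remove(paste0(path, ".yml"))
  expect_error(read_dose_map(path, format = "image"), "sidecar")
})

test_that("rebinning block-averages and preserves the mean", {
  const <- dose_map(matrix(7, 8, 8), 1)
  expect_true(all(rebin(const, 2)$values == 7))

  checker <- dose_map(outer(1:8, 1:8, function(i, j) 100 * ((i + j) %% 2)), 1)
  expect_true(all(abs(rebin(checker, 2)$values - 50) < 1e-12))

  set.seed(7)
  m <- dose_map(matrix(runif(96 * 96, 0, 50), 96, 96), 0.5)
  r <- rebin(m, 1.5)
  expect_lt(abs(mean(r$values) - mean(m$values)) / mean(m$values), 1e-6)

  expect_error(rebin(m, 0.25), "upsampling")
})

test_that("rebinned smooth maps keep their circle averages", {
  m <- gaussian_spot_map(n = 128, pixel_size = 0.5, sigma_cm = 1.5)
  d0 <- mean_dose_in_circle(m, radius = 1)
  for (px in c(1.0, 1.36, 2.0)) {
    r <- rebin(m, px)
    expect_lt(abs(mean_dose_in_circle(r, radius = 1) - d0) / d0, 0.02)
  }
})

test_that("max_point finds the maximum with the row-major tie rule", {
  v <- matrix(0, 5, 5)
  v[3, 4] <- 9
  expect_equal(max_point(dose_map(v, 1)), c(3L, 4L))
  v[2, 2] <- 9  # tie: row 2 comes first in row-major order
  expect_equal(max_point(dose_map(v, 1)), c(2L, 2L))
  g <- gaussian_spot_map(center_px = c(20, 44))
  expect_true(all(abs(max_point(g) - c(20, 44)) <= 1))
})

test_that("circle averages equal the brute-force pixel oracle", {
  expect_equal(mean_dose_in_circle(dose_map(matrix(3.5, 16, 16), 1.36),
                                   c(8, 8), 1),
               3.5)
  # delta map: D spread over the n pixels the circle covers
  v <- matrix(0, 21, 21)
  v[11, 11] <- 120
  delta <- dose_map(v, 2)
  for (r in c(0.3, 0.5, 1.1)) {
    expect_equal(mean_dose_in_circle(delta, c(11, 11), r),
                 oracle_circle_mean(delta, c(11, 11), r))
  }
  set.seed(11)
  noisy <- dose_map(matrix(rexp(40 * 40, 1 / 30), 40, 40), 1.36)
  for (r in 1:4) {
    expect_identical(mean_dose_in_circle(noisy, c(20, 20), r),
                     oracle_circle_mean(noisy, c(20, 20), r))
  }
  expect_error(mean_dose_in_circle(noisy, c(20, 20), -1), "radius")
})

test_that("D_Rx profiles are monotone on single-spot maps", {
  g <- gaussian_spot_map()
  prof <- drx_profile(g)
  expect_equal(prof$radii, c(1, 2, 3, 4))
  expect_true(all(diff(prof$values) <= 0))
  # composition: one radius equals the direct circle mean
  single <- drx_profile(g, radii = 1)
  expect_equal(single$values, mean_dose_in_circle(g, max_point(g), 1))
  expect_error(drx_profile(g, radii = c(2, 1)), "increasing")
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$mean_dose_cGy, prof$values)
})

test_that("constant maps give the constant at every radius", {
  const <- dose_map(matrix(42, 30, 30), 1.36)
  expect_true(all(drx_profile(const)$values == 42))
})

test_that("isodose areas count suprathreshold pixels", {
  const <- dose_map(matrix(100, 10, 10), 1.36)
  expect_equal(isodose_area(const, 90), 100 * 0.136^2)
  expect_equal(isodose_area(const, 101), 0)

  # exactly 500 suprathreshold pixels at 1.36 mm
  v <- matrix(0, 40, 40)
  v[seq_len(500)] <- 50
  expect_equal(isodose_area(dose_map(v, 1.36), 10), 500 * 0.018496,
               tolerance = 1e-12)

  g <- gaussian_spot_map()
  thresholds <- seq(5, 95, by = 5)
  areas <- vapply(thresholds, function(t) isodose_area(g, t), numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_equal(isodose_area(g, 30), oracle_isodose_area(g, 30))
})

test_that("A_y% levels are non-increasing and match hand computation", {
  zero <- dose_map(matrix(0, 8, 8), 1.36)
  expect_true(all(isodose_areas(zero, 300)$area_cm2 == 0))

  g <- gaussian_spot_map(peak = 200)
  ia <- isodose_areas(g, prescription = 300)
  expect_equal(ia$level, c(0.3, 0.5, 0.7, 0.9, 1.0))
  expect_true(all(diff(ia$area_cm2) <= 0))

  # two-level step map, areas computable by hand
  v <- matrix(10, 10, 10)
  v[1:3, 1:10] <- 200
  step <- dose_map(v, 10)  # 1 cm pixels
  ia2 <- isodose_areas(step, prescription = 300, levels = c(0.3, 0.5))
  expect_equal(ia2$area_cm2, c(30, 30))
  expect_equal(isodose_area(step, 5), 100)
  expect_error(isodose_areas(g, 300, levels = c(0, 0.5)), "levels")
})

test_that("metrics are invariant under transposition", {
  set.seed(3)
  m <- dose_map(matrix(rexp(30 * 20, 1 / 40), 30, 20), 1.36)
  mt <- dose_map(t(m$values), 1.36)
  c0 <- max_point(m)
  expect_equal(max_point(mt), rev(c0))
  for (r in c(1, 2.5)) {
    expect_equal(mean_dose_in_circle(m, c0, r),
                 mean_dose_in_circle(mt, rev(c0), r))
  }
  expect_equal(isodose_area(m, 40), isodose_area(mt, 40))
})
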