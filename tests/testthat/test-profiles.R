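test_that("profile construction enforces the q-grid invariants", {
  expect_s3_class(saxs_profile(1:3, c(1, 2, 3)), "tbl_df")
  expect_error(saxs_profile(c(1, 1, 2), 1:3), class = "saxsqc_error_profile")
  expect_error(saxs_profile(c(-1, 1), 1:2), class = "saxsqc_error_profile")
  expect_error(saxs_profile(1:3, 1:3, sigma = c(1, -1, 1)),
               class = "saxsqc_error_profile")
})

test_that(".dat round trip preserves q, intensity and sigma", {
  p <- saxs_profile(seq(0.01, 1, 0.01), exp(-seq(0.01, 1, 0.01)),
                    sigma = rep(0.01, 100))
  path <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, path, comment = c("synthetic curve", "units arbitrary"))
  p2 <- read_profile(path)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
})

test_that("q map follows the flat-detector geometry", {
  g <- saxs_geometry(1, 1000, 1, center = c(100, 100))
  qm <- compute_q_map(g, c(201, 201))
  # beam center pixel
  expect_equal(qm[101, 101], 0)
  # closed form at 100 px from center: q = 4 pi sin(atan(0.1)/2)
  expect_equal(qm[101, 201], 4 * pi * sin(atan(0.1) / 2), tolerance = 1e-10)
  # mirror symmetry about the center
  expect_equal(qm[101, 1], qm[101, 201])
  expect_equal(qm[1, 101], qm[201, 101])
  # rotation by 90 degrees about the center leaves the map unchanged
  expect_equal(qm, t(qm))
  expect_error(saxs_geometry(-1, 1000, 1, c(0, 0)),
               class = "saxsqc_error_geometry")
})

test_that("pie-slice averaging recovers the generating radial curve", {
  g <- saxs_geometry(1, 10000, 1, center = c(100, 100))
  qm <- compute_q_map(g, c(201, 201))
  # uniform image -> constant profile
  pat_u <- saxs_pattern(matrix(7, 201, 201), g)
  q_grid <- seq(0.005, 0.05, by = 0.002)
  pr <- pie_slice_average(pat_u, 90, 10, q_grid)
  expect_true(all(pr$intensity[!pr$empty] == 7))
  # noiseless isotropic q^-2 pattern -> q^-2 within binning error
  img <- qm^-2
  img[!is.finite(img)] <- 0
  pat <- saxs_pattern(img, g)
  # bins narrow relative to q so the bin mean tracks the center value
  q_fine <- seq(0.012, 0.05, by = 0.002)
  pr2 <- pie_slice_average(pat, 90, 10, q_fine)
  keep <- !pr2$empty
  rel <- abs(pr2$intensity[keep] - q_fine[keep]^-2) / q_fine[keep]^-2
  expect_lt(max(rel), 0.02)
  # centro-symmetric pattern: opposing slices identical
  up <- pie_slice_average(pat, 90, 10, q_grid)
  down <- pie_slice_average(pat, 270, 10, q_grid)
  expect_equal(up$intensity, down$intensity, tolerance = 1e-12)
})

test_that("pie-slice averaging respects the mask and flags empty bins", {
  g <- saxs_geometry(1, 10000, 1, center = c(50, 50))
  img <- matrix(1, 101, 101)
  mask <- matrix(FALSE, 101, 101)
  mask[, 61:101] <- TRUE   # mask the slice beyond ~10 px from the center
  pat <- saxs_pattern(img, g, mask = mask)
  pr <- pie_slice_average(pat, 0, 10, seq(0.002, 0.02, by = 0.002))
  expect_false(any(pr$empty[pr$q < 0.005]))
  expect_true(all(pr$empty[pr$q > 0.008]))   # masked radii yield empty bins
  expect_error(pie_slice_average(pat, 0, 10, seq(10, 11, 0.5)),
               class = "saxsqc_error_empty_slice")
  expect_error(pie_slice_average(pat, 0, 120, seq(0.001, 0.01, 1e-3)),
               class = "saxsqc_error_domain")
})

test_that("water-peak magnitude is the windowed maximum", {
  q <- seq(0.5, 2.5, by = 0.005)
  expect_equal(water_peak_magnitude(flat_profile(3, q)), 3)
  # planted Gaussian: baseline + amplitude at the center
  b <- 2; a <- 0.7
  p <- saxs_profile(q, b + a * exp(-(q - 2)^2 / (2 * 0.05^2)))
  expect_equal(water_peak_magnitude(p), b + a, tolerance = 1e-3)
  # intensity outside the window does not matter
  p2 <- p
  p2$intensity[p2$q < 1.5] <- p2$intensity[p2$q < 1.5] + 100
  expect_equal(water_peak_magnitude(p2), water_peak_magnitude(p))
  # truncated profile cannot be searched
  expect_error(water_peak_magnitude(flat_profile(1, seq(0.1, 1.5, 0.01))),
               class = "saxsqc_error_range")
})

test_that("pattern TIFF round trip preserves counts and geometry", {
  skip_if_not_installed("tiff")
  g <- saxs_geometry(1.2, 3000, 0.172, center = c(10.5, 12))
  img <- matrix(as.numeric(rpois(300, 50)), 15, 20)
  pat <- saxs_pattern(img, g)
  path <- withr::local_tempfile(fileext = ".tif")
  write_pattern(pat, path)
  pat2 <- read_pattern(path)
  expect_equal(pat2$image, img, tolerance = 1e-6)
  expect_equal(pat2$geometry$center, g$center)
  expect_equal(pat2$geometry$distance, g$distance)
})
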