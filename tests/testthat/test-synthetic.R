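test_that("generators are pure functions of parameters and seed", {
  q <- seq(0.01, 2.5, 0.01)
  par <- synth_params()
  b1 <- make_buffer_profile(par, q, seed = 5)
  b2 <- make_buffer_profile(par, q, seed = 5)
  expect_identical(b1$intensity, b2$intensity)
  s1 <- make_sample_profile(par, b1, seed = 6)
  s2 <- make_sample_profile(par, b2, seed = 6)
  expect_identical(s1$intensity, s2$intensity)
  p1 <- make_pattern2d(par, seed = 7)
  p2 <- make_pattern2d(par, seed = 7)
  expect_identical(p1$image, p2$image)
  expect_error(make_buffer_profile(par, c(-0.1, 0.1)),
               class = "saxsqc_error_domain")
})

test_that("planted water peak and mixing factor are recorded and recoverable", {
  q <- seq(0.01, 2.5, 0.01)
  par <- synth_params(counts_per_intensity = 0)   # noiseless
  buf <- make_buffer_profile(par, q)
  # windowed maximum recovers baseline + power law + planted amplitude
  expected_peak <- par$baseline + par$powerlaw_amp * 2^(-par$powerlaw_exp) +
    par$peak_amp
  expect_equal(water_peak_magnitude(buf), expected_peak, tolerance = 1e-3)
  # zero peak amplitude leaves a smooth monotone background
  par0 <- synth_params(peak_amp = 0, counts_per_intensity = 0)
  b0 <- make_buffer_profile(par0, q)
  expect_true(all(diff(b0$intensity) < 0))
  # planted truth stored
  smp <- make_sample_profile(par, buf)
  expect_equal(attr(smp, "truth")$buffer_factor, par$buffer_factor)
})

test_that("sphere form factor has the known limits and first zero", {
  expect_equal(sphere_form_factor(0), 1)
  # first zero at the smallest positive root of tan(x) = x
  root <- uniroot(function(x) tan(x) - x, c(pi, 1.5 * pi - 1e-6))$root
  expect_equal(root, 4.4934, tolerance = 1e-4)
  expect_lt(sphere_form_factor(root), 1e-10)
  x <- seq(0.1, 10, 0.1)
  expect_true(all(sphere_form_factor(x) >= 0 & sphere_form_factor(x) <= 1))
})

test_that("planted 2-D center offsets close the loop with the center scan", {
  pat <- make_pattern2d(synth_params(center_offset = c(0, 1)), seed = 21)
  expect_equal(pat$truth$offset, c(0, 1))
  expect_equal(center_scan(pat, "vertical")$recommendation, "shift_plus")
  expect_error(
    make_pattern2d(synth_params(center_offset = c(500, 0)), seed = 1),
    class = "saxsqc_error_domain")
})

test_that("sheet generator plants exactly the requested rule violations", {
  clean <- make_sheets(n_wells = 72, seed = 1)
  expect_true(validate_plate_sheet(clean$plate_sheet)$valid)
  expect_true(validate_measurement_sheet(clean$measurement_sheet)$valid)

  cases <- list(
    "buffer_every_5" = "plate+measurement",
    "well_rule" = "plate",
    "name_rule" = "plate+measurement",
    "dup_name" = "plate+measurement",
    "missing_buffer" = "plate+measurement",
    "holder_name_len" = "measurement",
    "dup_position" = "measurement")
  for (rule in names(cases)) {
    s <- make_sheets(n_wells = 72, planted_errors = rule, seed = 1)
    if (grepl("plate", cases[[rule]])) {
      r <- validate_plate_sheet(s$plate_sheet)
      expect_false(r$valid)
      expect_setequal(unique(r$errors$rule), rule)
    }
    if (grepl("measurement", cases[[rule]])) {
      r <- validate_measurement_sheet(s$measurement_sheet)
      expect_false(r$valid)
      expect_setequal(unique(r$errors$rule), rule)
    }
  }
  # two planted rules give exactly those two and no others
  s2 <- make_sheets(n_wells = 72, planted_errors = c("well_rule", "dup_name"),
                    seed = 1)
  r2 <- validate_plate_sheet(s2$plate_sheet)
  expect_setequal(unique(r2$errors$rule), c("well_rule", "dup_name"))
  expect_error(make_sheets(planted_errors = "not_a_rule"),
               class = "saxsqc_error_domain")
})
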