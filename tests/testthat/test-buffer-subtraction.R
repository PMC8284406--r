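test_that("water-peak matching computes the right prefactor", {
  q <- seq(0.01, 2.5, 0.01)
  buf <- make_buffer_profile(synth_params(counts_per_intensity = 0), q)
  m <- match_water_peak(buf, buf)
  expect_equal(m$prefactor, 1)
  expect_equal(m$buffer$intensity, buf$intensity)

  half <- buf
  half$intensity <- half$intensity * 0.5
  m2 <- match_water_peak(buf, half)
  expect_equal(m2$prefactor, 2)
  expect_equal(water_peak_magnitude(m2$buffer), water_peak_magnitude(buf))

  trunc <- dplyr::filter(buf, q < 1.5)
  expect_error(match_water_peak(dplyr::filter(buf, q < 1.5), trunc),
               class = "saxsqc_error_range")
  zero <- buf
  zero$intensity <- rep(0, nrow(zero))
  expect_error(match_water_peak(buf, zero),
               class = "saxsqc_error_degenerate_buffer")
})

test_that("subtraction propagates uncertainties in quadrature", {
  q <- seq(0.1, 1, 0.1)
  s <- saxs_profile(q, rep(10, 10), sigma = rep(3, 10))
  b <- saxs_profile(q, rep(4, 10), sigma = rep(4, 10))
  sub <- subtract_buffer(s, b, 1)
  expect_equal(sub$intensity, rep(6, 10))
  expect_equal(sub$sigma, rep(5, 10))            # sqrt(3^2 + 4^2)
  expect_equal(subtract_buffer(s, b, 0)$intensity, s$intensity)
  expect_equal(subtract_buffer(s, s, 1)$intensity, rep(0, 10))
  expect_error(subtract_buffer(s, saxs_profile(q + 1, b$intensity), 1),
               class = "saxsqc_error_grid")
})

test_that("over-subtraction criteria detect planted signatures", {
  q <- seq(0.01, 2.5, 0.01)
  opts <- scaling_options()
  # clean monotone positive curve: no violation
  clean <- saxs_profile(q, 2 / (1 + q))
  base <- log_span(clean, opts$q_floor)
  v0 <- criterion_violations(clean, base, opts)
  expect_false(v0[["c1"]]); expect_false(v0[["c2"]])

  # negative intensity fires criterion 1
  neg <- clean
  neg$intensity[200] <- -0.1
  expect_true(criterion_violations(neg, base, opts)[["c1"]])

  # planted dip in q*I at 2.0 fires criterion 1
  dip <- clean
  dip$intensity <- dip$intensity - 0.3 * exp(-(q - 2)^2 / (2 * 0.03^2))
  expect_true(criterion_violations(dip, base, opts)[["c1"]])

  # dynamic-range blow-up fires criterion 2: shrink the minimum 10x
  stretched <- clean
  i_min <- which.min(stretched$intensity[q > opts$q_floor])
  idx <- which(q > opts$q_floor)[i_min]
  stretched$intensity[idx] <- stretched$intensity[idx] / 10
  v <- criterion_violations(stretched, base, opts)
  expect_true(v[["c2"]])
})

test_that("scaling search: identity pair runs to the factor cap", {
  q <- seq(0.01, 2.5, 0.01)
  buf <- make_buffer_profile(synth_params(counts_per_intensity = 0), q)
  r <- estimate_scaling_factor(buf, buf)
  expect_equal(r$factor, 1.0)
  expect_equal(r$terminated_by, "max_factor_cap")
  # trace never exceeds the cap and starts at `start`
  expect_equal(min(r$trace$factor), 0.9)
  expect_lte(max(r$trace$factor), 1.0)
})

test_that("scaling search recovers planted mixing factors", {
  q <- seq(0.01, 2.5, 0.01)
  cs <- c(0.992, 0.995, 0.998)
  for (i in seq_along(cs)) {
    par <- synth_params(buffer_factor = cs[i])
    buf <- make_buffer_profile(par, q, seed = 30 + i)
    smp <- make_sample_profile(par, buf, seed = 60 + i)
    r <- estimate_scaling_factor(smp, buf)
    expect_lt(abs(r$factor - cs[i]), 0.002)
    # agreement with the brute-force grid oracle within one grid step
    expect_lt(abs(r$factor - grid_search_factor(smp, buf)), 1.5e-4)
    # monotone feasibility along the trace: no violation below the factor,
    # and the returned factor never exceeds the first finest-step violation
    viol <- r$trace$factor[r$trace$c1 | r$trace$c2]
    expect_true(all(viol > r$factor))
  }
})

test_that("full pipeline (match + estimate) lands below but near 1", {
  q <- seq(0.01, 2.5, 0.01)
  par <- synth_params(buffer_factor = 1.0)
  buf <- make_buffer_profile(par, q, seed = 5)
  smp <- make_sample_profile(par, buf, seed = 6)
  m <- match_water_peak(smp, buf)
  expect_gt(m$prefactor, 1)      # protein contributes under the water peak
  r <- estimate_scaling_factor(smp, m$buffer)
  expect_gte(r$factor, 0.99)
  expect_lt(r$factor, 1.0)
})

test_that("a pathological pair is rejected at the starting factor", {
  q <- seq(0.01, 2.5, 0.01)
  buf <- make_buffer_profile(synth_params(counts_per_intensity = 0), q)
  tiny <- buf
  tiny$intensity <- tiny$intensity * 0.5   # sample weaker than buffer at start
  expect_error(estimate_scaling_factor(tiny, buf),
               class = "saxsqc_error_start_infeasible")
})
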