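# Environmental matching, oxygen unit conversions, pO2, OMZ classification.

test_that("box averaging reproduces constant and linear fields", {
  env <- small_env()
  # constant field: mean is the constant at every depth
  cenv <- env
  cenv$fields$do[] <- 4.2
  s <- box_average(cenv, -20, 12)
  expect_equal(unname(s$do), rep(4.2, length(env$depth)))
  # field linear in lon: box mean equals the value at the box-centre lon
  lenv <- env
  lin <- outer(env$lon, rep(1, length(env$lat)))
  for (k in seq_along(env$depth)) lenv$fields$do[, , k] <- 2 * lin + 100
  s2 <- box_average(lenv, -20, 12)
  expect_equal(unname(s2$do[1]), 2 * -20 + 100, tolerance = 1e-9)
  # adding a constant commutes with box averaging
  senv <- env
  senv$fields$do <- env$fields$do + 1.5
  expect_equal(box_average(senv, -18, 9)$do,
               box_average(env, -18, 9)$do + 1.5)
  # a box clipped at the domain edge averages the remaining pixels
  edge <- box_average(env, min(env$lon) + 0.1, min(env$lat) + 0.1)
  expect_true(all(is.finite(edge$do)))
  expect_error(box_average(env, -60, 12), "outside")
})

test_that("oxygen unit conversions use the O2 molar volume and round-trip", {
  expect_equal(convert_o2_units(1, "ml/l", "umol/l"), 44.659,
               tolerance = 1e-4)
  expect_equal(convert_o2_units(1, "mg/l", "ml/l"), 0.69978,
               tolerance = 1e-5)
  expect_equal(convert_o2_units(0, "mg/l", "umol/kg", 15, 35), 0)
  units <- c("ml/l", "mg/l", "umol/l", "umol/kg")
  for (u1 in units) for (u2 in units) {
    x <- 3.37
    back <- convert_o2_units(convert_o2_units(x, u1, u2, 15, 35),
                             u2, u1, 15, 35)
    expect_equal(back, x, tolerance = 1e-9)
  }
  expect_error(convert_o2_units(1, "ml/l", "furlongs"), "unknown")
})

test_that("pO2 follows air-saturation physics", {
  expect_equal(po2_from_do(0, 15, 35), 0)
  # at air saturation pO2 equals the O2 partial pressure of humid air
  sat <- o2_saturation(15, 35)
  expect_equal(po2_from_do(sat, 15, 35),
               0.20946 * (101.325 - water_vapor_pressure(15, 35)),
               tolerance = 1e-12)
  # linear in DO at fixed (T, S)
  p1 <- po2_from_do(1, 18, 35.5)
  expect_equal(po2_from_do(c(2, 3.5), 18, 35.5), c(2, 3.5) * p1,
               tolerance = 1e-12)
  # warmer water holds less oxygen, so a fixed DO implies a higher pO2
  expect_true(po2_from_do(3, 20, 35) > po2_from_do(3, 10, 35))
  expect_error(po2_from_do(-1, 15, 35), "negative")
  # solubility fit reproduces its published check value C(10, 35)
  expect_equal(o2_saturation(10, 35), 6.315, tolerance = 1e-3)
})

test_that("OMZ classification is strict at the 3.5 ml/l boundary", {
  expect_true(classify_omz(3.49))
  expect_false(classify_omz(3.5))
  expect_false(classify_omz(5.0))
  expect_true(is.na(classify_omz(NA_real_)))
  env <- small_env()
  s_in <- box_average(env, -20, 12)
  s_out <- box_average(env, -11, 21)
  expect_true(classify_omz(s_in))
  expect_false(classify_omz(s_out))
})

test_that("track-day matching appends covariates and OMZ flags", {
  env <- small_env()
  sh <- gen_shark_track(env, shark_behavior_spec(seed = 5), n_days = 10)
  m <- match_environment(sh$track, env)
  expect_true(all(c("sst", "do_100", "npp_100", "po2_100", "inside_omz")
                  %in% names(m)))
  expect_true(all(is.finite(m$do_100)))
  expect_equal(m$inside_omz, m$do_100 < 3.5)
  expect_true(all(m$po2_100 > 0))
})
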