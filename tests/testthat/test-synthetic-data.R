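# Synthetic data generators: environment, sharks, vessels, logbooks.

test_that("generated environment has OMZ structure and is reproducible", {
  spec <- env_grid_spec(lon_range = c(-30, -10), lat_range = c(2, 22),
                        horizontal_resolution = 0.5)
  env <- gen_env_field(spec)
  # hypoxic at 100 m over the core, normoxic three radii away
  expect_lt(env_value_at(env, spec$omz_center[1], spec$omz_center[2],
                         100, "do"), 3.5)
  far <- c(spec$omz_center[1] + 3 * spec$omz_radius * 0.45,
           spec$omz_center[2] + 3 * spec$omz_radius * 0.45)
  expect_gt(env_value_at(env, far[1], far[2], 100, "do"), 3.5)
  # warm SST and elevated NPP inside
  expect_gt(env_value_at(env, -20, 12, 0, "temp"),
            env_value_at(env, -11, 21, 0, "temp"))
  expect_gt(env_value_at(env, -20, 12, 100, "npp"),
            env_value_at(env, -11, 21, 100, "npp"))
  # DO monotone non-increasing with depth in every column, never above the
  # column surface value
  dd <- apply(env$fields$do, c(1, 2), function(p) max(diff(p)))
  expect_true(all(dd <= 1e-9))
  expect_true(all(sweep(env$fields$do, c(1, 2), env$fields$do[, , 1],
                        "-") <= 1e-9))
  # bit-identical for the same seed
  expect_identical(gen_env_field(spec), env)
  expect_false(identical(gen_env_field(env_grid_spec(
    lon_range = c(-30, -10), lat_range = c(2, 22),
    horizontal_resolution = 0.5, seed = 2L)), env))
  # degenerate domains and invalid specs rejected
  expect_error(env_grid_spec(lon_range = c(-10, -10)), "degenerate")
  expect_error(env_grid_spec(do_surface = 0.5, do_core = 0.9), "do_core")
})

test_that("environment round-trips through NetCDF", {
  env <- small_env()
  path <- tempfile(fileext = ".nc")
  on.exit(unlink(path))
  write_env_nc(env, path)
  back <- read_env_nc(path)
  expect_equal(back$lon, env$lon)
  expect_equal(back$depth, env$depth)
  for (v in names(env$fields))
    expect_equal(back$fields[[v]], env$fields[[v]], tolerance = 1e-12)
})

test_that("shark generator yields one dive day per day with valid TAD", {
  env <- small_env()
  sh <- gen_shark_track(env, shark_behavior_spec(seed = 3), n_days = 40)
  expect_equal(nrow(sh$track), 40)
  expect_equal(nrow(sh$dive_days), 40)
  tad <- as.matrix(sh$dive_days[, grep("^tad\\.", names(sh$dive_days))])
  expect_true(all(abs(rowSums(tad) - 100) < 1e-9))
  expect_true(all(sh$dive_days$mdd_depth >= 10))
  expect_true(all(sh$dive_days$min_depth <= sh$dive_days$mdd_depth))
  # pure function of (spec, seed)
  sh2 <- gen_shark_track(env, shark_behavior_spec(seed = 3), n_days = 40)
  expect_identical(sh2$dive_days, sh$dive_days)
  # positions never leave the domain (reflection at the boundary)
  expect_true(all(env_contains(env, sh$track$lon, sh$track$lat)))
  expect_error(gen_shark_track(env, n_days = 1), "n_days")
  expect_error(gen_shark_track(env, n_days = 10, start = c(0, 0)), "outside")
})

test_that("unbiased sharks occupy the OMZ in proportion to its area", {
  env <- small_env()
  props <- vapply(1:200, function(r) {
    st <- withr::with_seed(5000 + r, c(runif(1, -29, -11), runif(1, 3, 21)))
    sh <- gen_shark_track(env, shark_behavior_spec(
      omz_residency_bias = 0, bearing_concentration = 0, seed = 6000 + r),
      n_days = 60, start = st)
    mean(sh$dive_days$inside_omz)
  }, numeric(1))
  frac <- mean(omz_mask(env))
  se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - frac), 3 * se)
})

test_that("MDD responds to the OMZ only through the programmed effects", {
  env <- small_env()
  # all effects disabled: mean MDD inside equals outside (within 2 SE)
  null_spec <- shark_behavior_spec(do_effect = FALSE, sst_effect = FALSE,
                                   npp_sensitivity = 0, seed = 11)
  dd <- do.call(rbind, lapply(1:12, function(r)
    gen_shark_track(env, shark_behavior_spec(
      do_effect = FALSE, sst_effect = FALSE, npp_sensitivity = 0,
      seed = 100 + r), n_days = 60)$dive_days))
  x <- dd$mdd_depth[dd$inside_omz]
  y <- dd$mdd_depth[!dd$inside_omz]
  se_diff <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs(mean(x) - mean(y)), 2 * se_diff)
  # default spec: habitat compression, shallower MDD inside
  dd2 <- do.call(rbind, lapply(1:8, function(r)
    gen_shark_track(env, shark_behavior_spec(seed = 200 + r),
                    n_days = 60)$dive_days))
  expect_lt(mean(dd2$mdd_depth[dd2$inside_omz]),
            mean(dd2$mdd_depth[!dd2$inside_omz]))
})

test_that("vessel generator produces the requested V-shaped deployments", {
  v0 <- gen_vessel_track(vessel_behavior_spec(n_sets_per_trip = 0, seed = 1),
                         start = c(-25, 10))
  expect_equal(nrow(v0$sets), 0)
  v3 <- gen_vessel_track(vessel_behavior_spec(seed = 2), start = c(-25, 10))
  expect_equal(nrow(v3$sets), 3)
  expect_true(all(v3$sets$outbound_km >= 80))
  expect_true(all(v3$sets$inbound_km >= 80 - 4 - 1)) # minus jitter allowance
  expect_true(all(v3$sets$line_length >= 80 & v3$sets$line_length <= 100))
  # ping stream is strictly time-ordered
  expect_true(all(diff(as.numeric(v3$track$timestamp)) > 0))
  expect_error(vessel_behavior_spec(longline_length_range = c(60, 100)))
})

test_that("logbook generator encodes a quadratic CPUE-DO relationship", {
  env <- small_env()
  lb <- gen_logbook(env, peak_do = 3.0, n_sets = 400, seed = 9)
  expect_equal(nrow(lb), 400)
  expect_true(all(lb$biomass > 0))
  expect_identical(gen_logbook(env, peak_do = 3.0, n_sets = 400, seed = 9),
                   lb)
  expect_error(gen_logbook(env, peak_do = 3.0, n_sets = 5), "unfittable")
  expect_error(gen_logbook(env, peak_do = 99, n_sets = 100), "peak_do")
  # zero noise, exact interpolation: downstream fit recovers the vertex
  lb0 <- gen_logbook(env, peak_do = 2.8, n_sets = 500, seed = 2,
                     noise_sd = 0)
  do100 <- env_value_at(env, lb0$lon, lb0$lat, 100, "do")
  qf <- fit_cpue_quadratic(do100, lb0$biomass)
  expect_equal(qf$peak_do, 2.8, tolerance = 1e-6)
})
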