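# Longline-set detection and fishing effort / intensity grids.

test_that("an ideal V is detected once with the turn at the apex", {
  set.seed(1)
  tr <- v_track(leg = 90, deviation = 173, endpoint_gap = 2)
  det <- detect_longline_sets(tr)
  expect_equal(nrow(det), 1)
  # apex of the fixture is the ping at the end of the outbound leg
  apex_i <- which.max(cumsum(c(0, gc_distance_km(
    tr$lon[-nrow(tr)], tr$lat[-nrow(tr)], tr$lon[-1], tr$lat[-1]))) >= 210)
  expect_lt(gc_distance_km(det$turn_lon, det$turn_lat,
                           tr$lon[apex_i], tr$lat[apex_i]), 8)
  expect_gt(det$turn_angle, 130)
  expect_gte(det$leg_in_km, 80)
  expect_gte(det$leg_out_km, 80)
})

test_that("gentle turns and straight transits are not sets", {
  set.seed(2)
  # a 120-degree heading change is below the >130-degree rule
  expect_equal(nrow(detect_longline_sets(v_track(deviation = 120))), 0)
  # straight 300 km transit
  straight <- v_track(leg = 90, deviation = 0, lead_km = 120)
  expect_equal(nrow(detect_longline_sets(straight)), 0)
  expect_equal(nrow(detect_longline_sets(straight[1:2, ])), 0)
})

test_that("detector recovers generated deployments with high fidelity", {
  score <- c(tp = 0, fp = 0, fn = 0)
  for (s in 1:25) {
    vt <- gen_vessel_track(vessel_behavior_spec(seed = s),
                           start = c(-25, 10),
                           vessel_id = paste0("V", s))
    det <- detect_longline_sets(vt$track)
    score <- score + detector_score(det, vt$sets)
  }
  precision <- score["tp"] / (score["tp"] + score["fp"])
  recall <- score["tp"] / (score["tp"] + score["fn"])
  expect_gte(unname(precision), 0.9)
  expect_gte(unname(recall), 0.9)
})

test_that("effort grid counts daily vessel centroids and conserves effort", {
  d1 <- as.Date("2010-03-01")
  # three same-day locations in one cell: one effort-day
  loc <- data.frame(vessel_id = "A", date = d1,
                    lon = c(-20.2, -20.4, -20.6), lat = c(10.1, 10.3, 10.2))
  g <- fishing_effort_grid(loc)
  expect_equal(nrow(g), 1)
  expect_equal(g$effort_days, 1L)
  expect_equal(c(g$cell_lon, g$cell_lat), c(-21, 10))
  # two vessels, same day, same cell: two effort-days
  loc2 <- rbind(loc, transform(loc, vessel_id = "B"))
  expect_equal(fishing_effort_grid(loc2)$effort_days, 2L)
  # conservation: total effort-days = sum over vessels of distinct days
  set.seed(12)
  big <- data.frame(vessel_id = sample(LETTERS[1:4], 120, TRUE),
                    date = d1 + sample(0:9, 120, TRUE),
                    lon = runif(120, -30, -10), lat = runif(120, 2, 22))
  gg <- fishing_effort_grid(big)
  expected <- sum(tapply(big$date, big$vessel_id,
                         function(d) length(unique(d))))
  expect_equal(sum(gg$effort_days), expected)
})

test_that("fishing intensity measures adjacent-day spatial clustering", {
  d1 <- as.Date("2010-03-01")
  # five consecutive days within 10 km: all ARS, intensity 1
  p <- gc_destination(-20.5, 10.5, 45, seq(0, 8, by = 2))
  clus <- data.frame(vessel_id = "A", date = d1 + 0:4,
                     lon = p[, 1], lat = p[, 2])
  fi <- fishing_intensity(clus)
  expect_equal(fi$intensity, 1.0)
  # isolated locations (far apart, non-adjacent days): intensity 0
  iso <- data.frame(vessel_id = "A", date = d1 + seq(0, 8, by = 2),
                    lon = seq(-30, -14, by = 4), lat = rep(10.5, 5))
  expect_true(all(fishing_intensity(iso)$intensity == 0))
  # half clustered, half isolated, same cell: intensity 0.5
  half <- rbind(
    data.frame(vessel_id = "A", date = d1 + 0:1,
               lon = c(-20.5, -20.55), lat = c(10.5, 10.5)),
    data.frame(vessel_id = "A", date = d1 + c(10, 20),
               lon = c(-20.4, -20.6), lat = c(10.4, 10.6)))
  expect_equal(fishing_intensity(half)$intensity, 0.5)
  # invariant to vessel relabelling
  relab <- clus
  relab$vessel_id <- "Z9"
  expect_equal(fishing_intensity(relab)$intensity, fi$intensity)
})

test_that("zone comparison detects shifts and is calibrated under the null", {
  set.seed(5)
  cells <- data.frame(cell_lon = rep(-30:-11, 2), cell_lat = rep(5:6, each = 20),
                      effort_days = rpois(40, 20),
                      omz_flag = rep(c(TRUE, FALSE), each = 20))
  # a +50 effort-day shift in OMZ cells is detected
  shifted <- cells
  shifted$effort_days[shifted$omz_flag] <-
    shifted$effort_days[shifted$omz_flag] + 50
  expect_lt(compare_zones(shifted, "effort_days")$p_value, 0.05)
  # complete ties: p = 1 by convention
  tied <- cells
  tied$effort_days <- 7
  expect_equal(compare_zones(tied, "effort_days")$p_value, 1)
  expect_error(compare_zones(cells[cells$omz_flag, ], "effort_days"),
               "2 cells")
  # label-permutation null: rejection rate close to the nominal 5%
  rej <- vapply(1:400, function(r) {
    perm <- cells
    perm$omz_flag <- sample(perm$omz_flag)
    compare_zones(perm, "effort_days")$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})
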