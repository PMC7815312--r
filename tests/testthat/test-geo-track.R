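# Track cleaning and daily regularization.

test_that("class-Z fixes are removed, order preserved, absent column tolerated", {
  p <- raw_positions(lon = c(-20, -20.1, -20.2, -20.3), lat = c(10, 10, 10, 10),
                     hours = 0:3, classes = c("3", "B", "Z", "1"))
  out <- drop_class_z(p)
  expect_equal(out$location_class, c("3", "B", "1"))
  expect_equal(nrow(drop_class_z(p[p$location_class == "Z", ])), 0)
  no_class <- raw_positions(-20, 10, 0)
  expect_identical(drop_class_z(no_class), no_class)
})

test_that("speed filter drops implausible moves greedily and is idempotent", {
  # 100 km in 24 h is 1.16 m/s: both kept
  p2 <- gc_destination(-20, 10, 45, 100)
  ok <- raw_positions(c(-20, p2[1]), c(10, p2[2]), c(0, 24))
  expect_equal(nrow(speed_filter(ok)), 2)
  # middle point 400 km away in 24 h (4.6 m/s) is removed; third point,
  # reachable from the first, is kept
  mid <- gc_destination(-20, 10, 90, 400)
  p3 <- gc_destination(-20, 10, 45, 120)
  bad <- raw_positions(c(-20, mid[1], p3[1]), c(10, mid[2], p3[2]),
                       c(0, 24, 48))
  out <- speed_filter(bad)
  expect_equal(nrow(out), 2)
  expect_equal(out$lon, c(-20, p3[1]))
  # single point kept; non-monotone rejected
  expect_equal(nrow(speed_filter(raw_positions(-20, 10, 0))), 1)
  expect_error(speed_filter(raw_positions(c(-20, -20.1), c(10, 10), c(5, 5))),
               "increasing")
  # idempotence on random jittery tracks
  set.seed(42)
  for (i in 1:5) {
    n <- 30
    walk <- raw_positions(cumsum(rnorm(n, 0, 2)) - 20,
                          cumsum(rnorm(n, 0, 2)) / 2 + 10, seq(0, n - 1) * 6)
    once <- speed_filter(walk)
    expect_identical(speed_filter(once), once)
    # no retained consecutive pair exceeds the limit
    d <- gc_distance_km(once$lon[-nrow(once)], once$lat[-nrow(once)],
                        once$lon[-1], once$lat[-1]) * 1000
    dt <- diff(as.numeric(once$timestamp))
    expect_true(all(d / dt <= 3 + 1e-9))
  }
})

test_that("daily regularization interpolates small gaps and splits large ones", {
  d0 <- as.POSIXct("2017-06-01 12:00:00", tz = "UTC")
  # fixes on days 1 and 7: five missing days interpolated, one segment
  p <- raw_positions(c(-20, -18), c(10, 12), c(0, 6 * 24))
  tr <- regularize_daily(p)
  expect_equal(nrow(tr), 7)
  expect_equal(unique(tr$segment), 1L)
  expect_equal(as.numeric(diff(tr$date)), rep(1, 6))
  # interpolated points lie on the great circle (cross-track error < 1 km)
  mids <- tr[2:6, ]
  xt <- abs(geosphere::dist2gc(c(-20, 10), c(-18, 12),
                               cbind(mids$lon, mids$lat), r = 6371))
  expect_true(all(xt < 1))
  # gap of 21 days (fixes on days 1 and 23) splits; exactly 20 does not
  p21 <- raw_positions(c(-20, -18), c(10, 12), c(0, 22 * 24))
  tr21 <- regularize_daily(p21)
  expect_equal(nrow(tr21), 2)
  expect_equal(tr21$segment, c(1L, 2L))
  p20 <- raw_positions(c(-20, -18), c(10, 12), c(0, 21 * 24))
  expect_equal(unique(regularize_daily(p20)$segment), 1L)
  # same-day fixes collapse to their centroid
  pc <- raw_positions(c(-20, -21), c(10, 11), c(1, 5))
  trc <- regularize_daily(pc)
  expect_equal(nrow(trc), 1)
  expect_equal(trc$lon, -20.5)
  expect_equal(trc$lat, 10.5)
  # empty input gives an empty track
  expect_equal(nrow(regularize_daily(raw_positions(numeric(), numeric(),
                                                   numeric()))), 0)
})

test_that("antimeridian gaps interpolate continuously along the great circle", {
  p <- raw_positions(c(179.2, -179.0), c(5, 6), c(0, 4 * 24))
  tr <- regularize_daily(p)
  expect_equal(nrow(tr), 5)
  # consecutive daily moves stay short (no spurious wrap across the map)
  d <- gc_distance_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                      tr$lon[-1], tr$lat[-1])
  expect_true(all(d < 80))
  xt <- abs(geosphere::dist2gc(c(179.2, 5), c(-179.0, 6),
                               cbind(tr$lon[2:4], tr$lat[2:4]), r = 6371))
  expect_true(all(xt < 1))
})
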