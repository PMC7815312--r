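# Time-at-depth and dive-depth summaries.

mk_dive_days <- function(tad_rows, scheme = depth_class_scheme("2010"),
                         mdd = NULL, inside = TRUE, id = "S1",
                         start_date = as.Date("2017-06-01")) {
  tad <- matrix(unlist(tad_rows), nrow = length(tad_rows), byrow = TRUE)
  colnames(tad) <- paste0("tad.", scheme$labels)
  n <- nrow(tad)
  d <- data.frame(animal_id = id, date = start_date + seq_len(n) - 1,
                  mdd_depth = if (is.null(mdd)) rep(100, n) else mdd,
                  min_depth = 0, inside_omz = rep_len(inside, n))
  cbind(d, tad)
}

test_that("percent time above a cutoff sums whole classes only", {
  sch <- depth_class_scheme("2010")
  d1 <- mk_dive_days(list(c(60, 20, 10, 5, 5, 0, 0, 0)))
  expect_equal(pct_time_upper(d1, sch, 250), 100)
  d2 <- mk_dive_days(list(rep(12.5, 8)))
  expect_equal(pct_time_upper(d2, sch, 250), 62.5)
  expect_error(pct_time_upper(d2, sch, 300), "not a class edge")
  # 300 is an edge of the 2017 scheme
  sch17 <- depth_class_scheme("2017")
  d3 <- mk_dive_days(list(rep(100 / 9, 9)), scheme = sch17)
  expect_equal(pct_time_upper(d3, sch17, 300), 600 / 9)
  # merging adjacent classes on the same side of the cutoff changes nothing
  merged <- depth_class_scheme(c(0, 100, 150, 200, 250, 400, 600))
  d4 <- mk_dive_days(list(c(25, 10, 5, 22.5, 17.5, 12, 8)), scheme = merged)
  split_sch <- depth_class_scheme(c(0, 50, 100, 150, 200, 250, 400, 600))
  d5 <- mk_dive_days(list(c(12.5, 12.5, 10, 5, 22.5, 17.5, 12, 8)),
                     scheme = split_sch)
  expect_equal(pct_time_upper(d4, merged, 250), pct_time_upper(d5, split_sch, 250))
})

test_that("deep-dive days are counted from daily maxima", {
  d <- data.frame(mdd_depth = c(500, 650, 700, 300))
  expect_equal(count_deep_dives(d), 2)
  expect_equal(count_deep_dives(data.frame(mdd_depth = c(100, 600))), 0)
  set.seed(3)
  r <- data.frame(mdd_depth = runif(200, 0, 1200))
  expect_equal(count_deep_dives(r), sum(r$mdd_depth > 600))
})

test_that("per-shark summaries split zones and aggregate with NA handling", {
  sch <- depth_class_scheme("2010")
  rows_in <- lapply(1:3, function(i) c(80, 10, 5, 5, 0, 0, 0, 0))
  rows_out <- lapply(1:2, function(i) c(40, 10, 10, 10, 10, 10, 10, 10))
  dd <- rbind(mk_dive_days(rows_in, mdd = c(200, 650, 300), inside = TRUE),
              mk_dive_days(rows_out, mdd = c(700, 900), inside = FALSE,
                           start_date = as.Date("2017-07-01")))
  vs <- vertical_summary(dd, sch)
  expect_equal(vs$pct_upper_omz, 100)
  expect_equal(vs$pct_upper_outside, 80)
  expect_equal(vs$deep_dives_omz, 1)
  expect_equal(vs$deep_dives_outside, 2)
  expect_equal(vs$max_depth_omz, 650)
  expect_equal(vs$max_depth_outside, 900)
  # a single shark: mean equals its own value, SD absent
  sv <- summarize_vertical(vs)
  expect_equal(sv["mean", "max_depth_omz"], 650)
  expect_true(is.na(sv["sd", "max_depth_omz"]))
  # absent zone cells are ignored by column means
  two <- rbind(vs, vs)
  two$shark_id <- c("A", "B")
  two$max_depth_omz <- c(600, NA)
  expect_equal(summarize_vertical(two)["mean", "max_depth_omz"], 600)
})

test_that("habitat-compression percentage follows its definition", {
  expect_equal(round(pct_reduction(754.0, 1250.3)), 40)
  expect_equal(pct_reduction(500, 500), 0)
  expect_equal(pct_reduction(0, 800), 100)
  expect_error(pct_reduction(100, 0), "> 0")
})

test_that("boundary-day pairs flank each OMZ entry event", {
  sch <- depth_class_scheme("2010")
  tad <- lapply(1:12, function(i) c(100, rep(0, 7)))
  dd <- mk_dive_days(tad, mdd = 101:112,
                     inside = c(rep(FALSE, 9), TRUE, TRUE, TRUE))
  # entry on day 10: pair (day 9 outside, day 11 inside)
  pairs <- boundary_day_comparison(dd)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$outside_date, dd$date[9])
  expect_equal(pairs$inside_date, dd$date[11])
  expect_equal(pairs$mdd_outside, 109)
  expect_equal(pairs$mdd_inside, 111)
  # entry on the first day of a segment: no event, no pair
  dd2 <- mk_dive_days(tad[1:4], mdd = 1:4,
                      inside = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(boundary_day_comparison(dd2)), 0)
  # entry on the last day lacks the following day: dropped with a warning
  dd2b <- mk_dive_days(tad[1:3], mdd = 1:3,
                       inside = c(FALSE, FALSE, TRUE))
  expect_warning(p2 <- boundary_day_comparison(dd2b), "dropped")
  expect_equal(nrow(p2), 0)
  # two entries give two pairs
  dd3 <- mk_dive_days(tad, mdd = 1:12,
                      inside = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                 FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(boundary_day_comparison(dd3)), 2)
})
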