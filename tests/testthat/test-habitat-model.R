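# Additive MDD habitat model: frame building, selection, partial effects,
# mixed layer depth, capped spatial prediction.

test_that("outlier filter removes the top decile with ties kept low", {
  dd <- data.frame(mdd_depth = (1:100) * 10, do_100 = runif(100, 1, 5),
                   sst = 25, npp_100 = 0.001)
  fr <- build_frame(dd, covariates = c("do_100", "sst", "npp_100"))
  expect_equal(nrow(fr), 90)
  expect_equal(max(fr$mdd_depth), 900)
  expect_equal(attr(fr, "n_removed"), 10)
  expect_gt(attr(fr, "outlier_threshold"), 900 - 10)
  # constant depths: quantile ties are kept, nothing removed
  cc <- data.frame(mdd_depth = rep(300, 50), do_100 = 3, sst = 25,
                   npp_100 = 0.001)
  expect_equal(nrow(build_frame(cc, covariates = "do_100")), 50)
  # rows with missing covariates are dropped before the quantile is taken
  dd$do_100[3] <- NA
  expect_equal(nrow(build_frame(dd, covariates = "do_100")), 89)
})

test_that("mixed layer depth interpolates the temperature criterion", {
  z <- c(0, 10, 25, 40, 60, 80, 120, 200)
  # step profile: 25 degC above 60 m, 15 degC below
  tt <- c(25, 25, 25, 25, 25, 15, 15, 15)
  mld <- compute_mld(z, tt)
  expect_lt(abs(mld - 60), 10.5) # within half the local level spacing
  expect_true(attr(mld, "criterion_met"))
  # isothermal: criterion never met, deepest level flagged
  iso <- compute_mld(z, rep(20, 8))
  expect_equal(as.numeric(iso), 200)
  expect_false(attr(iso, "criterion_met"))
  # degenerate criterion on a strictly decreasing profile: the reference depth
  dec <- compute_mld(z, 25 - z / 50, delta_t = 0)
  expect_equal(as.numeric(dec), 10)
  expect_error(compute_mld(c(20, 50), c(20, 18)), "span")
})

test_that("selection keeps true drivers, prefers the null when there are none", {
  # with effects: the three drivers are retained, noise is not, and the
  # final AIC is the lowest in the trace
  fr <- sim_mdd_frame(n_sharks = 8, days_per_shark = 60, seed = 77)
  fit <- fit_mdd_model(build_frame(fr),
                       candidates = c("sst", "do_100", "npp_100",
                                      "temp_100", "sal_100"), k = 8)
  covs <- vapply(fit$terms, `[[`, character(1), "cov")
  expect_true(all(c("sst", "do_100", "npp_100") %in% covs))
  expect_false(any(c("temp_100", "sal_100") %in% covs))
  # the AIC-elimination phase never increases AIC, and the selected model
  # improves on the full model (later prune steps trade AIC for parsimony)
  aic_phase <- fit$selection_trace$aic[fit$selection_trace$action
                                       %in% c("full", "drop", "linearize")]
  expect_true(all(diff(aic_phase) <= 1e-6))
  expect_lte(fit$aic_ml, fit$selection_trace$aic[1] + 1e-6)
  # held-out error: selected model beats intercept-plus-random-effects
  fr2 <- sim_mdd_frame(n_sharks = 8, days_per_shark = 80, seed = 88)
  train <- fr2[seq(1, nrow(fr2), by = 2), ]
  test <- fr2[seq(2, nrow(fr2), by = 2), ]
  fit2 <- fit_mdd_model(build_frame(train),
                        candidates = c("sst", "do_100", "npp_100"), k = 8)
  null2 <- fit_mdd_model(build_frame(train), candidates = character(0), k = 8)
  pr <- function(f) as.numeric(stats::predict(
    f$fit, newdata = test, exclude = "s(shark_id)",
    newdata.guaranteed = TRUE))
  rmse <- function(p) sqrt(mean((test$mdd_depth - p)^2))
  expect_lt(rmse(pr(fit2)), rmse(pr(null2)))
  # null frames: intercept-plus-random-effects selected in >= 80% of runs
  hits <- vapply(1:20, function(r) {
    nf <- sim_mdd_frame(n_sharks = 6, days_per_shark = 50,
                        null_model = TRUE, seed = 500 + r)
    nfit <- fit_mdd_model(build_frame(nf),
                          candidates = c("do_100", "sst", "npp_100"), k = 6)
    length(nfit$terms) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # precondition checks
  one <- sim_mdd_frame(n_sharks = 1, days_per_shark = 60, seed = 1)
  expect_error(fit_mdd_model(build_frame(one)), "2 sharks")
})

test_that("partial effects are centred with standard errors", {
  fr <- sim_mdd_frame(n_sharks = 8, days_per_shark = 60, seed = 42)
  fit <- fit_mdd_model(build_frame(fr),
                       candidates = c("sst", "do_100", "npp_100"), k = 8)
  pe <- partial_effect(fit, "do_100")
  expect_equal(mean(pe$effect), 0, tolerance = 1e-8)
  expect_true(all(pe$se > 0))
  expect_error(partial_effect(fit, "sal_100"), "not retained")
  # NPP effect decreases over the upper half of the NPP range
  covs <- vapply(fit$terms, `[[`, character(1), "cov")
  if ("npp_100" %in% covs) {
    pn <- partial_effect(fit, "npp_100")
    upper <- pn[pn$value >= stats::median(fr$npp_100), ]
    expect_lt(stats::cor(upper$value, upper$effect), 0)
  }
  # tensor-product candidates are accepted by the fitter
  fit_te <- fit_mdd_model(build_frame(fr),
                          candidates = c("sst", "do_100", "npp_100"),
                          include_tensors = TRUE, k = 6)
  expect_s3_class(fit_te, "mdd_fit")
})

test_that("spatial MDD prediction is capped at the mixed layer depth", {
  env <- small_env()
  set.seed(31)
  fr <- sim_mdd_frame(n_sharks = 6, days_per_shark = 50, seed = 31)
  fit <- fit_mdd_model(build_frame(fr),
                       candidates = c("sst", "do_100", "npp_100"), k = 6)
  mp <- predict_mdd_map(fit, env)
  expect_gt(nrow(mp), 100)
  expect_true(all(mp$capped %in% c(TRUE, FALSE)))
  expect_true(all(mp$predicted_mdd[mp$capped] <= mp$mld[mp$capped] + 1e-9))
  expect_true(all(mp$predicted_mdd <= mp$mld + 1e-9))
  # capped and uncapped cells partition the predicted cells
  expect_equal(sum(mp$capped) + sum(!mp$capped), nrow(mp))
  expect_equal(attr(mp, "n_cells"), nrow(mp))
})
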