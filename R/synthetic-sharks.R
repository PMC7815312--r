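# Synthetic shark movement and diving. The generator is the inverse of the
# habitat model: daily maximum dive depth (MDD) shrinks multiplicatively when
# local DO at 100 m falls below a threshold, when SST exceeds an optimum, and
# in proportion to NPP at 100 m, with lognormal day-to-day noise floored at
# 10 m. Horizontal movement is a correlated random walk with an optional
# residency bias toward the OMZ area.

#' Behavioural specification for the synthetic shark generator
#'
#' @param do_threshold DO (ml/l) below which MDD depth shrinks (default 3.5).
#' @param sst_optimum SST (degC) above which MDD depth shrinks (default 24).
#' @param npp_sensitivity Dimensionless `>= 0`; strength of the linear MDD
#'   shrinkage with NPP at 100 m (0 disables the NPP effect).
#' @param do_effect,sst_effect Logical switches for the DO and SST effects
#'   (disabling one yields a no-effect null for that covariate).
#' @param baseline_mdd Unconstrained MDD depth, metres (`> 0`).
#' @param mdd_noise_sd Day-to-day MDD noise, metres (applied on the log scale
#'   as a coefficient of variation `mdd_noise_sd / baseline_mdd`).
#' @param step_scale Daily move scale, km (Weibull scale, shape 1.5).
#' @param bearing_concentration Directional persistence `>= 0`; 0 gives
#'   independent uniform bearings, larger values straighter paths.
#' @param omz_residency_bias Dimensionless `>= 0`; probability of rejecting a
#'   proposed move that exits the OMZ is `1 - exp(-bias)`.
#' @param npp_scale NPP (g/l/d) at which the NPP shrinkage saturates.
#' @param seed Integer seed.
#' @return A list of class `shark_behavior_spec`.
#' @export
shark_behavior_spec <- function(do_threshold = 3.5, sst_optimum = 24,
                                npp_sensitivity = 0.5,
                                do_effect = TRUE, sst_effect = TRUE,
                                baseline_mdd = 900, mdd_noise_sd = 180,
                                step_scale = 35, bearing_concentration = 2,
                                omz_residency_bias = 1.5,
                                npp_scale = 0.009, seed = 1L) {
  stopifnot(baseline_mdd > 0, mdd_noise_sd >= 0, npp_sensitivity >= 0,
            omz_residency_bias >= 0, step_scale > 0)
  structure(list(do_threshold = do_threshold, sst_optimum = sst_optimum,
                 npp_sensitivity = npp_sensitivity, do_effect = do_effect,
                 sst_effect = sst_effect, baseline_mdd = baseline_mdd,
                 mdd_noise_sd = mdd_noise_sd, step_scale = step_scale,
                 bearing_concentration = bearing_concentration,
                 omz_residency_bias = omz_residency_bias,
                 npp_scale = npp_scale, seed = as.integer(seed)),
            class = "shark_behavior_spec")
}

#' Deterministic MDD response to the three habitat drivers
#'
#' Multiplicative shrinkage of baseline MDD depth: piecewise linear in DO
#' below `do_threshold` (flat above), tent-shaped in SST (a gentle rise to
#' the optimum, a steeper decline beyond it, so the thermal optimum is an
#' interior maximum of the response), linear in NPP. This is the generative
#' link the habitat model is asked to recover (signs, the DO threshold and
#' the SST optimum -- not the exact shape).
#'
#' @param do_100,sst,npp_100 Covariate vectors.
#' @param spec A [shark_behavior_spec()].
#' @return Expected MDD depth in metres (no noise).
#' @export
mdd_response <- function(do_100, sst, npp_100, spec = shark_behavior_spec()) {
  f_do <- if (spec$do_effect)
    ifelse(do_100 >= spec$do_threshold, 1,
           0.25 + 0.75 * pmax(do_100, 0) / spec$do_threshold) else 1
  f_sst <- if (spec$sst_effect)
    ifelse(sst <= spec$sst_optimum,
           pmax(0.4, 1 - 0.03 * (spec$sst_optimum - sst)), # gentle rise to the optimum
           pmax(0.4, 1 - 0.08 * (sst - spec$sst_optimum))) else 1
  f_npp <- pmax(0.3, 1 - spec$npp_sensitivity * npp_100 / spec$npp_scale)
  spec$baseline_mdd * f_do * f_sst * f_npp
}

# One wrapped-normal turning step: sd (deg) shrinks with concentration.
turn_sd_deg <- function(kappa) {
  if (kappa <= 0) return(Inf)
  180 / pi / sqrt(kappa)
}

#' Generate a synthetic shark track with daily dive summaries
#'
#' Simulates a correlated random walk over the environment grid (reflected at
#' the domain boundary) and, for each day, a true MDD depth from
#' [mdd_response()] at the local conditions plus lognormal noise floored at
#' 10 m, a minimum depth, and a time-at-depth (TAD) histogram over the given
#' depth-class scheme whose rows sum to 100%.
#'
#' @param env An [env_grid()].
#' @param spec A [shark_behavior_spec()].
#' @param n_days Number of tracked days (`>= 2`).
#' @param start `(lon, lat)` start position; defaults to the domain centre.
#' @param animal_id Identifier used in the output tables.
#' @param scheme_year TAD depth-class scheme (`"2010"` or `"2017"`).
#' @return List with `track` (a `shark_track` data.frame) and `dive_days`
#'   (one row per day: `mdd_depth`, `min_depth`, `inside_omz`, covariates,
#'   `tad.*` columns summing to 100). The generative truth (expected MDD and
#'   shrinkage factors per day) is attached as `attr(dive_days,
#'   "generative")`.
#' @export
gen_shark_track <- function(env, spec = shark_behavior_spec(), n_days,
                            start = NULL, animal_id = "S1",
                            scheme_year = "2010") {
  stopifnot(n_days >= 2)
  if (is.null(start))
    start <- c(mean(range(env$lon)), mean(range(env$lat)))
  if (!env_contains(env, start[1], start[2]))
    stop("track start outside environment domain")
  mask <- omz_mask(env)
  inside_at <- function(lon, lat) {
    ij <- env_cell_index(env, lon, lat)
    mask[ij]
  }
  withr_seed(spec$seed, {
    lon <- numeric(n_days); lat <- numeric(n_days)
    lon[1] <- start[1]; lat[1] <- start[2]
    sdb <- turn_sd_deg(spec$bearing_concentration)
    prev_b <- stats::runif(1, 0, 360)
    p_keep_exit <- exp(-spec$omz_residency_bias)
    for (t in 2:n_days) {
      cur_in <- inside_at(lon[t - 1], lat[t - 1])
      for (try in 1:25) {
        b <- if (is.finite(sdb)) (prev_b + stats::rnorm(1, 0, sdb)) %% 360
        else stats::runif(1, 0, 360)
        len <- stats::rweibull(1, shape = 1.5, scale = spec$step_scale)
        p <- gc_destination(lon[t - 1], lat[t - 1], b, len)
        # reflect at the domain boundary
        rng_x <- range(env$lon); rng_y <- range(env$lat)
        px <- p[1, "lon"]; py <- p[1, "lat"]
        if (px < rng_x[1]) px <- rng_x[1] + (rng_x[1] - px)
        if (px > rng_x[2]) px <- rng_x[2] - (px - rng_x[2])
        if (py < rng_y[1]) py <- rng_y[1] + (rng_y[1] - py)
        if (py > rng_y[2]) py <- rng_y[2] - (py - rng_y[2])
        px <- min(max(px, rng_x[1]), rng_x[2])
        py <- min(max(py, rng_y[1]), rng_y[2])
        ok <- TRUE
        if (spec$omz_residency_bias > 0 && isTRUE(cur_in) &&
            !isTRUE(inside_at(px, py)))
          ok <- stats::runif(1) < p_keep_exit
        if (ok || try == 25) {
          lon[t] <- px; lat[t] <- py
          prev_b <- b
          break
        }
      }
    }
    dates <- as.Date("2017-06-01") + seq_len(n_days) - 1
    track <- data.frame(animal_id = animal_id, segment = 1L, date = dates,
                        lon = lon, lat = lat)
    class(track) <- c("shark_track", "data.frame")

    do_100 <- env_value_at(env, lon, lat, 100, "do")
    sst <- env_value_at(env, lon, lat, 0, "temp")
    npp_100 <- env_value_at(env, lon, lat, 100, "npp")
    mdd_true <- mdd_response(do_100, sst, npp_100, spec)
    cv <- spec$mdd_noise_sd / spec$baseline_mdd
    mdd <- pmax(10, mdd_true * exp(stats::rnorm(n_days, 0, cv)))
    min_depth <- stats::runif(n_days, 0, pmin(10, mdd))
    inside <- mask[env_cell_index(env, lon, lat)]

    scheme <- depth_class_scheme(scheme_year)
    tad <- t(vapply(mdd, function(m) tad_from_mdd(m, scheme),
                    numeric(length(scheme$labels))))
    colnames(tad) <- paste0("tad.", scheme$labels)

    dive_days <- data.frame(animal_id = animal_id, date = dates,
                            lon = lon, lat = lat, mdd_depth = mdd,
                            min_depth = min_depth, inside_omz = inside,
                            do_100 = do_100, sst = sst, npp_100 = npp_100)
    dive_days <- cbind(dive_days, tad)
    attr(dive_days, "scheme") <- scheme
    attr(dive_days, "generative") <-
      list(spec = spec, mdd_true = mdd_true,
           factors = data.frame(do_100 = do_100, sst = sst,
                                npp_100 = npp_100))
    list(track = track, dive_days = dive_days)
  })
}

# Allocate 100% of a day across depth classes given the day's maximum depth:
# exponentially surface-weighted over classes whose lower edge is above the
# MDD depth; the class containing the MDD gets the tail mass.
tad_from_mdd <- function(mdd, scheme, scale = 120) {
  edges <- scheme$edges
  k <- length(edges) - 1
  lower <- edges[-length(edges)]
  upper <- edges[-1]
  w <- numeric(k)
  reach <- lower < mdd
  mid <- (lower + pmin(upper, ifelse(is.finite(upper), upper, lower + 200))) / 2
  w[reach] <- exp(-mid[reach] / scale)
  if (all(w == 0)) w[1] <- 1
  100 * w / sum(w)
}

#' Simulate a model frame for habitat-model recovery experiments
#'
#' Draws covariates independently (DO, SST and NPP over realistic OMZ-region
#' ranges, plus pure-noise covariates) for several sharks, then generates MDD
#' depths from [mdd_response()] with a per-shark random intercept and
#' lognormal noise. Used to test whether backward selection recovers the true
#' structure.
#'
#' @param n_sharks Number of sharks.
#' @param days_per_shark Days per shark.
#' @param spec A [shark_behavior_spec()].
#' @param shark_sd SD (m) of the per-shark multiplicative intercept (applied
#'   as `exp(N(0, shark_sd / baseline))`).
#' @param null_model If `TRUE`, MDD is independent of every covariate.
#' @param seed Integer seed.
#' @return data.frame with `shark_id`, `date`, `mdd_depth`, the three driver
#'   covariates and noise covariates (`temp_100`, `sal_surface`, `sal_100`,
#'   `chl_surface`, `chl_100`, `phyto_surface`, `phyto_100`).
#' @export
sim_mdd_frame <- function(n_sharks = 8, days_per_shark = 60,
                          spec = shark_behavior_spec(), shark_sd = 100,
                          null_model = FALSE, seed = 1L) {
  withr_seed(seed, {
    n <- n_sharks * days_per_shark
    id <- factor(rep(paste0("S", seq_len(n_sharks)), each = days_per_shark))
    do_100 <- stats::runif(n, 0.8, 5.5)
    sst <- stats::runif(n, 18, 27)
    npp_100 <- stats::runif(n, 0, spec$npp_scale)
    mdd_true <- if (null_model) rep(spec$baseline_mdd, n)
    else mdd_response(do_100, sst, npp_100, spec)
    b <- stats::rnorm(n_sharks, 0, shark_sd / spec$baseline_mdd)
    cv <- spec$mdd_noise_sd / spec$baseline_mdd
    mdd <- pmax(10, mdd_true * exp(b[as.integer(id)] +
                                     stats::rnorm(n, 0, cv)))
    data.frame(shark_id = id,
               date = as.Date("2017-06-01") + seq_len(n) - 1,
               mdd_depth = mdd, do_100 = do_100, sst = sst,
               npp_100 = npp_100,
               temp_100 = stats::runif(n, 8, 18),
               sal_surface = stats::runif(n, 35, 36.5),
               sal_100 = stats::runif(n, 34.8, 36.2),
               chl_surface = stats::runif(n, 0, 3),
               chl_100 = stats::runif(n, 0, 3),
               phyto_surface = stats::runif(n, 0, 5),
               phyto_100 = stats::runif(n, 0, 5))
  })
}
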