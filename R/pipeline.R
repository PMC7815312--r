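# End-to-end orchestration of the analysis with a single configuration and
# seed: simulate -> process tracks -> match environment -> CRW residency
# test -> dive summaries -> habitat model -> spatial prediction -> set
# detection -> effort/intensity grids -> CPUE transects and quadratic peak.

#' Pipeline configuration with canonical defaults
#'
#' Every threshold the analysis uses, with its canonical default: OMZ
#' definition DO < 3.5 ml/l at 100 m; 3 m/s speed filter; 20-day gap split;
#' deep-dive threshold 600 m; upper-layer cutoff 250 m; 0.90 MDD outlier
#' quantile; 100 CRW replicates; 80-100 km line bounds, >130-degree turns,
#' 25% endpoint tolerance, 30 km ARS radius; six CPUE transects at 20.5,
#' 15.5, 12.5, 11.5, 10.5 and 9.5 degrees N over -46.5 to -15.5 degrees E.
#' The configuration round-trips through JSON serialization.
#'
#' @param ... Named overrides of any default.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    omz_do_threshold = 3.5, omz_ref_depth = 100,
    speed_filter_ms = 3, max_gap_days = 20,
    deep_dive_threshold = 600, upper_cutoff = 250, outlier_quantile = 0.90,
    crw_replicates = 100,
    vms_line_bounds = c(80, 100), vms_turn_angle = 130,
    vms_endpoint_tol = 0.25, ars_radius_km = 30,
    model_k = 10, model_alpha = 0.01,
    model_candidates = c("sst", "temp_100", "sal_100", "do_100", "npp_100",
                         "chl_surface"),
    transect_latitudes = c(20.5, 15.5, 12.5, 11.5, 10.5, 9.5),
    transect_lon_range = c(-46.5, -15.5),
    n_sharks = 6, n_days = 90, n_vessels = 8, n_logbook_sets = 2000,
    logbook_peak_do = 3.0,
    output_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates the environment, sharks, vessels and logbook from `seed`, then
#' executes every analysis stage. All randomness derives from `seed`;
#' identical `(config, seed)` give identical results.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @return List of class `pipeline_result` with per-stage outputs and a
#'   `manifest` (seeds, stage names, timings in seconds).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L) {
  seed <- as.integer(seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  mark <- function(nm) {
    timings[[nm]] <<- tic() - t0
    t0 <<- tic()
  }

  env <- stage("simulate-env",
               gen_env_field(env_grid_spec(seed = seed)))
  mark("simulate-env")

  sharks <- stage("simulate-sharks", lapply(seq_len(config$n_sharks),
    function(i) gen_shark_track(
      env, shark_behavior_spec(seed = seed + i), n_days = config$n_days,
      animal_id = paste0("S", i))))
  mark("simulate-sharks")

  crw <- stage("crw-test", lapply(sharks, function(s)
    crw_omz_test(s$track, env, n_replicates = config$crw_replicates,
                 seed = seed + 1000L,
                 threshold = config$omz_do_threshold,
                 ref_depth = config$omz_ref_depth)))
  mark("crw-test")

  dive_days <- stage("dive-summary", do.call(rbind, lapply(sharks,
    function(s) s$dive_days)))
  per_shark <- stage("dive-summary",
                     vertical_summary(dive_days,
                                      upper_cutoff = config$upper_cutoff,
                                      deep_threshold =
                                        config$deep_dive_threshold))
  summary_stats <- summarize_vertical(per_shark)
  compression <- pct_reduction(summary_stats["mean", "max_depth_omz"],
                               summary_stats["mean", "max_depth_outside"])
  mark("dive-summary")

  frame <- stage("fit-gamm", build_frame(
    dive_days, covariates = intersect(config$model_candidates,
                                      names(dive_days)),
    outlier_quantile = config$outlier_quantile))
  frame$shark_id <- frame$animal_id
  fit <- stage("fit-gamm", fit_mdd_model(
    frame, candidates = intersect(config$model_candidates, names(frame)),
    k = min(config$model_k, 8), alpha = config$model_alpha))
  mark("fit-gamm")

  mdd_map <- stage("predict-map", predict_mdd_map(fit, env))
  mark("predict-map")

  vessels <- stage("vms-detect", lapply(seq_len(config$n_vessels),
    function(i) gen_vessel_track(
      vessel_behavior_spec(seed = seed + 2000L + i),
      start = c(stats::runif(1, min(env$lon) + 3, max(env$lon) - 3),
                stats::runif(1, min(env$lat) + 3, max(env$lat) - 3)))))
  detected <- stage("vms-detect", do.call(rbind, lapply(seq_along(vessels),
    function(i) {
      tr <- vessels[[i]]$track
      tr$vessel_id <- paste0("V", i)
      detect_longline_sets(tr, config$vms_line_bounds,
                           config$vms_turn_angle, config$vms_endpoint_tol)
    })))
  mark("vms-detect")

  effort <- stage("effort-grid", {
    locs <- data.frame(vessel_id = detected$vessel_id, date = detected$date,
                       lon = detected$turn_lon, lat = detected$turn_lat)
    eg <- fishing_effort_grid(locs)
    fi <- fishing_intensity(locs, ars_radius = config$ars_radius_km)
    g <- merge(eg, fi, by = c("cell_lon", "cell_lat"), all = TRUE)
    flag_omz_cells(g, env, config$omz_do_threshold, config$omz_ref_depth)
  })
  mark("effort-grid")

  logbook <- stage("cpue-transect", gen_logbook(
    env, peak_do = config$logbook_peak_do, n_sets = config$n_logbook_sets,
    seed = seed + 3000L))
  cpue <- stage("cpue-transect", add_cell_do(cpue_grid(logbook), env,
                                             config$omz_ref_depth))
  cpue_fit <- stage("cpue-transect",
                    fit_cpue_quadratic(cpue$do_100, cpue$mean_cpue))
  mark("cpue-transect")

  result <- list(
    env = env, sharks = sharks, crw = crw, dive_days = dive_days,
    per_shark = per_shark, summary_stats = summary_stats,
    compression_pct = compression, frame = frame, fit = fit,
    mdd_map = mdd_map, detected_sets = detected, effort_grid = effort,
    logbook = logbook, cpue_cells = cpue, cpue_fit = cpue_fit,
    manifest = list(seed = seed, config = unclass(config),
                    timings_s = as.list(timings)))
  class(result) <- "pipeline_result"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_results(result, config$output_dir)
  }
  result
}

#' Write the machine-readable pipeline outputs
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$per_shark,
                   file.path(dir, "vertical_summary_per_shark.csv"),
                   row.names = FALSE)
  utils::write.csv(result$effort_grid, file.path(dir, "effort_grid.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cpue_cells, file.path(dir, "cpue_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(result$mdd_map, file.path(dir, "mdd_prediction.csv"),
                   row.names = FALSE)
  summary_json <- list(
    compression_pct = result$compression_pct,
    crw_p_values = vapply(result$crw, `[[`, numeric(1), "p_value"),
    model_terms = result$fit$term_labels,
    model_aic = result$fit$aic,
    cpue_peak_do = result$cpue_fit$peak_do,
    n_detected_sets = nrow(result$detected_sets),
    manifest = result$manifest)
  jsonlite::write_json(summary_json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
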