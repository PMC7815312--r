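#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Builds the OMZ-structured environment (0.25-degree grid with a sharp
# oxycline near 60 m over the core and a deep one outside), six PSAT-style
# shark tracks with dive summaries, eight longliner trips, and a 2000-set
# logbook whose catches peak at DO = 3.0 ml/l. Everything downstream reads
# these files.

suppressMessages(library(omzshark))
seed <- 1L
set.seed(seed)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

env <- gen_env_field(env_grid_spec(seed = seed))
write_env_nc(env, file.path(out, "environment.nc"))
cat(sprintf("environment: %d x %d cells, OMZ area fraction %.2f\n",
            length(env$lon), length(env$lat), omz_area_fraction(env)))

dive_all <- list(); track_all <- list()
spec0 <- env_grid_spec(seed = seed)
for (i in 1:6) {
  # tagged above or near the OMZ area, as in the 2017 deployments
  start <- spec0$omz_center + runif(2, -3, 3)
  sh <- gen_shark_track(env, shark_behavior_spec(seed = seed + i),
                        n_days = 90, start = start,
                        animal_id = paste0("S", i))
  track_all[[i]] <- sh$track
  dive_all[[i]] <- sh$dive_days
}
tracks <- do.call(rbind, track_all)
dives <- do.call(rbind, dive_all)
write.csv(tracks, file.path(out, "shark_tracks.csv"), row.names = FALSE)
write.csv(dives, file.path(out, "shark_dive_days.csv"), row.names = FALSE)
cat(sprintf("sharks: %d tracks, %d dive days, %.0f%% of days over the OMZ\n",
            length(track_all), nrow(dives), 100 * mean(dives$inside_omz)))

pings <- list(); truth <- list()
for (i in 1:8) {
  # fleets concentrate above the OMZ: most trips start near its core, the
  # rest anywhere in the domain
  start <- if (i <= 5) spec0$omz_center + runif(2, -4, 4)
  else c(runif(1, -40, -15), runif(1, 4, 22))
  vt <- gen_vessel_track(vessel_behavior_spec(seed = seed + 100 + i),
                         start = start, vessel_id = paste0("V", i))
  pings[[i]] <- vt$track
  truth[[i]] <- vt$sets
}
write.csv(do.call(rbind, pings), file.path(out, "vessel_pings.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, truth), file.path(out, "vessel_sets_truth.csv"),
          row.names = FALSE)
cat(sprintf("vessels: %d trips, %d true deployments\n", 8,
            nrow(do.call(rbind, truth))))

logbook <- gen_logbook(env, peak_do = 3.0, n_sets = 2000, seed = seed + 200)
write.csv(logbook, file.path(out, "logbook.csv"), row.names = FALSE)
cat(sprintf("logbook: %d sets, %.0f t total catch\n", nrow(logbook),
            sum(logbook$biomass) / 1000))
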