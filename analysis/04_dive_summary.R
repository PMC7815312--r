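#!/usr/bin/env Rscript
# Stage 4: vertical habitat use inside vs outside the OMZ.
#
# Per-shark summaries (% time in the upper 250 m, days with dives below
# 600 m, maximum dive depth) split by zone, cross-shark means and SDs, the
# habitat-compression percentage, and the boundary-day comparison around
# OMZ entries. The same summary is also computed for the package's
# reference table of ten PSAT-tracked blue sharks.

suppressMessages(library(omzshark))
dives <- read.csv("results/data/shark_dive_days.csv")
dives$date <- as.Date(dives$date)

per_shark <- vertical_summary(dives)
stats <- summarize_vertical(per_shark)
write.csv(per_shark, "results/vertical_summary_per_shark.csv",
          row.names = FALSE)
write.csv(cbind(stat = rownames(stats), stats), "results/vertical_summary.csv",
          row.names = FALSE)
cat("synthetic sharks:\n")
cat(sprintf("  %% time upper 250 m: %.1f inside vs %.1f outside\n",
            stats["mean", "pct_upper_omz"], stats["mean", "pct_upper_outside"]))
cat(sprintf("  deep-dive days (>600 m): %.1f inside vs %.1f outside\n",
            stats["mean", "deep_dives_omz"],
            stats["mean", "deep_dives_outside"]))
cat(sprintf("  max dive depth: %.0f m inside vs %.0f m outside -> %.0f%% habitat compression\n",
            stats["mean", "max_depth_omz"], stats["mean", "max_depth_outside"],
            pct_reduction(stats["mean", "max_depth_omz"],
                          stats["mean", "max_depth_outside"])))

pairs <- suppressWarnings(boundary_day_comparison(dives))
if (nrow(pairs) > 0) {
  write.csv(pairs, "results/boundary_day_pairs.csv", row.names = FALSE)
  cat(sprintf("boundary days: %d entry events; MDD %.0f m the day before entry vs %.0f m the day after\n",
              nrow(pairs), mean(pairs$mdd_outside), mean(pairs$mdd_inside)))
}

ref <- reference_vertical_summary()
rstats <- summarize_vertical(ref)
cat("reference PSAT table (10 blue sharks):\n")
cat(sprintf("  max dive depth %.1f m inside vs %.1f m outside -> %.0f%% reduction\n",
            rstats["mean", "max_depth_omz"],
            rstats["mean", "max_depth_outside"],
            pct_reduction(rstats["mean", "max_depth_omz"],
                          rstats["mean", "max_depth_outside"])))
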