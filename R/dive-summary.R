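# Vertical-behaviour summaries: time-at-depth above a cutoff, deep-dive
# counts, per-shark inside/outside-OMZ summary tables with cross-shark means,
# boundary-day pairs, and the habitat-compression percentage.

#' Time-at-depth depth-class schemes
#'
#' Tag deployments binned time-at-depth into fixed depth classes; the class
#' edges differed between deployment years. `"2010"` uses edges
#' 0-50-100-150-200-250-400-600->600 m; `"2017"` uses
#' 0-50-100-150-200-250-300-500-700->700 m.
#'
#' @param year `"2010"` or `"2017"`, or a numeric vector of ascending edges
#'   starting at 0 (an open top class is appended).
#' @return List with `edges` (including `Inf`) and `labels`.
#' @export
depth_class_scheme <- function(year = "2010") {
  edges <- if (is.numeric(year)) c(year, Inf)
  else switch(as.character(year),
              "2010" = c(0, 50, 100, 150, 200, 250, 400, 600, Inf),
              "2017" = c(0, 50, 100, 150, 200, 250, 300, 500, 700, Inf),
              stop("unknown scheme year: ", year))
  if (edges[1] != 0 || any(diff(edges) <= 0))
    stop("scheme edges must start at 0 and increase strictly")
  k <- length(edges) - 1
  labels <- ifelse(is.finite(edges[-1]),
                   paste0(edges[-length(edges)], "_", edges[-1]),
                   paste0("gt", edges[k]))
  list(edges = edges, labels = labels)
}

tad_matrix <- function(dive_days, scheme) {
  cols <- paste0("tad.", scheme$labels)
  missing <- setdiff(cols, names(dive_days))
  if (length(missing) > 0)
    stop("dive table lacks TAD columns: ", paste(missing, collapse = ", "))
  as.matrix(dive_days[, cols, drop = FALSE])
}

#' Percentage of time above a depth cutoff
#'
#' Mean over days of the summed TAD percentages of all classes lying
#' entirely above `cutoff`. The cutoff must coincide with a class edge (no
#' within-class interpolation).
#'
#' @param dive_days data.frame with `tad.*` columns for `scheme`.
#' @param scheme A [depth_class_scheme()].
#' @param cutoff Depth cutoff in metres (default 250).
#' @return Percentage in `[0, 100]`.
#' @export
pct_time_upper <- function(dive_days, scheme = depth_class_scheme("2010"),
                           cutoff = 250) {
  if (!cutoff %in% scheme$edges)
    stop("cutoff ", cutoff, " m is not a class edge of this scheme")
  tad <- tad_matrix(dive_days, scheme)
  above <- scheme$edges[-1] <= cutoff
  mean(rowSums(tad[, above, drop = FALSE]))
}

#' Count days with a dive below a threshold
#'
#' Dive records are daily summaries, so a day with one or more excursions
#' past the threshold counts once: the count is the number of days whose
#' daily maximum depth exceeds `threshold`.
#'
#' @param dive_days data.frame with `mdd_depth`.
#' @param threshold Depth threshold in metres (default 600).
#' @return Integer count.
#' @export
count_deep_dives <- function(dive_days, threshold = 600) {
  sum(dive_days$mdd_depth > threshold, na.rm = TRUE)
}

#' Per-shark vertical summary inside and outside the OMZ
#'
#' For each shark and zone: percent time in the upper `upper_cutoff` metres,
#' number of days with dives below `deep_threshold`, and maximum dive depth.
#' Sharks with no days in a zone get `NA` in that zone's columns.
#'
#' @param dive_days data.frame with `animal_id`, `inside_omz`, `mdd_depth`
#'   and `tad.*` columns.
#' @param scheme A [depth_class_scheme()] matching the TAD columns.
#' @param upper_cutoff,deep_threshold Metres (defaults 250 and 600).
#' @return data.frame, one row per shark, columns `pct_upper_omz`,
#'   `pct_upper_outside`, `deep_dives_omz`, `deep_dives_outside`,
#'   `max_depth_omz`, `max_depth_outside`.
#' @export
vertical_summary <- function(dive_days, scheme = depth_class_scheme("2010"),
                             upper_cutoff = 250, deep_threshold = 600) {
  one_zone <- function(d) {
    if (nrow(d) == 0)
      return(c(pct_upper = NA_real_, deep_dives = NA_real_,
               max_depth = NA_real_))
    c(pct_upper = pct_time_upper(d, scheme, upper_cutoff),
      deep_dives = as.numeric(count_deep_dives(d, deep_threshold)),
      max_depth = max(d$mdd_depth, na.rm = TRUE))
  }
  ids <- unique(dive_days$animal_id)
  rows <- lapply(ids, function(id) {
    d <- dive_days[dive_days$animal_id == id, , drop = FALSE]
    zin <- one_zone(d[isTRUE_v(d$inside_omz), , drop = FALSE])
    zout <- one_zone(d[!isTRUE_v(d$inside_omz) & !is.na(d$inside_omz), ,
                       drop = FALSE])
    data.frame(shark_id = id,
               pct_upper_omz = zin["pct_upper"],
               pct_upper_outside = zout["pct_upper"],
               deep_dives_omz = zin["deep_dives"],
               deep_dives_outside = zout["deep_dives"],
               max_depth_omz = zin["max_depth"],
               max_depth_outside = zout["max_depth"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Cross-shark means and SDs of a per-shark vertical summary
#'
#' Column means ignore absent (NA) cells, e.g. sharks whose tag reported in
#' only one zone; the SD is the sample (n-1) standard deviation.
#'
#' @param per_shark Output of [vertical_summary()], or any data.frame whose
#'   non-id numeric columns are per-shark statistics.
#' @return data.frame with rows `mean` and `sd`.
#' @export
summarize_vertical <- function(per_shark) {
  num <- per_shark[, vapply(per_shark, is.numeric, logical(1)), drop = FALSE]
  out <- rbind(mean = vapply(num, function(x) mean(x, na.rm = TRUE),
                             numeric(1)),
               sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE),
                           numeric(1)))
  as.data.frame(out)
}

#' Percentage reduction of a mean inside relative to outside
#'
#' `100 * (1 - mean_inside / mean_outside)`; the habitat-compression
#' headline number when applied to mean maximum dive depths.
#'
#' @param mean_inside,mean_outside Means (same units); `mean_outside > 0`.
#' @return Percentage.
#' @export
pct_reduction <- function(mean_inside, mean_outside) {
  if (mean_outside <= 0) stop("mean_outside must be > 0")
  100 * (1 - mean_inside / mean_outside)
}

#' Boundary-day pairs around OMZ entries
#'
#' For each OMZ entry event (a day classified inside whose previous day was
#' outside), pairs the day prior to entry (outside) with the day following
#' entry (inside). Events lacking either flanking day -- or whose following
#' day is not inside -- are dropped with a warning.
#'
#' @param dive_days data.frame with `animal_id`, `date`, `inside_omz` and
#'   dive columns.
#' @return data.frame with one row per usable entry event: `animal_id`,
#'   `entry_date`, `outside_date`, `inside_date`, `mdd_outside`,
#'   `mdd_inside`.
#' @export
boundary_day_comparison <- function(dive_days) {
  out <- list()
  dropped <- 0L
  for (id in unique(dive_days$animal_id)) {
    d <- dive_days[dive_days$animal_id == id, , drop = FALSE]
    d <- d[order(d$date), ]
    ins <- isTRUE_v(d$inside_omz)
    entries <- which(ins & c(FALSE, !ins[-length(ins)]))
    for (e in entries) {
      prev_ok <- e > 1 && d$date[e - 1] == d$date[e] - 1 && !ins[e - 1]
      next_ok <- e < nrow(d) && d$date[e + 1] == d$date[e] + 1 && ins[e + 1]
      if (prev_ok && next_ok) {
        out[[length(out) + 1]] <- data.frame(
          animal_id = id, entry_date = d$date[e],
          outside_date = d$date[e - 1], inside_date = d$date[e + 1],
          mdd_outside = d$mdd_depth[e - 1], mdd_inside = d$mdd_depth[e + 1])
      } else dropped <- dropped + 1L
    }
  }
  if (dropped > 0)
    warning(dropped, " entry event(s) lacked a flanking day and were dropped")
  if (length(out) == 0)
    return(data.frame(animal_id = character(), entry_date = as.Date(character()),
                      outside_date = as.Date(character()),
                      inside_date = as.Date(character()),
                      mdd_outside = numeric(), mdd_inside = numeric()))
  do.call(rbind, out)
}

#' Reference per-shark vertical summary table
#'
#' Loads the package's reference table of per-shark vertical-movement
#' summaries for ten PSAT-tracked blue sharks that encountered the eastern
#' tropical Atlantic OMZ area (percent time in the upper 250 m, days with
#' dives below 600 m, and maximum dive depth, inside and outside the OMZ;
#' non-reporting cells are `NA`).
#'
#' @return data.frame in the layout of [vertical_summary()].
#' @export
reference_vertical_summary <- function() {
  path <- system.file("extdata", "psat_vertical_summary.csv",
                      package = "omzshark", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
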