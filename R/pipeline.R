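# End-to-end convenience wrapper: raw fixes -> cleaned trips -> bird-days ->
# ARS labels -> environmental annotation, ready for the behaviour tests and
# the per-day habitat forests.

#' Run the track-to-ARS pipeline on a study
#'
#' For every bird: speed-filters the fixes, splits trips at the colony
#' buffer, removes overnight rest and splits multi-day trips into bird-days,
#' interpolates each bird-day at `spacing_m`, runs the FPT scan and Lavielle
#' segmentation to label ARS locations at the smallest fine scale, and
#' (optionally) annotates every location with the environmental fields.
#'
#' @param tracks Fix table (`bird_id`, `timestamp` UTC seconds, `lon`,
#'   `lat`), e.g. `simulate_study()$tracks` or [read_study()]`$tracks`.
#' @param colony_lonlat Colony coordinates `c(lon, lat)`.
#' @param rasters Optional named list of environmental fields for
#'   [annotate_locations()].
#' @param buffer_m Colony buffer radius (default 1000 m).
#' @param max_kmh Speed-filter threshold (default 90 km/h).
#' @param spacing_m Interpolation spacing (default 100 m).
#' @param r_step FPT radius increment in metres (default 10, faithful but
#'   slow; 50-100 loses little for fine scales above a few hundred metres).
#' @param r_max Largest FPT radius; default half the mean colony distance of
#'   each bird-day.
#' @param fine_scale_max_m Fine-scale ceiling for ARS labelling (8 km).
#' @param min_locations Minimum interpolated locations per bird-day.
#' @return List: `trips` (descriptors per trip), `day_metrics` (per
#'   bird-day: scales, zones, ARS metrics), `locations` (all interpolated
#'   locations with `label` and any covariate columns), `n_removed_speed`.
#' @export
run_ars_pipeline <- function(tracks, colony_lonlat, rasters = NULL,
                             buffer_m = 1000, max_kmh = 90, spacing_m = 100,
                             r_step = 10, r_max = NULL,
                             fine_scale_max_m = 8000, min_locations = 50) {
  trips_out <- list(); days_out <- list(); locs_out <- list()
  n_removed <- 0L
  for (b in unique(tracks$bird_id)) {
    tr <- tracks[tracks$bird_id == b, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    tr <- filter_speed(tr, max_kmh = max_kmh)
    n_removed <- n_removed + attr(tr, "n_removed")
    tr <- project_fixes(tr, colony_lonlat)
    trips <- split_trips(tr, colony_lonlat, buffer_m = buffer_m)
    for (ti in seq_along(trips)) {
      trip <- trips[[ti]]
      trip$trip_id <- ti
      desc <- trip_descriptors(trip, colony_lonlat)
      desc$bird_id <- b; desc$trip_id <- ti
      bds <- split_bird_days(trip, colony_lonlat, spacing_m = spacing_m,
                             min_locations = min_locations)
      desc$n_days <- length(bds)
      trips_out[[length(trips_out) + 1]] <- desc
      for (bd in bds) {
        rmax_d <- if (is.null(r_max)) {
          tryCatch(rmax_from_data(bd$colony_dist_m), error = function(e) NA)
        } else r_max
        if (is.na(rmax_d) || rmax_d < r_step) next
        day <- ars_day(bd, radii = seq(r_step, rmax_d, by = r_step),
                       fine_scale_max_m = fine_scale_max_m)
        met <- day$metrics
        met$bird_id <- b; met$trip_id <- ti; met$day_index <- bd$day_index[1]
        days_out[[length(days_out) + 1]] <- met
        bd$label <- day$labels
        locs_out[[length(locs_out) + 1]] <- bd
      }
    }
  }
  locations <- do.call(rbind, locs_out)
  if (!is.null(rasters) && !is.null(locations)) {
    locations <- annotate_locations(locations, rasters)
  }
  list(trips = do.call(rbind, trips_out),
       day_metrics = do.call(rbind, days_out),
       locations = locations,
       n_removed_speed = n_removed)
}

#' Trip-level behaviour metric table
#'
#' Joins trip descriptors with day-level ARS summaries averaged per trip:
#' the five trip descriptors (duration, distance, max colony distance,
#' smallest and largest ARS scale) and the six small-scale ARS
#' characteristics (scales, zones, duration, distance, colony distance,
#' angle), ready for [behavior_distance()].
#'
#' @param pipeline Result of [run_ars_pipeline()].
#' @param metadata Optional per-bird metadata (`bird_id`, grouping factors)
#'   merged onto the result.
#' @return Data frame with one row per trip.
#' @export
trip_behavior_table <- function(pipeline, metadata = NULL) {
  dm <- pipeline$day_metrics
  agg <- stats::aggregate(
    dm[, c("n_scales", "n_zones", "ars_duration_h", "ars_distance_km",
           "colony_to_ars_km")],
    by = list(bird_id = dm$bird_id, trip_id = dm$trip_id),
    FUN = mean, na.rm = TRUE)
  ang <- stats::aggregate(list(angle_to_ars_deg = dm$angle_to_ars_deg),
                          by = list(bird_id = dm$bird_id,
                                    trip_id = dm$trip_id),
                          FUN = function(a) circular_mean_deg(a[!is.na(a)]))
  scl <- stats::aggregate(list(smallest_scale_km = dm$smallest_scale_m / 1000,
                               largest_scale_km = dm$largest_scale_m / 1000),
                          by = list(bird_id = dm$bird_id,
                                    trip_id = dm$trip_id),
                          FUN = mean, na.rm = TRUE)
  out <- merge(merge(pipeline$trips, agg, by = c("bird_id", "trip_id")),
               merge(ang, scl, by = c("bird_id", "trip_id")),
               by = c("bird_id", "trip_id"))
  if (!is.null(metadata)) out <- merge(out, metadata, by = "bird_id")
  out
}
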