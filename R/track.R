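# Raw-fix cleaning and structuring: planar projection, the 90 km/h speed
# filter, trip splitting at the colony buffer, overnight-rest removal with
# bird-day splitting, and 100-m path interpolation.

#' Project fixes onto the local plane and compute speeds
#'
#' Adds planar `x`, `y` (metres, azimuthal-equidistant about the colony) and
#' `speed_kmh` (from the previous fix; `NA` for the first) to a fix table.
#'
#' @param fixes Data frame with `timestamp` (UTC seconds), `lon`, `lat`,
#'   sorted by time within one bird.
#' @param colony_lonlat Colony coordinates `c(lon, lat)`.
#' @return `fixes` with `x`, `y`, `speed_kmh` columns.
#' @export
project_fixes <- function(fixes, colony_lonlat) {
  stopifnot(all(c("timestamp", "lon", "lat") %in% names(fixes)))
  if (is.unsorted(fixes$timestamp)) {
    stop("timestamps must be non-decreasing within a track")
  }
  xy <- lonlat_to_xy(fixes$lon, fixes$lat, colony_lonlat)
  fixes$x <- xy[, "x"]; fixes$y <- xy[, "y"]
  fixes$speed_kmh <- fix_speeds_kmh(fixes)
  fixes
}

fix_speeds_kmh <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(rep(NA_real_, n))
  d <- haversine_m(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1])
  dt <- diff(fixes$timestamp)
  c(NA_real_, ifelse(dt > 0, d / dt * 3.6, Inf))
}

#' Remove fixes implying unrealistic flight speeds
#'
#' Iteratively removes the later fix of any pair whose implied speed exceeds
#' `max_kmh` (default 90 km/h), recomputing speeds after each removal, until
#' no violation remains.
#'
#' @param fixes Fix table (one bird, time-sorted) with `timestamp`, `lon`,
#'   `lat`.
#' @param max_kmh Speed threshold in km/h.
#' @return The filtered fix table; the number of removals is attached as
#'   attribute `"n_removed"`.
#' @export
filter_speed <- function(fixes, max_kmh = 90) {
  stopifnot(nrow(fixes) >= 2)
  removed <- 0L
  repeat {
    sp <- fix_speeds_kmh(fixes)
    bad <- which(sp > max_kmh)
    if (!length(bad)) break
    fixes <- fixes[-bad[1], , drop = FALSE]
    removed <- removed + 1L
    if (nrow(fixes) < 2) stop("speed filter removed nearly all fixes")
  }
  attr(fixes, "n_removed") <- removed
  fixes
}

#' Split a bird's track into foraging trips
#'
#' A trip is a maximal excursion beyond the colony buffer, extended to
#' include the location immediately prior to departure and the location
#' immediately following return. Fixes wholly inside the buffer are colony
#' attendance, not trips.
#'
#' @param fixes Fix table for one bird (time-sorted).
#' @param colony_lonlat Colony coordinates `c(lon, lat)`.
#' @param buffer_m At-colony buffer radius in metres (default 1000; the
#'   colony islet is well under 1 km across).
#' @return A list of fix tables, one per trip (possibly empty).
#' @export
split_trips <- function(fixes, colony_lonlat, buffer_m = 1000) {
  d <- haversine_m(fixes$lon, fixes$lat, colony_lonlat[1], colony_lonlat[2])
  away <- d > buffer_m
  if (!any(away)) return(list())
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (k in which(r$values)) {
    i0 <- max(1L, starts[k] - 1L)            # fix just before departure
    i1 <- min(nrow(fixes), ends[k] + 1L)     # fix just after return
    out[[length(out) + 1]] <- fixes[i0:i1, , drop = FALSE]
  }
  out
}

#' Remove overnight rest and split a trip into bird-days
#'
#' A rest bout is a maximal run of fixes during local night (solar
#' 20:00-05:00 at the colony longitude) whose implied speeds are all below
#' `rest_kmh`, lasting at least `min_rest_s`. Rest fixes are removed; the
#' remaining at-sea stretches become bird-days, each interpolated to
#' `spacing_m` with [interpolate_path()]. Bird-days with fewer than
#' `min_locations` interpolated locations are dropped with a message.
#'
#' @param trip One trip's fix table (with `x`, `y`; see [project_fixes()]).
#' @param colony_lonlat Colony coordinates (for solar time and bearings).
#' @param rest_kmh Rest speed ceiling, km/h.
#' @param min_rest_s Minimum rest-bout duration, seconds.
#' @param spacing_m Interpolation spacing, metres.
#' @param min_locations Minimum interpolated locations per bird-day.
#' @param interpolate Interpolate each bird-day (default); `FALSE` returns
#'   the raw segments.
#' @return A list of bird-day location tables (columns `x`, `y`, `lon`,
#'   `lat`, `timestamp`, `colony_dist_m`, `colony_bearing_deg`, plus
#'   `day_index`); removed rest fixes are attached as attribute
#'   `"removed_rest"`.
#' @export
split_bird_days <- function(trip, colony_lonlat, rest_kmh = 2,
                            min_rest_s = 3600, spacing_m = 100,
                            min_locations = 50, interpolate = TRUE) {
  stopifnot(all(c("x", "y", "timestamp") %in% names(trip)))
  n <- nrow(trip)
  sp <- fix_speeds_kmh(trip)
  hour <- solar_hour(trip$timestamp, colony_lonlat[1])
  night <- hour >= 20 | hour < 5
  resty <- night & (is.na(sp) | sp < rest_kmh)
  r <- rle(resty)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  rest_idx <- integer(0)
  for (k in which(r$values)) {
    if (trip$timestamp[ends[k]] - trip$timestamp[starts[k]] >= min_rest_s) {
      rest_idx <- c(rest_idx, starts[k]:ends[k])
    }
  }
  keep <- setdiff(seq_len(n), rest_idx)
  seg_id <- cumsum(c(1L, diff(keep) > 1L))
  days <- split(trip[keep, , drop = FALSE], seg_id)
  out <- list()
  for (d in seq_along(days)) {
    bd <- days[[d]]
    if (nrow(bd) < 2) next
    if (interpolate) {
      bd <- interpolate_path(bd, spacing_m)
      if (nrow(bd) < min_locations) {
        message("dropping bird-day ", d, ": only ", nrow(bd),
                " interpolated locations")
        next
      }
    }
    bd$day_index <- length(out) + 1L
    ll <- xy_to_lonlat(bd$x, bd$y, colony_lonlat)
    bd$lon <- ll[, "lon"]; bd$lat <- ll[, "lat"]
    bd$colony_dist_m <- sqrt(bd$x^2 + bd$y^2)
    bd$colony_bearing_deg <- (atan2(bd$x, bd$y) * 180 / pi) %% 360
    out[[length(out) + 1]] <- bd
  }
  attr(out, "removed_rest") <- trip[rest_idx, , drop = FALSE]
  out
}

#' Interpolate a path at fixed spacing
#'
#' Resamples the planar polyline through the fixes at exactly `spacing_m`
#' metres of arc length (the final point is the original endpoint and may
#' close a shorter step). Timestamps are interpolated linearly along each
#' original segment, so the resampled path preserves both geometry and
#' timing.
#'
#' @param fixes Fix table with planar `x`, `y` and `timestamp`.
#' @param spacing_m Spacing in metres (default 100, the standard for
#'   first-passage-time analysis of interpolated tracks).
#' @return Data frame `x`, `y`, `timestamp` (other columns are dropped;
#'   identifiers `bird_id`/`trip_id` are carried over when constant).
#' @export
interpolate_path <- function(fixes, spacing_m = 100) {
  stopifnot(nrow(fixes) >= 2)
  dx <- diff(fixes$x); dy <- diff(fixes$y)
  seg <- sqrt(dx^2 + dy^2)
  keep <- c(TRUE, seg > 1e-9)
  f <- fixes[keep, , drop = FALSE]
  if (nrow(f) < 2) stop("zero-length path cannot be interpolated")
  s <- c(0, cumsum(sqrt(diff(f$x)^2 + diff(f$y)^2)))
  total <- s[length(s)]
  targets <- seq(0, total, by = spacing_m)
  if (targets[length(targets)] < total - 1e-9) targets <- c(targets, total)
  out <- data.frame(
    x = stats::approx(s, f$x, xout = targets)$y,
    y = stats::approx(s, f$y, xout = targets)$y,
    timestamp = stats::approx(s, f$timestamp, xout = targets)$y
  )
  for (id in c("bird_id", "trip_id")) {
    if (id %in% names(fixes) && length(unique(fixes[[id]])) == 1) {
      out[[id]] <- fixes[[id]][1]
    }
  }
  out
}

#' Trip summary descriptors
#'
#' Duration (hours, first to last fix), total distance travelled (km, polyline
#' length) and maximum distance from the colony (km).
#'
#' @param trip One trip's fix table with `lon`, `lat`, `timestamp`.
#' @param colony_lonlat Colony coordinates.
#' @return One-row data frame `duration_h`, `distance_km`, `max_dist_km`
#'   (plus `bird_id`/`trip_id` when present).
#' @export
trip_descriptors <- function(trip, colony_lonlat) {
  n <- nrow(trip)
  stopifnot(n >= 2)
  d <- haversine_m(trip$lon[-n], trip$lat[-n], trip$lon[-1], trip$lat[-1])
  cd <- haversine_m(trip$lon, trip$lat, colony_lonlat[1], colony_lonlat[2])
  out <- data.frame(
    duration_h = (trip$timestamp[n] - trip$timestamp[1]) / 3600,
    distance_km = sum(d) / 1000,
    max_dist_km = max(cd) / 1000
  )
  for (id in c("bird_id", "trip_id")) {
    if (id %in% names(trip)) out[[id]] <- trip[[id]][1]
  }
  out
}
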