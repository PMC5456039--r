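# Synthetic tracking study generator. Produces seeded GPS tracks (commute
# legs alternating with area-restricted-search bouts confined to patches of
# known radius), gridded environmental fields whose "driver" variables take
# designated value bands inside the ARS patches, and a ground-truth record,
# so every downstream stage can be validated against known answers.

PERIOD_STARTS <- c(
  May2013 = "2013-05-17", Nov2013 = "2013-11-01", Dec2014 = "2014-12-04"
)

#' The eleven oceanographic covariates
#'
#' Name, observed value range, native grid resolution and units for the
#' eleven environmental variables used throughout the package (sea surface
#' height anomaly, currents, temperature at three cadences, chlorophyll-a at
#' two cadences, mixed layer depth, wind, bathymetry, and distance to the
#' nearest SST front).
#'
#' @return A data frame with columns `variable`, `min`, `max`, `res_deg`,
#'   `units`, `cadence`.
#' @export
table1_variables <- function() {
  data.frame(
    variable = c("bathymetry", "chla_8day", "chla_monthly", "dist_front",
                 "mld", "ssha", "sst_daily", "sst_8day", "sst_monthly",
                 "velocity", "wind_speed"),
    min = c(-3788, 0.05, 0.06, 0, 1.0, -0.1, 23.5, 24.2, 24.3, 0.01, 2.2),
    max = c(-1, 3.4, 2.9, 142, 97.8, 0.4, 28.2, 28.0, 28.2, 0.2, 23.0),
    res_deg = c(0.016, 0.05, 0.05, 0.05, 0.05, 0.05, 0.01, 0.05, 0.05,
                0.33, 0.25),
    units = c("m", "mg/m3", "mg/m3", "km", "m", "m", "degC", "degC", "degC",
              "m/s", "m/s"),
    cadence = c("static", "8day", "monthly", "14day", "daily", "daily",
                "daily", "8day", "monthly", "5day", "6hour"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the sampling design of a 135-bird Masked Booby tracking
#' study: 1-9 trips per bird (mean about 2.2), trips of 1-3 days (67/30/3
#' percent), GPS fixes every 10/33/50/100 s, commuting flight at about
#' 38 km/h, ARS bouts confined to patches of known radius, and sea surface
#' height anomaly plus current velocity as the environmental drivers of
#' where ARS happens.
#'
#' @param seed Integer seed; a fixed seed makes every product byte-identical.
#' @param n_birds Number of birds.
#' @param trips_per_bird_range Integer pair, inclusive range of trips per
#'   bird (sampled with a decaying-probability profile, mean about 2.2).
#' @param fix_interval_s Fix interval in seconds, one of 10/33/50/100;
#'   `NULL` (default) samples one of the four per bird, emulating tags
#'   reprogrammed during the study.
#' @param travel_speed_mps Commuting flight speed, m/s.
#' @param ars_patch_radii_m Patch radii in metres, ascending; more than one
#'   value nests small bouts inside a larger slow search region. Must lie in
#'   \[200, 35000\].
#' @param ars_bouts_per_day Number of ARS bouts per day at sea.
#' @param ars_bout_duration_s Duration of one bout, seconds.
#' @param night_rest Simulate near-zero-speed drift on the water between
#'   local 20:00 and 05:00 for multi-day trips.
#' @param colony_lonlat Colony coordinates, degrees `c(lon, lat)`.
#' @param domain_extent Half-width of the square simulation domain, degrees.
#' @param driver_vars Named list of value bands `c(lo, hi)`; inside ARS
#'   patches each named variable sits at its band (midpoint plus noise),
#'   outside it avoids the band. Bands must lie within the variable's
#'   [table1_variables()] range.
#' @param noise_sd Named numeric vector of per-variable field noise standard
#'   deviations; default 2 percent of each variable's range.
#' @param gps_jitter_m GPS position error standard deviation, metres
#'   (default 10 m, the approximate accuracy of the loggers). Applied as an
#'   AR(1) process decorrelating over ~15 minutes, as archival logger error
#'   does.
#' @param trip_max_dist_m Range `c(lo, hi)` from which a trip's planned
#'   maximum colony distance is drawn (log-uniform), metres.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_birds = 135L,
                       trips_per_bird_range = c(1L, 9L),
                       fix_interval_s = NULL,
                       travel_speed_mps = 10.5,
                       ars_patch_radii_m = 1000,
                       ars_bouts_per_day = 2L,
                       ars_bout_duration_s = 3600,
                       night_rest = TRUE,
                       colony_lonlat = c(-89.7, 22.4),
                       domain_extent = 2.5,
                       driver_vars = list(ssha = c(0.0, 0.1),
                                          velocity = c(0.05, 0.1)),
                       noise_sd = NULL,
                       gps_jitter_m = 10,
                       trip_max_dist_m = c(30000, 120000)) {
  t1 <- table1_variables()
  if (!is.null(fix_interval_s) && !fix_interval_s %in% c(10, 33, 50, 100)) {
    stop("fix_interval_s must be one of 10, 33, 50, 100 seconds")
  }
  if (length(ars_patch_radii_m) > 0 &&
      (any(ars_patch_radii_m < 200) || any(ars_patch_radii_m > 35000))) {
    stop("ars_patch_radii_m must lie within [200, 35000] m")
  }
  for (nm in names(driver_vars)) {
    row <- t1[t1$variable == nm, ]
    if (nrow(row) == 0) stop("unknown driver variable: ", nm)
    b <- driver_vars[[nm]]
    if (b[1] < row$min || b[2] > row$max || b[1] > b[2]) {
      stop("driver band for ", nm, " outside the variable's range [",
           row$min, ", ", row$max, "]")
    }
  }
  if (is.null(noise_sd)) {
    noise_sd <- stats::setNames(0.02 * (t1$max - t1$min), t1$variable)
  }
  structure(list(
    seed = as.integer(seed), n_birds = as.integer(n_birds),
    trips_per_bird_range = as.integer(trips_per_bird_range),
    fix_interval_s = fix_interval_s,
    travel_speed_mps = travel_speed_mps,
    ars_patch_radii_m = sort(ars_patch_radii_m),
    ars_bouts_per_day = as.integer(ars_bouts_per_day),
    ars_bout_duration_s = ars_bout_duration_s,
    night_rest = night_rest,
    colony_lonlat = colony_lonlat,
    domain_extent = domain_extent,
    driver_vars = driver_vars,
    noise_sd = noise_sd,
    gps_jitter_m = gps_jitter_m,
    trip_max_dist_m = trip_max_dist_m
  ), class = "sim_config")
}

# deterministic small-integer seed from mixed ids
derive_seed <- function(...) {
  h <- 0
  for (x in list(...)) {
    x <- if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else
      sum(as.numeric(x), na.rm = TRUE)
    h <- (h * 69069 + x + 1) %% 2147483647
  }
  as.integer(h)
}

# local solar hour at the colony longitude
solar_hour <- function(t_utc, lon) {
  ((t_utc / 3600) %% 24 + lon / 15) %% 24
}

# --- movement primitives on the planar (colony-origin) plane ----------------

new_walk_state <- function(t0, dt) {
  e <- new.env(parent = emptyenv())
  e$x <- 0; e$y <- 0; e$t <- t0; e$dt <- dt
  e$bx <- numeric(4096); e$by <- numeric(4096); e$bt <- numeric(4096)
  e$n <- 0L
  e
}

emit_fix <- function(st) {
  n <- st$n + 1L
  if (n > length(st$bx)) {
    st$bx <- c(st$bx, numeric(length(st$bx)))
    st$by <- c(st$by, numeric(length(st$by)))
    st$bt <- c(st$bt, numeric(length(st$bt)))
  }
  st$bx[n] <- st$x; st$by[n] <- st$y; st$bt[n] <- st$t
  st$n <- n
}

step_to <- function(st, dx, dy) {
  st$x <- st$x + dx; st$y <- st$y + dy; st$t <- st$t + st$dt
  emit_fix(st)
}

# directed commute: heading towards the target with ~5 degree noise
commute_to <- function(st, target, speed, ang_sd = 5) {
  repeat {
    dx <- target[1] - st$x; dy <- target[2] - st$y
    d <- sqrt(dx^2 + dy^2)
    step <- speed * st$dt
    if (d <= step) {
      st$x <- target[1]; st$y <- target[2]; st$t <- st$t + st$dt
      emit_fix(st)
      break
    }
    a <- atan2(dy, dx) + stats::rnorm(1, 0, ang_sd * pi / 180)
    step_to(st, step * cos(a), step * sin(a))
  }
}

# tortuous search confined to a patch: wide turning angles, redirected
# towards the centre whenever a step would leave 0.9 * radius
bout_walk <- function(st, center, radius, duration_s, base_speed) {
  speed <- min(base_speed / 3, radius / (2 * st$dt))
  n_steps <- max(3L, ceiling(duration_s / st$dt))
  a <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(n_steps)) {
    a <- a + stats::runif(1, -100, 100) * pi / 180
    step <- speed * st$dt
    nx <- st$x + step * cos(a); ny <- st$y + step * sin(a)
    if (sqrt((nx - center[1])^2 + (ny - center[2])^2) > 0.9 * radius) {
      a <- atan2(center[2] - st$y, center[1] - st$x) +
        stats::runif(1, -30, 30) * pi / 180
      nx <- st$x + step * cos(a); ny <- st$y + step * sin(a)
    }
    st$x <- nx; st$y <- ny; st$t <- st$t + st$dt
    emit_fix(st)
  }
}

# near-stationary drift (night rest), speed <= 0.5 km/h
drift_until <- function(st, end_condition, speed = 0.1) {
  a <- stats::runif(1, 0, 2 * pi)
  while (!end_condition(st$t)) {
    a <- a + stats::rnorm(1, 0, 0.3)
    step_to(st, speed * st$dt * cos(a), speed * st$dt * sin(a))
  }
}

# large-scale low-tortuosity wandering until a clock condition; waypoints
# are kept > 6 km from the colony so a multi-day trip is never mistaken for
# two separate trips by the colony-buffer splitter
wander_until <- function(st, end_condition, speed) {
  while (!end_condition(st$t)) {
    repeat {
      wp <- c(st$x, st$y) +
        stats::runif(1, 8000, 15000) * c(cos(a <- stats::runif(1, 0, 2 * pi)),
                                         sin(a))
      if (sqrt(sum(wp^2)) > 6000) break
    }
    repeat {
      dx <- wp[1] - st$x; dy <- wp[2] - st$y
      d <- sqrt(dx^2 + dy^2)
      if (d <= speed * st$dt || end_condition(st$t)) break
      aa <- atan2(dy, dx) + stats::rnorm(1, 0, 5 * pi / 180)
      step_to(st, speed * st$dt * cos(aa), speed * st$dt * sin(aa))
    }
  }
}

# one ARS visit; nested radii put small bouts inside a larger slow region.
# Returns a data.frame of truth bouts (one row per scale).
do_ars_visit <- function(st, center, radii, duration_s, base_speed) {
  rec <- list()
  if (length(radii) == 1) {
    i0 <- st$n + 1L; t0 <- st$t + st$dt
    bout_walk(st, center, radii, duration_s, base_speed)
    rec[[1]] <- data.frame(scale_m = radii, start_idx = i0, end_idx = st$n,
                           t_start = t0, t_end = st$bt[st$n],
                           cx = center[1], cy = center[2])
  } else {
    # nested: several small bouts scattered across the outer region, with
    # full-speed transits between them, so the track is tortuous at BOTH the
    # inner-bout scale and the outer-region scale
    outer_r <- radii[length(radii)]
    inner <- radii[-length(radii)]
    o0 <- st$n + 1L; ot0 <- st$t + st$dt
    for (r in inner) {
      for (s in 1:4) {
        sub <- center + stats::runif(1, 0.4 * outer_r,
                                     max(0.45 * outer_r, 0.9 * outer_r - r)) *
          c(cos(a <- stats::runif(1, 0, 2 * pi)), sin(a))
        commute_to(st, sub, base_speed)
        i0 <- st$n + 1L; t0 <- st$t + st$dt
        bout_walk(st, sub, r, duration_s * 0.5, base_speed)
        rec[[length(rec) + 1]] <- data.frame(
          scale_m = r, start_idx = i0, end_idx = st$n,
          t_start = t0, t_end = st$bt[st$n], cx = sub[1], cy = sub[2])
      }
    }
    rec[[length(rec) + 1]] <- data.frame(
      scale_m = outer_r, start_idx = o0, end_idx = st$n,
      t_start = ot0, t_end = st$bt[st$n], cx = center[1], cy = center[2])
  }
  do.call(rbind, rec)
}

#' Simulate one foraging trip with known ARS ground truth
#'
#' Builds a trip that leaves the colony, alternates directed commuting legs
#' (turning-angle spread about 5 degrees) with ARS bouts confined to patches
#' of the configured radii, optionally drifts overnight (multi-day trips),
#' and returns to the colony. Positions receive Gaussian GPS jitter before
#' conversion to lon/lat.
#'
#' @param config A [sim_config()].
#' @param bird_id,trip_id Identifiers (also drive the per-trip random seed).
#' @param n_days Trip length in days (1-3).
#' @param max_dist_m Planned maximum colony distance; drawn from
#'   `config$trip_max_dist_m` when `NULL`. Must exceed twice the largest
#'   patch radius.
#' @param start_time Departure time, UTC seconds; default 06:00 local solar
#'   time on the first study day.
#' @param reseed Set the RNG deterministically from `config$seed`, `bird_id`
#'   and `trip_id` (default); `FALSE` continues the caller's RNG stream.
#' @return A list with `track` (data frame: `bird_id`, `trip_id`,
#'   `timestamp`, `lon`, `lat`, `x`, `y`) and `truth` (list: `bouts` data
#'   frame with one row per bout and scale, `trip` summary row, `nights`).
#' @export
simulate_track <- function(config, bird_id = 1L, trip_id = 1L, n_days = 1L,
                           max_dist_m = NULL, start_time = NULL,
                           reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_days >= 1)
  if (reseed) set.seed(derive_seed(config$seed, bird_id, trip_id))
  dt <- config$fix_interval_s
  if (is.null(dt)) dt <- sample(c(10, 33, 50, 100), 1)
  v <- config$travel_speed_mps
  radii <- config$ars_patch_radii_m
  if (is.null(max_dist_m)) {
    lo <- config$trip_max_dist_m[1]; hi <- config$trip_max_dist_m[2]
    max_dist_m <- exp(stats::runif(1, log(lo), log(hi)))
  }
  if (length(radii) > 0 && max(radii) > max_dist_m / 2) {
    stop("patch radius ", max(radii),
         " m exceeds half the trip extent (", round(max_dist_m), " m)")
  }
  lon0 <- config$colony_lonlat[1]
  if (is.null(start_time)) {
    day0 <- as.numeric(as.POSIXct(paste(PERIOD_STARTS[["May2013"]],
                                        "00:00:00"), tz = "UTC"))
    start_time <- day0 + (6 - lon0 / 15) * 3600
  }
  B <- config$ars_bouts_per_day
  st <- new_walk_state(start_time, dt)
  # colony attendance before departure
  for (k in 1:5) {
    st$x <- stats::rnorm(1, 0, 5); st$y <- stats::rnorm(1, 0, 5)
    emit_fix(st); st$t <- st$t + dt
  }
  st$t <- st$t - dt
  theta <- stats::runif(1, 0, 2 * pi)
  bouts <- list(); nights <- list()
  for (day in seq_len(n_days)) {
    if (B > 0) {
      # patch centres keep clear of the colony buffer by a full bout radius
      clear_m <- if (length(radii)) 1.3 * max(radii) + 2000 else 2000
      if (day == 1) {
        f_lo <- min(0.9, max(0.35, clear_m / max_dist_m))
        f <- sort(stats::runif(B, f_lo, 0.95))
        brg <- theta + stats::runif(B, -40, 40) * pi / 180
        centers <- lapply(seq_len(B), function(i) {
          f[i] * max_dist_m * c(cos(brg[i]), sin(brg[i]))
        })
      } else {
        centers <- lapply(seq_len(B), function(i) {
          repeat {
            ctr <- c(st$x, st$y) + stats::runif(1, 5000, 20000) *
              c(cos(a <- stats::runif(1, 0, 2 * pi)), sin(a))
            if (sqrt(sum(ctr^2)) > clear_m) return(ctr)
          }
        })
      }
      for (b in seq_len(B)) {
        commute_to(st, centers[[b]], v)
        rec <- do_ars_visit(st, centers[[b]], radii,
                            config$ars_bout_duration_s, v)
        rec$bird_id <- bird_id; rec$trip_id <- trip_id; rec$day_index <- day
        bouts[[length(bouts) + 1]] <- rec
      }
    } else if (day == 1) {
      commute_to(st, max_dist_m * c(cos(theta), sin(theta)), v)
    }
    if (day < n_days) {
      # keep moving until local evening, then rest on the water
      wander_until(st, function(t) solar_hour(t, lon0) >= 19.9 &
                     solar_hour(t, lon0) < 20.6, v)
      if (config$night_rest) {
        n0 <- st$n + 1L; t0 <- st$t + dt
        drift_until(st, function(t) {
          h <- solar_hour(t, lon0); h >= 5 & h < 19
        })
        nights[[length(nights) + 1]] <- data.frame(
          bird_id = bird_id, trip_id = trip_id, day_index = day,
          start_idx = n0, end_idx = st$n, t_start = t0, t_end = st$bt[st$n])
      }
    }
  }
  commute_to(st, c(0, 0), v)
  # colony attendance after return
  for (k in 1:5) {
    st$t <- st$t + dt
    st$x <- stats::rnorm(1, 0, 5); st$y <- stats::rnorm(1, 0, 5)
    emit_fix(st)
  }
  n <- st$n
  # GPS error is temporally autocorrelated (error decorrelates over ~15 min,
  # not between consecutive fixes), so jitter is AR(1) with stationary sd
  # gps_jitter_m; white jitter would fake km/h-scale speeds at 10-s intervals
  rho <- exp(-dt / 900)
  ar1_jitter <- function(n) {
    z <- stats::rnorm(n, 0, config$gps_jitter_m * sqrt(1 - rho^2))
    as.numeric(stats::filter(z, rho, method = "recursive")) +
      rho^seq_len(n) * stats::rnorm(1, 0, config$gps_jitter_m)
  }
  x <- st$bx[1:n] + ar1_jitter(n)
  y <- st$by[1:n] + ar1_jitter(n)
  ll <- xy_to_lonlat(x, y, config$colony_lonlat)
  track <- data.frame(bird_id = bird_id, trip_id = trip_id,
                      timestamp = st$bt[1:n],
                      lon = ll[, "lon"], lat = ll[, "lat"], x = x, y = y)
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(scale_m = numeric(0), start_idx = integer(0),
               end_idx = integer(0), t_start = numeric(0),
               t_end = numeric(0), cx = numeric(0), cy = numeric(0),
               bird_id = character(0), trip_id = integer(0),
               day_index = integer(0))
  if (nrow(bouts)) {
    cll <- xy_to_lonlat(bouts$cx, bouts$cy, config$colony_lonlat)
    bouts$center_lon <- cll[, "lon"]; bouts$center_lat <- cll[, "lat"]
  } else {
    bouts$center_lon <- numeric(0); bouts$center_lat <- numeric(0)
  }
  # truth descriptors measured over the excursion the way the trip splitter
  # defines it: from the fix just before leaving a 1-km colony buffer to the
  # fix just after returning (jitter-free positions)
  cd <- sqrt(st$bx[1:n]^2 + st$by[1:n]^2)
  away <- which(cd > 1000)
  i0 <- max(1L, away[1] - 1L); i1 <- min(n, away[length(away)] + 1L)
  seg <- sqrt(diff(st$bx[i0:i1])^2 + diff(st$by[i0:i1])^2)
  trip_sum <- data.frame(
    bird_id = bird_id, trip_id = trip_id, n_days = n_days,
    fix_interval_s = dt, planned_max_dist_m = max_dist_m,
    duration_h = (st$bt[i1] - st$bt[i0]) / 3600,
    distance_km = sum(seg) / 1000,
    max_dist_km = max(cd) / 1000,
    t_start = st$bt[i0], t_end = st$bt[i1])
  list(track = track,
       truth = list(bouts = bouts, trip = trip_sum,
                    nights = if (length(nights)) do.call(rbind, nights) else
                      NULL))
}

# --- environmental fields ----------------------------------------------------

run_mean <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n == 1) return(v)
  half <- w %/% 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(0L, i - half - 1L); hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# smooth random field on an nx x ny grid, scaled to [0, 1]
smooth_field <- function(nx, ny, scale_cells) {
  m <- matrix(stats::rnorm(nx * ny), nx, ny)
  w <- max(3L, as.integer(scale_cells))
  for (pass in 1:3) {
    m <- apply(m, 2, run_mean, w = w)
    m <- t(apply(m, 1, run_mean, w = w))
  }
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, nx, ny))
  (m - rng[1]) / diff(rng)
}

# map a [0,1] field into a variable range while avoiding a band
avoid_band <- function(u, vmin, vmax, band) {
  gap <- 0.10 * (vmax - vmin)
  lo_hi <- max(vmin, band[1] - gap)
  hi_lo <- min(vmax, band[2] + gap)
  lower <- vmin + (u / 0.5) * (lo_hi - vmin)
  upper <- hi_lo + ((u - 0.5) / 0.5) * (vmax - hi_lo)
  ifelse(u < 0.5, lower, upper)
}

#' Simulate the gridded environmental fields of a study
#'
#' Produces one gridded field per covariate of [table1_variables()] plus a
#' `front_probability` field (12 rasters in all; `dist_front` is the
#' distance-to-front grid derived from `front_probability`). Driver variables
#' named in `config$driver_vars` sit at their band midpoint (plus noise)
#' inside every recorded ARS patch footprint and avoid the band elsewhere;
#' all other variables are smooth random fields unrelated to the patches.
#' All values are truncated to the variable's observed range.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth with a `bouts` data frame (patch centres and
#'   radii) as produced by [simulate_track()]/[simulate_study()].
#' @param reseed Seed the RNG from `config$seed` (default).
#' @return Named list of 12 `env_raster` objects.
#' @export
simulate_env_fields <- function(config, truth, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(derive_seed(config$seed, "env"))
  t1 <- table1_variables()
  ext <- config$domain_extent
  lon0 <- config$colony_lonlat[1]; lat0 <- config$colony_lonlat[2]
  bouts <- truth$bouts
  patches <- if (!is.null(bouts) && nrow(bouts)) {
    unique(bouts[, c("center_lon", "center_lat", "scale_m")])
  } else {
    data.frame(center_lon = numeric(0), center_lat = numeric(0),
               scale_m = numeric(0))
  }
  min_r <- if (nrow(patches)) min(patches$scale_m) else 1000

  axes <- function(res) {
    list(lon = seq(lon0 - ext, lon0 + ext, by = res),
         lat = seq(lat0 - ext, lat0 + ext, by = res))
  }
  # patch plateau weight: 1 inside the footprint, linear taper to 0 at 1.3r;
  # only cells inside each patch's bounding box are touched
  patch_weight <- function(lon, lat) {
    w <- matrix(0, length(lon), length(lat))
    coslat <- cos(lat0 * pi / 180)
    for (p in seq_len(nrow(patches))) {
      r <- patches$scale_m[p]
      clon <- patches$center_lon[p]; clat <- patches$center_lat[p]
      rd_lat <- 1.5 * r / 111195
      rd_lon <- rd_lat / coslat
      ii <- which(lon >= clon - rd_lon & lon <= clon + rd_lon)
      jj <- which(lat >= clat - rd_lat & lat <= clat + rd_lat)
      if (!length(ii) || !length(jj)) next
      g <- expand.grid(lon = lon[ii], lat = lat[jj])
      d <- haversine_m(g$lon, g$lat, clon, clat)
      w[ii, jj] <- pmax(w[ii, jj],
                        matrix(pmin(1, pmax(0, (1.3 - d / r) / 0.3)),
                               length(ii), length(jj)))
    }
    w
  }

  out <- list()
  for (i in seq_len(nrow(t1))) {
    nm <- t1$variable[i]
    if (nm == "dist_front") next  # derived below
    res <- t1$res_deg[i]
    is_driver <- nm %in% names(config$driver_vars)
    if (is_driver && nrow(patches)) {
      res <- min(res, min_r / 111000 / 3)  # resolve the smallest footprint
    }
    ax <- axes(res)
    nx <- length(ax$lon); ny <- length(ax$lat)
    scale_cells <- max(3, round(0.15 / res))
    u <- smooth_field(nx, ny, scale_cells)
    sdv <- config$noise_sd[[nm]]
    if (is.na(sdv) || is.null(sdv)) sdv <- 0
    if (is_driver) {
      band <- config$driver_vars[[nm]]
      base <- avoid_band(u, t1$min[i], t1$max[i], band)
      w <- if (nrow(patches)) patch_weight(ax$lon, ax$lat) else 0
      vals <- base + w * (mean(band) - base)
    } else {
      vals <- t1$min[i] + u * (t1$max[i] - t1$min[i])
    }
    if (sdv > 0) vals <- vals + stats::rnorm(length(vals), 0, sdv)
    vals <- pmin(t1$max[i], pmax(t1$min[i], vals))
    out[[nm]] <- env_raster(nm, ax$lon, ax$lat,
                            matrix(vals, nx, ny), units = t1$units[i])
  }

  # fronts: one short arc through the centre of each block of a 4x4
  # partition, so no point of the domain is farther than ~100 km from a
  # front (the observed distance-to-front range tops out at 142 km)
  ax <- axes(0.05)
  nb <- 4L
  block <- 2 * ext / nb
  ctrs <- expand.grid(
    cx = lon0 - ext + block * (seq_len(nb) - 0.5),
    cy = lat0 - ext + block * (seq_len(nb) - 0.5))
  g <- expand.grid(lon = ax$lon, lat = ax$lat)
  dmin <- rep(Inf, nrow(g))
  for (b in seq_len(nrow(ctrs))) {
    ang <- stats::runif(1, 0, pi)
    half <- 0.3 * block
    ex <- half * cos(ang); ey <- half * sin(ang)
    # distance (deg, approx planar) from grid points to the arc segment
    px <- g$lon - ctrs$cx[b]; py <- g$lat - ctrs$cy[b]
    tt <- pmin(1, pmax(-1, (px * ex + py * ey) / (ex^2 + ey^2)))
    dmin <- pmin(dmin, sqrt((px - tt * ex)^2 + (py - tt * ey)^2))
  }
  width <- 0.1
  fp <- pmax(0, 1 - dmin / width)
  out$front_probability <- env_raster(
    "front_probability", ax$lon, ax$lat,
    matrix(fp, length(ax$lon), length(ax$lat)), units = "probability")
  out$dist_front <- raster_distance_to_front(out$front_probability)
  out$dist_front$units <- "km"
  # Table-1 order with front probability last
  ord <- c(setdiff(t1$variable, "dist_front"), "dist_front",
           "front_probability")
  out[ord]
}

# --- whole-study bundle ------------------------------------------------------

#' Simulate a complete tracking study
#'
#' Draws per-bird metadata (sex, nest stage, sampling period, tag fix
#' interval, number of trips), simulates every trip with [simulate_track()],
#' generates the environmental fields with [simulate_env_fields()], and
#' optionally writes a self-contained study directory (per-bird track CSVs,
#' metadata CSV, raster CSVs, truth JSON).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; refused if it already exists unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing directory.
#' @return A list with `tracks` (one data frame of all fixes), `metadata`
#'   (per bird), `trips` (per trip), `rasters` (named list), and `truth`
#'   (list with `bouts`, `trips`, `nights`, `drivers`).
#' @export
simulate_study <- function(config, dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(dir) && dir.exists(dir) && !overwrite) {
    stop("output directory ", dir, " exists; use overwrite = TRUE")
  }
  set.seed(config$seed)
  nb <- config$n_birds
  periods <- names(PERIOD_STARTS)
  lo <- config$trips_per_bird_range[1]; hi <- config$trips_per_bird_range[2]
  ntrip_probs <- 0.55^(seq(lo, hi) - lo)
  meta <- data.frame(
    bird_id = sprintf("b%03d", seq_len(nb)),
    sex = rep_len(c("F", "M"), nb),
    stage = sample(c("incubating", "chick-rearing"), nb, replace = TRUE,
                   prob = c(51, 84)),
    period = sample(periods, nb, replace = TRUE, prob = c(0.27, 0.43, 0.30)),
    fix_interval_s = if (is.null(config$fix_interval_s)) {
      sample(c(10, 33, 50, 100), nb, replace = TRUE)
    } else rep(config$fix_interval_s, nb),
    n_trips = sample(seq(lo, hi), nb, replace = TRUE, prob = ntrip_probs)
  )
  tracks <- list(); bouts <- list(); trips <- list(); nights <- list()
  for (i in seq_len(nb)) {
    cfg_b <- config
    cfg_b$fix_interval_s <- meta$fix_interval_s[i]
    p0 <- as.numeric(as.POSIXct(paste(PERIOD_STARTS[[meta$period[i]]],
                                      "00:00:00"), tz = "UTC"))
    day_cursor <- (i %% 5)  # stagger deployment dates
    for (tr in seq_len(meta$n_trips[i])) {
      nd <- sample(1:3, 1, prob = c(0.67, 0.30, 0.03))
      t0 <- p0 + day_cursor * 86400 +
        (6 - config$colony_lonlat[1] / 15) * 3600
      sim <- simulate_track(cfg_b, bird_id = meta$bird_id[i], trip_id = tr,
                            n_days = nd, start_time = t0)
      tracks[[length(tracks) + 1]] <- sim$track
      trips[[length(trips) + 1]] <- sim$truth$trip
      if (nrow(sim$truth$bouts)) bouts[[length(bouts) + 1]] <- sim$truth$bouts
      if (!is.null(sim$truth$nights)) {
        nights[[length(nights) + 1]] <- sim$truth$nights
      }
      day_cursor <- day_cursor + nd + 1  # a recovery day at the colony
    }
  }
  truth <- list(
    bouts = if (length(bouts)) do.call(rbind, bouts) else NULL,
    trips = do.call(rbind, trips),
    nights = if (length(nights)) do.call(rbind, nights) else NULL,
    drivers = config$driver_vars
  )
  rasters <- simulate_env_fields(config, truth)
  study <- list(tracks = do.call(rbind, tracks), metadata = meta,
                trips = truth$trips, rasters = rasters, truth = truth)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a simulated study to a self-contained directory
#'
#' Layout: `tracks/<bird_id>.csv` (columns `bird_id`, `trip_hint`,
#' `timestamp` ISO-8601 UTC, `lon`, `lat`), `metadata.csv`,
#' `rasters/<variable>.csv`, `truth.json`.
#'
#' @param study A bundle from [simulate_study()].
#' @param dir Output directory (created).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "rasters"), showWarnings = FALSE)
  for (b in unique(study$tracks$bird_id)) {
    tr <- study$tracks[study$tracks$bird_id == b, ]
    out <- data.frame(
      bird_id = tr$bird_id, trip_hint = tr$trip_id,
      timestamp = format(as.POSIXct(tr$timestamp, origin = "1970-01-01",
                                    tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ"),
      lon = sprintf("%.7f", tr$lon), lat = sprintf("%.7f", tr$lat))
    utils::write.csv(out, file.path(dir, "tracks", paste0(b, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(study$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (nm in names(study$rasters)) {
    write_raster_csv(study$rasters[[nm]],
                     file.path(dir, "rasters", paste0(nm, ".csv")))
  }
  jsonlite::write_json(
    list(bouts = study$truth$bouts, trips = study$truth$trips,
         nights = study$truth$nights, drivers = study$truth$drivers),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return A list with `tracks`, `metadata`, `rasters`, `truth` (timestamps
#'   converted back to UTC seconds).
#' @export
read_study <- function(dir) {
  files <- list.files(file.path(dir, "tracks"), full.names = TRUE)
  tracks <- do.call(rbind, lapply(files, function(f) {
    d <- utils::read.csv(f)
    d$timestamp <- as.numeric(as.POSIXct(d$timestamp,
                                         format = "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC"))
    d
  }))
  rfiles <- list.files(file.path(dir, "rasters"), full.names = TRUE)
  rasters <- lapply(rfiles, read_raster_csv)
  names(rasters) <- sub("\\.csv$", "", basename(rfiles))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(tracks = tracks,
       metadata = utils::read.csv(file.path(dir, "metadata.csv")),
       rasters = rasters, truth = truth)
}

#' Label locations from simulator ground truth
#'
#' Marks a location `"ARS"` when its timestamp falls inside any recorded
#' bout window of the same bird and trip (any scale), `"nonARS"` otherwise.
#' Useful for validating the detection pipeline and for experiments that
#' need the true response uncontaminated by segmentation error.
#'
#' @param locations Data frame with `bird_id`, `trip_id`, `timestamp`.
#' @param bouts Truth bout table (`simulate_study()$truth$bouts`).
#' @return Character vector of labels, one per location row.
#' @export
truth_ars_labels <- function(locations, bouts) {
  lab <- rep("nonARS", nrow(locations))
  if (is.null(bouts) || nrow(bouts) == 0) return(lab)
  key_loc <- paste(locations$bird_id, locations$trip_id)
  key_bout <- paste(bouts$bird_id, bouts$trip_id)
  for (k in seq_len(nrow(bouts))) {
    hit <- key_loc == key_bout[k] &
      locations$timestamp >= bouts$t_start[k] &
      locations$timestamp <= bouts$t_end[k]
    lab[hit] <- "ARS"
  }
  lab
}
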