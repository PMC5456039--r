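# Minimal gridded-field container used for the oceanographic covariates.
# Fields live on a regular lon/lat grid, optionally stacked along time.
# Values are stored as a matrix [lon x lat] (array [lon x lat x time] for
# stacks); NA marks masked cells.

#' Create a gridded environmental field
#'
#' @param variable Character scalar, the covariate name (e.g. `"ssha"`).
#' @param lon,lat Strictly increasing numeric axes in decimal degrees giving
#'   the cell centres of a regular grid.
#' @param values Numeric matrix `length(lon) x length(lat)`, or an array
#'   `length(lon) x length(lat) x length(time)` when `time` is given.
#'   `NA` marks masked cells.
#' @param time Optional numeric vector of layer times (UTC seconds),
#'   strictly increasing.
#' @param units Optional character scalar describing the units.
#' @return An object of class `env_raster` (or `env_stack` when `time` is
#'   present).
#' @export
env_raster <- function(variable, lon, lat, values, time = NULL, units = NULL) {
  stopifnot(is.character(variable), length(variable) == 1)
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE)) {
    stop("raster axes must be strictly increasing")
  }
  if (is.null(time)) {
    values <- as.matrix(values)
    if (!all(dim(values) == c(length(lon), length(lat)))) {
      stop("values must be a length(lon) x length(lat) matrix")
    }
    structure(list(variable = variable, lon = lon, lat = lat,
                   values = values, units = units),
              class = "env_raster")
  } else {
    if (is.unsorted(time, strictly = TRUE)) {
      stop("time axis must be strictly increasing")
    }
    if (!all(dim(values) == c(length(lon), length(lat), length(time)))) {
      stop("values must be a length(lon) x length(lat) x length(time) array")
    }
    structure(list(variable = variable, lon = lon, lat = lat, time = time,
                   values = values, units = units),
              class = "env_stack")
  }
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("<env_raster> %s: %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              x$variable, length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values [%g, %g]%s, %d masked\n", rng[1], rng[2],
              if (is.null(x$units)) "" else paste0(" ", x$units),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %s: %d x %d cells, %d layers\n",
              x$variable, length(x$lon), length(x$lat), length(x$time)))
  invisible(x)
}

#' Bilinear sampling of a gridded field
#'
#' Linearly interpolates the field in lon then lat between the four
#' surrounding cell centres. Queries outside the axis range, or with any of
#' the four neighbours masked, return `NA` (out-of-bounds additionally
#' warns).
#'
#' @param raster An `env_raster`.
#' @param lon,lat Query coordinates (vectors, recycled to common length).
#' @return Numeric vector of interpolated values.
#' @export
sample_bilinear <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "env_raster"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  gx <- raster$lon; gy <- raster$lat
  out <- rep(NA_real_, n)
  inside <- lon >= gx[1] & lon <= gx[length(gx)] &
    lat >= gy[1] & lat <= gy[length(gy)] & !is.na(lon) & !is.na(lat)
  if (any(!inside)) {
    warning(sum(!inside), " query point(s) outside raster bounds; returned NA")
  }
  if (!any(inside)) return(out)
  i <- findInterval(lon[inside], gx, rightmost.closed = TRUE)
  j <- findInterval(lat[inside], gy, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(gx) - 1L)
  j <- pmin(pmax(j, 1L), length(gy) - 1L)
  tx <- (lon[inside] - gx[i]) / (gx[i + 1L] - gx[i])
  ty <- (lat[inside] - gy[j]) / (gy[j + 1L] - gy[j])
  v <- raster$values
  n1 <- length(gx)
  idx <- function(ii, jj) v[(jj - 1L) * n1 + ii]
  v00 <- idx(i, j); v10 <- idx(i + 1L, j)
  v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
  out[inside] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

#' Temporal-match windows for common satellite cadences
#'
#' Half-window (seconds) inside which a query time may be matched to a layer:
#' 6 h for 6-hourly wind, 12 h for daily, 2.5 d for 5-day, 4 d for 8-day and
#' 15 d for monthly products.
#' @export
match_windows <- c(
  "6hour"   = 6 * 3600,
  daily     = 12 * 3600,
  "5day"    = 2.5 * 86400,
  "8day"    = 4 * 86400,
  "14day"   = 7 * 86400,
  monthly   = 15 * 86400
)

#' Select the temporally matching layer of a stack
#'
#' Returns the layer nearest in time to `timestamp`, provided the offset is
#' within `window_s`; when the query falls exactly between two layers, the
#' earlier layer wins. Returns `NULL` when no layer qualifies.
#'
#' @param stack An `env_stack`.
#' @param timestamp Numeric UTC seconds.
#' @param window_s Maximum |time offset| in seconds; defaults to half the
#'   median layer spacing. See [match_windows] for standard cadences.
#' @return An `env_raster` for the matched layer, or `NULL`.
#' @export
match_time <- function(stack, timestamp, window_s = NULL) {
  stopifnot(inherits(stack, "env_stack"), length(timestamp) == 1)
  if (length(stack$time) == 0) stop("stack has no layers")
  if (is.null(window_s)) {
    window_s <- if (length(stack$time) > 1) {
      stats::median(diff(stack$time)) / 2
    } else Inf
  }
  dt <- abs(stack$time - timestamp)
  k <- which(dt == min(dt))[1]  # ties resolve to the earlier layer
  if (dt[k] > window_s) return(NULL)
  env_raster(stack$variable, stack$lon, stack$lat, stack$values[, , k],
             units = stack$units)
}

frontal_cells <- function(front_raster, threshold = 0) {
  f <- front_raster$values > threshold & !is.na(front_raster$values)
  which(f, arr.ind = TRUE)
}

#' Distance to the nearest oceanic front
#'
#' Great-circle distance (km) from each query point to the centre of the
#' nearest cell of `front_raster` whose front probability exceeds
#' `threshold`. A point whose own cell is frontal gets distance 0.
#'
#' @param front_raster An `env_raster` of front probabilities.
#' @param lon,lat Query coordinates (vectors).
#' @param threshold Frontal cut-off: a cell is frontal when its probability
#'   is strictly greater than this (default 0).
#' @return Numeric vector of distances in km (`NA` if no frontal cell).
#' @export
distance_to_front <- function(front_raster, lon, lat, threshold = 0) {
  stopifnot(inherits(front_raster, "env_raster"))
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  fc <- frontal_cells(front_raster, threshold)
  if (nrow(fc) == 0) {
    warning("no frontal cells above threshold; distances are NA")
    return(rep(NA_real_, n))
  }
  flon <- front_raster$lon[fc[, 1]]
  flat <- front_raster$lat[fc[, 2]]
  # own-cell membership by nearest cell centre
  ci <- pmin(pmax(findInterval(lon, cell_edges(front_raster$lon)), 1L),
             length(front_raster$lon))
  cj <- pmin(pmax(findInterval(lat, cell_edges(front_raster$lat)), 1L),
             length(front_raster$lat))
  fmask <- matrix(FALSE, length(front_raster$lon), length(front_raster$lat))
  fmask[fc] <- TRUE
  own <- fmask[cbind(ci, cj)]
  out <- numeric(n)
  todo <- which(!own)
  chunk <- 2000L
  if (length(todo)) {
    for (s in seq(1L, length(todo), by = chunk)) {
      ii <- todo[s:min(s + chunk - 1L, length(todo))]
      d <- outer_haversine(lon[ii], lat[ii], flon, flat)
      out[ii] <- apply(d, 1, min) / 1000
    }
  }
  out
}

# edges between cell centres (for own-cell lookup)
cell_edges <- function(centers) {
  if (length(centers) == 1) return(c(-Inf, Inf))
  c(-Inf, centers[-length(centers)] + diff(centers) / 2, Inf)[-1]
}

# matrix of haversine distances, points x cells
outer_haversine <- function(lon, lat, flon, flat) {
  to_rad <- pi / 180
  la1 <- lat * to_rad; la2 <- flat * to_rad
  sdlat <- outer(la1, la2, function(a, b) sin((b - a) / 2)^2)
  sdlon <- outer(lon * to_rad, flon * to_rad, function(a, b) sin((b - a) / 2)^2)
  a <- sdlat + outer(cos(la1), cos(la2)) * sdlon
  2 * EARTH_RADIUS_M * asin(sqrt(pmin(a, 1)))
}

#' Rasterized distance-to-front field
#'
#' Evaluates [distance_to_front()] at every cell centre of the front raster,
#' returning a `dist_front` field in km.
#'
#' @inheritParams distance_to_front
#' @return An `env_raster` named `dist_front`.
#' @export
raster_distance_to_front <- function(front_raster, threshold = 0) {
  g <- expand.grid(lon = front_raster$lon, lat = front_raster$lat)
  d <- distance_to_front(front_raster, g$lon, g$lat, threshold)
  env_raster("dist_front", front_raster$lon, front_raster$lat,
             matrix(d, length(front_raster$lon), length(front_raster$lat)),
             units = "km")
}

#' Annotate locations with environmental covariates
#'
#' Samples every supplied field at each location by bilinear interpolation
#' (time-stacked fields are first matched by timestamp), and appends a
#' `distance_to_front_km` column when a `front_probability` field is present.
#'
#' @param locations Data frame with columns `lon`, `lat` and (for stacks)
#'   `timestamp` in UTC seconds.
#' @param rasters Named list of `env_raster`/`env_stack` objects; names
#'   default to each field's `variable`.
#' @param front_threshold Frontal probability cut-off for
#'   `distance_to_front_km`.
#' @return `locations` with one extra column per covariate; a per-variable
#'   completeness report is attached as attribute `"completeness"`.
#' @export
annotate_locations <- function(locations, rasters, front_threshold = 0) {
  stopifnot(is.data.frame(locations), all(c("lon", "lat") %in% names(locations)))
  if (is.null(names(rasters)) || any(names(rasters) == "")) {
    names(rasters) <- vapply(rasters, function(r) r$variable, character(1))
  }
  out <- locations
  front <- rasters[["front_probability"]]
  covars <- rasters[setdiff(names(rasters), "front_probability")]
  for (nm in names(covars)) {
    r <- covars[[nm]]
    if (inherits(r, "env_stack")) {
      if (!"timestamp" %in% names(locations)) {
        stop("time-stacked field '", nm, "' needs a timestamp column")
      }
      vals <- rep(NA_real_, nrow(locations))
      for (tt in unique(locations$timestamp)) {
        sel <- locations$timestamp == tt
        layer <- match_time(r, tt)
        if (!is.null(layer)) {
          vals[sel] <- sample_bilinear(layer, locations$lon[sel],
                                       locations$lat[sel])
        }
      }
      out[[nm]] <- vals
    } else {
      out[[nm]] <- sample_bilinear(r, locations$lon, locations$lat)
    }
  }
  if (!is.null(front)) {
    fr <- if (inherits(front, "env_stack")) {
      match_time(front, locations$timestamp[1])
    } else front
    out$distance_to_front_km <- distance_to_front(
      fr, locations$lon, locations$lat, front_threshold)
  }
  added <- setdiff(names(out), names(locations))
  attr(out, "completeness") <- vapply(
    added, function(nm) mean(!is.na(out[[nm]])), numeric(1))
  out
}

#' Write a gridded field as a long-format CSV
#'
#' Columns `lon,lat,value` (plus `time` for stacks); readable back with
#' [read_raster_csv()].
#'
#' @param raster An `env_raster` or `env_stack`.
#' @param path Output file path.
#' @export
write_raster_csv <- function(raster, path) {
  if (inherits(raster, "env_stack")) {
    g <- expand.grid(lon = raster$lon, lat = raster$lat, time = raster$time)
    g$value <- as.vector(raster$values)
  } else {
    g <- expand.grid(lon = raster$lon, lat = raster$lat)
    g$value <- as.vector(raster$values)
  }
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from a long-format CSV
#'
#' @param path CSV file written by [write_raster_csv()] (columns
#'   `lon,lat[,time],value`).
#' @param variable Covariate name; defaults to the file name without
#'   extension.
#' @return An `env_raster` or `env_stack`.
#' @export
read_raster_csv <- function(path, variable = NULL) {
  if (is.null(variable)) {
    variable <- sub("\\.[^.]*$", "", basename(path))
  }
  g <- utils::read.csv(path)
  lon <- sort(unique(g$lon)); lat <- sort(unique(g$lat))
  if ("time" %in% names(g)) {
    tm <- sort(unique(g$time))
    o <- order(g$time, g$lat, g$lon)
    arr <- array(g$value[o], dim = c(length(lon), length(lat), length(tm)))
    env_raster(variable, lon, lat, arr, time = tm)
  } else {
    o <- order(g$lat, g$lon)
    env_raster(variable, lon, lat,
               matrix(g$value[o], length(lon), length(lat)))
  }
}
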