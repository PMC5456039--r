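# First-passage time and ARS scale detection. FPT at radius r for a track
# location is the time to first cross a circle of radius r centred there,
# walking the interpolated track forward plus backward; the variance of
# log(FPT) over locations, as a function of r, peaks at the characteristic
# scales of area-restricted search.

#' First-passage time at one radius
#'
#' @param bird_day Interpolated bird-day (columns `x`, `y`, `timestamp`; see
#'   [split_bird_days()]).
#' @param radius_m Circle radius in metres (positive scalar).
#' @return Numeric vector of FPT in seconds per location; `NA` where the
#'   track ends inside the circle in either direction.
#' @export
first_passage_time <- function(bird_day, radius_m) {
  stopifnot(radius_m > 0, length(radius_m) == 1)
  as.vector(fpt_matrix_cpp(bird_day$x, bird_day$y, bird_day$timestamp,
                           radius_m))
}

#' Upper radius for the FPT scan
#'
#' Half the mean colony distance over all locations, rounded down to a 10-m
#' multiple.
#'
#' @param colony_dist_m Numeric vector of colony distances in metres.
#' @return Radius in metres.
#' @export
rmax_from_data <- function(colony_dist_m) {
  if (length(colony_dist_m) == 0) stop("no locations supplied")
  r <- floor(mean(colony_dist_m) / 2 / 10) * 10
  if (r < 10) stop("degenerate input: locations are essentially at the colony")
  r
}

#' FPT profile over a radius grid
#'
#' Evaluates FPT at every location for every radius and computes the
#' variance of log(FPT) per radius over the locations where FPT is defined.
#'
#' @param bird_day Interpolated bird-day.
#' @param radii Strictly increasing radii (m); default `seq(r_step, r_max,
#'   r_step)`.
#' @param r_max Largest radius; default [rmax_from_data()] on the bird-day's
#'   colony distances (requires a `colony_dist_m` column).
#' @param r_step Radius increment, metres (default 10).
#' @return An object of class `fpt_profile`: list with `radii`, `fpt`
#'   (locations x radii matrix, seconds), `varlog`, `coverage` (fraction of
#'   locations with defined FPT per radius).
#' @export
fpt_profile <- function(bird_day, radii = NULL, r_max = NULL, r_step = 10) {
  if (is.null(radii)) {
    if (is.null(r_max)) r_max <- rmax_from_data(bird_day$colony_dist_m)
    radii <- seq(r_step, r_max, by = r_step)
  }
  m <- fpt_matrix_cpp(bird_day$x, bird_day$y, bird_day$timestamp, radii)
  lg <- log(m)
  structure(list(
    radii = radii,
    fpt = m,
    varlog = apply(lg, 2, stats::var, na.rm = TRUE),
    coverage = colMeans(!is.na(m))
  ), class = "fpt_profile")
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("<fpt_profile> %d locations x %d radii [%g, %g] m\n",
              nrow(x$fpt), length(x$radii), min(x$radii), max(x$radii)))
  invisible(x)
}

# local maxima with a simple prominence measure: walk away from the peak on
# both sides until a higher value, tracking the deepest valley
peak_prominence <- function(v) {
  n <- length(v)
  peaks <- which(diff(sign(diff(v))) < 0) + 1L
  prom <- vapply(peaks, function(i) {
    lmin <- v[i]; j <- i
    while (j > 1 && v[j] <= v[i]) { j <- j - 1; lmin <- min(lmin, v[j]) }
    rmin <- v[i]; j <- i
    while (j < n && v[j] <= v[i]) { j <- j + 1; rmin <- min(rmin, v[j]) }
    v[i] - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Detect ARS scales from an FPT profile
#'
#' ARS scales are the radii of local maxima of the (lightly smoothed)
#' variance-of-log-FPT curve, restricted to radii where at least
#' `min_coverage` of locations have defined FPT and to peaks whose
#' prominence exceeds `prominence_frac` of the curve's range. Fine-scale
#' analysis conventionally keeps only scales at or below 8 km.
#'
#' @param profile An [fpt_profile()].
#' @param min_coverage Minimum fraction of locations with defined FPT for a
#'   radius to enter peak-picking (default 0.5).
#' @param smooth_window Moving-average window (radius bins) applied before
#'   peak-picking (default 5).
#' @param prominence_frac Prominence floor as a fraction of the smoothed
#'   curve's range (default 0.05).
#' @return List of class `scale_set`: `scales` (ascending radii, m, possibly
#'   empty), `n_scales`, `smallest`, `largest`, and `varlog_smooth` on the
#'   retained radii.
#' @export
detect_scales <- function(profile, min_coverage = 0.5, smooth_window = 5,
                          prominence_frac = 0.05) {
  ok <- profile$coverage >= min_coverage & is.finite(profile$varlog)
  radii <- profile$radii[ok]
  v <- profile$varlog[ok]
  empty <- structure(list(scales = numeric(0), n_scales = 0L,
                          smallest = NA_real_, largest = NA_real_,
                          radii = radii, varlog_smooth = numeric(0)),
                     class = "scale_set")
  if (length(v) < 3) return(empty)
  vs <- run_mean(v, smooth_window)
  if (diff(range(vs)) < .Machine$double.eps) return(empty)
  pk <- peak_prominence(vs)
  keep <- pk$prominence >= prominence_frac * diff(range(vs))
  scales <- sort(radii[pk$peaks[keep]])
  structure(list(scales = scales, n_scales = length(scales),
                 smallest = if (length(scales)) min(scales) else NA_real_,
                 largest = if (length(scales)) max(scales) else NA_real_,
                 radii = radii, varlog_smooth = vs),
            class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  if (x$n_scales == 0) cat("<scale_set> no ARS scale detected\n")
  else cat("<scale_set>", x$n_scales, "scale(s):",
           paste(round(x$scales), collapse = ", "), "m\n")
  invisible(x)
}

#' Smallest fine ARS scale of a day
#'
#' The smallest detected scale not exceeding `max_m` (default 8 km; larger
#' scales reflect mesoscale search rather than targeted prey capture).
#'
#' @param scale_set A [detect_scales()] result.
#' @param max_m Fine-scale ceiling in metres.
#' @return Radius in metres, or `NA` when no fine scale exists.
#' @export
smallest_fine_scale <- function(scale_set, max_m = 8000) {
  s <- scale_set$scales[scale_set$scales <= max_m]
  if (length(s)) min(s) else NA_real_
}
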