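# Penalized-contrast segmentation of log(FPT) series and ARS labelling.
# The dynamic program finds, for every candidate segment count K, the exact
# partition minimising the within-segment sum of squares; K is then chosen
# by the normalized-contrast threshold rule: scale the contrast J(K) so its
# total decrease over K = 1..Kmax is Kmax - 1 (i.e. an average decrease of 1
# per added segment) and keep the largest K whose decrease still exceeds S.

#' Penalized-contrast segmentation of a series
#'
#' @param series Numeric vector (typically log FPT at one ARS scale).
#' @param Kmin,Kmax Candidate segment-count range (defaults 2 and 20).
#' @param Lmin Minimum segment length in locations (default 5).
#' @param S Threshold on the normalized contrast decrease (default 0.75);
#'   when no candidate K reaches it the series is kept as a single segment.
#' @return List of class `segmentation`: `K`, `ends` (segment end indices),
#'   `changepoints` (`ends` without the last), `seg_means`, `contrast`
#'   (J(K) for K = 1..Kmax), and `fallback` (`TRUE` when the series was too
#'   short to segment).
#' @export
lavielle_segment <- function(series, Kmin = 2, Kmax = 20, Lmin = 5,
                             S = 0.75) {
  n <- length(series)
  if (any(!is.finite(series))) stop("series must be finite")
  if (n < 2 * Lmin) {
    message("series of length ", n, " is shorter than 2*Lmin; ",
            "keeping a single segment")
    return(structure(list(K = 1L, ends = n, changepoints = integer(0),
                          seg_means = mean(series), contrast = NA_real_,
                          fallback = TRUE),
                     class = "segmentation"))
  }
  Kmax_eff <- min(Kmax, n %/% Lmin)
  dp <- lavielle_dp_cpp(series, Kmax_eff, Lmin)
  J <- dp$contrast
  K <- 1L
  if (Kmax_eff >= max(2, Kmin) && J[1] - J[Kmax_eff] > 1e-12) {
    Jt <- (J[Kmax_eff] - J) / (J[Kmax_eff] - J[1]) * (Kmax_eff - 1) + 1
    D <- -diff(Jt)  # D[k] is the decrease going from k to k+1 segments
    cand <- seq(max(2, Kmin), Kmax_eff)
    hit <- cand[D[cand - 1] > S]
    if (length(hit)) K <- max(hit)
  }
  ends <- dp$breaks[[K]]
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg_means <- vapply(seq_len(K), function(k) {
    mean(series[starts[k]:ends[k]])
  }, numeric(1))
  structure(list(K = K, ends = as.integer(ends),
                 changepoints = as.integer(utils::head(ends, -1)),
                 seg_means = seg_means, contrast = J, fallback = FALSE),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>", x$K, "segment(s); changepoints:",
      if (length(x$changepoints)) paste(x$changepoints, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Label locations as ARS or non-ARS
#'
#' Segments whose mean of the segmented series strictly exceeds the overall
#' location mean are ARS; all of a segment's locations share its label.
#'
#' @param segmentation A [lavielle_segment()] result.
#' @param series The series that was segmented.
#' @return Character vector of per-location labels, `"ARS"` or `"nonARS"`.
#' @export
classify_ars <- function(segmentation, series) {
  ends <- segmentation$ends
  starts <- c(1L, utils::head(ends, -1) + 1L)
  overall <- mean(series)
  lab <- rep("nonARS", length(series))
  for (k in seq_len(segmentation$K)) {
    if (segmentation$seg_means[k] > overall) {
      lab[starts[k]:ends[k]] <- "ARS"
    }
  }
  lab
}

#' Per-day ARS metrics
#'
#' Counts ARS zones (maximal runs of ARS locations) and sums their duration
#' and path length; reports the mean colony distance of ARS locations and
#' the circular mean of colony-to-ARS bearings.
#'
#' @param bird_day Interpolated bird-day with `x`, `y`, `timestamp`,
#'   `colony_dist_m`, `colony_bearing_deg`.
#' @param labels Per-location labels from [classify_ars()].
#' @return One-row data frame: `n_zones`, `ars_duration_h`,
#'   `ars_distance_km`, `colony_to_ars_km`, `angle_to_ars_deg` (metrics are
#'   `NA` with `n_zones = 0` when no location is ARS).
#' @export
ars_metrics <- function(bird_day, labels) {
  stopifnot(nrow(bird_day) == length(labels))
  is_ars <- labels == "ARS"
  if (!any(is_ars)) {
    return(data.frame(n_zones = 0L, ars_duration_h = NA_real_,
                      ars_distance_km = NA_real_, colony_to_ars_km = NA_real_,
                      angle_to_ars_deg = NA_real_))
  }
  r <- rle(is_ars)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  zs <- which(r$values)
  dur <- 0; dist <- 0
  for (k in zs) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- dur + bird_day$timestamp[i1] - bird_day$timestamp[i0]
    if (i1 > i0) {
      dist <- dist + sum(sqrt(diff(bird_day$x[i0:i1])^2 +
                                diff(bird_day$y[i0:i1])^2))
    }
  }
  data.frame(
    n_zones = length(zs),
    ars_duration_h = dur / 3600,
    ars_distance_km = dist / 1000,
    colony_to_ars_km = mean(bird_day$colony_dist_m[is_ars]) / 1000,
    angle_to_ars_deg = circular_mean_deg(bird_day$colony_bearing_deg[is_ars])
  )
}

#' Full ARS analysis of one bird-day
#'
#' Runs the FPT scan, detects scales, keeps the smallest fine scale
#' (<= `fine_scale_max_m`), segments log(FPT) at that radius and labels
#' locations. Locations whose FPT is undefined at the chosen radius (track
#' ends inside the circle) are labelled non-ARS; interior gaps are bridged
#' by linear interpolation of the log-FPT series before segmenting.
#'
#' @param bird_day Interpolated bird-day.
#' @param radii,r_step Passed to [fpt_profile()].
#' @param fine_scale_max_m Fine-scale ceiling (default 8000 m).
#' @param Kmin,Kmax,Lmin,S Passed to [lavielle_segment()].
#' @return List: `profile`, `scales` (a `scale_set`), `scale_m` (chosen
#'   radius or `NA`), `labels` (per location), `metrics` (one row, including
#'   `n_scales`), `segmentation`.
#' @export
ars_day <- function(bird_day, radii = NULL, r_step = 10,
                    fine_scale_max_m = 8000, Kmin = 2, Kmax = 20, Lmin = 5,
                    S = 0.75) {
  profile <- fpt_profile(bird_day, radii = radii, r_step = r_step)
  scales <- detect_scales(profile)
  scale_m <- smallest_fine_scale(scales, fine_scale_max_m)
  n <- nrow(bird_day)
  labels <- rep("nonARS", n)
  seg <- NULL
  metrics <- data.frame(n_zones = 0L, ars_duration_h = NA_real_,
                        ars_distance_km = NA_real_,
                        colony_to_ars_km = NA_real_,
                        angle_to_ars_deg = NA_real_)
  if (!is.na(scale_m)) {
    ridx <- which.min(abs(profile$radii - scale_m))
    series <- log(profile$fpt[, ridx])
    ok <- which(is.finite(series))
    if (length(ok) >= 2) {
      rng <- ok[1]:ok[length(ok)]
      s <- series[rng]
      if (anyNA(s)) {
        s <- stats::approx(rng[is.finite(s)], s[is.finite(s)], xout = rng)$y
      }
      seg <- lavielle_segment(s, Kmin = Kmin, Kmax = Kmax, Lmin = Lmin, S = S)
      labels[rng] <- classify_ars(seg, s)
      metrics <- ars_metrics(bird_day, labels)
    }
  }
  metrics <- cbind(data.frame(n_scales = scales$n_scales,
                              scale_m = scale_m,
                              smallest_scale_m = scales$smallest,
                              largest_scale_m = scales$largest), metrics)
  list(profile = profile, scales = scales, scale_m = scale_m,
       labels = labels, metrics = metrics, segmentation = seg)
}
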