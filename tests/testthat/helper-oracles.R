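# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementations they check.

# Spherical law of cosines distance (m) -- independent of the package's
# haversine implementation.
oracle_dist_m <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  a <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371008.8 * acos(pmin(1, pmax(-1, a)))
}

# Brute-force first-passage time by dense path resampling: walk the planar
# polyline at `pitch`-metre steps, scan forward and backward from location i
# for the first step at which distance from location i reaches r, and
# interpolate the crossing linearly within that step.
oracle_fpt <- function(x, y, t, i, r, pitch = 0.01) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  ss <- seq(0, s[length(s)], by = pitch)
  px <- approx(s, x, xout = ss)$y
  py <- approx(s, y, xout = ss)$y
  pt <- approx(s, t, xout = ss)$y
  i0 <- which.min(abs(ss - s[i]))
  one_way <- function(idx_seq) {
    d <- sqrt((px[idx_seq] - x[i])^2 + (py[idx_seq] - y[i])^2)
    k <- which(d >= r)[1]
    if (is.na(k) || k == 1) return(NA_real_)
    frac <- (r - d[k - 1]) / (d[k] - d[k - 1])
    tk <- pt[idx_seq[k - 1]] + frac * (pt[idx_seq[k]] - pt[idx_seq[k - 1]])
    abs(tk - t[i])
  }
  fwd <- one_way(i0:length(ss))
  bwd <- one_way(i0:1)
  if (is.na(fwd) || is.na(bwd)) NA_real_ else fwd + bwd
}

# Exhaustive best segmentation: enumerate all placements of K-1 changepoints
# with minimum segment length Lmin, return the minimal within-segment sum of
# squared deviations.
oracle_best_contrast <- function(series, K, Lmin) {
  n <- length(series)
  seg_cost <- function(i, j) {
    v <- series[i:j]
    sum((v - mean(v))^2)
  }
  if (K == 1) return(seg_cost(1, n))
  best <- Inf
  cps <- utils::combn(n - 1, K - 1)
  for (c_i in seq_len(ncol(cps))) {
    ends <- c(cps[, c_i], n)
    lens <- diff(c(0, ends))
    if (any(lens < Lmin)) next
    starts <- c(1, head(ends, -1) + 1)
    cost <- sum(mapply(seg_cost, starts, ends))
    if (cost < best) best <- cost
  }
  best
}

# distance (m) of planar points to the polyline through (px, py)
oracle_dist_to_polyline <- function(x, y, px, py) {
  vapply(seq_along(x), function(i) {
    dmin <- Inf
    for (s in seq_len(length(px) - 1)) {
      vx <- px[s + 1] - px[s]; vy <- py[s + 1] - py[s]
      L2 <- vx^2 + vy^2
      tt <- if (L2 == 0) 0 else
        max(0, min(1, ((x[i] - px[s]) * vx + (y[i] - py[s]) * vy) / L2))
      d <- sqrt((x[i] - px[s] - tt * vx)^2 + (y[i] - py[s] - tt * vy)^2)
      if (d < dmin) dmin <- d
    }
    dmin
  }, numeric(1))
}

# simple planar fix table builder (constant-speed polyline, lon/lat around a
# reference point)
make_track <- function(x, y, speed_mps = 10, t0 = 0,
                       center = c(-89.7, 22.4)) {
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  ll <- trackars::xy_to_lonlat(x, y, center)
  data.frame(timestamp = t0 + s / speed_mps, lon = ll[, "lon"],
             lat = ll[, "lat"], x = x, y = y)
}

# small labelled design for forest tests: ARS iff ssha below 0, ten inert
# standard-normal covariates
make_separable_day <- function(n = 300, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 11), n, 11)
  colnames(x) <- trackars::rf_predictors
  y <- as.integer(x[, "ssha"] < 0)
  list(bird_id = "b1", trip_id = 1L, day_index = 1L, x = x, y = y)
}
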