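grid4 <- env_raster("demo", lon = c(0, 1), lat = c(0, 1),
                    values = matrix(c(1, 2, 3, 4), 2, 2))

test_that("bilinear sampling is exact at nodes and averages at cell centre", {
  expect_equal(sample_bilinear(grid4, 0, 0), 1)
  expect_equal(sample_bilinear(grid4, 1, 0), 2)
  expect_equal(sample_bilinear(grid4, 0, 1), 3)
  expect_equal(sample_bilinear(grid4, 1, 1), 4)
  expect_equal(sample_bilinear(grid4, 0.5, 0.5), 2.5)
})

test_that("bilinear sampling equals a two-pass linear interpolation oracle", {
  set.seed(5)
  lon <- seq(-2, 2, by = 0.5); lat <- seq(10, 13, by = 0.5)
  v <- matrix(rnorm(length(lon) * length(lat)), length(lon), length(lat))
  r <- env_raster("noise", lon, lat, v)
  qlon <- runif(50, -2, 2); qlat <- runif(50, 10, 13)
  # oracle: interpolate along lon at the two bracketing lat rows, then
  # along lat between those values
  oracle <- vapply(seq_along(qlon), function(k) {
    j <- findInterval(qlat[k], lat, rightmost.closed = TRUE)
    v1 <- approx(lon, v[, j], xout = qlon[k])$y
    v2 <- approx(lon, v[, j + 1], xout = qlon[k])$y
    approx(lat[j:(j + 1)], c(v1, v2), xout = qlat[k])$y
  }, numeric(1))
  expect_equal(sample_bilinear(r, qlon, qlat), oracle, tolerance = 1e-12)
  # continuity across a cell boundary
  eps <- 1e-9
  a <- sample_bilinear(r, 0.5 - eps, 11.3)
  b <- sample_bilinear(r, 0.5 + eps, 11.3)
  expect_lt(abs(a - b), 1e-6)
})

test_that("out-of-bounds and masked-neighbour queries return NA", {
  expect_warning(v <- sample_bilinear(grid4, 2, 0.5), "outside")
  expect_true(is.na(v))
  masked <- env_raster("demo", 0:2, 0:2, matrix(1:9, 3, 3))
  masked$values[1, 1] <- NA
  expect_true(is.na(sample_bilinear(masked, 0.4, 0.4)))
  expect_false(is.na(sample_bilinear(masked, 1.5, 1.5)))
})

test_that("temporal matching takes the nearest in-window layer, earlier on ties", {
  tm <- c(0, 6, 12, 18) * 3600
  arr <- array(rep(1:4, each = 4), dim = c(2, 2, 4))
  stk <- env_raster("wind_speed", c(0, 1), c(0, 1), arr, time = tm)
  # 05:00 matches the 06:00 layer
  expect_equal(match_time(stk, 5 * 3600, window_s = 6 * 3600)$values[1, 1], 2)
  # exactly between 06:00 and 12:00 -> earlier layer
  expect_equal(match_time(stk, 9 * 3600, window_s = 6 * 3600)$values[1, 1], 2)
  # a daily stack queried 20 h from the nearest layer -> no match
  daily <- env_raster("sst_daily", c(0, 1), c(0, 1),
                      array(1:8, dim = c(2, 2, 2)),
                      time = c(0, 86400))
  expect_null(match_time(daily, 86400 + 20 * 3600,
                         window_s = match_windows[["daily"]]))
})

test_that("distance to front is zero in frontal cells and haversine elsewhere", {
  lon <- seq(-90, -88, by = 0.5); lat <- seq(21, 23, by = 0.5)
  fp <- matrix(0, length(lon), length(lat))
  fp[3, 5] <- 1  # frontal cell at (-89, 23)
  fr <- env_raster("front_probability", lon, lat, fp)
  expect_equal(distance_to_front(fr, -89, 23), 0)
  # nearest frontal cell 1 degree due north of the query
  d <- distance_to_front(fr, -89, 22)
  expect_equal(d, 111.2, tolerance = 0.5 / 111.2)
  expect_warning(dn <- distance_to_front(fr, -89, 22, threshold = 2),
                 "no frontal cells")
  expect_true(is.na(dn))
})

test_that("annotation fills one column per field plus distance to front", {
  cfg <- sim_config(seed = 12, n_birds = 1, fix_interval_s = 50,
                    ars_patch_radii_m = 1000, ars_bouts_per_day = 1,
                    domain_extent = 1.2, trip_max_dist_m = c(25000, 40000))
  sim <- simulate_track(cfg, bird_id = "b1", trip_id = 1, n_days = 1)
  rast <- simulate_env_fields(cfg, sim$truth)
  tr <- project_fixes(sim$track, cfg$colony_lonlat)
  bd <- split_bird_days(split_trips(tr, cfg$colony_lonlat)[[1]],
                        cfg$colony_lonlat)[[1]]
  ann <- annotate_locations(bd, rast)
  added <- setdiff(names(ann), names(bd))
  expect_length(added, 12)  # 11 covariates + distance_to_front_km
  expect_true("distance_to_front_km" %in% added)
  expect_true(all(attr(ann, "completeness") == 1))
  # row order does not affect values
  perm <- sample(nrow(bd))
  ann2 <- annotate_locations(bd[perm, ], rast)
  expect_equal(ann2$ssha, ann$ssha[perm])
  expect_equal(ann2$distance_to_front_km, ann$distance_to_front_km[perm])
})

test_that("raster CSV round-trips exactly, for static fields and stacks", {
  f <- file.path(tempdir(), "ssha.csv")
  r <- env_raster("ssha", seq(-90, -89, by = 0.25), seq(22, 23, by = 0.25),
                  matrix(rnorm(25), 5, 5))
  write_raster_csv(r, f)
  r2 <- read_raster_csv(f)
  expect_equal(r2$variable, "ssha")
  expect_equal(r2$lon, r$lon)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
  unlink(f)
  fs <- file.path(tempdir(), "wind_speed.csv")
  stk <- env_raster("wind_speed", c(0, 1), c(0, 1),
                    array(rnorm(12), dim = c(2, 2, 3)),
                    time = c(0, 21600, 43200))
  write_raster_csv(stk, fs)
  s2 <- read_raster_csv(fs)
  expect_s3_class(s2, "env_stack")
  expect_equal(s2$values, stk$values, tolerance = 1e-12)
  unlink(fs)
})
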