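test_that("a fixed seed reproduces tracks and studies byte-identically", {
  cfg <- sim_config(seed = 1, fix_interval_s = 50, ars_patch_radii_m = 1000)
  a <- simulate_track(cfg, bird_id = "b1", trip_id = 1)
  b <- simulate_track(cfg, bird_id = "b1", trip_id = 1)
  expect_identical(a$track, b$track)
  expect_identical(a$truth$bouts, b$truth$bouts)

  cfg2 <- sim_config(seed = 2, n_birds = 3, trips_per_bird_range = c(1, 2),
                     fix_interval_s = 100, domain_extent = 1.0,
                     trip_max_dist_m = c(25000, 40000))
  s1 <- simulate_study(cfg2)
  s2 <- simulate_study(cfg2)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$rasters$ssha$values, s2$rasters$ssha$values)
})

test_that("zero ARS bouts gives a plain out-and-back commute", {
  cfg <- sim_config(seed = 3, fix_interval_s = 50, ars_bouts_per_day = 0,
                    ars_patch_radii_m = 1000)
  sim <- simulate_track(cfg, bird_id = "b", trip_id = 1)
  expect_equal(nrow(sim$truth$bouts), 0)
  # track leaves the colony and returns to it
  d <- haversine_m(sim$track$lon, sim$track$lat,
                   cfg$colony_lonlat[1], cfg$colony_lonlat[2])
  expect_lt(d[1], 100); expect_lt(d[length(d)], 100)
  expect_gt(max(d), 20000)
})

test_that("bout fixes stay inside the recorded patch (independent recount)", {
  cfg <- sim_config(seed = 7, fix_interval_s = 50, ars_patch_radii_m = 1000,
                    ars_bouts_per_day = 1)
  sim <- simulate_track(cfg, bird_id = "b7", trip_id = 1)
  b <- sim$truth$bouts
  expect_equal(nrow(b), 1)
  idx <- b$start_idx[1]:b$end_idx[1]
  d <- oracle_dist_m(sim$track$lon[idx], sim$track$lat[idx],
                     b$center_lon[1], b$center_lat[1])
  expect_gte(mean(d <= b$scale_m[1]), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fix_interval_s = 60), "10, 33, 50, 100")
  expect_error(sim_config(ars_patch_radii_m = 100), "\\[200, 35000\\]")
  expect_error(sim_config(driver_vars = list(ssha = c(-0.5, 0.1))),
               "outside the variable's range")
  cfg <- sim_config(seed = 1, fix_interval_s = 50,
                    ars_patch_radii_m = 20000)
  expect_error(simulate_track(cfg, max_dist_m = 30000),
               "exceeds half the trip extent")
})

test_that("environmental fields respect the observed variable ranges", {
  cfg <- sim_config(seed = 5, fix_interval_s = 100, ars_patch_radii_m = 2000,
                    ars_bouts_per_day = 2, domain_extent = 1.0,
                    trip_max_dist_m = c(25000, 50000))
  sim <- simulate_track(cfg, bird_id = "b", trip_id = 1)
  rast <- simulate_env_fields(cfg, sim$truth)
  t1 <- table1_variables()
  for (i in seq_len(nrow(t1))) {
    v <- rast[[t1$variable[i]]]$values
    expect_gte(min(v), t1$min[i])
    expect_lte(max(v), t1$max[i])
  }
  expect_true(all(rast$front_probability$values >= 0 &
                    rast$front_probability$values <= 1))
})

test_that("a noiseless driver field equals the band midpoint at a patch centre", {
  cfg <- sim_config(seed = 6, fix_interval_s = 100, ars_patch_radii_m = 2000,
                    ars_bouts_per_day = 1, domain_extent = 1.0,
                    trip_max_dist_m = c(25000, 50000))
  cfg$noise_sd[] <- 0
  sim <- simulate_track(cfg, bird_id = "b", trip_id = 1)
  rast <- simulate_env_fields(cfg, sim$truth)
  b <- sim$truth$bouts[1, ]
  expect_equal(sample_bilinear(rast$ssha, b$center_lon, b$center_lat),
               mean(cfg$driver_vars$ssha), tolerance = 1e-12)
  expect_equal(sample_bilinear(rast$velocity, b$center_lon, b$center_lat),
               mean(cfg$driver_vars$velocity), tolerance = 1e-12)
})

test_that("a study directory has one track file per bird, metadata and 12 rasters", {
  cfg <- sim_config(seed = 4, n_birds = 4, trips_per_bird_range = c(1, 1),
                    fix_interval_s = 100, domain_extent = 1.0,
                    ars_patch_radii_m = 2000,
                    trip_max_dist_m = c(25000, 40000))
  dir <- file.path(tempdir(), "study4")
  unlink(dir, recursive = TRUE)
  st <- simulate_study(cfg, dir = dir)
  expect_length(list.files(file.path(dir, "tracks")), 4)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_length(list.files(file.path(dir, "rasters")), 12)
  expect_true(file.exists(file.path(dir, "truth.json")))
  # collision refused without overwrite
  expect_error(simulate_study(cfg, dir = dir), "overwrite")
  # round trip preserves fixes to CSV precision
  back <- read_study(dir)
  expect_equal(nrow(back$tracks), nrow(st$tracks))
  expect_equal(sort(unique(back$tracks$bird_id)), sort(st$metadata$bird_id))
  expect_equal(back$tracks$timestamp, st$tracks$timestamp)
  unlink(dir, recursive = TRUE)
})

test_that("trips per bird stay inside the configured range", {
  cfg <- sim_config(seed = 3, n_birds = 30, trips_per_bird_range = c(1, 9),
                    fix_interval_s = 100, ars_bouts_per_day = 0,
                    domain_extent = 1.0, trip_max_dist_m = c(25000, 40000))
  set.seed(cfg$seed)
  lo <- cfg$trips_per_bird_range[1]; hi <- cfg$trips_per_bird_range[2]
  n_trips <- sample(seq(lo, hi), cfg$n_birds, replace = TRUE,
                    prob = 0.55^(seq(lo, hi) - lo))
  m <- mean(n_trips)
  expect_gte(m, 1); expect_lte(m, 9)
  # full (small) study agrees with its own metadata
  cfg$n_birds <- 6L
  st <- simulate_study(cfg)
  counted <- tapply(st$trips$trip_id, st$trips$bird_id, max)
  expect_equal(as.integer(counted[st$metadata$bird_id]),
               st$metadata$n_trips)
})

test_that("truth bout windows really contain tortuous, patch-bound movement", {
  cfg <- sim_config(seed = 10, fix_interval_s = 50, ars_patch_radii_m = 1000,
                    ars_bouts_per_day = 2)
  sim <- simulate_track(cfg, bird_id = "b", trip_id = 1)
  tr <- sim$track
  for (k in seq_len(nrow(sim$truth$bouts))) {
    b <- sim$truth$bouts[k, ]
    idx <- which(tr$timestamp >= b$t_start & tr$timestamp <= b$t_end)
    expect_equal(idx, b$start_idx:b$end_idx)
    d <- oracle_dist_m(tr$lon[idx], tr$lat[idx], b$center_lon, b$center_lat)
    expect_gte(mean(d <= b$scale_m), 0.95)
  }
  # bouts at the same scale do not overlap
  b1 <- sim$truth$bouts
  expect_true(all(b1$start_idx[-1] > head(b1$end_idx, -1)))
})
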