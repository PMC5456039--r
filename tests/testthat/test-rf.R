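test_that("a separable day is learned with the driver ranked first", {
  day <- make_separable_day(n = 300, seed = 2)
  fit <- fit_day_forest(day, n_trees = 100, seed = 7)
  expect_equal(fit$mtry, 3)  # floor(sqrt(11))
  expect_gte(fit$sensitivity, 0.95)
  expect_gte(fit$specificity, 0.95)
  expect_equal(names(which.max(fit$importance_pct)), "ssha")
  expect_equal(sum(fit$importance_pct), 100, tolerance = 1e-9)
  # prediction separates the classes
  pr <- predict(fit, day$x)
  expect_gt(mean(pr[day$y == 1]), 0.8)
  expect_lt(mean(pr[day$y == 0]), 0.2)
})

test_that("forests are deterministic under a fixed seed", {
  day <- make_separable_day(n = 150, seed = 3)
  f1 <- fit_day_forest(day, n_trees = 50, seed = 11)
  f2 <- fit_day_forest(day, n_trees = 50, seed = 11)
  expect_identical(f1$importance_raw, f2$importance_raw)
  expect_identical(predict(f1, day$x), predict(f2, day$x))
})

test_that("per-tree validation rows never intersect that tree's training rows", {
  day <- make_separable_day(n = 90, seed = 4)
  fit <- fit_day_forest(day, n_trees = 20, seed = 5, keep_train_idx = TRUE)
  for (b in seq_along(fit$train_idx)) {
    tr <- fit$train_idx[[b]]
    expect_equal(length(tr), floor(2 / 3 * 90))
    expect_equal(anyDuplicated(tr), 0)
  }
})

test_that("importance standardization is a scale-free percentage", {
  raw <- c(2, 3, 5, rep(0, 8))
  expect_equal(standardize_importance(raw),
               c(20, 30, 50, rep(0, 8)))
  expect_equal(standardize_importance(rep(4, 11)), rep(100 / 11, 11))
  expect_equal(standardize_importance(raw * 17),
               standardize_importance(raw))
  expect_error(standardize_importance(rep(0, 11)), "all raw")
  expect_error(standardize_importance(c(-1, 2)), "non-negative")
})

test_that("single-class days are excluded from the design list", {
  locs <- data.frame(bird_id = rep(c("a", "b"), each = 20),
                     trip_id = 1L, day_index = 1L,
                     label = c(rep("nonARS", 20),
                               rep(c("ARS", "nonARS"), 10)))
  for (v in rf_predictors) locs[[v]] <- rnorm(40)
  expect_message(dd <- day_designs(locs), "single-class")
  expect_length(dd, 1)
  expect_equal(dd[[1]]$bird_id, "b")
})

test_that("stratified bootstrap means keep the 100% normalization", {
  set.seed(40)
  prof <- data.frame(bird_id = rep(sprintf("b%02d", 1:6), times = c(1, 1, 2, 2, 3, 3)),
                     trip_id = c(1, 1, 1, 1, 1, 2, 1, 1, 2, 1, 1, 1)[1:12],
                     day_index = 1)
  prof$trip_id <- c(1, 1, 1, 2, 1, 1, 1, 2, 3, 1, 1, 2)
  raw <- matrix(rexp(12 * 11), 12, 11)
  pct <- t(apply(raw, 1, function(r) 100 * r / sum(r)))
  colnames(pct) <- rf_predictors
  prof <- cbind(prof, as.data.frame(pct))
  bs <- bootstrap_importance(prof, n_iter = 200, seed = 2)
  expect_equal(rowSums(bs$iterations), rep(100, 200), tolerance = 1e-9)
  expect_equal(sum(bs$mean), 100, tolerance = 1e-9)
  # one day per trip per bird: nothing to resample, SD identically zero
  one <- prof[!duplicated(interaction(prof$bird_id, prof$trip_id)), ]
  bs1 <- bootstrap_importance(one, n_iter = 50, seed = 3)
  expect_equal(unname(bs1$sd), rep(0, 11))
  # per-bird stratification draws one row per bird
  bsb <- bootstrap_importance(prof, n_iter = 50, seed = 4, one_per = "bird")
  expect_equal(sum(bsb$mean), 100, tolerance = 1e-9)
})

test_that("partial dependence tracks a single-variable band rule", {
  set.seed(41)
  n <- 400
  x <- matrix(rnorm(n * 11), n, 11)
  colnames(x) <- rf_predictors
  x[, "velocity"] <- runif(n, 0.01, 0.2)
  y <- as.integer(x[, "velocity"] >= 0.05 & x[, "velocity"] <= 0.1)
  fit <- fit_day_forest(list(x = x, y = y), n_trees = 150, seed = 6)
  pd <- partial_dependence(fit, x, "velocity", grid_size = 40)
  inside <- pd$value >= 0.06 & pd$value <= 0.09
  outside <- pd$value < 0.04 | pd$value > 0.12
  expect_gt(min(pd$pd[inside]), max(pd$pd[outside]))
  expect_true(all(pd$pd >= 0 & pd$pd <= 1))
  # an uninformative variable has a nearly flat curve
  pd0 <- partial_dependence(fit, x, "bathymetry", grid_size = 40)
  expect_lt(diff(range(pd0$pd)), 0.05)
})

test_that("the cross-day GAM smooth passes through consistent curves", {
  grid <- seq(0, 1, length.out = 30)
  shape <- function(v) 0.2 + 0.6 * exp(-((v - 0.5) / 0.2)^2)
  one <- data.frame(value = grid, pd = shape(grid), day = 1)
  # single curve: pass-through
  sm1 <- smooth_pd_across_days(one)
  expect_equal(sm1$fit, one$pd)
  expect_equal(sm1$lower, sm1$upper)
  # identical curves: smooth reproduces them closely, band stays narrow
  many <- do.call(rbind, lapply(1:5, function(d) transform(one, day = d)))
  sm <- smooth_pd_across_days(many)
  expect_lt(max(abs(sm$fit - shape(sm$value))), 0.03)
  expect_lt(max(sm$upper - sm$lower), 0.05)
  # noisy copies: smooth stays within the noise of the shared truth
  set.seed(43)
  noisy <- do.call(rbind, lapply(1:8, function(d) {
    transform(one, pd = pmin(1, pmax(0, pd + rnorm(30, 0, 0.05))), day = d)
  }))
  smn <- smooth_pd_across_days(noisy)
  expect_lt(mean(abs(smn$fit - shape(smn$value))), 0.03)
  expect_gte(min(smn$fit), min(noisy$pd) - 0.05)
  expect_lte(max(smn$fit), max(noisy$pd) + 0.05)
})

test_that("the 75th-percentile tally flags the informative variable", {
  set.seed(44)
  pct <- matrix(100 / 11, 40, 11)
  pct <- pct + matrix(rnorm(440, 0, 0.5), 40, 11)
  pct[, 6] <- pct[, 6] + 10  # one variable consistently high
  pct <- t(apply(pct, 1, function(r) 100 * pmax(r, 0) / sum(pmax(r, 0))))
  colnames(pct) <- rf_predictors
  prof <- cbind(data.frame(bird_id = "b", trip_id = 1, day_index = 1:40),
                as.data.frame(pct))
  tal <- importance_tally(prof)
  expect_equal(names(which.max(tal$fraction)), rf_predictors[6])
  expect_gte(tal$fraction[[rf_predictors[6]]], 0.9)
})
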