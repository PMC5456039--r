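# Per-bird-day habitat models: a classification forest of ARS vs non-ARS
# locations on the eleven environmental covariates, standardized Gini
# importance, stratified-bootstrap population summaries, and
# partial-dependence curves with a GAM smooth across days.

#' The standard predictor set
#'
#' The eleven covariate column names expected in an annotated location
#' table, with `distance_to_front_km` standing in for the raw front
#' probability.
#' @export
rf_predictors <- c("bathymetry", "chla_8day", "chla_monthly",
                   "distance_to_front_km", "mld", "ssha", "sst_daily",
                   "sst_8day", "sst_monthly", "velocity", "wind_speed")

#' Assemble per-bird-day design matrices
#'
#' Splits an annotated, labelled location table into one design per
#' bird-day; rows with missing predictors are dropped, and days whose
#' response has a single class are excluded with a message.
#'
#' @param locations Data frame with `bird_id`, `trip_id`, `day_index`, a
#'   label column, and the predictor columns.
#' @param predictors Predictor column names (default [rf_predictors]).
#' @param label_col Name of the label column (values `"ARS"`/`"nonARS"`).
#' @return List of designs; each has `bird_id`, `trip_id`, `day_index`,
#'   `x` (numeric matrix) and `y` (integer 0/1, 1 = ARS).
#' @export
day_designs <- function(locations, predictors = rf_predictors,
                        label_col = "label") {
  miss <- setdiff(c(predictors, label_col), names(locations))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keys <- interaction(locations$bird_id, locations$trip_id,
                      locations$day_index, drop = TRUE)
  out <- list()
  for (k in levels(keys)) {
    df <- locations[keys == k, , drop = FALSE]
    x <- as.matrix(df[, predictors, drop = FALSE])
    ok <- stats::complete.cases(x)
    x <- x[ok, , drop = FALSE]
    y <- as.integer(df[[label_col]][ok] == "ARS")
    if (length(unique(y)) < 2) {
      message("skipping single-class bird-day ", k)
      next
    }
    out[[length(out) + 1]] <- list(bird_id = df$bird_id[1],
                                   trip_id = df$trip_id[1],
                                   day_index = df$day_index[1],
                                   x = x, y = y)
  }
  out
}

#' Standardize raw Gini importances to percentages
#'
#' @param raw Non-negative raw importances (named vector), not all zero.
#' @return Percentages summing to 100.
#' @export
standardize_importance <- function(raw) {
  if (any(raw < 0)) stop("raw importances must be non-negative")
  s <- sum(raw)
  if (s <= 0) stop("all raw importances are zero")
  100 * raw / s
}

#' Fit the classification forest for one bird-day
#'
#' Each of `n_trees` trees is grown on an independent random `train_frac`
#' subsample of the locations drawn without replacement and validated on its
#' held-out complement; splits minimise Gini impurity over `mtry` predictors
#' drawn at random per node (3 for 11 predictors, the square root of the
#' predictor count); trees grow to purity or to `min_node` locations. Raw
#' importance is the mean over trees of each variable total impurity
#' decrease; `importance_pct` standardizes it to sum to 100.
#'
#' @param design One element of [day_designs()], or a list with `x`, `y`.
#' @param n_trees Trees in the ensemble (default 1000).
#' @param mtry Predictors tried per node; default `floor(sqrt(ncol(x)))`.
#' @param train_frac Per-tree training fraction (default 2/3).
#' @param min_node Do not split nodes at or below this size (default 5).
#' @param seed Optional RNG seed.
#' @param keep_train_idx Keep each tree's training rows (for audits).
#' @return List of class `day_forest`: `trees`, `importance_raw`,
#'   `importance_pct`, `sensitivity`, `specificity`, `accuracy` (held-out
#'   validation: each location is predicted by the majority vote of the
#'   trees that did not train on it), plus the day identifiers.
#' @export
fit_day_forest <- function(design, n_trees = 1000,
                           mtry = NULL, train_frac = 2 / 3,
                           min_node = 5, seed = NULL,
                           keep_train_idx = FALSE) {
  x <- design$x; y <- design$y
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("single-class day cannot be modelled")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  fit <- rf_fit_cpp(x, as.integer(y), as.integer(n_trees), as.integer(mtry),
                    as.integer(min_node), train_frac, keep_train_idx)
  raw <- stats::setNames(fit$importance, colnames(x))
  structure(list(
    trees = fit$trees,
    importance_raw = raw,
    importance_pct = standardize_importance(raw),
    sensitivity = fit$sensitivity,
    specificity = fit$specificity,
    accuracy = fit$accuracy,
    train_idx = fit$train_idx,
    n_trees = n_trees, mtry = mtry,
    bird_id = design$bird_id, trip_id = design$trip_id,
    day_index = design$day_index
  ), class = "day_forest")
}

#' @export
print.day_forest <- function(x, ...) {
  cat(sprintf(paste0("<day_forest> %d trees, mtry %d; validation ",
                     "sens %.3f spec %.3f acc %.3f\n"),
              x$n_trees, x$mtry, x$sensitivity, x$specificity, x$accuracy))
  top <- sort(x$importance_pct, decreasing = TRUE)[1:3]
  cat("  top importance:",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Ensemble prediction (vote fraction)
#'
#' @param object A `day_forest`.
#' @param newdata Numeric matrix with the forest's predictor columns.
#' @param ... Unused.
#' @return Predicted ARS probability (fraction of trees voting ARS) per row.
#' @export
predict.day_forest <- function(object, newdata, ...) {
  nm <- names(object$importance_raw)
  if (!is.null(colnames(newdata))) {
    newdata <- newdata[, nm, drop = FALSE]
  }
  rf_predict_cpp(object$trees, as.matrix(newdata))
}

#' Collect day-level importance profiles
#'
#' @param forests List of `day_forest` objects.
#' @return Data frame: `bird_id`, `trip_id`, `day_index`, `sensitivity`,
#'   `specificity`, `accuracy`, and one standardized-importance column per
#'   predictor (each row sums to 100).
#' @export
importance_profiles <- function(forests) {
  do.call(rbind, lapply(forests, function(f) {
    cbind(data.frame(bird_id = f$bird_id, trip_id = f$trip_id,
                     day_index = f$day_index,
                     sensitivity = f$sensitivity,
                     specificity = f$specificity, accuracy = f$accuracy),
          as.data.frame(as.list(f$importance_pct)))
  }))
}

#' Stratified-bootstrap population importance
#'
#' Tracking effort is uneven (1-10 days per bird), so each bootstrap
#' iteration draws one bird-day per trip per bird (or one day per bird when
#' `one_per` is `"bird"`, as used within a sampling period), averages the
#' standardized importances over the draw, and the population summary is the
#' mean and SD of those averages over `n_iter` iterations.
#'
#' @param profiles Output of [importance_profiles()] (optionally
#'   pre-filtered to one sampling period).
#' @param variables Importance column names; default [rf_predictors]
#'   intersected with the columns present.
#' @param n_iter Bootstrap iterations (default 1000).
#' @param seed Optional RNG seed.
#' @param one_per Stratification unit: `"trip"` (default) or `"bird"`.
#' @return List of class `bootstrap_summary`: `mean`, `sd` (per variable),
#'   `n_iter`, and the `iterations` matrix (n_iter x variables; each row
#'   sums to 100).
#' @export
bootstrap_importance <- function(profiles, variables = NULL, n_iter = 1000,
                                 seed = NULL, one_per = c("trip", "bird")) {
  one_per <- match.arg(one_per)
  if (nrow(profiles) == 0) stop("no importance profiles supplied")
  if (is.null(variables)) {
    variables <- intersect(rf_predictors, names(profiles))
    if (!length(variables)) {
      variables <- setdiff(names(profiles),
                           c("bird_id", "trip_id", "day_index", "sensitivity",
                             "specificity", "accuracy"))
    }
  }
  key <- if (one_per == "trip") {
    interaction(profiles$bird_id, profiles$trip_id, drop = TRUE)
  } else {
    factor(profiles$bird_id)
  }
  idx_by <- split(seq_len(nrow(profiles)), key)
  m <- as.matrix(profiles[, variables, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  iters <- matrix(NA_real_, n_iter, length(variables),
                  dimnames = list(NULL, variables))
  for (b in seq_len(n_iter)) {
    pick <- vapply(idx_by, function(ix) ix[sample.int(length(ix), 1L)],
                   integer(1))
    iters[b, ] <- colMeans(m[pick, , drop = FALSE])
  }
  structure(list(mean = colMeans(iters), sd = apply(iters, 2, stats::sd),
                 n_iter = n_iter, iterations = iters),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  ord <- order(x$mean, decreasing = TRUE)
  cat("<bootstrap_summary>", x$n_iter, "iterations\n")
  print(round(rbind(mean = x$mean[ord], sd = x$sd[ord]), 2))
  invisible(x)
}

#' Partial dependence of the ensemble on one variable
#'
#' PD(v) is the mean predicted ARS probability over the day's locations with
#' the variable forced to v, evaluated on a grid of observed quantiles.
#'
#' @param forest A `day_forest`.
#' @param x The day's predictor matrix.
#' @param variable Predictor name.
#' @param grid_size Number of grid values (default 50).
#' @return Data frame `value`, `pd` (probabilities in \[0, 1\]).
#' @export
partial_dependence <- function(forest, x, variable, grid_size = 50) {
  stopifnot(variable %in% colnames(x))
  v <- x[, variable]
  if (diff(range(v)) < .Machine$double.eps) {
    warning("constant predictor '", variable, "': flat curve")
    grid <- v[1]
  } else {
    grid <- unique(stats::quantile(v, probs = seq(0, 1,
                                                  length.out = grid_size),
                                   names = FALSE, type = 7))
  }
  n <- nrow(x)
  big <- x[rep(seq_len(n), length(grid)), , drop = FALSE]
  big[, variable] <- rep(grid, each = n)
  pr <- rf_predict_cpp(forest$trees, big)
  data.frame(value = grid,
             pd = colMeans(matrix(pr, n, length(grid))))
}

#' Smooth partial-dependence curves across days
#'
#' Pools (value, PD) points from many per-day curves and fits a penalized
#' spline ([mgcv::gam()]) with a pointwise 95 percent confidence band. A
#' single curve passes through unchanged (zero-width band).
#'
#' @param curves Data frame with columns `value`, `pd` and a day identifier
#'   column `day` (any type).
#' @param grid_size Prediction grid size over the pooled value range.
#' @return Data frame `value`, `fit`, `lower`, `upper`.
#' @export
smooth_pd_across_days <- function(curves, grid_size = 100) {
  stopifnot(all(c("value", "pd", "day") %in% names(curves)))
  nday <- length(unique(curves$day))
  if (nday < 2) {
    return(data.frame(value = curves$value, fit = curves$pd,
                      lower = curves$pd, upper = curves$pd))
  }
  kk <- min(10, max(4, floor(length(unique(curves$value)) / 2)))
  g <- mgcv::gam(pd ~ s(value, k = kk), data = curves)
  grid <- seq(min(curves$value), max(curves$value), length.out = grid_size)
  pr <- mgcv::predict.gam(g, newdata = data.frame(value = grid),
                          se.fit = TRUE)
  data.frame(value = grid, fit = as.numeric(pr$fit),
             lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
             upper = as.numeric(pr$fit + 1.96 * pr$se.fit))
}

#' Tally of "important" variables per day
#'
#' A variable counts as important in a day when its standardized importance
#' exceeds the `q` quantile of all day-level importances pooled over
#' variables and days (the conventional 75th-percentile rule).
#'
#' @param profiles Output of [importance_profiles()].
#' @param variables Importance columns; default as in
#'   [bootstrap_importance()].
#' @param q Quantile (default 0.75).
#' @return List: `threshold` and `fraction` (per variable, the share of days
#'   in which it exceeds the threshold).
#' @export
importance_tally <- function(profiles, variables = NULL, q = 0.75) {
  if (is.null(variables)) variables <- intersect(rf_predictors,
                                                 names(profiles))
  m <- as.matrix(profiles[, variables, drop = FALSE])
  thr <- stats::quantile(as.vector(m), q, names = FALSE)
  list(threshold = thr, fraction = colMeans(m > thr))
}
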