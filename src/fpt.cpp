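#include <Rcpp.h>
using namespace Rcpp;

// First time (within [ta, tb], linear in arc position) at which the point
// moving from (ax,ay) to (bx,by) reaches distance r from (cx,cy), given the
// start is strictly inside the circle. d^2(s) is a convex quadratic that is
// negative (minus r^2) at s=0 and non-negative at the far endpoint, so the
// positive root is the unique crossing in (0, 1].
static double cross_time(double ax, double ay, double bx, double by,
                         double cx, double cy, double ta, double tb,
                         double r) {
  double px = ax - cx, py = ay - cy;
  double vx = bx - ax, vy = by - ay;
  double A = vx * vx + vy * vy;
  if (A < 1e-300) return NA_REAL;
  double B = 2.0 * (px * vx + py * vy);
  double C = px * px + py * py - r * r;
  double disc = B * B - 4.0 * A * C;
  if (disc < 0) disc = 0;
  double s = (-B + std::sqrt(disc)) / (2.0 * A);
  if (s < 0) s = 0;
  if (s > 1) s = 1;
  return ta + s * (tb - ta);
}

// First-passage time at every location for every radius. Positions are
// planar metres, times seconds, radii strictly increasing. FPT(i, r) is the
// time to first exit the circle of radius r centred at location i walking
// forward plus the same walking backward; NA when the track ends inside the
// circle in either direction. Exits are located by exact segment-circle
// intersection; because point-to-segment distance is convex, the running
// maximum over segment endpoints tells which radii are first crossed within
// each segment.
// [[Rcpp::export]]
NumericMatrix fpt_matrix_cpp(NumericVector x, NumericVector y,
                             NumericVector t, NumericVector radii) {
  const int n = x.size();
  const int R = radii.size();
  for (int k = 0; k < R; ++k) {
    if (radii[k] <= 0) stop("radii must be positive");
    if (k > 0 && radii[k] <= radii[k - 1])
      stop("radii must be strictly increasing");
  }
  NumericMatrix out(n, R);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> fwd(R), bwd(R);

  for (int i = 0; i < n; ++i) {
    std::fill(fwd.begin(), fwd.end(), NA_REAL);
    std::fill(bwd.begin(), bwd.end(), NA_REAL);
    const double cx = x[i], cy = y[i];
    // forward
    double M = 0.0;
    int k = 0;
    for (int j = i; j + 1 < n && k < R; ++j) {
      double d1 = std::hypot(x[j + 1] - cx, y[j + 1] - cy);
      if (d1 > M) {
        while (k < R && radii[k] <= d1) {
          double tc = cross_time(x[j], y[j], x[j + 1], y[j + 1], cx, cy,
                                 t[j], t[j + 1], radii[k]);
          fwd[k] = tc - t[i];
          ++k;
        }
        M = d1;
      }
    }
    // backward (elapsed time measured back from t[i])
    M = 0.0;
    k = 0;
    for (int j = i; j - 1 >= 0 && k < R; --j) {
      double d1 = std::hypot(x[j - 1] - cx, y[j - 1] - cy);
      if (d1 > M) {
        while (k < R && radii[k] <= d1) {
          double tc = cross_time(x[j], y[j], x[j - 1], y[j - 1], cx, cy,
                                 t[i] - t[j], t[i] - t[j - 1], radii[k]);
          bwd[k] = tc;
          ++k;
        }
        M = d1;
      }
    }
    for (int r = 0; r < R; ++r) {
      if (!ISNA(fwd[r]) && !ISNA(bwd[r])) out(i, r) = fwd[r] + bwd[r];
    }
  }
  return out;
}
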