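#include <Rcpp.h>
using namespace Rcpp;

// Optimal partition of a series into K contiguous segments minimising the
// within-segment sum of squared deviations (the least-squares contrast),
// for every K = 1..Kmax, with a minimum segment length. Exact dynamic
// programming, O(Kmax * n^2) with O(1) segment costs from cumulative sums.
// Returns the contrast J(K) and the optimal segment end indices (1-based)
// for each K.
// [[Rcpp::export]]
List lavielle_dp_cpp(NumericVector yv, int Kmax, int Lmin) {
  const int n = yv.size();
  if (Lmin < 1) stop("Lmin must be >= 1");
  if (Kmax < 1) stop("Kmax must be >= 1");
  if (n < (long long)Kmax * Lmin)
    stop("series too short for Kmax segments of length Lmin");

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + yv[i];
    s2[i + 1] = s2[i] + yv[i] * yv[i];
  }
  // cost of segment covering 0-based [i, j]
  auto cost = [&](int i, int j) {
    double len = j - i + 1;
    double sum = s1[j + 1] - s1[i];
    return (s2[j + 1] - s2[i]) - sum * sum / len;
  };

  const double INF = std::numeric_limits<double>::infinity();
  // J[k][j]: best cost of splitting [0, j] into k+1 segments
  std::vector<std::vector<double>> J(Kmax, std::vector<double>(n, INF));
  std::vector<std::vector<int>> back(Kmax, std::vector<int>(n, -1));
  for (int j = Lmin - 1; j < n; ++j) J[0][j] = cost(0, j);
  for (int k = 1; k < Kmax; ++k) {
    for (int j = (k + 1) * Lmin - 1; j < n; ++j) {
      double best = INF;
      int arg = -1;
      for (int i = k * Lmin - 1; i <= j - Lmin; ++i) {
        double v = J[k - 1][i] + cost(i + 1, j);
        if (v < best) { best = v; arg = i; }
      }
      J[k][j] = best;
      back[k][j] = arg;
    }
  }
  NumericVector contrast(Kmax);
  List breaks(Kmax);
  for (int k = 0; k < Kmax; ++k) {
    contrast[k] = J[k][n - 1];
    IntegerVector ends(k + 1);
    int j = n - 1;
    for (int kk = k; kk >= 0; --kk) {
      ends[kk] = j + 1;  // 1-based inclusive segment end
      if (kk > 0) j = back[kk][j];
    }
    breaks[k] = ends;
  }
  return List::create(_["contrast"] = contrast, _["breaks"] = breaks);
}
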