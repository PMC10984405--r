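#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

// Weighted pair-distance histogram for the Debye sum and P(r).
// coords: n x 3 (nm); b: scattering lengths. Bin k covers
// [k*bin_width, (k+1)*bin_width); weights are b_i*b_j for i<j.
// Returns the histogram, sum(b_i^2) (self terms), exact max pair
// distance, and the sum of all b.
// [[Rcpp::export]]
List pair_hist_cpp(NumericMatrix coords, NumericVector b,
                   double bin_width, int nbins) {
  const int n = coords.nrow();
  if (b.size() != n) stop("length(b) must equal nrow(coords)");
  std::vector<double> hist(nbins, 0.0);
  double dmax = 0.0, bsum = 0.0, bself = 0.0;
  const double *x = &coords(0, 0), *y = &coords(0, 1), *z = &coords(0, 2);
  for (int i = 0; i < n; ++i) { bsum += b[i]; bself += b[i] * b[i]; }
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], bi = b[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > dmax) dmax = d;
      int k = (int)(d / bin_width);
      if (k >= nbins) k = nbins - 1;
      hist[k] += bi * b[j];
    }
  }
  return List::create(_["hist"] = NumericVector(hist.begin(), hist.end()),
                      _["self"] = bself, _["dmax"] = dmax, _["bsum"] = bsum);
}

// Steric-clash detection with a cell list (near-linear in atoms).
// Only pairs in different rigid bodies, or pairs involving body 0
// (the flexible linker), count; pairs listed in `excl` (1-2 and 1-3
// connected, encoded i*n+j with i<j, 0-based) are ignored.
// idx: 0-based indices of the (heavy) atoms to consider.
// [[Rcpp::export]]
bool detect_clash_cpp(NumericMatrix coords, IntegerVector idx,
                      IntegerVector body, NumericVector excl_keys,
                      double cutoff) {
  const int m = idx.size();
  const int n = coords.nrow();
  if (m < 2) return false;
  std::unordered_set<double> excl(excl_keys.begin(), excl_keys.end());
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int a = 0; a < m; ++a) {
    int i = idx[a];
    xmin = std::min(xmin, coords(i, 0));
    ymin = std::min(ymin, coords(i, 1));
    zmin = std::min(zmin, coords(i, 2));
  }
  const double cell = cutoff;
  // hash grid: map cell -> atom list
  std::vector<long long> key(m);
  std::unordered_multimap<long long, int> grid;
  grid.reserve(m * 2);
  auto cell_key = [](long long cx, long long cy, long long cz) {
    return (cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL);
  };
  std::vector<long long> cx(m), cy(m), cz(m);
  for (int a = 0; a < m; ++a) {
    int i = idx[a];
    cx[a] = (long long)std::floor((coords(i, 0) - xmin) / cell);
    cy[a] = (long long)std::floor((coords(i, 1) - ymin) / cell);
    cz[a] = (long long)std::floor((coords(i, 2) - zmin) / cell);
    grid.insert({cell_key(cx[a], cy[a], cz[a]), a});
  }
  const double cut2 = cutoff * cutoff;
  for (int a = 0; a < m; ++a) {
    const int i = idx[a];
    const int bi = body[i];
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto range = grid.equal_range(
            cell_key(cx[a] + dx, cy[a] + dy, cz[a] + dz));
          for (auto it = range.first; it != range.second; ++it) {
            const int bnb = it->second;
            if (bnb <= a) continue;
            // hash collisions are possible: verify the actual cell
            if (std::llabs(cx[bnb] - cx[a]) > 1 ||
                std::llabs(cy[bnb] - cy[a]) > 1 ||
                std::llabs(cz[bnb] - cz[a]) > 1) continue;
            const int j = idx[bnb];
            const int bj = body[j];
            if (bi == bj && bi != 0) continue;  // same rigid body
            const double ddx = coords(i, 0) - coords(j, 0);
            const double ddy = coords(i, 1) - coords(j, 1);
            const double ddz = coords(i, 2) - coords(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < cut2) {
              const int lo = std::min(i, j), hi = std::max(i, j);
              const double k = (double)lo * n + hi;
              if (excl.find(k) == excl.end()) return true;
            }
          }
        }
  }
  return false;
}
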