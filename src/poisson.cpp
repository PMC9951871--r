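#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Dart-throwing Poisson-disc sampler for K x K patch anchors.
//
// Anchors are 0-based top-left corners, uniform over [0, H-K] x [0, W-K].
// Patch centers (anchor + K/2) must be >= K*sqrt(2) apart (Euclidean),
// which guarantees pairwise-disjoint patches. A background grid with cell
// size d/sqrt(2) (= K) holds at most one accepted center per cell, so each
// candidate is checked against a bounded neighborhood.
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// If the process stalls (too many consecutive rejections) it restarts from
// an empty set; after `max_restarts` restarts it gives up.
// [[Rcpp::export(name = ".poisson_anchors_cpp")]]
IntegerMatrix poisson_anchors_cpp(int H, int W, int K, int n_target,
                                  int max_consecutive_reject = 5000,
                                  int max_restarts = 100) {
  if (K > H || K > W) stop("patch size K exceeds image dimensions");
  const double d2 = 2.0 * K * K;  // squared minimum distance (K*sqrt(2))^2
  const double cell = (double)K;  // d / sqrt(2)
  const int gh = (int)std::ceil(H / cell) + 1;
  const int gw = (int)std::ceil(W / cell) + 1;
  const int ar = H - K;  // anchor rows in [0, ar]
  const int ac = W - K;

  std::vector<double> cr, cc;        // accepted centers
  std::vector<int> grid(gh * gw, -1);

  RNGScope scope;
  int restarts = 0;
  int consec = 0;
  cr.reserve(n_target); cc.reserve(n_target);

  while ((int)cr.size() < n_target) {
    double r = std::floor(unif_rand() * (ar + 1));
    double c = std::floor(unif_rand() * (ac + 1));
    if (r > ar) r = ar;  // guard against unif_rand() == 1
    if (c > ac) c = ac;
    double yr = r + K / 2.0, yc = c + K / 2.0;
    int gi = (int)(yr / cell), gj = (int)(yc / cell);
    bool ok = true;
    for (int di = -2; di <= 2 && ok; ++di) {
      int ii = gi + di;
      if (ii < 0 || ii >= gh) continue;
      for (int dj = -2; dj <= 2; ++dj) {
        int jj = gj + dj;
        if (jj < 0 || jj >= gw) continue;
        int idx = grid[ii * gw + jj];
        if (idx >= 0) {
          double dr = cr[idx] - yr, dc = cc[idx] - yc;
          if (dr * dr + dc * dc < d2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      grid[gi * gw + gj] = (int)cr.size();
      cr.push_back(yr); cc.push_back(yc);
      consec = 0;
    } else if (++consec >= max_consecutive_reject) {
      if (++restarts > max_restarts)
        stop("Poisson-disc sampling failed: could not place %d disjoint %dx%d patches in a %dx%d image",
             n_target, K, K, H, W);
      std::fill(grid.begin(), grid.end(), -1);
      cr.clear(); cc.clear();
      consec = 0;
    }
  }

  IntegerMatrix out(n_target, 2);
  for (int i = 0; i < n_target; ++i) {
    out(i, 0) = (int)(cr[i] - K / 2.0);
    out(i, 1) = (int)(cc[i] - K / 2.0);
  }
  return out;
}
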