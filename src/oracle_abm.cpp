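// Naive reference implementation of the colony-growth rules, kept
// deliberately simple and structurally independent of the optimized engine
// in abm.cpp: plain occupancy matrix, linear searches instead of an id grid,
// everything recomputed from scratch each round. Used to validate the main
// simulator (mu = 0, fixed division probability, no death).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static int runif_int(int n) {
  // uniform integer in 0..n-1 from R's RNG
  int j = static_cast<int>(std::floor(unif_rand() * n));
  return j >= n ? n - 1 : j;
}

// [[Rcpp::export]]
int oracle_colony_cpp(double p, int n_updates, int side) {
  const int dx[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dy[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  IntegerMatrix occ(side, side);
  std::vector<int> xs, ys;
  xs.push_back(side / 2);
  ys.push_back(side / 2);
  occ(side / 2, side / 2) = 1;

  for (int t = 0; t < n_updates; ++t) {
    int n0 = static_cast<int>(xs.size());
    // randomized order over the cells present at the start of the round
    std::vector<int> order(n0);
    for (int i = 0; i < n0; ++i) order[i] = i;
    for (int i = n0 - 1; i > 0; --i) std::swap(order[i], order[runif_int(i + 1)]);

    for (int oi = 0; oi < n0; ++oi) {
      int me = order[oi];
      if (unif_rand() >= p) continue;
      int x = xs[me], y = ys[me];
      // daughter placement options: empty neighbours, or occupied
      // neighbours that themselves have an empty neighbour
      std::vector<int> opts;
      for (int d = 0; d < 8; ++d) {
        int nx = x + dx[d], ny = y + dy[d];
        if (nx < 0 || ny < 0 || nx >= side || ny >= side) continue;
        if (occ(nx, ny) == 0) {
          opts.push_back(d);
        } else {
          for (int e = 0; e < 8; ++e) {
            int ex = nx + dx[e], ey = ny + dy[e];
            if (ex >= 0 && ey >= 0 && ex < side && ey < side &&
                occ(ex, ey) == 0) {
              opts.push_back(d);
              break;
            }
          }
        }
      }
      if (opts.empty()) continue;
      int d = opts[runif_int(static_cast<int>(opts.size()))];
      int nx = x + dx[d], ny = y + dy[d];
      if (occ(nx, ny) == 1) {
        // push the occupant into a uniformly chosen empty neighbour of its own
        std::vector<int> esc;
        for (int e = 0; e < 8; ++e) {
          int ex = nx + dx[e], ey = ny + dy[e];
          if (ex >= 0 && ey >= 0 && ex < side && ey < side && occ(ex, ey) == 0)
            esc.push_back(e);
        }
        int e = esc[runif_int(static_cast<int>(esc.size()))];
        int ex = nx + dx[e], ey = ny + dy[e];
        // find which cell sits at (nx, ny) by linear search and move it
        for (size_t c = 0; c < xs.size(); ++c) {
          if (xs[c] == nx && ys[c] == ny) {
            xs[c] = ex;
            ys[c] = ey;
            break;
          }
        }
        occ(ex, ey) = 1;
        // (nx, ny) is immediately re-filled by the daughter below
      }
      occ(nx, ny) = 1;
      xs.push_back(nx);
      ys.push_back(ny);
    }
  }
  return static_cast<int>(xs.size());
}
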