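// Lattice agent-based model of colony growth under drug.
//
// Cells live on a 2D square lattice (one cell per site). Each update round,
// cells act one by one in freshly randomized order: a cell first survives a
// death check, then divides with its current division probability provided an
// empty site is reachable -- either an empty neighbour, or an occupied
// neighbour that can be pushed one site outward into an empty site of its own
// (at most one cell separates the divider from free space). Each daughter of
// a division (both post-division cells) independently gains one
// (epi)mutational step with probability mu; step k maps to division
// probability p(k) = p_init + k * (p_max - p_init) / n_steps.
//
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct AbmParams {
  double p_init, p_max, mu, death_prob, effect_sd;
  int n_steps;
  bool bidirectional, moore;
};

AbmParams unpack_params(const List& par) {
  AbmParams p;
  p.p_init = as<double>(par["p_init"]);
  p.p_max = as<double>(par["p_max"]);
  p.n_steps = as<int>(par["n_steps"]);
  p.mu = as<double>(par["mu"]);
  p.death_prob = as<double>(par["death_prob"]);
  p.bidirectional = as<bool>(par["bidirectional"]);
  p.effect_sd = as<double>(par["effect_sd"]);
  p.moore = as<bool>(par["moore"]);
  return p;
}

// Moore offsets first 8; von Neumann = first 4 after reorder below.
const int DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
const int DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};

class Engine {
public:
  Engine(int width, int height, const AbmParams& par, bool periodic,
         bool error_on_boundary)
      : w_(width), h_(height), par_(par), periodic_(periodic),
        error_on_boundary_(error_on_boundary),
        grid_(static_cast<size_t>(width) * height, -1) {
    n_nbr_ = par_.moore ? 8 : 4;
    delta_ = par_.n_steps > 0
                 ? (par_.p_max - par_.p_init) / par_.n_steps
                 : 0.0;
    minx_ = w_;
    miny_ = h_;
    maxx_ = maxy_ = -1;
  }

  int add_cell(int x, int y, int k, double pcell) {
    int id = static_cast<int>(cx_.size());
    cx_.push_back(x);
    cy_.push_back(y);
    ck_.push_back(k);
    cp_.push_back(pcell);
    alive_.push_back(1);
    grid_[idx(x, y)] = id;
    touch(x, y);
    return id;
  }

  double p_of_step(int k) const { return par_.p_init + k * delta_; }

  // One full update round (asynchronous, randomized order).
  void step() {
    std::vector<int> order;
    order.reserve(cx_.size());
    for (size_t i = 0; i < cx_.size(); ++i)
      if (alive_[i]) order.push_back(static_cast<int>(i));
    shuffle(order);
    for (int id : order) {
      if (!alive_[id]) continue;
      if (par_.death_prob > 0 && unif_rand() < par_.death_prob) {
        kill(id);
        continue;
      }
      if (unif_rand() < cp_[id]) attempt_division(id);
    }
    ++rounds_;
  }

  int n_alive() const {
    int n = 0;
    for (size_t i = 0; i < alive_.size(); ++i) n += alive_[i];
    return n;
  }

  int bbox_side() const {
    if (maxx_ < 0) return 0;
    int sx = maxx_ - minx_ + 1, sy = maxy_ - miny_ + 1;
    return sx > sy ? sx : sy;
  }

  int rounds() const { return rounds_; }

  IntegerVector step_histogram() const {
    IntegerVector h(par_.n_steps + 1);
    for (size_t i = 0; i < ck_.size(); ++i)
      if (alive_[i]) h[ck_[i]] += 1;
    return h;
  }

  void fill_matrix(IntegerMatrix& m) const {
    for (int x = 0; x < w_; ++x)
      for (int y = 0; y < h_; ++y) {
        int id = grid_[idx(x, y)];
        m(x, y) = (id >= 0 && alive_[id]) ? ck_[id] : NA_INTEGER;
      }
  }

private:
  int w_, h_, n_nbr_, rounds_ = 0;
  AbmParams par_;
  bool periodic_, error_on_boundary_;
  double delta_;
  std::vector<int> grid_;
  std::vector<int> cx_, cy_, ck_;
  std::vector<double> cp_;
  std::vector<char> alive_;
  int minx_, maxx_, miny_, maxy_;

  size_t idx(int x, int y) const {
    return static_cast<size_t>(x) * h_ + y;
  }

  void touch(int x, int y) {
    if (x < minx_) minx_ = x;
    if (x > maxx_) maxx_ = x;
    if (y < miny_) miny_ = y;
    if (y > maxy_) maxy_ = y;
    if (error_on_boundary_ &&
        (x == 0 || y == 0 || x == w_ - 1 || y == h_ - 1))
      stop("colony reached the lattice boundary; lattice too small");
  }

  void kill(int id) {
    alive_[id] = 0;
    grid_[idx(cx_[id], cy_[id])] = -1;
  }

  // Returns false if (x,y) falls outside a non-periodic lattice.
  bool resolve(int& x, int& y) const {
    if (periodic_) {
      x = (x % w_ + w_) % w_;
      y = (y % h_ + h_) % h_;
      return true;
    }
    return x >= 0 && y >= 0 && x < w_ && y < h_;
  }

  bool is_empty(int x, int y) const {
    int xx = x, yy = y;
    if (!resolve(xx, yy)) return false;  // wall boundary counts as occupied
    return grid_[idx(xx, yy)] == -1;
  }

  void shuffle(std::vector<int>& v) const {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
  }

  void mutate(int id) {
    if (par_.mu <= 0 || unif_rand() >= par_.mu) return;
    int dir = 1;
    if (par_.bidirectional && unif_rand() < 0.5) dir = -1;
    int k = ck_[id] + dir;
    if (k < 0) k = 0;
    if (k > par_.n_steps) k = par_.n_steps;
    if (k == ck_[id]) return;
    ck_[id] = k;
    if (par_.effect_sd <= 0) {
      cp_[id] = p_of_step(k);
    } else {
      double inc = norm_rand() * par_.effect_sd * delta_ + delta_;
      if (inc < 0) inc = 0;  // fitness increments truncated at zero
      double p = cp_[id] + dir * inc;
      if (p < 0) p = 0;
      if (p > par_.p_max) p = par_.p_max;
      cp_[id] = p;
    }
  }

  void attempt_division(int id) {
    int x = cx_[id], y = cy_[id];
    // Candidate daughter sites: empty neighbours (direct) and occupied
    // neighbours with an empty escape site of their own (push).
    int cand[8];
    bool push[8];
    int ncand = 0;
    for (int d = 0; d < n_nbr_; ++d) {
      int nx = x + DX8[d], ny = y + DY8[d];
      int rx = nx, ry = ny;
      if (!resolve(rx, ry)) continue;
      if (grid_[idx(rx, ry)] == -1) {
        cand[ncand] = d;
        push[ncand] = false;
        ++ncand;
      } else {
        // occupied: pushable iff it has an empty neighbour itself
        bool ok = false;
        for (int e = 0; e < n_nbr_ && !ok; ++e)
          ok = is_empty(nx + DX8[e], ny + DY8[e]);
        if (ok) {
          cand[ncand] = d;
          push[ncand] = true;
          ++ncand;
        }
      }
    }
    if (ncand == 0) return;  // fully enclosed: division blocked
    int pick = static_cast<int>(std::floor(unif_rand() * ncand));
    if (pick >= ncand) pick = ncand - 1;
    int d = cand[pick];
    int tx = x + DX8[d], ty = y + DY8[d];
    resolve(tx, ty);
    if (push[pick]) {
      // displace the occupant one site outward into a uniformly chosen
      // empty neighbour of its own
      int esc[8], nesc = 0;
      for (int e = 0; e < n_nbr_; ++e) {
        int ex = tx + DX8[e], ey = ty + DY8[e];
        if (is_empty(ex, ey)) {
          esc[nesc++] = e;
        }
      }
      int pe = static_cast<int>(std::floor(unif_rand() * nesc));
      if (pe >= nesc) pe = nesc - 1;
      int e = esc[pe];
      int ex = tx + DX8[e], ey = ty + DY8[e];
      resolve(ex, ey);
      int occ = grid_[idx(tx, ty)];
      grid_[idx(ex, ey)] = occ;
      grid_[idx(tx, ty)] = -1;
      cx_[occ] = ex;
      cy_[occ] = ey;
      touch(ex, ey);
    }
    int child = add_cell(tx, ty, ck_[id], cp_[id]);
    // both post-division cells count as daughters for mutation
    mutate(id);
    mutate(child);
  }
};

}  // namespace

// [[Rcpp::export]]
List abm_simulate_colony_cpp(int founder_step, List par, int n_updates,
                             int lattice_side, bool record_trajectory) {
  AbmParams p = unpack_params(par);
  Engine eng(lattice_side, lattice_side, p, false, true);
  eng.add_cell(lattice_side / 2, lattice_side / 2, founder_step,
               eng.p_of_step(founder_step));
  IntegerVector traj(record_trajectory ? n_updates + 1 : 0);
  if (record_trajectory) traj[0] = 1;
  for (int t = 0; t < n_updates; ++t) {
    eng.step();
    if (eng.bbox_side() > 1 + 4 * eng.rounds())
      stop("internal error: bounding-box growth bound violated");
    if (record_trajectory) traj[t + 1] = eng.n_alive();
  }
  return List::create(_["final_size"] = eng.n_alive(),
                      _["size_trajectory"] = traj,
                      _["step_index_histogram"] = eng.step_histogram(),
                      _["bbox_side"] = eng.bbox_side());
}

// [[Rcpp::export]]
IntegerVector abm_simulate_cohort_cpp(IntegerVector founder_steps,
                                      NumericVector p_max_each, List par,
                                      int n_updates, int lattice_side) {
  int n = founder_steps.size();
  IntegerVector out(n);
  List par_i = clone(par);
  for (int i = 0; i < n; ++i) {
    par_i["p_max"] = p_max_each[i];
    AbmParams p = unpack_params(par_i);
    Engine eng(lattice_side, lattice_side, p, false, true);
    eng.add_cell(lattice_side / 2, lattice_side / 2, founder_steps[i],
                 eng.p_of_step(founder_steps[i]));
    for (int t = 0; t < n_updates; ++t) eng.step();
    if (eng.bbox_side() > 1 + 4 * n_updates)
      stop("internal error: bounding-box growth bound violated");
    out[i] = eng.n_alive();
    if (i % 256 == 0) checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix abm_step_matrix_cpp(IntegerMatrix state, List par, int n_rounds,
                                  bool periodic) {
  AbmParams p = unpack_params(par);
  int w = state.nrow(), h = state.ncol();
  Engine eng(w, h, p, periodic, false);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (state(x, y) != NA_INTEGER)
        eng.add_cell(x, y, state(x, y), eng.p_of_step(state(x, y)));
  for (int t = 0; t < n_rounds; ++t) eng.step();
  IntegerMatrix out(w, h);
  eng.fill_matrix(out);
  return out;
}
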