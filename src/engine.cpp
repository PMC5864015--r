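// Tick engine for the grazing/toxicosis agent-based model.
//
// Grid convention: matrices are indexed (row = y, col = x); cell (x, y) with
// 0 <= x < W, 0 <= y < H has its center at (x + 0.5, y + 0.5) metres.
// One cell = 1 m^2. All randomness draws from R's RNG (unif_rand/norm_rand)
// so set.seed() on the R side makes runs fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

static const double EPS_ANG = 1e-9;

struct Offsets {
  std::vector<int> dx, dy;
  std::vector<double> d;     // centre-to-centre distance
  int R;                     // integer bounding radius
};

// integer offsets with rmin <= dist <= rmax (centre-to-centre); excludes the
// origin unless rmin == 0
static Offsets make_offsets(double rmin, double rmax, bool include_origin) {
  // dx outer / dy inner: consecutive dy are contiguous in R's column-major
  // matrices, which keeps the disc sweeps cache-friendly
  Offsets o;
  int R = (int)std::ceil(rmax);
  o.R = R;
  for (int dx = -R; dx <= R; ++dx) {
    for (int dy = -R; dy <= R; ++dy) {
      if (dx == 0 && dy == 0 && !include_origin) continue;
      double d = std::sqrt((double)(dx * dx + dy * dy));
      if (d <= rmax + 1e-12 && d >= rmin - 1e-12) {
        o.dx.push_back(dx);
        o.dy.push_back(dy);
        o.d.push_back(d);
      }
    }
  }
  return o;
}

// [[Rcpp::export(name = ".neighborhood_mean_cpp")]]
NumericMatrix neighborhood_mean_cpp(NumericMatrix grid, double radius) {
  int H = grid.nrow(), W = grid.ncol();
  Offsets off = make_offsets(0.0, radius, true);
  NumericMatrix out(H, W);
  int m = off.dx.size();
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double s = 0.0;
      int c = 0;
      for (int i = 0; i < m; ++i) {
        int xx = x + off.dx[i], yy = y + off.dy[i];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
        s += grid(yy, xx);
        ++c;
      }
      out(y, x) = c > 0 ? s / c : NA_REAL;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".disc_cell_count_cpp")]]
int disc_cell_count_cpp(double radius) {
  Offsets off = make_offsets(0.0, radius, true);
  return (int)off.dx.size();
}

// shared eat rule: returns (forage intake g, msal intake mg) for one visit
static inline void eat_rule(double forage, double msal, int times_grazed,
                            double attraction, double &fi, double &mi) {
  double f = times_grazed == 0 ? 0.40 : (times_grazed == 1 ? 0.50 : 0.60);
  fi = f * forage;
  mi = f * msal * attraction;
  if (mi > msal) mi = msal;  // attraction > 1 cannot eat more than present
}

// [[Rcpp::export(name = ".eat_kernel_cpp")]]
List eat_kernel_cpp(double forage_g, double msal_mg, int times_grazed,
                    double attraction) {
  double fi, mi;
  eat_rule(forage_g, msal_mg, times_grazed, attraction, fi, mi);
  return List::create(_["forage_intake_g"] = fi, _["msal_intake_mg"] = mi);
}

// summed-area table over a W x H grid (value supplied per cell); sums of
// clipped inclusive windows in O(1)
struct SAT {
  int W = 0, H = 0;
  std::vector<double> s;
  template <class F> void build(int W_, int H_, F val) {
    W = W_;
    H = H_;
    s.assign((size_t)(W + 1) * (H + 1), 0.0);
    for (int y = 0; y < H; ++y) {
      double *row = &s[(size_t)(y + 1) * (W + 1)];
      const double *prev = &s[(size_t)y * (W + 1)];
      for (int x = 0; x < W; ++x)
        row[x + 1] = val(y, x) + prev[x + 1] + row[x] - prev[x];
    }
  }
  double sum(int x0, int y0, int x1, int y1) const {
    x0 = std::max(x0, 0);
    y0 = std::max(y0, 0);
    x1 = std::min(x1, W - 1);
    y1 = std::min(y1, H - 1);
    if (x0 > x1 || y0 > y1) return 0.0;
    return s[(size_t)(y1 + 1) * (W + 1) + x1 + 1] -
           s[(size_t)y0 * (W + 1) + x1 + 1] -
           s[(size_t)(y1 + 1) * (W + 1) + x0] + s[(size_t)y0 * (W + 1) + x0];
  }
};

// ---------------------------------------------------------------------------
// Simulation state
// ---------------------------------------------------------------------------

struct Sim {
  int W, H, n;
  NumericMatrix forage, msal, nforage;
  IntegerMatrix times;
  LogicalMatrix acc;
  IntegerMatrix occ;

  // cows
  std::vector<double> x, y, heading, tol, attr, level, hydr;
  std::vector<double> cum_cons, day_cons, day_msal, total_msal, travel_today;
  std::vector<int> role, rtg, deaths_cow;  // role: 0 leader, 1 follower, 2 indep

  // parameters
  double herd_distance, space_per_cow, hyd_cap, daily_intake, target_aums;
  double satiation_g;
  double au_per_cow, days_per_month, water_frac;
  int site_tolerance, herdmate_count, lattice_spacing;
  double site_radius;

  // water cells
  std::vector<int> wx, wy;

  // bookkeeping
  long n_acc;
  double times_sum;                 // sum of times_grazed over accessible cells
  double F0, M0, consumedF, consumedM;
  long ticks, water_visits, site_changes, herd_moves, env_moves;
  int day;
  double audit_max_relerr;
  int audit_every;
  long max_ticks;

  // logs
  std::vector<int> rec_day, rec_cow, rec_role, rec_died;
  std::vector<double> rec_msal, rec_forage;
  std::vector<int> ev_cow, ev_day, ev_role;
  std::vector<double> ev_level, ev_tol, ev_attr;
  std::vector<double> day_travel_mean, day_site_changes;
  std::vector<double> max_day_msal;
  long site_changes_at_day_start;

  Offsets disc10, ann2, ann10, ann_herd;

  bool inb(int xx, int yy) const { return xx >= 0 && xx < W && yy >= 0 && yy < H; }
  int cellx(int i) const { return (int)std::floor(x[i]); }
  int celly(int i) const { return (int)std::floor(y[i]); }

  double local_times_mean(int cx, int cy) const {
    double s = 0.0;
    long c = 0;
    int m = disc10.dx.size();
    const int *tp = INTEGER(times);
    const int *ap = LOGICAL(acc);
    if (cx >= 10 && cx < W - 10 && cy >= 10 && cy < H - 10) {
      for (int i = 0; i < m; ++i) {
        size_t k = (size_t)(cx + disc10.dx[i]) * H + (cy + disc10.dy[i]);
        if (!ap[k]) continue;
        s += tp[k];
        ++c;
      }
    } else {
      for (int i = 0; i < m; ++i) {
        int xx = cx + disc10.dx[i], yy = cy + disc10.dy[i];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H || !acc(yy, xx)) continue;
        s += times(yy, xx);
        ++c;
      }
    }
    return c > 0 ? s / c : 0.0;
  }

  double global_times_mean() const { return n_acc > 0 ? times_sum / n_acc : 0.0; }

  void shuffle(std::vector<int> &v) const {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
  }

  void move_cow(int i, int tx, int ty) {
    double nx = tx + 0.5, ny = ty + 0.5;
    double dx = nx - x[i], dy = ny - y[i];
    double d = std::sqrt(dx * dx + dy * dy);
    travel_today[i] += d;
    occ(celly(i), cellx(i)) -= 1;
    if (d > 0) heading[i] = std::atan2(dy, dx);
    x[i] = nx;
    y[i] = ny;
    occ(ty, tx) += 1;
  }

  // pick, among offset cells around (cx, cy), the accessible cell maximizing
  // forage (ties: nearest, then lowest linear index y*W + x); cone filter
  // about `bearing` with half-angle whose cosine is cos_tol (cos_tol <= -1
  // disables the cone). Returns false if no candidate.
  bool choose_cell(int cx, int cy, const Offsets &off, double bearing,
                   double cos_tol, int &bx, int &by) const {
    double ux = std::cos(bearing), uy = std::sin(bearing);
    bool found = false;
    double bestF = 0.0, bestD = 0.0;
    long bestIdx = 0;
    int m = off.dx.size();
    const int *ap = LOGICAL(acc);
    const double *fp = REAL(forage);
    bool interior =
        cx >= off.R && cx < W - off.R && cy >= off.R && cy < H - off.R;
    for (int i = 0; i < m; ++i) {
      int xx = cx + off.dx[i], yy = cy + off.dy[i];
      if (!interior && (xx < 0 || xx >= W || yy < 0 || yy >= H)) continue;
      size_t kk = (size_t)xx * H + yy;
      if (!ap[kk]) continue;
      if (cos_tol > -1.5) {
        double dot = (off.dx[i] * ux + off.dy[i] * uy) / off.d[i];
        if (dot < cos_tol - EPS_ANG) continue;
      }
      double f = fp[kk];
      long idx = (long)yy * W + xx;
      bool better;
      if (!found) better = true;
      else if (f != bestF) better = f > bestF;
      else if (off.d[i] != bestD) better = off.d[i] < bestD;
      else better = idx < bestIdx;
      if (better) {
        found = true;
        bestF = f;
        bestD = off.d[i];
        bestIdx = idx;
        bx = xx;
        by = yy;
      }
    }
    return found;
  }

  void eat(int i) {
    int cx = cellx(i), cy = celly(i);
    if (!acc(cy, cx)) return;  // defensive; cows only move to accessible cells
    // satiation: voluntary intake bound; a sated cow moves but stops grazing
    if (satiation_g > 0 && day_cons[i] >= satiation_g) return;
    double fi, mi;
    eat_rule(forage(cy, cx), msal(cy, cx), times(cy, cx), attr[i], fi, mi);
    forage(cy, cx) -= fi;
    msal(cy, cx) -= mi;
    times(cy, cx) += 1;
    times_sum += 1.0;
    consumedF += fi;
    consumedM += mi;
    cum_cons[i] += fi;
    day_cons[i] += fi;
    hydr[i] -= fi;
    level[i] += mi;
    day_msal[i] += mi;
    total_msal[i] += mi;
  }

  void go_to_water(std::vector<int> &order) {
    ++water_visits;
    if (wx.empty()) {  // degenerate pasture without water: reset in place
      for (int i = 0; i < n; ++i) hydr[i] = hyd_cap;
      for (int i = 0; i < n; ++i) if (role[i] == 0) rtg[i] = site_tolerance - 1;
      return;
    }
    int nw = wx.size();
    std::vector<int> wocc(nw, 0);
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      int best = -1, best_any = -1;
      double bd = 0.0, bd_any = 0.0;
      for (int w = 0; w < nw; ++w) {
        double dx = (wx[w] + 0.5) - x[i], dy = (wy[w] + 0.5) - y[i];
        double d = dx * dx + dy * dy;
        if (best_any < 0 || d < bd_any) { best_any = w; bd_any = d; }
        if (wocc[w] <= 2 && (best < 0 || d < bd)) { best = w; bd = d; }
      }
      if (best < 0) best = best_any;  // overflow rule: all waterers full
      wocc[best] += 1;
      move_cow(i, wx[best], wy[best]);
      hydr[i] = hyd_cap;
    }
    for (int i = 0; i < n; ++i) if (role[i] == 0) rtg[i] = site_tolerance - 1;
  }

  SAT sat_t, sat_f, sat_nf, sat_a;
  bool sat_static_built = false;

  // identify the new site centre for the deciding leader; returns false if no
  // candidate (pathological); best-five-by-score then nearest-to-leader.
  // Candidate neighborhoods are square windows of half-width = site radius
  // (summed-area tables make each window O(1)); value layers are zeroed on
  // inaccessible cells and normalized by the accessible count.
  bool select_site(int leader, int &sx, int &sy) {
    int hw = std::max(1, (int)std::lround(site_radius));
    const int *tp = INTEGER(times);
    const int *ap = LOGICAL(acc);
    const double *fp = REAL(forage);
    const double *nfp = REAL(nforage);
    int Wl = W, Hl = H;
    if (!sat_static_built) {
      sat_a.build(W, H, [&](int y, int x) {
        return ap[(size_t)x * Hl + y] ? 1.0 : 0.0;
      });
      sat_nf.build(W, H, [&](int y, int x) {
        size_t k = (size_t)x * Hl + y;
        return ap[k] ? nfp[k] : 0.0;
      });
      sat_static_built = true;
    }
    sat_t.build(W, H, [&](int y, int x) {
      size_t k = (size_t)x * Hl + y;
      return ap[k] ? (double)tp[k] : 0.0;
    });
    sat_f.build(W, H, [&](int y, int x) {
      size_t k = (size_t)x * Hl + y;
      return ap[k] ? fp[k] : 0.0;
    });
    const SAT &s_t = sat_t, &s_f = sat_f, &s_nf = sat_nf, &s_a = sat_a;

    std::vector<int> cx_, cy_;
    std::vector<double> m_t, m_f, m_nf;
    int half = lattice_spacing / 2;
    for (int yy = half; yy < H; yy += lattice_spacing)
      for (int xx = half; xx < W; xx += lattice_spacing) {
        if (!acc(yy, xx)) continue;
        double na = s_a.sum(xx - hw, yy - hw, xx + hw, yy + hw);
        if (na <= 0) continue;
        cx_.push_back(xx);
        cy_.push_back(yy);
        m_t.push_back(s_t.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
        m_f.push_back(s_f.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
        m_nf.push_back(s_nf.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
      }
    int m = cx_.size();
    if (m == 0) return false;

    // rank_high: 1..m ascending (m = best); low times is good so rank -times
    std::vector<double> score(m, 0.0);
    auto add_ranks = [&](const std::vector<double> &v, bool high_good) {
      std::vector<int> ord(m);
      std::iota(ord.begin(), ord.end(), 0);
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        double va = high_good ? v[a] : -v[a];
        double vb = high_good ? v[b] : -v[b];
        return va < vb;
      });
      for (int r = 0; r < m; ++r) score[ord[r]] += (r + 1);
    };
    add_ranks(m_t, false);
    add_ranks(m_f, true);
    add_ranks(m_nf, true);

    int keep = std::min(5, m);
    std::vector<int> ord(m);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return score[a] > score[b]; });
    // nearest of the top-`keep` to the deciding leader
    int best = -1;
    double bd = 0.0;
    for (int k = 0; k < keep; ++k) {
      int c = ord[k];
      double dx = (cx_[c] + 0.5) - x[leader], dy = (cy_[c] + 0.5) - y[leader];
      double d = dx * dx + dy * dy;
      if (best < 0 || d < bd) { best = c; bd = d; }
    }
    sx = cx_[best];
    sy = cy_[best];
    return true;
  }

  // place all cows in the new site (leaders, then followers, then
  // independents; shuffled within role)
  void change_site(int sx, int sy) {
    ++site_changes;
    // everyone leaves its current cell first
    for (int i = 0; i < n; ++i) occ(celly(i), cellx(i)) -= 1;
    std::vector<int> order;
    for (int r = 0; r < 3; ++r) {
      std::vector<int> grp;
      for (int i = 0; i < n; ++i) if (role[i] == r) grp.push_back(i);
      shuffle(grp);
      order.insert(order.end(), grp.begin(), grp.end());
    }
    // site cells
    int R = (int)std::ceil(site_radius);
    std::vector<int> scx, scy;
    std::vector<double> scd;
    for (int yy = std::max(0, sy - R); yy <= std::min(H - 1, sy + R); ++yy)
      for (int xx = std::max(0, sx - R); xx <= std::min(W - 1, sx + R); ++xx) {
        if (!acc(yy, xx)) continue;
        double dx = xx - sx, dy = yy - sy;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= site_radius + 1e-12) {
          scx.push_back(xx);
          scy.push_back(yy);
          scd.push_back(d);
        }
      }
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      int bx = -1, by = -1;
      for (int pass = 0; pass < 2 && bx < 0; ++pass) {
        bool found = false;
        double bestF = 0.0, bestD = 0.0;
        long bestIdx = 0;
        for (size_t c = 0; c < scx.size(); ++c) {
          int xx = scx[c], yy = scy[c];
          if (occ(yy, xx) > 0) continue;
          if (pass == 0) {  // strict: 4-neighborhood also free
            bool clash = false;
            const int nx4[4] = {1, -1, 0, 0}, ny4[4] = {0, 0, 1, -1};
            for (int q = 0; q < 4; ++q) {
              int ax = xx + nx4[q], ay = yy + ny4[q];
              if (inb(ax, ay) && occ(ay, ax) > 0) { clash = true; break; }
            }
            if (clash) continue;
          }
          double f = forage(yy, xx);
          long idx = (long)yy * W + xx;
          bool better;
          if (!found) better = true;
          else if (f != bestF) better = f > bestF;
          else if (scd[c] != bestD) better = scd[c] < bestD;
          else better = idx < bestIdx;
          if (better) {
            found = true;
            bestF = f;
            bestD = scd[c];
            bestIdx = idx;
            bx = xx;
            by = yy;
          }
        }
        if (found) break;
      }
      if (bx < 0) {
        // overflow: nearest free accessible cell to the site centre
        double bd = 0.0;
        for (int yy = 0; yy < H; ++yy)
          for (int xx = 0; xx < W; ++xx) {
            if (!acc(yy, xx) || occ(yy, xx) > 0) continue;
            double dx = xx - sx, dy = yy - sy;
            double d = dx * dx + dy * dy;
            if (bx < 0 || d < bd) { bx = xx; by = yy; bd = d; }
          }
        if (bx < 0) { bx = cellx(i); by = celly(i); }  // give up: stay
      }
      // manual move (occ of origin already decremented)
      double nx = bx + 0.5, ny = by + 0.5;
      double dx = nx - x[i], dy = ny - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      travel_today[i] += d;
      if (d > 0) heading[i] = std::atan2(dy, dx);
      x[i] = nx;
      y[i] = ny;
      occ(by, bx) += 1;
    }
    for (int i = 0; i < n; ++i) if (role[i] == 0) rtg[i] = 0;
  }

  // returns true if the cow moved via the herding rule
  bool assess_herd(int i) {
    if (n < 2) return false;
    int k = std::min(herdmate_count, n - 1);
    // nearest k other cows
    std::vector<std::pair<double, int> > ds;
    ds.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      ds.push_back(std::make_pair(dx * dx + dy * dy, j));
    }
    std::partial_sort(ds.begin(), ds.begin() + k, ds.end());
    double md = 0.0, cx = 0.0, cy = 0.0;
    for (int q = 0; q < k; ++q) {
      md += std::sqrt(ds[q].first);
      cx += x[ds[q].second];
      cy += y[ds[q].second];
    }
    md /= k;
    cx /= k;
    cy /= k;

    bool toward;
    if (role[i] == 2) {  // independent
      if (md > 2.5 * herd_distance) toward = true;
      else if (md < 0.5 * herd_distance) toward = false;
      else return false;
    } else {
      if (md > herd_distance) toward = true;
      else return false;
    }
    double bearing = std::atan2(cy - y[i], cx - x[i]);
    if (!toward) bearing += M_PI;
    int ccx = cellx(i), ccy = celly(i), bx, by;
    const double COS45 = 0.70710678118654752440;
    if (choose_cell(ccx, ccy, ann_herd, bearing, COS45, bx, by) ||
        choose_cell(ccx, ccy, ann_herd, bearing, 0.0, bx, by)) {
      move_cow(i, bx, by);
      return true;
    }
    // fall back: nearest accessible cell toward the target point 10 m out
    double txf = x[i] + 10.0 * std::cos(bearing);
    double tyf = y[i] + 10.0 * std::sin(bearing);
    int tx = std::min(W - 1, std::max(0, (int)std::floor(txf)));
    int ty = std::min(H - 1, std::max(0, (int)std::floor(tyf)));
    int fx = -1, fy = -1;
    double bd = 0.0;
    for (int yy = 0; yy < H; ++yy)
      for (int xx = 0; xx < W; ++xx) {
        if (!acc(yy, xx)) continue;
        double ddx = xx - tx, ddy = yy - ty;
        double d = ddx * ddx + ddy * ddy;
        if (fx < 0 || d < bd) { fx = xx; fy = yy; bd = d; }
      }
    if (fx >= 0 && !(fx == ccx && fy == ccy)) {
      move_cow(i, fx, fy);
      return true;
    }
    return false;
  }

  void environmental_move(int i) {
    int ccx = cellx(i), ccy = celly(i);
    double local = local_times_mean(ccx, ccy);
    const Offsets &off = local < 0.5 ? ann2 : ann10;
    const double COS45 = 0.70710678118654752440;
    int bx, by;
    if (choose_cell(ccx, ccy, off, heading[i], COS45, bx, by) ||
        choose_cell(ccx, ccy, off, heading[i], 0.0, bx, by) ||
        choose_cell(ccx, ccy, off, 0.0, -2.0, bx, by)) {
      move_cow(i, bx, by);
    }
    // tiny/fenced-in grids can have no candidate at all: stay put
  }

  void end_of_day(bool record) {
    double mean_travel = 0.0;
    for (int i = 0; i < n; ++i) {
      int died = level[i] > tol[i] ? 1 : 0;
      if (record) {
        rec_day.push_back(day);
        rec_cow.push_back(i + 1);
        rec_role.push_back(role[i]);
        rec_msal.push_back(day_msal[i]);
        rec_forage.push_back(day_cons[i]);
        rec_died.push_back(died);
      }
      if (day_msal[i] > max_day_msal[i]) max_day_msal[i] = day_msal[i];
      if (died) {
        deaths_cow[i] += 1;
        ev_cow.push_back(i + 1);
        ev_day.push_back(day);
        ev_role.push_back(role[i]);
        ev_level.push_back(level[i]);
        ev_tol.push_back(tol[i]);
        ev_attr.push_back(attr[i]);
        level[i] = 0.0;
      }
      level[i] *= 0.5;
      day_msal[i] = 0.0;
      day_cons[i] = 0.0;
      mean_travel += travel_today[i];
      travel_today[i] = 0.0;
    }
    day_travel_mean.push_back(mean_travel / n);
    day_site_changes.push_back((double)(site_changes - site_changes_at_day_start));
    site_changes_at_day_start = site_changes;
    ++day;
  }
};

// [[Rcpp::export(name = ".run_sim_cpp")]]
List run_sim_cpp(NumericMatrix forage, NumericMatrix msal,
                 NumericMatrix nforage, IntegerMatrix times,
                 LogicalMatrix accessible, LogicalMatrix water,
                 DataFrame herd, List par) {
  Sim S;
  S.forage = clone(forage);
  S.msal = clone(msal);
  S.nforage = nforage;
  S.times = clone(times);
  S.acc = accessible;
  S.H = forage.nrow();
  S.W = forage.ncol();
  S.occ = IntegerMatrix(S.H, S.W);

  NumericVector hx = herd["x"], hy = herd["y"], hh = herd["heading"];
  NumericVector htol = herd["msal_tolerance"], hattr = herd["larkspur_attraction"];
  IntegerVector hrole = herd["role_code"];
  NumericVector hlev = herd["msal_level"], hhyd = herd["hydration"];
  S.n = hx.size();
  for (int i = 0; i < S.n; ++i) {
    S.x.push_back(hx[i]);
    S.y.push_back(hy[i]);
    S.heading.push_back(hh[i]);
    S.tol.push_back(htol[i]);
    S.attr.push_back(hattr[i]);
    S.level.push_back(hlev[i]);
    S.hydr.push_back(hhyd[i]);
    S.role.push_back(hrole[i]);
    S.rtg.push_back(0);
    S.deaths_cow.push_back(0);
    S.cum_cons.push_back(0.0);
    S.day_cons.push_back(0.0);
    S.day_msal.push_back(0.0);
    S.total_msal.push_back(0.0);
    S.travel_today.push_back(0.0);
    S.max_day_msal.push_back(0.0);
    S.occ(S.celly(i), S.cellx(i)) += 1;
  }

  S.herd_distance = as<double>(par["herd_distance_m"]);
  S.space_per_cow = as<double>(par["space_per_cow_m2"]);
  S.site_tolerance = as<int>(par["site_tolerance"]);
  S.hyd_cap = as<double>(par["hydration_capacity_g"]);
  S.daily_intake = as<double>(par["daily_intake_g"]);
  S.satiation_g = as<double>(par["satiation_g"]);
  S.target_aums = as<double>(par["target_aums"]);
  S.au_per_cow = as<double>(par["au_per_cow"]);
  S.days_per_month = as<double>(par["days_per_month"]);
  S.water_frac = as<double>(par["water_threshold_frac"]);
  S.herdmate_count = as<int>(par["herdmate_count"]);
  S.lattice_spacing = as<int>(par["lattice_spacing_m"]);
  S.audit_every = as<int>(par["audit_every"]);
  S.max_ticks = (long)as<double>(par["max_ticks"]);
  bool record = as<bool>(par["record_daily"]);
  S.site_radius = std::sqrt(S.n * S.space_per_cow / M_PI);

  S.n_acc = 0;
  S.times_sum = 0.0;
  S.F0 = 0.0;
  S.M0 = 0.0;
  for (int yy = 0; yy < S.H; ++yy)
    for (int xx = 0; xx < S.W; ++xx) {
      if (S.acc(yy, xx)) {
        ++S.n_acc;
        S.times_sum += S.times(yy, xx);
        if (water(yy, xx)) {
          S.wx.push_back(xx);
          S.wy.push_back(yy);
        }
      }
      S.F0 += S.forage(yy, xx);
      S.M0 += S.msal(yy, xx);
    }

  S.consumedF = 0.0;
  S.consumedM = 0.0;
  S.ticks = 0;
  S.water_visits = 0;
  S.site_changes = 0;
  S.herd_moves = 0;
  S.env_moves = 0;
  S.day = 0;
  S.audit_max_relerr = 0.0;
  S.site_changes_at_day_start = 0;

  S.disc10 = make_offsets(0.0, 10.0, true);
  S.ann2 = make_offsets(1.0, 2.0, false);
  S.ann10 = make_offsets(1.0, 10.0, false);
  S.ann_herd = make_offsets(10.0, 25.0, false);

  std::string status = "completed";
  long hard_cap = 100000000L;
  long starved_ticks = 0;  // consecutive ticks with ~zero herd intake
  std::vector<int> order(S.n);
  std::iota(order.begin(), order.end(), 0);

  while (true) {
    if (S.max_ticks > 0 && S.ticks >= S.max_ticks) { status = "max_ticks"; break; }
    if (S.ticks >= hard_cap) { status = "tick_limit"; break; }
    ++S.ticks;
    S.shuffle(order);

    // 1. hydration check (leaders)
    bool water_tick = false;
    for (int k = 0; k < S.n && !water_tick; ++k) {
      int i = order[k];
      if (S.role[i] == 0 && S.hydr[i] <= 0.0) water_tick = true;
    }

    // 2. site-change check (leaders, first trigger wins)
    bool site_tick = false;
    int site_x = 0, site_y = 0;
    if (!water_tick) {
      double gmean = S.global_times_mean();
      for (int k = 0; k < S.n; ++k) {
        int i = order[k];
        if (S.role[i] != 0) continue;
        double local = S.local_times_mean(S.cellx(i), S.celly(i));
        if (local > 0.5 * gmean + 1.2) S.rtg[i] += 1;
        if (S.rtg[i] >= S.site_tolerance) {
          if (S.hydr[i] < S.water_frac * S.hyd_cap) {
            water_tick = true;
          } else if (S.select_site(i, site_x, site_y)) {
            site_tick = true;
          }
          break;
        }
      }
    }

    if (water_tick) {
      S.go_to_water(order);
    } else if (site_tick) {
      S.change_site(site_x, site_y);
    } else {
      // 3. movement + eat
      double tick_intake_before = S.consumedF;
      for (int k = 0; k < S.n; ++k) {
        int i = order[k];
        if (S.assess_herd(i)) ++S.herd_moves;
        else { S.environmental_move(i); ++S.env_moves; }
        S.eat(i);
      }
      // a single near-zero tick can be one laggard cow crossing a
      // ground-down area while its sated herdmates skip grazing; only a
      // sustained stretch means the pasture cannot support the herd
      if (S.consumedF - tick_intake_before < 1e-9) {
        if (++starved_ticks >= 5000) {
          status = "forage_exhausted";
          break;
        }
      } else {
        starved_ticks = 0;
      }
      // 4. grazing-day check
      double mean_day = 0.0;
      for (int i = 0; i < S.n; ++i) mean_day += S.day_cons[i];
      mean_day /= S.n;
      if (mean_day >= S.daily_intake) {
        S.end_of_day(record);
        double aums = (double)S.day * S.n * S.au_per_cow / S.days_per_month;
        if (aums >= S.target_aums - 1e-9) break;
      }
    }

    if (S.audit_every > 0 && (S.ticks % S.audit_every) == 0) {
      double Fc = 0.0, Mc = 0.0;
      for (int yy = 0; yy < S.H; ++yy)
        for (int xx = 0; xx < S.W; ++xx) {
          Fc += S.forage(yy, xx);
          Mc += S.msal(yy, xx);
        }
      double ef = std::fabs((S.F0 - Fc) - S.consumedF) / std::max(S.F0, 1.0);
      double em = std::fabs((S.M0 - Mc) - S.consumedM) / std::max(S.M0, 1.0);
      if (ef > S.audit_max_relerr) S.audit_max_relerr = ef;
      if (em > S.audit_max_relerr) S.audit_max_relerr = em;
    }
  }

  int total_deaths = 0, d_lead = 0, d_fol = 0, d_ind = 0;
  for (size_t e = 0; e < S.ev_role.size(); ++e) {
    ++total_deaths;
    if (S.ev_role[e] == 0) ++d_lead;
    else if (S.ev_role[e] == 1) ++d_fol;
    else ++d_ind;
  }

  return List::create(
      _["status"] = status,
      _["ticks"] = (double)S.ticks,
      _["grazing_days"] = S.day,
      _["deaths"] = total_deaths,
      _["deaths_by_role"] =
          IntegerVector::create(_["leader"] = d_lead, _["follower"] = d_fol,
                                _["independent"] = d_ind),
      _["water_visits"] = (double)S.water_visits,
      _["site_changes"] = (double)S.site_changes,
      _["herd_moves"] = (double)S.herd_moves,
      _["env_moves"] = (double)S.env_moves,
      _["consumed_forage_g"] = S.consumedF,
      _["consumed_msal_mg"] = S.consumedM,
      _["initial_forage_g"] = S.F0,
      _["initial_msal_mg"] = S.M0,
      _["audit_max_relerr"] = S.audit_max_relerr,
      _["day_travel_mean_m"] = wrap(S.day_travel_mean),
      _["day_site_changes"] = wrap(S.day_site_changes),
      _["cow"] = DataFrame::create(
          _["id"] = seq_len(S.n), _["role_code"] = wrap(S.role),
          _["x"] = wrap(S.x), _["y"] = wrap(S.y),
          _["msal_level_mg"] = wrap(S.level),
          _["msal_tolerance_mg"] = wrap(S.tol),
          _["larkspur_attraction"] = wrap(S.attr),
          _["cumulative_consumption_g"] = wrap(S.cum_cons),
          _["total_msal_mg"] = wrap(S.total_msal),
          _["max_day_msal_mg"] = wrap(S.max_day_msal),
          _["deaths"] = wrap(S.deaths_cow)),
      _["daily"] = DataFrame::create(
          _["grazing_day"] = wrap(S.rec_day), _["cow"] = wrap(S.rec_cow),
          _["role_code"] = wrap(S.rec_role),
          _["daily_msal_mg"] = wrap(S.rec_msal),
          _["daily_forage_g"] = wrap(S.rec_forage),
          _["died"] = wrap(S.rec_died)),
      _["death_events"] = DataFrame::create(
          _["cow"] = wrap(S.ev_cow), _["grazing_day"] = wrap(S.ev_day),
          _["role_code"] = wrap(S.ev_role),
          _["msal_level_mg"] = wrap(S.ev_level),
          _["msal_tolerance_mg"] = wrap(S.ev_tol),
          _["larkspur_attraction"] = wrap(S.ev_attr)),
      _["forage_g"] = S.forage, _["msal_mg"] = S.msal,
      _["times_grazed"] = S.times);
}

// standalone site-placement routine sharing the change-site rules, for
// direct testing: returns placement (x, y) per cow in placement order
// [[Rcpp::export(name = ".site_placement_cpp")]]
DataFrame site_placement_cpp(NumericMatrix forage, LogicalMatrix accessible,
                             int center_x, int center_y, double radius,
                             IntegerVector role_code) {
  int H = forage.nrow(), W = forage.ncol();
  int n = role_code.size();
  IntegerMatrix occ(H, W);
  std::vector<int> px(n, -1), py(n, -1), ord;
  for (int r = 0; r < 3; ++r)
    for (int i = 0; i < n; ++i) if (role_code[i] == r) ord.push_back(i);
  int R = (int)std::ceil(radius);
  for (size_t k = 0; k < ord.size(); ++k) {
    int i = ord[k];
    int bx = -1, by = -1;
    for (int pass = 0; pass < 2 && bx < 0; ++pass) {
      bool found = false;
      double bestF = 0.0, bestD = 0.0;
      long bestIdx = 0;
      for (int yy = std::max(0, center_y - R); yy <= std::min(H - 1, center_y + R); ++yy)
        for (int xx = std::max(0, center_x - R); xx <= std::min(W - 1, center_x + R); ++xx) {
          if (!accessible(yy, xx) || occ(yy, xx) > 0) continue;
          double ddx = xx - center_x, ddy = yy - center_y;
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d > radius + 1e-12) continue;
          if (pass == 0) {
            bool clash = false;
            const int nx4[4] = {1, -1, 0, 0}, ny4[4] = {0, 0, 1, -1};
            for (int q = 0; q < 4; ++q) {
              int ax = xx + nx4[q], ay = yy + ny4[q];
              if (ax >= 0 && ax < W && ay >= 0 && ay < H && occ(ay, ax) > 0) {
                clash = true;
                break;
              }
            }
            if (clash) continue;
          }
          double f = forage(yy, xx);
          long idx = (long)yy * W + xx;
          bool better;
          if (!found) better = true;
          else if (f != bestF) better = f > bestF;
          else if (d != bestD) better = d < bestD;
          else better = idx < bestIdx;
          if (better) {
            found = true;
            bestF = f;
            bestD = d;
            bestIdx = idx;
            bx = xx;
            by = yy;
          }
        }
      if (found) break;
    }
    if (bx < 0) {  // nearest free accessible cell anywhere
      double bd = 0.0;
      for (int yy = 0; yy < H; ++yy)
        for (int xx = 0; xx < W; ++xx) {
          if (!accessible(yy, xx) || occ(yy, xx) > 0) continue;
          double ddx = xx - center_x, ddy = yy - center_y;
          double d = ddx * ddx + ddy * ddy;
          if (bx < 0 || d < bd) { bx = xx; by = yy; bd = d; }
        }
    }
    px[i] = bx;
    py[i] = by;
    if (bx >= 0) occ(by, bx) += 1;
  }
  return DataFrame::create(_["cow"] = seq_len(n), _["x"] = wrap(px),
                           _["y"] = wrap(py));
}

// candidate-site scores on the evaluation lattice, for oracle testing
// [[Rcpp::export(name = ".rank_sites_cpp")]]
DataFrame rank_sites_cpp(NumericMatrix forage, NumericMatrix nforage,
                         IntegerMatrix times, LogicalMatrix accessible,
                         double radius, int lattice_spacing) {
  Sim S;
  S.forage = forage;
  S.nforage = nforage;
  S.times = times;
  S.acc = accessible;
  S.H = forage.nrow();
  S.W = forage.ncol();
  S.site_radius = radius;
  S.lattice_spacing = lattice_spacing;

  int hw = std::max(1, (int)std::lround(radius));
  SAT s_t, s_f, s_nf, s_a;
  s_a.build(S.W, S.H, [&](int y, int x) {
    return accessible(y, x) ? 1.0 : 0.0;
  });
  s_nf.build(S.W, S.H, [&](int y, int x) {
    return accessible(y, x) ? nforage(y, x) : 0.0;
  });
  s_t.build(S.W, S.H, [&](int y, int x) {
    return accessible(y, x) ? (double)times(y, x) : 0.0;
  });
  s_f.build(S.W, S.H, [&](int y, int x) {
    return accessible(y, x) ? forage(y, x) : 0.0;
  });

  std::vector<int> cx_, cy_;
  std::vector<double> m_t, m_f, m_nf;
  int half = lattice_spacing / 2;
  for (int yy = half; yy < S.H; yy += lattice_spacing)
    for (int xx = half; xx < S.W; xx += lattice_spacing) {
      if (!accessible(yy, xx)) continue;
      double na = s_a.sum(xx - hw, yy - hw, xx + hw, yy + hw);
      if (na <= 0) continue;
      cx_.push_back(xx);
      cy_.push_back(yy);
      m_t.push_back(s_t.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
      m_f.push_back(s_f.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
      m_nf.push_back(s_nf.sum(xx - hw, yy - hw, xx + hw, yy + hw) / na);
    }
  int m = cx_.size();
  std::vector<double> score(m, 0.0);
  auto add_ranks = [&](const std::vector<double> &v, bool high_good) {
    std::vector<int> ord(m);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      double va = high_good ? v[a] : -v[a];
      double vb = high_good ? v[b] : -v[b];
      return va < vb;
    });
    for (int r = 0; r < m; ++r) score[ord[r]] += (r + 1);
  };
  add_ranks(m_t, false);
  add_ranks(m_f, true);
  add_ranks(m_nf, true);
  return DataFrame::create(_["x"] = wrap(cx_), _["y"] = wrap(cy_),
                           _["mean_times"] = wrap(m_t),
                           _["mean_forage"] = wrap(m_f),
                           _["mean_n_forage"] = wrap(m_nf),
                           _["score"] = wrap(score));
}
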