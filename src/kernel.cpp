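// Overdamped Langevin propagator for 2D membrane particles among fences.
//
// Per step and particle the proposed displacement is
//   d = sqrt(2 D0 dt) * xi + (dt / gamma) * F
// with F the sum of linear pair repulsions (mobile particles and pickets),
// the triangular fence-potential force, and the drift term gamma * v_drift.
// For probabilistic fences the whole proposal is accepted or rejected by
// one uniform draw per crossed fence. Boundaries wrap (periodic) or
// reflect (repulsive). Randomness comes from R's RNG (norm_rand /
// unif_rand) so R-level set.seed() governs reproducibility; the draw order
// is fixed: all xi pairs in particle order, then crossing draws in
// particle order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <climits>

using namespace Rcpp;

static const double KB_AJ = 1.380649e-5; // aJ / K

// ---------------------------------------------------------------- geometry

// Intersection parameter t of path p -> p+d with segment a-b, or -1.
// Inclusive bounds: endpoint and vertex hits count as crossings.
static double path_segment_t(double px, double py, double dx, double dy,
                             double ax, double ay, double bx, double by) {
  const double ex = bx - ax, ey = by - ay;
  const double den = dx * ey - dy * ex;
  if (std::fabs(den) < 1e-14) return -1.0;
  const double t = ((ax - px) * ey - (ay - py) * ex) / den;
  const double u = ((ax - px) * dy - (ay - py) * dx) / den;
  if (t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0) return t;
  return -1.0;
}

// Distance from point to segment; (ox,oy) receives point - foot.
static double point_segment_dist(double px, double py,
                                 double ax, double ay, double bx, double by,
                                 double &ox, double &oy) {
  const double ex = bx - ax, ey = by - ay;
  const double L2 = ex * ex + ey * ey;
  double t = ((px - ax) * ex + (py - ay) * ey) / L2;
  t = std::min(1.0, std::max(0.0, t));
  const double qx = ax + t * ex, qy = ay + t * ey;
  ox = px - qx;
  oy = py - qy;
  return std::sqrt(ox * ox + oy * oy);
}

// --------------------------------------------------- static bbox item grid

// Uniform grid over a fixed rectangle; items are inserted into every cell
// their bounding box overlaps, so querying the cells overlapped by a query
// bbox yields a superset of all intersecting items.
struct StaticGrid {
  double ox, oy, hx, hy;
  int nx, ny;
  std::vector<std::vector<int> > cells;

  void init(double ox_, double oy_, double w, double h, double target_cell) {
    ox = ox_; oy = oy_;
    nx = std::max(1, (int)std::floor(w / target_cell));
    ny = std::max(1, (int)std::floor(h / target_cell));
    nx = std::min(nx, 512); ny = std::min(ny, 512);
    hx = w / nx; hy = h / ny;
    cells.assign((size_t)nx * ny, std::vector<int>());
  }
  int cx(double x) const {
    int c = (int)std::floor((x - ox) / hx);
    return std::min(std::max(c, 0), nx - 1);
  }
  int cy(double y) const {
    int c = (int)std::floor((y - oy) / hy);
    return std::min(std::max(c, 0), ny - 1);
  }
  void insert(int id, double x1, double y1, double x2, double y2) {
    const int a = cx(std::min(x1, x2)), b = cx(std::max(x1, x2));
    const int c = cy(std::min(y1, y2)), d = cy(std::max(y1, y2));
    for (int i = a; i <= b; ++i)
      for (int j = c; j <= d; ++j)
        cells[(size_t)i * ny + j].push_back(id);
  }
  void query(double x1, double y1, double x2, double y2,
             std::vector<int> &out, std::vector<int> &stamp, int tick) const {
    const int a = cx(std::min(x1, x2)), b = cx(std::max(x1, x2));
    const int c = cy(std::min(y1, y2)), d = cy(std::max(y1, y2));
    out.clear();
    for (int i = a; i <= b; ++i)
      for (int j = c; j <= d; ++j) {
        const std::vector<int> &v = cells[(size_t)i * ny + j];
        for (size_t k = 0; k < v.size(); ++k) {
          if (stamp[v[k]] != tick) {
            stamp[v[k]] = tick;
            out.push_back(v[k]);
          }
        }
      }
  }
};

// ----------------------------------------------------------------- kernel

// [[Rcpp::export]]
List run_kernel(NumericMatrix pos0, NumericVector radius, NumericVector D0,
                double dt, int nsteps, int sample_every,
                double W, double H, bool perx, bool pery,
                double Tk, double kpair, double vdx, double vdy,
                int fence_model, // 0 none, 1 probabilistic, 2 potential, 3 picket
                double p_hop, double k_fence, double x0,
                NumericMatrix segs, IntegerVector seg_canon,
                NumericMatrix pickets, double picket_r,
                int neighbor_mode, // 0 auto, 1 brute, 2 voxel
                IntegerMatrix images0) {
  const int n = pos0.nrow();
  const int nseg = segs.nrow();
  const int npick = pickets.nrow();
  if (nsteps % sample_every != 0)
    stop("nsteps must be a multiple of sample_every");
  const int nframes = nsteps / sample_every + 1;

  std::vector<double> x(n), y(n), ux(n), uy(n), gam(n), sig(n);
  std::vector<int> imx(n), imy(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    imx[i] = images0(i, 0); imy[i] = images0(i, 1);
    ux[i] = x[i] + imx[i] * W; uy[i] = y[i] + imy[i] * H;
    gam[i] = KB_AJ * Tk / D0[i];
    sig[i] = std::sqrt(2.0 * D0[i] * dt);
    rmax = std::max(rmax, (double)radius[i]);
  }

  // --- static grids for fences and pickets (tiled items, plain geometry)
  const double gx0 = perx ? -W : 0.0, gy0 = pery ? -H : 0.0;
  const double gw = perx ? 3.0 * W : W, gh = pery ? 3.0 * H : H;
  StaticGrid seg_grid;
  std::vector<int> seg_stamp;
  int ncanon = 0;
  if (nseg > 0) {
    for (int i = 0; i < nseg; ++i) ncanon = std::max(ncanon, seg_canon[i] + 1);
    seg_grid.init(gx0, gy0, gw, gh, std::max(2.0, std::min(gw, gh) / 64.0));
    for (int i = 0; i < nseg; ++i)
      seg_grid.insert(i, segs(i, 0), segs(i, 1), segs(i, 2), segs(i, 3));
    seg_stamp.assign(nseg, -1);
  }
  StaticGrid pick_grid;
  std::vector<int> pick_stamp;
  const double prange = picket_r + rmax;
  if (npick > 0) {
    pick_grid.init(gx0, gy0, gw, gh, std::max(2.0 * prange, std::min(gw, gh) / 128.0));
    for (int i = 0; i < npick; ++i)
      pick_grid.insert(i, pickets(i, 0), pickets(i, 1), pickets(i, 0), pickets(i, 1));
    pick_stamp.assign(npick, -1);
  }

  // --- dynamic particle cell list
  bool use_voxel;
  if (neighbor_mode == 1) use_voxel = false;
  else if (neighbor_mode == 2) use_voxel = true;
  else use_voxel = (n >= 16);
  const double pr = std::max(2.0 * rmax, 1e-6);
  int pnx = std::max(1, (int)std::floor(W / pr));
  int pny = std::max(1, (int)std::floor(H / pr));
  pnx = std::min(pnx, 1024); pny = std::min(pny, 1024);
  const double phx = W / pnx, phy = H / pny;
  std::vector<std::vector<int> > pcells;
  if (use_voxel) pcells.assign((size_t)pnx * pny, std::vector<int>());

  // scratch
  std::vector<double> fx(n), fy(n), px_(n), py_(n), xi_x(n), xi_y(n);
  std::vector<int> cand;
  std::vector<int> canon_stamp(ncanon > 0 ? ncanon : 1, -1);
  std::vector<double> canon_best(ncanon > 0 ? ncanon : 1, 0.0);
  std::vector<double> canon_vx(ncanon > 0 ? ncanon : 1, 0.0);
  std::vector<double> canon_vy(ncanon > 0 ? ncanon : 1, 0.0);
  std::vector<int> canon_seen;
  std::vector<std::pair<double, int> > cross_t;
  int tick = 0;

  NumericVector traj(Dimension(nframes, 2, n));
  long long multi_cross = 0, reflections = 0, rejected = 0;

  const double halfW = W / 2.0, halfH = H / 2.0;

  // record frame 0
  for (int i = 0; i < n; ++i) {
    traj[0 + nframes * (0 + 2 * i)] = ux[i];
    traj[0 + nframes * (1 + 2 * i)] = uy[i];
  }

  for (int s = 1; s <= nsteps; ++s) {
    // 1. diffusion draws, in particle order
    for (int i = 0; i < n; ++i) {
      xi_x[i] = norm_rand();
      xi_y[i] = norm_rand();
    }

    // 2. forces from the start-of-step state
    if (use_voxel) {
      for (size_t c = 0; c < pcells.size(); ++c) pcells[c].clear();
      for (int i = 0; i < n; ++i) {
        int cx = std::min(pnx - 1, std::max(0, (int)std::floor(x[i] / phx)));
        int cy = std::min(pny - 1, std::max(0, (int)std::floor(y[i] / phy)));
        pcells[(size_t)cx * pny + cy].push_back(i);
      }
    }
    for (int i = 0; i < n; ++i) {
      double Fx = 0.0, Fy = 0.0;
      const double ri = radius[i];
      // pair forces with mobile particles, accumulated in ascending j order
      if (!use_voxel) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          if (perx) dx -= std::round(dx / W) * W;
          if (pery) dy -= std::round(dy / H) * H;
          const double rsum = ri + radius[j];
          const double d2 = dx * dx + dy * dy;
          if (d2 < rsum * rsum) {
            const double d = std::sqrt(d2);
            if (d <= 0.0) stop("coincident particles at step %d", s);
            const double mag = kpair * (rsum - d);
            Fx -= mag * dx / d;
            Fy -= mag * dy / d;
          }
        }
      } else {
        cand.clear();
        int cx = std::min(pnx - 1, std::max(0, (int)std::floor(x[i] / phx)));
        int cy = std::min(pny - 1, std::max(0, (int)std::floor(y[i] / phy)));
        // distinct neighbour columns/rows (wrapping can alias on tiny grids)
        int colv[3], ncol = 0, rowv[3], nrow_ = 0;
        for (int dcx = -1; dcx <= 1; ++dcx) {
          int ccx = cx + dcx;
          if (perx) ccx = (ccx + pnx) % pnx;
          if (ccx < 0 || ccx >= pnx) continue;
          bool dup = false;
          for (int q = 0; q < ncol; ++q) if (colv[q] == ccx) dup = true;
          if (!dup) colv[ncol++] = ccx;
        }
        for (int dcy = -1; dcy <= 1; ++dcy) {
          int ccy = cy + dcy;
          if (pery) ccy = (ccy + pny) % pny;
          if (ccy < 0 || ccy >= pny) continue;
          bool dup = false;
          for (int q = 0; q < nrow_; ++q) if (rowv[q] == ccy) dup = true;
          if (!dup) rowv[nrow_++] = ccy;
        }
        for (int a = 0; a < ncol; ++a)
          for (int b = 0; b < nrow_; ++b) {
            const std::vector<int> &v = pcells[(size_t)colv[a] * pny + rowv[b]];
            cand.insert(cand.end(), v.begin(), v.end());
          }
        std::sort(cand.begin(), cand.end());
        for (size_t k = 0; k < cand.size(); ++k) {
          const int j = cand[k];
          if (j == i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          if (perx) dx -= std::round(dx / W) * W;
          if (pery) dy -= std::round(dy / H) * H;
          const double rsum = ri + radius[j];
          const double d2 = dx * dx + dy * dy;
          if (d2 < rsum * rsum) {
            const double d = std::sqrt(d2);
            if (d <= 0.0) stop("coincident particles at step %d", s);
            const double mag = kpair * (rsum - d);
            Fx -= mag * dx / d;
            Fy -= mag * dy / d;
          }
        }
      }
      // picket repulsion (tiled pickets, plain distances), ascending id
      if (npick > 0) {
        ++tick;
        const double rr = ri + picket_r;
        pick_grid.query(x[i] - rr, y[i] - rr, x[i] + rr, y[i] + rr,
                        cand, pick_stamp, tick);
        std::sort(cand.begin(), cand.end());
        for (size_t k = 0; k < cand.size(); ++k) {
          const int j = cand[k];
          const double dx = pickets(j, 0) - x[i], dy = pickets(j, 1) - y[i];
          const double d2 = dx * dx + dy * dy;
          if (d2 < rr * rr) {
            const double d = std::sqrt(d2);
            if (d <= 0.0) stop("particle coincides with picket at step %d", s);
            const double mag = kpair * (rr - d);
            Fx -= mag * dx / d;
            Fy -= mag * dy / d;
          }
        }
      }
      // triangular fence potential: per canonical fence the nearest image;
      // direction = vector sum of candidates, magnitude = strongest one
      if (fence_model == 2 && nseg > 0) {
        ++tick;
        seg_grid.query(x[i] - x0, y[i] - x0, x[i] + x0, y[i] + x0,
                       cand, seg_stamp, tick);
        canon_seen.clear();
        for (size_t k = 0; k < cand.size(); ++k) {
          const int j = cand[k];
          double ox_, oy_;
          const double d = point_segment_dist(x[i], y[i], segs(j, 0), segs(j, 1),
                                              segs(j, 2), segs(j, 3), ox_, oy_);
          const int c = seg_canon[j];
          if (canon_stamp[c] != tick) {
            canon_stamp[c] = tick;
            canon_best[c] = d;
            canon_vx[c] = ox_; canon_vy[c] = oy_;
            canon_seen.push_back(c);
          } else if (d < canon_best[c]) {
            canon_best[c] = d;
            canon_vx[c] = ox_; canon_vy[c] = oy_;
          }
        }
        double sx = 0.0, sy = 0.0;
        bool any = false;
        const double mag = k_fence / x0;
        for (size_t k = 0; k < canon_seen.size(); ++k) {
          const int c = canon_seen[k];
          if (canon_best[c] < x0 && canon_best[c] > 0.0) {
            sx += canon_vx[c] / canon_best[c] * mag;
            sy += canon_vy[c] / canon_best[c] * mag;
            any = true;
          }
        }
        if (any) {
          const double nv = std::sqrt(sx * sx + sy * sy);
          if (nv > 0.0) {
            Fx += sx / nv * mag;
            Fy += sy / nv * mag;
          }
        }
      }
      // drift
      Fx += gam[i] * vdx;
      Fy += gam[i] * vdy;
      fx[i] = Fx; fy[i] = Fy;
    }

    // 3. proposals
    for (int i = 0; i < n; ++i) {
      px_[i] = sig[i] * xi_x[i] + dt / gam[i] * fx[i];
      py_[i] = sig[i] * xi_y[i] + dt / gam[i] * fy[i];
      if ((perx && std::fabs(px_[i]) > halfW) ||
          (pery && std::fabs(py_[i]) > halfH))
        stop("step too large: displacement exceeds half a periodic axis (step %d, particle %d)",
             s, i + 1);
    }

    // 4. probabilistic crossing test, draws in particle then path order
    for (int i = 0; i < n; ++i) {
      bool accept = true;
      if (fence_model == 1 && nseg > 0) {
        ++tick;
        const double qx1 = std::min(x[i], x[i] + px_[i]);
        const double qx2 = std::max(x[i], x[i] + px_[i]);
        const double qy1 = std::min(y[i], y[i] + py_[i]);
        const double qy2 = std::max(y[i], y[i] + py_[i]);
        seg_grid.query(qx1, qy1, qx2, qy2, cand, seg_stamp, tick);
        canon_seen.clear();
        for (size_t k = 0; k < cand.size(); ++k) {
          const int j = cand[k];
          const double t = path_segment_t(x[i], y[i], px_[i], py_[i],
                                          segs(j, 0), segs(j, 1),
                                          segs(j, 2), segs(j, 3));
          if (t >= 0.0) {
            const int c = seg_canon[j];
            if (canon_stamp[c] != tick) {
              canon_stamp[c] = tick;
              canon_best[c] = t;
              canon_seen.push_back(c);
            } else if (t < canon_best[c]) {
              canon_best[c] = t;
            }
          }
        }
        const int m = (int)canon_seen.size();
        if (m > 1) ++multi_cross;
        if (m > 0) {
          cross_t.clear();
          for (int k = 0; k < m; ++k)
            cross_t.push_back(std::make_pair(canon_best[canon_seen[k]],
                                             canon_seen[k]));
          std::sort(cross_t.begin(), cross_t.end());
          for (int k = 0; k < m; ++k) {  // consume all draws
            const double u = unif_rand();
            if (u >= p_hop) accept = false;
          }
        }
      }
      if (!accept) {
        ++rejected;
        continue;
      }
      // 5. apply displacement + boundary conditions
      double nxp = x[i] + px_[i];
      double nyp = y[i] + py_[i];
      ux[i] += px_[i];
      uy[i] += py_[i];
      if (perx) {
        while (nxp < 0) { nxp += W; --imx[i]; }
        while (nxp >= W) { nxp -= W; ++imx[i]; }
      } else {
        while (nxp < 0 || nxp > W) {
          if (nxp < 0) nxp = -nxp; else nxp = 2 * W - nxp;
          ++reflections;
        }
        ux[i] = nxp; // actual coordinate is the unwrapped one
      }
      if (pery) {
        while (nyp < 0) { nyp += H; --imy[i]; }
        while (nyp >= H) { nyp -= H; ++imy[i]; }
      } else {
        while (nyp < 0 || nyp > H) {
          if (nyp < 0) nyp = -nyp; else nyp = 2 * H - nyp;
          ++reflections;
        }
        uy[i] = nyp;
      }
      x[i] = nxp;
      y[i] = nyp;
    }

    // 6. record
    if (s % sample_every == 0) {
      const int f = s / sample_every;
      for (int i = 0; i < n; ++i) {
        traj[f + nframes * (0 + 2 * i)] = ux[i];
        traj[f + nframes * (1 + 2 * i)] = uy[i];
      }
    }
  }

  NumericMatrix final_pos(n, 2);
  IntegerMatrix final_img(n, 2);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = x[i]; final_pos(i, 1) = y[i];
    final_img(i, 0) = imx[i]; final_img(i, 1) = imy[i];
  }
  return List::create(
    _["traj"] = traj,
    _["final_positions"] = final_pos,
    _["final_images"] = final_img,
    _["counters"] = IntegerVector::create(
      _["multi_cross"] = (int)std::min<long long>(multi_cross, INT_MAX),
      _["reflections"] = (int)std::min<long long>(reflections, INT_MAX),
      _["rejected"] = (int)std::min<long long>(rejected, INT_MAX)));
}
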