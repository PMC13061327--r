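// Performance kernels for the tumoroid simulator.  All randomness comes
// from R's global RNG (exp_rand / unif_rand), so seeded runs are
// reproducible end-to-end from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int NG = 3;  // genes: 0 = CD133, 1 = SYP, 2 = CyclinE

// closed-form relaxation of (M, P) for one gene over time t
static inline void relax_gene(double &M, double &P, double t,
                              double d0, double d1, double s1) {
  double eM = std::exp(-d0 * t);
  double e1 = std::exp(-d1 * t);
  double conv;
  if (std::fabs(d0 - d1) < 1e-12)
    conv = t * std::exp(-d0 * t);
  else
    conv = (e1 - eM) / (d0 - d1);
  P = P * e1 + s1 * M * conv;
  M = M * eM;
}

// Advance the bursty PDMP for every cell over one step of length dt.
// M, P are n x 3 (cells x genes); theta is 3 x 3 (source x target);
// signal is added to the sigmoid argument of gene 0 (CD133) only.
// Clocks: one exponential draw per gene per iteration, in fixed gene
// order; rates are recomputed after every burst.
// [[Rcpp::export]]
List pdmp_advance_cpp(NumericMatrix M, NumericMatrix P, double dt,
                      NumericVector d0, NumericVector d1, NumericVector s1,
                      NumericVector k0, NumericVector k1, NumericVector beta,
                      NumericVector burst_mean, NumericMatrix theta,
                      NumericVector signal) {
  int n = M.nrow();
  NumericMatrix Mo(clone(M)), Po(clone(P));
  IntegerVector bursts(n);
  for (int c = 0; c < n; ++c) {
    double m[NG], p[NG];
    for (int g = 0; g < NG; ++g) { m[g] = Mo(c, g); p[g] = Po(c, g); }
    double remaining = dt;
    for (;;) {
      double k[NG], tau[NG];
      for (int g = 0; g < NG; ++g) {
        double sigma = beta[g];
        for (int s = 0; s < NG; ++s) sigma += theta(s, g) * p[s];
        if (g == 0) sigma += signal[c];
        k[g] = k0[g] + (k1[g] - k0[g]) / (1.0 + std::exp(-sigma));
      }
      for (int g = 0; g < NG; ++g) {
        double u = exp_rand();
        tau[g] = (k[g] > 0.0) ? u / k[g] : R_PosInf;
      }
      int gmin = 0;
      for (int g = 1; g < NG; ++g) if (tau[g] < tau[gmin]) gmin = g;
      if (!(tau[gmin] <= remaining)) {  // no burst in what is left
        for (int g = 0; g < NG; ++g)
          relax_gene(m[g], p[g], remaining, d0[g], d1[g], s1[g]);
        break;
      }
      for (int g = 0; g < NG; ++g)
        relax_gene(m[g], p[g], tau[gmin], d0[g], d1[g], s1[g]);
      m[gmin] += exp_rand() * burst_mean[gmin];
      bursts[c] += 1;
      remaining -= tau[gmin];
    }
    for (int g = 0; g < NG; ++g) { Mo(c, g) = m[g]; Po(c, g) = p[g]; }
  }
  return List::create(_["M"] = Mo, _["P"] = Po, _["bursts"] = bursts);
}

// ---- uniform-grid neighbor search -----------------------------------------

// flat CSR cell-list grid over the bounding box of a point set
struct Grid {
  double x0, y0, z0, h;
  int nx, ny, nz;
  std::vector<int> start;  // bin -> offset into `items`
  std::vector<int> items;  // point indices ordered by bin
  Grid(const double *px, const double *py, const double *pz, int n,
       double h_) : h(h_) {
    x0 = y0 = z0 = 0.0;
    double x1 = 0.0, y1 = 0.0, z1 = 0.0;
    if (n > 0) {
      x0 = x1 = px[0]; y0 = y1 = py[0]; z0 = z1 = pz[0];
      for (int i = 1; i < n; ++i) {
        x0 = std::min(x0, px[i]); x1 = std::max(x1, px[i]);
        y0 = std::min(y0, py[i]); y1 = std::max(y1, py[i]);
        z0 = std::min(z0, pz[i]); z1 = std::max(z1, pz[i]);
      }
    }
    nx = std::max(1, (int)std::floor((x1 - x0) / h) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / h) + 1);
    nz = std::max(1, (int)std::floor((z1 - z0) / h) + 1);
    size_t nb = (size_t)nx * ny * nz;
    std::vector<int> count(nb + 1, 0);
    std::vector<int> binof(n);
    for (int i = 0; i < n; ++i) {
      binof[i] = (int)bin_of(px[i], py[i], pz[i]);
      ++count[binof[i] + 1];
    }
    for (size_t b = 1; b <= nb; ++b) count[b] += count[b - 1];
    start = count;
    items.assign(n, 0);
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) items[cursor[binof[i]]++] = i;
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  inline size_t bin_of(double x, double y, double z) const {
    int cx = clampi((int)std::floor((x - x0) / h), 0, nx - 1);
    int cy = clampi((int)std::floor((y - y0) / h), 0, ny - 1);
    int cz = clampi((int)std::floor((z - z0) / h), 0, nz - 1);
    return ((size_t)cz * ny + cy) * nx + cx;
  }
};

static void collect_pairs(const double *px, const double *py,
                          const double *pz, const double *r, int n,
                          std::vector<int> &ii, std::vector<int> &jj) {
  ii.clear(); jj.clear();
  if (n < 2) return;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  Grid grid(px, py, pz, n, std::max(2.0 * rmax, 1e-8));
  const int *st = grid.start.data();
  const int *it = grid.items.data();
  // half-space neighbor offsets: self bin plus 13 forward neighbors
  for (int cz = 0; cz < grid.nz; ++cz)
    for (int cy = 0; cy < grid.ny; ++cy)
      for (int cx = 0; cx < grid.nx; ++cx) {
        size_t ab = ((size_t)cz * grid.ny + cy) * grid.nx + cx;
        int a0 = st[ab], a1 = st[ab + 1];
        if (a0 == a1) continue;
        for (int dz = 0; dz <= 1; ++dz) {
          int oz = cz + dz;
          if (oz >= grid.nz) continue;
          for (int dy = (dz ? -1 : 0); dy <= 1; ++dy) {
            int oy = cy + dy;
            if (oy < 0 || oy >= grid.ny) continue;
            for (int dx = ((dz || dy) ? -1 : 0); dx <= 1; ++dx) {
              int ox = cx + dx;
              if (ox < 0 || ox >= grid.nx) continue;
              size_t bb = ((size_t)oz * grid.ny + oy) * grid.nx + ox;
              int b0 = st[bb], b1 = st[bb + 1];
              bool same = (bb == ab);
              for (int u = a0; u < a1; ++u) {
                int i = it[u];
                double xi = px[i], yi = py[i], zi = pz[i], ri = r[i];
                for (int v = same ? u + 1 : b0; v < b1; ++v) {
                  int j = it[v];
                  double ddx = xi - px[j];
                  double ddy = yi - py[j];
                  double ddz = zi - pz[j];
                  double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                  double rr = ri + r[j];
                  if (d2 < rr * rr) {
                    ii.push_back(std::min(i, j));
                    jj.push_back(std::max(i, j));
                  }
                }
              }
            }
          }
        }
      }
}

// column-major accessor bridge for NumericMatrix positions (n x 3)
static void collect_pairs(const NumericMatrix &pos, const NumericVector &r,
                          std::vector<int> &ii, std::vector<int> &jj) {
  int n = pos.nrow();
  ii.clear(); jj.clear();
  if (n < 2) return;
  collect_pairs(&pos[0], &pos[n], &pos[2 * n], &r[0], n, ii, jj);
}

// Contact pairs: centres closer than the sum of external radii.
// Returns a 2-column (i, j) integer matrix, 1-based, i < j, sorted.
// [[Rcpp::export]]
IntegerMatrix find_contacts_cpp(NumericMatrix pos, NumericVector r_ext) {
  std::vector<int> ii, jj;
  collect_pairs(pos, r_ext, ii, jj);
  int m = (int)ii.size();
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ii[a] != ii[b] ? ii[a] < ii[b] : jj[a] < jj[b];
  });
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = ii[ord[k]] + 1;
    out(k, 1) = jj[ord[k]] + 1;
  }
  return out;
}

// Pairwise central repulsion of overlapping visco-elastic spheres with a
// rigid core: soft push on external-radius overlap, a much stiffer one on
// internal (core) overlap.  Jacobi sweeps (displacements accumulated,
// then applied), iterated until the worst core overlap is below tol or
// max_sweeps is reached; positions are reflected into [0, L]^3 after
// every sweep.  Deterministic given positions.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericMatrix pos, NumericVector r_int,
                        NumericVector r_ext, double L,
                        double eta_shell, double eta_core,
                        double tol, int max_sweeps) {
  NumericMatrix p(clone(pos));
  int n = p.nrow();
  std::vector<double> dx(n), dy(n), dz(n);
  std::vector<int> ii, jj;
  bool converged = false;
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    collect_pairs(p, r_ext, ii, jj);
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);
    double worst_core = 0.0;
    for (size_t k = 0; k < ii.size(); ++k) {
      int i = ii[k], j = jj[k];
      double vx = p(i, 0) - p(j, 0);
      double vy = p(i, 1) - p(j, 1);
      double vz = p(i, 2) - p(j, 2);
      double d = std::sqrt(vx * vx + vy * vy + vz * vz);
      double ux, uy, uz;
      if (d > 1e-12) { ux = vx / d; uy = vy / d; uz = vz / d; }
      else { ux = 1.0; uy = 0.0; uz = 0.0; }  // coincident: fixed axis
      double ov_shell = (r_ext[i] + r_ext[j]) - d;
      if (ov_shell <= 0.0) continue;
      double ov_core = (r_int[i] + r_int[j]) - d;
      if (ov_core > worst_core) worst_core = ov_core;
      double move = eta_shell * ov_shell;
      if (ov_core > 0.0) move += eta_core * ov_core;
      move = std::min(move, 0.5 * ov_shell);  // never overshoot separation
      double half = 0.5 * move;
      dx[i] += half * ux; dy[i] += half * uy; dz[i] += half * uz;
      dx[j] -= half * ux; dy[j] -= half * uy; dz[j] -= half * uz;
    }
    if (sweep > 0 && worst_core < tol) { converged = true; break; }
    if (ii.empty()) { converged = true; break; }
    for (int i = 0; i < n; ++i) {
      // cap per-sweep displacement for stability in crowded regions
      double norm = std::sqrt(dx[i] * dx[i] + dy[i] * dy[i] + dz[i] * dz[i]);
      double cap = 0.25;
      double s = (norm > cap) ? cap / norm : 1.0;
      p(i, 0) += s * dx[i];
      p(i, 1) += s * dy[i];
      p(i, 2) += s * dz[i];
      for (int c = 0; c < 3; ++c) {
        double x = p(i, c);
        if (x < 0.0) x = -x;
        if (x > L) x = 2.0 * L - x;
        if (x < 0.0) x = 0.0;  // pathological: fold back once more
        if (x > L) x = L;
        p(i, c) = x;
      }
    }
    if (worst_core < tol) { converged = true; break; }
  }
  return List::create(_["pos"] = p, _["sweeps"] = sweep + 1,
                      _["converged"] = converged);
}

// Direct Gauss transform: out[t] = sum_j q[j] exp(-||x_t - h_j||^2 / delta)
// [[Rcpp::export]]
NumericVector gauss_direct_cpp(NumericMatrix src, NumericVector q,
                               double delta, NumericMatrix tgt) {
  int ns = src.nrow(), nt = tgt.nrow(), d = tgt.ncol();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    double acc = 0.0;
    for (int j = 0; j < ns; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = tgt(t, c) - src(j, c);
        d2 += v * v;
      }
      acc += q[j] * std::exp(-d2 / delta);
    }
    out[t] = acc;
  }
  return out;
}

// Truncated (grid-binned) Gauss transform with a per-target relative
// error guarantee: for each target the nearest source (distance dmin) is
// found by expanding grid shells; all sources within
// sqrt(dmin^2 + delta * log(n_src * qmax / (eps * qmin))) are then summed.
// The neglected tail is bounded by n_src * qmax * exp(-cut^2/delta)
// <= eps * qmin * exp(-dmin^2/delta) <= eps * (retained sum), so the
// relative error is at most eps.
// [[Rcpp::export]]
NumericVector gauss_fast_cpp(NumericMatrix src, NumericVector q,
                             double delta, NumericMatrix tgt, double eps) {
  int ns = src.nrow(), nt = tgt.nrow();
  NumericVector out(nt);
  if (ns == 0) return out;
  double qmax = 0.0, qmin = R_PosInf;
  for (int j = 0; j < ns; ++j) {
    qmax = std::max(qmax, q[j]);
    qmin = std::min(qmin, std::max(q[j], 1e-300));
  }
  double slack = delta * std::log(std::max(1.0, ns * qmax / (eps * qmin)));
  double h = std::sqrt(delta);  // bin size of order the kernel length
  Grid grid(&src[0], &src[ns], &src[2 * ns], ns, h);
  for (int t = 0; t < nt; ++t) {
    double tx = tgt(t, 0), ty = tgt(t, 1), tz = tgt(t, 2);
    int cx = grid.clampi((int)std::floor((tx - grid.x0) / h), 0, grid.nx - 1);
    int cy = grid.clampi((int)std::floor((ty - grid.y0) / h), 0, grid.ny - 1);
    int cz = grid.clampi((int)std::floor((tz - grid.z0) / h), 0, grid.nz - 1);
    // nearest-source distance by expanding shells of bins
    double dmin2 = R_PosInf;
    int maxring = std::max(std::max(grid.nx, grid.ny), grid.nz);
    for (int ring = 0; ring <= maxring; ++ring) {
      double ring_lb = (ring - 1) * h;  // lower bound on distance to ring
      if (dmin2 < ring_lb * ring_lb && ring > 0) break;
      for (int oz = cz - ring; oz <= cz + ring; ++oz) {
        if (oz < 0 || oz >= grid.nz) continue;
        for (int oy = cy - ring; oy <= cy + ring; ++oy) {
          if (oy < 0 || oy >= grid.ny) continue;
          for (int ox = cx - ring; ox <= cx + ring; ++ox) {
            if (ox < 0 || ox >= grid.nx) continue;
            int rr = std::max(std::max(std::abs(ox - cx), std::abs(oy - cy)),
                              std::abs(oz - cz));
            if (rr != ring) continue;  // shell only
            size_t bb = ((size_t)oz * grid.ny + oy) * grid.nx + ox;
            for (int u = grid.start[bb]; u < grid.start[bb + 1]; ++u) {
              int j = grid.items[u];
              double vx = tx - src(j, 0), vy = ty - src(j, 1),
                     vz = tz - src(j, 2);
              double d2 = vx * vx + vy * vy + vz * vz;
              if (d2 < dmin2) dmin2 = d2;
            }
          }
        }
      }
    }
    double cut2 = dmin2 + slack;
    double cut = std::sqrt(cut2);
    int nring = (int)std::floor(cut / h) + 1;
    double acc = 0.0;
    for (int oz = std::max(0, cz - nring);
         oz <= std::min(grid.nz - 1, cz + nring); ++oz)
      for (int oy = std::max(0, cy - nring);
           oy <= std::min(grid.ny - 1, cy + nring); ++oy)
        for (int ox = std::max(0, cx - nring);
             ox <= std::min(grid.nx - 1, cx + nring); ++ox) {
          size_t bb = ((size_t)oz * grid.ny + oy) * grid.nx + ox;
          for (int u = grid.start[bb]; u < grid.start[bb + 1]; ++u) {
            int j = grid.items[u];
            double vx = tx - src(j, 0), vy = ty - src(j, 1),
                   vz = tz - src(j, 2);
            double d2 = vx * vx + vy * vy + vz * vz;
            if (d2 <= cut2) acc += q[j] * std::exp(-d2 / delta);
          }
        }
    out[t] = acc;
  }
  return out;
}

// Pairwise distances of a 2-D point set below a cutoff, as a compressed
// neighbor list (used by the spatial statistics on cell tables).
// Returns 1-based pair indices (i < j) and the distances.
// [[Rcpp::export]]
List neighbor_pairs_2d_cpp(NumericVector x, NumericVector y, double cutoff) {
  int n = x.size();
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i];
    pos(i, 1) = y[i];
    pos(i, 2) = 0.0;
  }
  NumericVector r(n, cutoff / 2.0 + 1e-9);
  // collect_pairs uses strict '<' on r_i + r_j = cutoff + 2e-9, so pairs
  // at exactly the cutoff distance are retained (inclusive boundary)
  std::vector<int> ii, jj;
  collect_pairs(pos, r, ii, jj);
  int m = (int)ii.size();
  IntegerVector oi(m), oj(m);
  NumericVector dd(m);
  for (int k = 0; k < m; ++k) {
    double vx = x[ii[k]] - x[jj[k]], vy = y[ii[k]] - y[jj[k]];
    double d = std::sqrt(vx * vx + vy * vy);
    oi[k] = ii[k] + 1;
    oj[k] = jj[k] + 1;
    dd[k] = d;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["d"] = dd);
}
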